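Package: apexfree
Title: Idealized Left-Ventricular Mechanics of Aortic Stiffening and Apical Release
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale continuum-mechanics model of the human left ventricle
    used to study how a stiff ascending aorta degrades left-ventricular
    function and how releasing the apical pericardial constraint restores it.
    Provides an idealized truncated-ellipsoid ventricle with rule-based fiber
    architecture, the Holzapfel-Ogden passive myocardium law, a
    time-varying-elastance active fiber stress with sarcomere-length
    dependence, pericardial and aortic spring boundary conditions, a
    closed-loop lumped-parameter circulation, and the pressure-volume,
    strain, stress and displacement post-processing needed to compare an
    elastic-aorta baseline against a stiff aorta with and without a freed
    apex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
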