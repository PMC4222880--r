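Package: pelagostat
Title: Geostatistical Analysis of Pelagic Acoustic Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the spatial distribution of small pelagic
    fish from acoustic survey transect data. Implements aggregation
    indicators (presence area, concentration curves and the space
    selectivity index), bidirectional empirical variograms with automatic
    fitting of nested anisotropic spherical models, turning-bands
    simulation of Gaussian random fields and a simulation-envelope test of
    the interannual stability of spatial structure, ordinary kriging with
    an anisotropic moving neighbourhood, classification of recurrent,
    occasional and unfavourable areas, centre-of-gravity and inertia
    indicators, an anisotropic recursive patch-identification algorithm,
    empirical orthogonal function decomposition of annual maps, and
    interspecific collocation indices at global, intermediate and local
    scales with randomization tests. A synthetic acoustic-survey generator
    emulating a systematic parallel-transect design is included so the
    whole pipeline can be exercised and tested without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
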