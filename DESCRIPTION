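Package: fedvein
Title: Personalized Federated Learning with Prototype Sharing for
    Finger-Vein Verification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale simulator for personalized federated learning on
    finger-vein biometrics. Clients train margin-loss embedding models whose
    classifier weight matrices are expanded with class prototypes shared by
    the other clients; a central server aggregates encoder parameters and
    prototypes each communication round. Includes Sobel-gradient image
    enhancement with per-class edge-intensity quality scores that drive a
    quality-adaptive additive margin, a seeded generator of heterogeneous
    multi-client synthetic vein images, open-set verification metrics
    (EER, TAR at fixed FAR), and communication-cost accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
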