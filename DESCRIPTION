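Package: bondbundles
Title: Gradient Bundle Analysis of Electron Charge Densities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Partitions molecular and periodic electron densities into bond
    wedges and bond bundles by condensing three-dimensional scalar fields
    (charge density, kinetic-energy density, volume) onto triangulated
    reference spheres around each nucleus, one differential gradient bundle
    per surface element.  Provides the supporting density-topology toolkit
    (critical point location and classification, gradient path tracing,
    Bader basin assignment), watershed segmentation of condensed fields,
    solid angles, bond-bundle electron counts, virial-theorem regional
    energies, core/valence splits and bond energies relative to isolated
    atoms.  Densities are read from Gaussian cube files or built
    analytically as promolecular superpositions of Slater-type atomic
    shells.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
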