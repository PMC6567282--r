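Package: cdlattice
Title: Stability and Shape of DNA-Linked Nanoparticle Cubic-Diamond Superlattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained modelling and analysis of nanoparticle superlattices
    with cubic-diamond symmetry assembled from DNA-origami tetrahedral cages and
    DNA-functionalized nanoparticles. Builds bead-spring topologies (cages,
    dodecahedral nanoparticles, grafted DNA strands, bulk lattices and crystal
    slabs), runs reduced-scale molecular dynamics with FENE/expanded-WCA
    potentials, and generates harmonic-surrogate trajectories with known spring
    constants. Analysis tools compute broken-bond and slab surface energies with
    Wulff-construction crystallite shapes, center-of-body structure factors with
    Miller-indexed Bragg peaks, fluctuation dynamical matrices with phonon
    dispersions and harmonic free energies, and the translational/rotational
    entropy decomposition of lattice stability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
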