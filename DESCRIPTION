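Package: decbct
Title: Dual-Energy Cone-Beam CT Simulation, Virtual Monoenergetic Imaging,
    and Air-Kerma Dose Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sequential dual-energy (80/140 kVp) cone-beam CT
    acquisitions of a digital Catphan-style sensitometry phantom, decomposes the
    paired polyenergetic log-sinograms into aluminum/PMMA equivalent-thickness
    projections, reconstructs basis-material images by filtered backprojection,
    and synthesizes virtual monoenergetic images (VMIs) at any energy between
    40 and 150 keV by voxel-wise linear combination of the two basis images --
    an exact shortcut that needs only two reconstructions for an arbitrary
    number of energies.  Includes contrast-to-noise ratio, HU accuracy and HU
    uniformity metrics with a CNR-optimal energy search, and an air-kerma
    (K_air) surrogate dosimetry framework: linear regressions of K_air against
    cumulative mAs and of cone-beam dose indices (CBDI/CBDIw) against K_air,
    protocol dose estimation, and combined dual-energy dose reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
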