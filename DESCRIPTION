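Package: neurosculpt
Title: Skeleton-Driven Progressive Surface Meshing of Neuronal Morphologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates closed, watertight, quasi-uniform triangular membrane
    meshes from point-and-diameter neuronal morphologies (SWC files). An
    initial spherical mesh placed at the soma is progressively deformed along
    the neuronal tree under a finite-support quartic convolution-surface
    field, with Newton projection onto the iso-surface, incremental
    split/collapse/flip remeshing with area-weighted tangential relaxation,
    and adaptive vertex density at branches and thin neurites. Includes an
    SWC reader/writer, synthetic-morphology generators, a halfedge mesh
    kernel with local operators and topology audits, OBJ/PLY/STL export,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
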