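Package: NeuroPepNet
Title: Reconstruction and Topology of Neuropeptidergic Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds draft "wireless" neuropeptide signaling connectomes for the
    302-neuron C. elegans nervous system by integrating binary gene expression
    calls, peptide-receptor biochemistry (EC50-thresholded ligand-receptor
    couples) and process-bundle anatomy. Provides the four spatial diffusion
    models (long, mid, short, contact), per-couple network construction and
    weighted aggregation, directed topology metrics (density, transitivity,
    reciprocity, degree), rich-club analysis against degree-preserving null
    ensembles, per-couple topology classification (local, pervasive,
    broadcaster, integrative), mesoscale clustering of incoming-connectivity
    profiles, NPP-GPCR co-expression enrichment with FDR control, autocrine
    loop detection, and a synthetic-data generator with planted motifs so the
    whole pipeline is testable without the deposited datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
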