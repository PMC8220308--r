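Package: lecatrace
Title: Protein Family Clustering and the Prokaryotic Contributions to the
    Eukaryotic Root
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds protein families from amino-acid proteomes by all-versus-all
    pairwise alignment, reciprocal best hits and Markov clustering, merges
    eukaryotic with prokaryotic families through the reciprocal best cluster
    rule into eukaryote-prokaryote clusters (EA/EB/EAB), filters families
    traceable to the last eukaryotic common ancestor by six-supergroup
    coverage, and quantifies lineage-unique (e.g. asgard archaeal)
    contributions. Also provides per-proteome hit-category profiling with
    genus exclusion, protein length-distribution statistics
    (Kolmogorov-Smirnov with FDR correction), presence-absence matrices with
    deterministic orderings, and a synthetic proteome generator with planted
    family structure for end-to-end validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'io.R'
    'synth.R'
    'align.R'
    'mcl.R'
    'epc.R'
    'profiles.R'
    'pap.R'
    'pipeline.R'
    'lecatrace-package.R'
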