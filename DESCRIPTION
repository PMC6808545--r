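Package: contamscreen
Title: Cross-Contamination Screening for De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects cross-contamination between de novo assembled
    transcriptome libraries from all-vs-all sequence similarity searches.
    Builds per-pair percent-identity distributions of best-matched
    sequences, places the contamination cutoff at the first minimum below
    the near-100% identity peak, excludes taxonomically close library
    pairs using family labels and a consensus phylogeny, discriminates
    donor from recipient libraries with a top-hit re-search rule, splits
    libraries into clean and contaminant sequence sets, validates sample
    identity from 18S rRNA reference hits, summarises transcriptome
    completeness, and ships a synthetic contaminated-library simulator
    with ground-truth labels so the whole pipeline can be exercised at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
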