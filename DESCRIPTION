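Package: readlm
Title: Language-Model Pretraining on Aligned Short Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for pretraining nucleotide language models
    directly on aligned short sequencing reads rather than on assembled
    genomes. Provides a seeded exome-style read simulator (reference and
    donor genomes, multi-subject cohorts, a diverged second genome),
    plain-text FASTA/SAM/VCF input and output, a compact nucleotide
    tokenizer, quality-aware k-fold read filtration that preserves variant
    evidence, four read-packing strategies that assemble 151-bp reads into
    fixed-length contexts, inverse-allele-frequency dynamic loss weighting,
    a miniature decoder transformer written in base R supporting causal and
    masked objectives, four positional-encoding schemes and sliding-window
    attention, two-phase weighted pretraining with corpus mixing, next-token
    accuracy evaluation and an ablation-grid runner, plus downstream
    variant-classification benchmark construction, fine-tuning with the
    Matthews correlation coefficient, and per-layer probing with
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
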