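Package: codonAdapt
Title: Codon Usage Bias and Adaptation to the tRNA Pool
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes synonymous codon usage and translational-adaptation
    indices from coding sequences and a tRNA gene-copy table: relative
    synonymous codon usage (RSCU), the codon adaptation index (CAI), Wright's
    effective number of codons (Nc), codon-pair scores and the per-gene
    codon-pair bias (CPS/CPB), and the tRNA adaptation index under wobble
    pairing rules (tAI) together with its amino-acid-normalized variant
    (AAtAI). Integrates the per-gene indices with two-condition expression
    data to test whether transcriptionally induced genes are better adapted
    to the cellular tRNA pool, via rank-based group comparisons and
    stratified Spearman correlations. Includes parsers for tRNAscan-SE
    tabular output and EMBOSS-cusp-compatible codon usage tables, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: Genetics, Software, SequenceAnalysis, GeneExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
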