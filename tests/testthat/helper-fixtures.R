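# Programmatic fixtures shared across test files.

# write a FASTA and return its path
fixtureFasta <- function(records) {
    path <- tempfile(fileext = ".fasta")
    writeLines(as.vector(rbind(paste0(">", names(records)),
                               unname(records))), path)
    path
}

# corpus in which every ordered sense-codon pair occurs exactly once as a
# two-codon gene: every pair frequency equals its independence expectation,
# so CPS = 0 for all pairs and every codon/family is observed
balancedPairCorpus <- function(code = standardGeneticCode()) {
    sense <- senseCodons(code)
    genes <- as.vector(outer(sense, sense, paste0))
    names(genes) <- sprintf("bp%04d", seq_along(genes))
    genes
}

# Phe-only two-codon genes engineered so that the pair TTT|TTC occurs at
# exactly twice its independence expectation: CPS(TTT,TTC) = ln 2
ln2Corpus <- function() {
    genes <- c(rep("TTTTTT", 2), rep("TTTTTC", 6),
               rep("TTCTTT", 2), rep("TTCTTC", 2))
    names(genes) <- sprintf("ln2_%02d", seq_along(genes))
    genes
}

# minimal TRNAGeneSet built directly from anticodon copies
trnaPoolFixture <- function(anticodons, scaffolds = NULL, introns = FALSE,
                            aa = NULL) {
    n <- length(anticodons)
    if (is.null(scaffolds)) scaffolds <- rep("scaffold_1", n)
    if (is.null(aa)) {
        map <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                 Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                 L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                 S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
        aa <- unname(map[translateCodon(anticodonToCodon(anticodons))])
    }
    g <- data.frame(scaffold = scaffolds, geneIndex = seq_len(n),
                    begin = 1000 * seq_len(n), end = 1000 * seq_len(n) + 71,
                    aa = aa, anticodon = anticodons,
                    intronBegin = ifelse(rep(introns, length.out = n),
                                         1000 * seq_len(n) + 37, 0),
                    intronEnd = ifelse(rep(introns, length.out = n),
                                       1000 * seq_len(n) + 46, 0),
                    score = 60, hasIntron = rep(introns, length.out = n),
                    discordant = FALSE, stringsAsFactors = FALSE)
    new("TRNAGeneSet", genes = g)
}

# random valid CDS (uniform codon usage), independent of the simulator
randomGenes <- function(n, len, seed, code = standardGeneticCode()) {
    set.seed(seed)
    sense <- senseCodons(code)
    genes <- vapply(seq_len(n), function(i)
        paste(sample(sense, len, replace = TRUE), collapse = ""),
        character(1))
    names(genes) <- sprintf("rg%03d", seq_len(n))
    genes
}

# a rule-set with Watson-Crick rows only (no wobble), for formula checks
wcOnlyRules <- function(code = standardGeneticCode()) {
    full <- wobbleRules(code)
    r <- wobbleRuleTable(full)
    new("WobbleRuleSet", rules = r[r$pairing == "WC", ],
        organism = "eukaryote", sValues = full@sValues)
}

# gene lengths in codons from a CDSSet
.geneLengthsTest <- function(cds)
    Biostrings::width(cdsSequences(cds)) %/% 3L

# the 61 x 61 ordered sense-pair hexamer names, package order
.sensePairNamesTest <- function() {
    sense <- senseCodons()
    as.vector(t(outer(sense, sense, paste0)))
}

# tRNAscan-SE tabular fixture writer
writeTrnascanFixture <- function(rows, path = tempfile(fileext = ".tsv")) {
    hdr <- c("Sequence\t\ttRNA\tBounds\tBounds\ttRNA\tAnti\tIntron\tIntron\tInf",
             "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
             "--------\t------\t-----\t----\t----\t-----\t-----\t---\t------")
    writeLines(c(hdr, rows), path)
    path
}
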