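test_that("codon translation and anticodon decoding follow the standard code", {
    expect_identical(translateCodon(c("ATG", "TAA", "TGG")), c("M", "*", "W"))
    expect_error(translateCodon("AXG"), "invalid codon")
    expect_error(translateCodon("AT"), "invalid codon")

    expect_identical(anticodonToCodon(c("GCC", "AAA", "CAT")),
                     c("GGC", "TTT", "ATG"))
    expect_identical(translateCodon(anticodonToCodon("GCC")), "G")
    expect_error(anticodonToCodon("GXC"), "invalid anticodon")
    # decoding is an involution together with codonToAnticodon
    sense <- senseCodons()
    expect_identical(anticodonToCodon(codonToAnticodon(sense)), sense)
})

test_that("the standard code has the expected family structure", {
    code <- standardGeneticCode()
    expect_length(senseCodons(code), 61L)
    expect_length(stopCodons(code), 3L)
    expect_setequal(lengths(codonFamilies(code)),
                    c(1L, 2L, 3L, 4L, 6L))
    expect_identical(sort(unlist(codonFamilies(code), use.names = FALSE)),
                     sort(senseCodons(code)))
})

test_that("loadCDS validates records and strips terminal stops", {
    fa <- fixtureFasta(c(ok = "ATGGCCTAA",        # terminal stop stripped
                         len10 = "ATGGCCTAAG",    # not a multiple of 3
                         internal = "ATGTAAGCC",  # internal stop
                         ambig = "ATGNNNTAA",     # non-ACGT
                         nostop = "ATGGAA"))      # fine without stop
    cds <- loadCDS(fa)
    expect_setequal(names(cds), c("ok", "nostop"))
    expect_identical(as.character(cdsSequences(cds)[["ok"]]), "ATGGCC")
    rej <- rejectedRecords(cds)
    expect_identical(rej$reason[rej$id == "len10"], "length not multiple of 3")
    expect_identical(rej$reason[rej$id == "internal"], "internal stop")
    expect_identical(rej$reason[rej$id == "ambig"], "invalid alphabet")

    # lone stop codon records are rejected, not kept as empty genes
    cds2 <- loadCDS(fixtureFasta(c(stopOnly = "TAA", keep = "ATGGCC")))
    expect_identical(rejectedRecords(cds2)$reason, "empty after stop removal")

    expect_error(loadCDS(fixtureFasta(c(a = "ATG", a = "GCC"))), "duplicate")
    emptyFa <- tempfile(fileext = ".fasta"); file.create(emptyFa)
    expect_error(loadCDS(emptyFa))
})

test_that("loadCDS is idempotent on its own accepted output", {
    genes <- randomGenes(10, 40, seed = 11)
    cds1 <- loadCDS(fixtureFasta(genes))
    refa <- tempfile(fileext = ".fasta")
    Biostrings::writeXStringSet(cdsSequences(cds1), refa)
    cds2 <- loadCDS(refa)
    expect_identical(as.character(cdsSequences(cds2)),
                     as.character(cdsSequences(cds1)))
    expect_identical(nrow(rejectedRecords(cds2)), 0L)
})

test_that("codon counting and per-thousand frequencies", {
    counts <- countCodons(c(g = "ATGGCC"))
    expect_equal(unname(freqPerThousand(counts)[c("ATG", "GCC")]),
                 c(500, 500))
    expect_equal(sum(freqPerThousand(counts)), 1000)

    two <- countCodons(c(a = "ATG", b = "ATG"))
    expect_equal(unname(codonCounts(two)["ATG"]), 2)
    expect_equal(unname(freqPerThousand(two)["ATG"]), 1000)

    expect_error(countCodons(Biostrings::DNAStringSet()), "no coding")
})

test_that("codon-pair counting: adjacency, totals, no cross-gene pairs", {
    ps <- countCodonPairs(c(g = "ATGGCCGAA"))
    expect_equal(unname(codonPairCounts(ps)[c("ATGGCC", "GCCGAA")]), c(1, 1))
    expect_equal(sum(codonPairCounts(ps)), 2)

    ps2 <- countCodonPairs(c(a = "ATGGCC", b = "GAATTT"))
    expect_equal(unname(codonPairCounts(ps2)["GCCGAA"]), 0)
    expect_equal(sum(codonPairCounts(ps2)), 2)  # sum_g (l_g - 1)

    genes <- randomGenes(8, 30, seed = 3)
    ps3 <- countCodonPairs(genes)
    expect_equal(sum(codonPairCounts(ps3)), 8 * 29)

    expect_error(countCodonPairs(c(one = "ATG")), "two or more codons")
})

test_that("pair marginals are conserved: sum_B n(A,B) + genes ending in A = n(A)", {
    genes <- randomGenes(12, 25, seed = 7)
    counts <- codonCounts(countCodons(genes))
    pc <- codonPairCounts(countCodonPairs(genes))
    lastCodon <- substring(genes, nchar(genes) - 2, nchar(genes))
    for (A in unique(substring(genes, 1, 3))) {
        marg <- sum(pc[substring(names(pc), 1, 3) == A])
        expect_equal(marg + sum(lastCodon == A), unname(counts[A]))
    }
})

test_that("RSCU matches its definition and sums to family size", {
    # equal usage in every family -> RSCU = 1 everywhere
    bal <- computeRSCU(countCodons(balancedPairCorpus()))
    expect_true(all(abs(bal$rscu - 1) < 1e-12))

    # Phe 3:1 split
    genes <- c(a = "TTTTTTTTTTTC")
    r <- computeRSCU(countCodons(genes))
    expect_equal(r$rscu[r$codon == "TTT"], 1.5)
    expect_equal(r$rscu[r$codon == "TTC"], 0.5)
    # 4-fold family used as a single codon
    r2 <- computeRSCU(countCodons(c(a = "GCTGCTGCT")))
    expect_equal(r2$rscu[r2$codon == "GCT"], 4)
    expect_equal(r2$rscu[r2$codon %in% c("GCC", "GCA", "GCG")], rep(0, 3))
    # unobserved families are NA and flagged, not zero
    expect_true("F" %in% attr(r2, "unobservedFamilies"))
    expect_true(all(is.na(r2$rscu[r2$aa == "F"])))

    # family sums equal family size for observed families
    genes3 <- randomGenes(5, 200, seed = 5)
    r3 <- computeRSCU(countCodons(genes3))
    sums <- tapply(r3$rscu, r3$aa, sum)
    sizes <- lengths(codonFamilies())[names(sums)]
    expect_equal(as.numeric(sums), as.numeric(sizes), tolerance = 1e-12)
})

test_that("cusp output is EMBOSS-shaped and consistent", {
    genes <- randomGenes(4, 50, seed = 9)
    counts <- countCodons(genes)
    path <- tempfile(fileext = ".cusp")
    writeCusp(counts, path)
    df <- read.table(path, comment.char = "#",
                     col.names = c("codon", "aa", "fraction", "freq", "n"))
    expect_equal(nrow(df), 61L)
    expect_equal(sum(df$n), 4 * 50)
    expect_equal(sum(df$freq), 1000, tolerance = 0.1)
})
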