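test_that("CAI weights are family-relative with a floor for unused codons", {
    # balanced corpus: every codon equally used -> all weights 1
    wAll <- caiWeights(countCodons(balancedPairCorpus()))
    expect_true(all(wAll == 1))

    # Phe at 1:3 -> weight(TTT) = 1/3, weight(TTC) = 1 on top of a balanced
    # background
    genes <- c(balancedPairCorpus(), extra = strrep("TTC", 122))
    w <- caiWeights(countCodons(genes))
    expect_equal(unname(w["TTC"]), 1)
    expect_equal(unname(w["TTT"]), 122 / 244)

    # unused codons get the floor weight, not zero
    few <- countCodons(c(a = "GCTATG"))
    expect_error(caiWeights(few), "entirely absent")
    wFloor <- caiWeights(countCodons(c(a = paste(
        vapply(codonFamilies(), `[`, "", 1), collapse = ""))))
    expect_true(all(wFloor[wFloor < 1] == 0.01))
})

test_that("CAI is the geometric mean of weights, order-invariant, 1 at optimum", {
    w <- setNames(rep(1, 61), senseCodons())
    w["GCT"] <- 1 / 3
    expect_equal(computeCAI(c(g = "GCTGCC"), w), sqrt(1 / 3))
    expect_equal(computeCAI(c(g = "GCCGCT"), w), sqrt(1 / 3))
    expect_equal(computeCAI(c(g = "GCCGCC"), w), 1)

    # Sharp-Li convention drops the single-codon families
    w2 <- w; w2["ATG"] <- 1  # Met weight is 1 either way
    expect_equal(computeCAI(c(g = "ATGGCT"), w, TRUE), sqrt(1 / 3))
    expect_equal(computeCAI(c(g = "ATGGCT"), w,
                            includeSingleCodonFamilies = FALSE), 1 / 3)

    expect_error(computeCAI(c(g = "GCT"), w[-1]), "cover all sense codons")
})

test_that("Nc hits Wright's bounds and matches the brute-force oracle", {
    # one codon per family, used many times -> F = 1 everywhere -> Nc = 20
    one <- paste(rep(vapply(codonFamilies(), `[`, "", 1), 10), collapse = "")
    expect_equal(unname(computeNc(c(g = one))), 20)

    # uniform synonymous usage at large length -> Nc near 61 (capped)
    set.seed(2)
    unif <- paste(sample(senseCodons(), 5000, replace = TRUE), collapse = "")
    expect_gte(unname(computeNc(c(g = unif))), 60)
    expect_lte(unname(computeNc(c(g = unif))), 61)

    # oracle equivalence on biased genes of moderate length
    genes <- randomGenes(20, 300, seed = 31)
    nc <- computeNc(genes)
    for (g in names(genes))
        expect_equal(unname(nc[g]), orcNc(orcSplitCodons(genes[[g]])),
                     tolerance = 1e-12)

    # a gene too short for any family is flagged NA
    expect_true(is.na(computeNc(c(g = "ATGTGG"))))
})

test_that("CPS: zero on a balanced corpus, ln 2 on the engineered doubling", {
    bal <- balancedPairCorpus()
    cps <- buildCPSTable(countCodonPairs(bal), countCodons(bal))
    expect_true(all(abs(cpsValues(cps)) < 1e-12))
    # usage-weighted corpus mean of CPS is 0 here by construction
    pc <- codonPairCounts(countCodonPairs(bal))
    expect_lt(abs(sum(pc * cpsValues(cps)) / sum(pc)), 1e-6)

    genes <- ln2Corpus()
    cps2 <- buildCPSTable(countCodonPairs(genes), countCodons(genes))
    expect_equal(unname(cpsValues(cps2)["TTTTTC"]), log(2))
    # verified against the independent frequency-arithmetic oracle
    orc <- orcCPS(unname(genes))
    expect_equal(unname(cpsValues(cps2)["TTTTTC"]), unname(orc["TTTTTC"]),
                 tolerance = 1e-12)

    # unobserved pairs are NA-flagged, never -Inf
    expect_true(all(is.na(cpsValues(cps2)[!cps2@observed])))
    expect_false(any(is.infinite(cpsValues(cps2)), na.rm = TRUE))
    # pseudocount mode scores them finitely instead
    cps3 <- buildCPSTable(countCodonPairs(genes), countCodons(genes),
                          pseudocount = TRUE)
    expect_true(is.finite(cpsValues(cps3)["TTCTTC"]))
})

test_that("CPS matches the oracle pairwise on a random corpus", {
    genes <- randomGenes(30, 60, seed = 17)
    cps <- buildCPSTable(countCodonPairs(genes), countCodons(genes))
    orc <- orcCPS(unname(genes))
    got <- cpsValues(cps)[names(orc)]
    expect_equal(unname(got), unname(orc), tolerance = 1e-10)
})

test_that("CPB is the mean pair score with strict missing-pair handling", {
    # constructed table: pairs scored 0.2 and 0.4 -> CPB = 0.3
    pn <- .sensePairNamesTest()
    cpsv <- setNames(rep(0, length(pn)), pn)
    cpsv["ATGGCT"] <- 0.2; cpsv["GCTGAA"] <- 0.4
    tab <- new("CPSTable", cps = cpsv, observed = rep(TRUE, length(pn)),
               pseudocount = FALSE, provenance = list())
    expect_equal(unname(computeCPB(c(g = "ATGGCTGAA"), tab)), 0.3)

    # all-zero scores -> CPB 0
    zero <- new("CPSTable", cps = setNames(rep(0, length(pn)), pn),
                observed = rep(TRUE, length(pn)), pseudocount = FALSE,
                provenance = list())
    expect_equal(unname(computeCPB(c(g = "ATGGCTGAA"), zero)), 0)

    # strict mode errors naming a pair missing from the table
    hole <- cpsv; hole["ATGGCT"] <- NA
    tabH <- new("CPSTable", cps = hole, observed = pn != "ATGGCT",
                pseudocount = FALSE, provenance = list())
    expect_error(computeCPB(c(g = "ATGGCTGAA"), tabH), "ATG\\|GCT")

    # single-codon genes are NA with a warning
    expect_warning(v <- computeCPB(c(g1 = "ATG", g2 = "ATGGCTGAA"), tab),
                   "shorter than 2")
    expect_true(is.na(v["g1"]))
    expect_equal(unname(v["g2"]), 0.3)
})

test_that("self-concatenation shifts CPB only through the junction pair", {
    genes <- randomGenes(40, 50, seed = 23)
    cps <- buildCPSTable(countCodonPairs(genes), countCodons(genes),
                         pseudocount = TRUE)
    g <- unname(genes[1])
    doubled <- paste0(g, g)
    cpb1 <- unname(computeCPB(setNames(g, "a"), cps, strict = FALSE))
    cpb2 <- unname(computeCPB(setNames(doubled, "a"), cps, strict = FALSE))
    l <- nchar(g) / 3
    junction <- paste0(substring(g, nchar(g) - 2), substring(g, 1, 3))
    expected <- (2 * (l - 1) * cpb1 + cpsValues(cps)[junction]) / (2 * l - 1)
    expect_equal(cpb2, unname(expected), tolerance = 1e-12)
})

test_that("tAI and AAtAI: geometric means with AAtAI >= tAI", {
    phe <- trnaPoolFixture(rep("GAA", 5))
    ad <- computeWi(phe, wobbleRules())
    expect_equal(unname(computeTAI(c(g = "TTTTTC"), ad)), sqrt(0.59))
    expect_equal(unname(computeAAtAI(c(g = "TTTTTC"), ad)), sqrt(0.59))
    expect_equal(unname(computeTAI(c(g = "TTCTTT"), ad)),
                 unname(computeTAI(c(g = "TTTTTC"), ad)))  # order invariance
    expect_equal(unname(computeTAI(c(g = "TTCTTC"), ad)), 1)

    pool <- simulateTrnaPool(simulationConfig(seed = 12))
    ad2 <- computeWi(pool, wobbleRules())
    # gene made of the best-served codon of every family -> AAtAI = 1
    best <- vapply(codonFamilies(), function(fam)
        names(which.max(absoluteW(ad2)[fam])), character(1))
    expect_equal(unname(computeAAtAI(c(g = paste(best, collapse = "")), ad2)),
                 1)
    genes <- randomGenes(100, 120, seed = 19)
    expect_true(all(computeAAtAI(genes, ad2) >= computeTAI(genes, ad2) - 1e-12))
})

test_that("Z-scores standardize with the population SD", {
    df <- data.frame(gene_id = c("a", "b", "c"), x = c(1, 2, 3))
    z <- zscoreIndices(df, "x")$z_x
    expect_equal(z, orcZ(c(1, 2, 3)))          # +/- sqrt(3/2), 0
    expect_equal(z[2], 0)                      # the mean gene
    # affine transforms leave Z unchanged
    df$y <- 5 - 2 * df$x
    z2 <- zscoreIndices(df, "y")$z_y
    expect_equal(abs(z2), abs(z))
    expect_error(zscoreIndices(data.frame(x = c(1, 1, 1)), "x"),
                 "zero standard deviation")
    expect_error(zscoreIndices(data.frame(x = 1), "x"), "fewer than 2")
})

test_that("every index agrees with its brute-force oracle to 1e-10", {
    # 240 codons: long enough that every degeneracy class is observed and
    # Nc is defined for every gene
    genes <- randomGenes(100, 240, seed = 101)
    cds <- loadCDS(fixtureFasta(genes))
    pool <- simulateTrnaPool(simulationConfig(seed = 101))
    ad <- computeWi(pool, wobbleRules())
    counts <- countCodons(cds)
    w <- caiWeights(counts)
    cps <- buildCPSTable(countCodonPairs(cds), counts, pseudocount = TRUE)

    df <- computeGeneIndices(cds, adapt = ad, caiReference = w, cps = cps)
    cpsv <- cpsValues(cps)
    for (i in seq_along(genes)) {
        cd <- orcSplitCodons(genes[[i]])
        expect_equal(df$cai[i], orcGeomIndex(cd, w), tolerance = 1e-10)
        expect_equal(df$tai[i], orcGeomIndex(cd, wValues(ad)),
                     tolerance = 1e-10)
        expect_equal(df$aatai[i], orcGeomIndex(cd, aaWValues(ad)),
                     tolerance = 1e-10)
        expect_equal(df$nc[i], orcNc(cd), tolerance = 1e-10)
        expect_equal(df$cpb[i], orcCPB(cd, cpsv), tolerance = 1e-10)
    }
    # Z columns recompute from the index columns
    expect_equal(df$z_cai, orcZ(df$cai), tolerance = 1e-12)
    expect_equal(df$z_nc, orcZ(df$nc), tolerance = 1e-12)
})
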