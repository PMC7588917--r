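test_that("parseTRNAscan reads rows, flags introns, drops undetermined", {
    path <- writeTrnascanFixture(c(
        "scaffold_1\t1\t100\t172\tGly\tGCC\t0\t0\t65.3",
        "scaffold_2\t1\t500\t572\tGly\tGCC\t538\t547\t60.1",
        "scaffold_3\t1\t900\t972\tCys\tGCA\t0\t0\t55.0"))
    pool <- parseTRNAscan(path)
    expect_equal(length(pool), 3L)
    expect_equal(tGCN(pool), c(GCA = 1, GCC = 2))
    expect_identical(trnaGenes(pool)$hasIntron, c(FALSE, TRUE, FALSE))

    # undetermined anticodons and pseudogenes are dropped with a warning
    path2 <- writeTrnascanFixture(c(
        "s1\t1\t1\t72\tGly\tGCC\t0\t0\t60.0",
        "s1\t2\t200\t272\tUndet\tNNN\t0\t0\t30.0",
        "s1\t3\t400\t472\tPseudo\tGCA\t0\t0\t25.0"))
    expect_warning(pool2 <- parseTRNAscan(path2), "dropped 2")
    expect_equal(length(pool2), 1L)

    # malformed rows error with the line number
    path3 <- writeTrnascanFixture(c("s1\t1\t1\t72\tGly\tGCC\t0\t0\t60.0",
                                    "s1\t2\t300\tGly"))
    expect_error(parseTRNAscan(path3), "line 5")

    # empty body -> empty set with a warning
    path4 <- writeTrnascanFixture(character(0))
    expect_warning(pool4 <- parseTRNAscan(path4), "no tRNA gene rows")
    expect_equal(length(pool4), 0L)
})

test_that("isotype/anticodon discordance is flagged but the anticodon wins", {
    path <- writeTrnascanFixture(c(
        "s1\t1\t1\t72\tSer\tCAT\t0\t0\t50.0",   # CAT decodes ATG = Met
        "s1\t2\t200\t272\tMet\tCAT\t0\t0\t60.0"))
    expect_warning(pool <- parseTRNAscan(path), "discordant")
    g <- trnaGenes(pool)
    expect_identical(g$discordant, c(TRUE, FALSE))
    expect_equal(unname(tGCN(pool)["CAT"]), 2)  # both copies counted
})

test_that("round trip write -> parse is lossless on retained rows", {
    pool <- simulateTrnaPool(simulationConfig(seed = 42))
    path <- tempfile(fileext = ".tsv")
    writeTRNAscan(pool, path)
    back <- parseTRNAscan(path)
    cols <- c("scaffold", "geneIndex", "aa", "anticodon", "hasIntron")
    expect_equal(trnaGenes(back)[, cols], trnaGenes(pool)[, cols])
    expect_equal(trnaGenes(back)$score, trnaGenes(pool)$score)
})

test_that("per-amino-acid summary reproduces the published table shape", {
    # 17 Gly genes split CCC:2 GCC:12 TCC:3 over 8 scaffolds; 3 Cys on 3
    glyAnti <- c(rep("CCC", 2), rep("GCC", 12), rep("TCC", 3))
    glyScaf <- paste0("scaffold_", c(1, 2, rep(c(1, 2, 5, 7, 9, 10, 13, 20),
                                               length.out = 12), 5, 7, 9))
    pool <- trnaPoolFixture(c(glyAnti, rep("GCA", 3)),
                            scaffolds = c(glyScaf, paste0("scaffold_",
                                                          c(10, 13, 20))))
    smry <- summarizeTRNASet(pool)
    gly <- smry[smry$aa == "Gly", ]
    expect_equal(gly$n, 17L)
    expect_identical(gly$anticodons, "CCC^2, GCC^12, TCC^3")
    cys <- smry[smry$aa == "Cys", ]
    expect_equal(cys$n, 3L)
    expect_equal(cys$nScaffolds, 3L)
    expect_equal(sum(smry$n), length(pool))
})

test_that("wobble rule set: WC rows, coverage, and the special cases", {
    rules <- wobbleRules()
    tab <- wobbleRuleTable(rules)
    expect_true(all(tab$S[tab$pairing == "WC"] == 0))
    expect_setequal(unique(tab$codon), senseCodons())
    # every codon matched by at least one rule
    expect_true(all(table(tab$codon) >= 1))

    pool <- trnaPoolFixture("GAA")
    rec <- codonRecognizers("TTC", rules, pool)
    expect_identical(rec$anticodon, c("GAA", "AAA"))
    expect_equal(rec$S, c(0, 0.28))
    expect_equal(rec$tGCN, c(1, 0))  # zero-copy isoacceptors retained

    # Trp has no wobble partner (its U:G donor would decode a stop)
    recW <- codonRecognizers("TGG", rules, pool)
    expect_identical(recW$anticodon, "CCA")
    # elongator Met is read by its own anticodon only
    recM <- codonRecognizers("ATG", rules, pool)
    expect_identical(recM$anticodon, "CAT")

    expect_error(codonRecognizers("TAA", rules, pool), "stop codon")

    # prokaryote mode: lysidine reading of ATA
    prok <- wobbleRules(organism = "prokaryote")
    recI <- codonRecognizers("ATA", prok, pool)
    expect_identical(recI$anticodon, "CAT")
    expect_equal(recI$S, 0.89)
})

test_that("computeWi implements W = sum (1 - S) tGCN with normalizations", {
    # uniform pool under WC-only rules: every W = 5, every w = 1
    sense <- senseCodons()
    pool <- trnaPoolFixture(rep(codonToAnticodon(sense), each = 5))
    ad <- computeWi(pool, wcOnlyRules())
    expect_true(all(absoluteW(ad) == 5))
    expect_true(all(wValues(ad) == 1))

    # Phe-only pool: GAA x5 -> W(TTC) = 5, W(TTT) = (1 - 0.41) * 5
    phe <- trnaPoolFixture(rep("GAA", 5))
    adPhe <- computeWi(phe, wobbleRules())
    expect_equal(unname(absoluteW(adPhe)[c("TTT", "TTC")]), c(2.95, 5))
    expect_equal(unname(wValues(adPhe)[c("TTT", "TTC")]), c(0.59, 1))
    expect_equal(unname(aaWValues(adPhe)[c("TTT", "TTC")]), c(0.59, 1))
    # all other codons were zero-W substituted and flagged
    expect_setequal(substitutedCodons(adPhe), setdiff(sense, c("TTT", "TTC")))
    expect_equal(unname(wValues(adPhe)["GGG"]), exp(mean(log(c(0.59, 1)))))

    expect_error(computeWi(trnaPoolFixture(character(0)), wobbleRules()))
})

test_that("w is invariant under uniform tGCN scaling; aaW >= w always", {
    cfg <- simulationConfig(seed = 5)
    pool <- simulateTrnaPool(cfg)
    rules <- wobbleRules()
    ad1 <- computeWi(pool, rules)
    doubled <- new("TRNAGeneSet",
                   genes = rbind(trnaGenes(pool), trnaGenes(pool)))
    ad2 <- computeWi(doubled, rules)
    expect_equal(absoluteW(ad2), 2 * absoluteW(ad1))
    expect_equal(wValues(ad2), wValues(ad1))
    expect_equal(aaWValues(ad2), aaWValues(ad1))

    expect_true(all(aaWValues(ad1) >= wValues(ad1) - 1e-12))
    # the family holding the global maximum has aaW == w
    top <- names(which.max(absoluteW(ad1)))
    fam <- codonFamilies()[[translateCodon(top)]]
    expect_equal(aaWValues(ad1)[fam], wValues(ad1)[fam])
    # every family maximum of aaW is 1 (for families with any W > 0)
    for (fam in codonFamilies()) {
        if (any(absoluteW(ad1)[fam] > 0))
            expect_equal(max(aaWValues(ad1)[fam]), 1)
    }
})

test_that("family normalization switch rescales famW by family size", {
    pool <- simulateTrnaPool(simulationConfig(seed = 8))
    rules <- wobbleRules()
    a <- computeWi(pool, rules, familyNormScale = "none")
    b <- computeWi(pool, rules, familyNormScale = "family_size")
    sizes <- lengths(codonFamilies())
    fam <- codonFamilies()[["L"]]
    expect_equal(famWValues(b)[fam], famWValues(a)[fam] * 6)
    # famW sums to 1 (or family size) within each family
    expect_equal(sum(famWValues(a)[fam]), 1)
})
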