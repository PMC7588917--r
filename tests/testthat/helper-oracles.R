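# Independent brute-force oracles: literal transcriptions of the index
# definitions as per-gene loops over codon strings. They share no code with
# the package's vectorized implementations.

orcSplitCodons <- function(s) {
    n <- nchar(s)
    substring(s, seq(1, n, 3), seq(3, n, 3))
}

orcGeomMean <- function(x) exp(sum(log(x)) / length(x))

# CAI / tAI / AAtAI: geometric mean of per-codon weights
orcGeomIndex <- function(codons, weights) orcGeomMean(weights[codons])

# Wright's Nc with the CodonW-style 3-fold imputation, direct transcription
orcNc <- function(codons, code = standardGeneticCode()) {
    fams <- codonFamilies(code)
    fams <- fams[lengths(fams) > 1L]
    Fhat <- numeric(0)
    size <- integer(0)
    for (aa in names(fams)) {
        fam <- fams[[aa]]
        cnt <- vapply(fam, function(cd) sum(codons == cd), numeric(1))
        n <- sum(cnt)
        if (n < 2) { Fhat <- c(Fhat, NA); size <- c(size, length(fam)); next }
        p <- cnt / n
        Fhat <- c(Fhat, (n * sum(p^2) - 1) / (n - 1))
        size <- c(size, length(fam))
    }
    avg <- function(k) mean(Fhat[size == k], na.rm = TRUE)
    F2 <- avg(2); F3 <- avg(3); F4 <- avg(4); F6 <- avg(6)
    if (is.nan(F3)) F3 <- (F2 + F4) / 2
    if (any(is.nan(c(F2, F4, F6))) || any(c(F2, F3, F4, F6) <= 0))
        return(NA_real_)
    n2 <- sum(size == 2); n3 <- sum(size == 3)
    n4 <- sum(size == 4); n6 <- sum(size == 6)
    min(2 + n2 / F2 + n3 / F3 + n4 / F4 + n6 / F6, 61)
}

# CPS from a character vector of gene sequences, computed with literal
# per-thousand frequencies (the package uses raw counts; the scalings cancel)
orcCPS <- function(genes, code = standardGeneticCode()) {
    tab <- code@table
    codonCnt <- integer(0)
    pairCnt <- list()
    for (g in genes) {
        cds <- orcSplitCodons(g)
        for (cd in cds)
            codonCnt[cd] <- (if (is.na(codonCnt[cd])) 0 else codonCnt[cd]) + 1
        if (length(cds) >= 2)
            for (i in seq_len(length(cds) - 1)) {
                key <- paste0(cds[i], cds[i + 1])
                pairCnt[[key]] <- (if (is.null(pairCnt[[key]])) 0
                                   else pairCnt[[key]]) + 1
            }
    }
    pairCnt <- unlist(pairCnt)
    totalCodons <- sum(codonCnt)
    totalPairs <- sum(pairCnt)
    fA <- 1000 * codonCnt / totalCodons
    aaCnt <- tapply(codonCnt, tab[names(codonCnt)], sum)
    fX <- 1000 * aaCnt / totalCodons
    aaPairCnt <- tapply(pairCnt,
                        paste0(tab[substr(names(pairCnt), 1, 3)],
                               tab[substr(names(pairCnt), 4, 6)]), sum)
    fXY <- 1000 * aaPairCnt / totalPairs
    fAB <- 1000 * pairCnt / totalPairs
    out <- numeric(length(pairCnt))
    names(out) <- names(pairCnt)
    for (key in names(pairCnt)) {
        A <- substr(key, 1, 3); B <- substr(key, 4, 6)
        X <- tab[A]; Y <- tab[B]
        out[key] <- log(fAB[key] / (fA[A] * fA[B]) *
                        (fX[X] * fX[Y]) / fXY[paste0(X, Y)])
    }
    out
}

# mean CPS over a gene's adjacent pairs
orcCPB <- function(codons, cps) {
    l <- length(codons)
    stopifnot(l >= 2)
    tot <- 0
    for (i in seq_len(l - 1)) tot <- tot + cps[paste0(codons[i], codons[i + 1])]
    unname(tot / (l - 1))
}

# population-SD standardization
orcZ <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
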