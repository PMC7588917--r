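# gene lengths in codons for any accepted input
.geneLengths <- function(x) {
    seqs <- .asDNAStringSet(x)
    setNames(Biostrings::width(seqs) %/% 3L, names(seqs))
}

# geometric mean of per-codon weights over each gene, from a count matrix:
# exp( sum_c n_gc log w_c / l_g )
.geomIndex <- function(m, logw) {
    l <- rowSums(m)
    if (any(l == 0)) .stopf("gene of zero length")
    as.vector(exp((m %*% logw) / l))
}

#' CAI reference weights from a codon usage table
#'
#' Relative adaptiveness of each codon for the codon adaptation index:
#' weight_c = f(c) / max f over c's synonymous family, from a reference
#' usage corpus (by default the analyzed gene set itself, i.e. genome-wide
#' usage). Codons with zero frequency receive a floor weight (0.01, the
#' EMBOSS-compatible convention) so genes using them keep a finite CAI.
#'
#' @param counts a [CodonCountTable-class] (the reference corpus).
#' @param code a [GeneticCode-class].
#' @param floorWeight weight assigned to zero-frequency codons.
#' @return named numeric weights over the sense codons, in (0, 1].
#' @export
caiWeights <- function(counts, code = standardGeneticCode(),
                       floorWeight = 0.01) {
    stopifnot(is(counts, "CodonCountTable"))
    n <- counts@counts[code@sense]
    w <- setNames(rep(NA_real_, length(n)), names(n))
    for (aa in names(code@families)) {
        fam <- code@families[[aa]]
        mx <- max(n[fam])
        if (mx == 0)
            .stopf("synonymous family %s entirely absent from the reference corpus",
                   aa)
        w[fam] <- n[fam] / mx
    }
    w[w == 0] <- floorWeight
    w
}

#' Codon adaptation index
#'
#' Geometric mean of the reference relative-adaptiveness weights over all
#' codons of each gene. Met and Trp codons are included by default (the
#' EMBOSS convention); set \code{includeSingleCodonFamilies = FALSE} for the
#' Sharp-Li convention that excludes the single-codon families.
#'
#' @param x a [CDSSet-class], \code{DNAStringSet}, or character vector of
#'   validated coding sequences.
#' @param weights named weights from [caiWeights()].
#' @param includeSingleCodonFamilies include Met/Trp codons (default TRUE).
#' @param code a [GeneticCode-class].
#' @return named numeric CAI per gene, in (0, 1].
#' @examples
#' counts <- countCodons(c(a = "GCTGCC", b = "GCCGCC"))
#' computeCAI(c(g = "GCTGCC"), caiWeights(counts))
#' @export
computeCAI <- function(x, weights, includeSingleCodonFamilies = TRUE,
                       code = standardGeneticCode()) {
    m <- .codonCountMatrix(x, code)
    if (!all(code@sense %in% names(weights)))
        .stopf("weights must cover all sense codons")
    if (any(weights[code@sense] <= 0))
        .stopf("CAI weights must be strictly positive (apply a floor first)")
    keep <- code@sense
    if (!includeSingleCodonFamilies) {
        single <- unlist(code@families[lengths(code@families) == 1L])
        keep <- setdiff(keep, single)
        m <- m[, keep, drop = FALSE]
    }
    .geomIndex(m, log(weights[keep]))
}

# synonymous families by degeneracy class, excluding single-codon families
.degenClasses <- function(code) {
    fams <- code@families[lengths(code@families) > 1L]
    split(fams, lengths(fams))
}

#' Effective number of codons (Wright's Nc)
#'
#' Wright's statistic from per-family codon homozygosity: for each synonymous
#' family with usage n >= 2, \eqn{\hat F = (n \sum p^2 - 1)/(n - 1)}; class
#' averages over families of degeneracy 2, 3, 4 and 6 give
#' \deqn{N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6,}
#' capped at 61. A missing 3-fold average (Ile unused) is imputed as
#' \eqn{(\bar F_2 + \bar F_4)/2} (the CodonW convention); if any other class
#' is missing or non-positive the gene's Nc is NA (flagged).
#'
#' @inheritParams computeCAI
#' @return named numeric Nc per gene in [20, 61], NA where undefined.
#' @export
computeNc <- function(x, code = standardGeneticCode()) {
    m <- .codonCountMatrix(x, code)
    classes <- .degenClasses(code)
    classF <- matrix(NA_real_, nrow(m), length(classes),
                     dimnames = list(rownames(m), names(classes)))
    for (k in names(classes)) {
        fams <- classes[[k]]
        Fhat <- matrix(NA_real_, nrow(m), length(fams))
        for (j in seq_along(fams)) {
            sub <- m[, fams[[j]], drop = FALSE]
            n <- rowSums(sub)
            sumP2 <- rowSums((sub / pmax(n, 1))^2)
            ok <- n >= 2
            Fhat[ok, j] <- (n[ok] * sumP2[ok] - 1) / (n[ok] - 1)
        }
        classF[, k] <- rowMeans(Fhat, na.rm = TRUE)
    }
    classF[is.nan(classF)] <- NA_real_
    # impute the Ile class from its neighbours where absent
    miss3 <- is.na(classF[, "3"])
    classF[miss3, "3"] <- (classF[miss3, "2"] + classF[miss3, "4"]) / 2
    nFam <- vapply(classes, length, integer(1))
    nc <- 2 + nFam["2"] / classF[, "2"] + nFam["3"] / classF[, "3"] +
        nFam["4"] / classF[, "4"] + nFam["6"] / classF[, "6"]
    bad <- apply(classF <= 0 | is.na(classF), 1L, any)
    nc[bad] <- NA_real_
    pmin(nc, 61)
}

#' Codon-pair score table
#'
#' For every ordered sense-codon pair AB coding the amino-acid pair XY,
#' \deqn{CPS(AB) = \ln\left(\frac{f(AB)}{f(A)f(B)} \cdot
#'   \frac{f(X)f(Y)}{f(XY)}\right)}
#' with pair frequencies per thousand pairs and codon/amino-acid frequencies
#' per thousand codons (the per-thousand scalings cancel, so the score is
#' computed exactly from raw counts). Pairs unobserved in the corpus are NA
#' and flagged; with \code{pseudocount = TRUE} they are scored with a 0.5
#' pair count instead (flagged in the table).
#'
#' @param pairs a [CodonPairStats-class].
#' @param counts a [CodonCountTable-class] from the same corpus.
#' @param code a [GeneticCode-class].
#' @param pseudocount score unobserved pairs with a 0.5 count.
#' @return A [CPSTable-class].
#' @export
buildCPSTable <- function(pairs, counts, code = standardGeneticCode(),
                          pseudocount = FALSE) {
    stopifnot(is(pairs, "CodonPairStats"), is(counts, "CodonCountTable"))
    pn <- names(pairs@counts)
    A <- substring(pn, 1L, 3L)
    B <- substring(pn, 4L, 6L)
    X <- code@table[A]
    Y <- code@table[B]
    nAB <- pairs@counts
    nA <- counts@counts[A]
    nB <- counts@counts[B]
    aaCount <- vapply(split(counts@counts[code@sense],
                            code@table[code@sense]), sum, numeric(1))
    nX <- aaCount[X]
    nY <- aaCount[Y]
    aaPair <- paste0(X, Y)
    nXY <- vapply(split(nAB, aaPair), sum, numeric(1))[aaPair]
    if (any(nXY == 0 & nAB > 0))
        .stopf("internal inconsistency: amino-acid pair frequency zero for an observed codon pair")
    observed <- nAB > 0
    num <- nAB
    if (pseudocount) num[!observed] <- 0.5
    cps <- rep(NA_real_, length(nAB))
    scoreable <- (observed | pseudocount) & nXY > 0 & nA > 0 & nB > 0
    cps[scoreable] <- log(num[scoreable] * nX[scoreable] * nY[scoreable] /
                          (nA[scoreable] * nB[scoreable] * nXY[scoreable]))
    new("CPSTable", cps = setNames(cps, pn), observed = unname(observed),
        pseudocount = pseudocount,
        provenance = list(nPairs = sum(nAB), nGenes = pairs@nGenes))
}

#' Codon-pair bias of genes
#'
#' Arithmetic mean of the codon-pair scores over a gene's l - 1 adjacent
#' codon pairs. Genes of fewer than two codons get NA (flagged by a warning).
#' In strict mode a gene containing a pair missing from the CPS table is an
#' error naming the pair; build the table with \code{pseudocount = TRUE} for
#' lenient scoring.
#'
#' @inheritParams computeCAI
#' @param cps a [CPSTable-class].
#' @param strict error on pairs without a score (default TRUE).
#' @return named numeric CPB per gene.
#' @export
computeCPB <- function(x, cps, strict = TRUE, code = standardGeneticCode()) {
    stopifnot(is(cps, "CPSTable"))
    m <- .pairCountMatrix(x)[, names(cps@cps), drop = FALSE]
    nPairs <- rowSums(m)
    missing <- is.na(cps@cps)
    if (any(missing)) {
        hit <- m[, missing, drop = FALSE]
        genesHit <- rowSums(hit) > 0
        if (any(genesHit)) {
            if (strict) {
                badPair <- colnames(hit)[which(colSums(hit) > 0)[1]]
                .stopf("pair %s|%s has no CPS (unobserved in reference corpus)",
                       substring(badPair, 1, 3), substring(badPair, 4, 6))
            }
            .warnf("%d gene(s) use pairs without a CPS; those pairs contribute 0",
                   sum(genesHit))
        }
    }
    v <- cps@cps
    v[is.na(v)] <- 0  # unreachable in strict mode; lenient tables have no NA for used pairs
    cpb <- as.vector(m %*% v) / nPairs
    cpb[nPairs == 0] <- NA_real_
    if (any(nPairs == 0))
        .warnf("%d gene(s) shorter than 2 codons: CPB undefined (NA)",
               sum(nPairs == 0))
    setNames(cpb, rownames(m))
}

#' tRNA adaptation index
#'
#' Geometric mean of the relative adaptiveness w = W/Wmax over the codons of
#' each gene (zero-W substitution already applied in the
#' [AdaptivenessVector-class]).
#'
#' @inheritParams computeCAI
#' @param adapt an [AdaptivenessVector-class].
#' @return named numeric tAI per gene, in (0, 1].
#' @export
computeTAI <- function(x, adapt, code = standardGeneticCode()) {
    stopifnot(is(adapt, "AdaptivenessVector"))
    m <- .codonCountMatrix(x, code)
    .geomIndex(m, log(adapt@w[code@sense]))
}

#' Amino-acid-normalized tRNA adaptation index
#'
#' Geometric mean of the amino-acid-relative adaptiveness W/W_AAmax over the
#' codons of each gene. Because W_AAmax <= Wmax for every family,
#' AAtAI >= tAI for every gene; AAtAI = 1 means the gene uses the
#' best-served codon of every family.
#'
#' @inheritParams computeTAI
#' @return named numeric AAtAI per gene, in (0, 1].
#' @export
computeAAtAI <- function(x, adapt, code = standardGeneticCode()) {
    stopifnot(is(adapt, "AdaptivenessVector"))
    m <- .codonCountMatrix(x, code)
    .geomIndex(m, log(adapt@aaW[code@sense]))
}

#' Z-standardize index columns over the gene set
#'
#' Z = (x - mean) / SD per column, with the population SD (n denominator)
#' and moments taken over the genes with a finite value of that index.
#'
#' @param df data.frame of per-gene indices.
#' @param columns columns to standardize (default: all numeric except
#'   \code{l_g}).
#' @return \code{df} with added \code{z_<column>} columns.
#' @export
zscoreIndices <- function(df, columns = NULL) {
    if (is.null(columns)) {
        columns <- names(df)[vapply(df, is.numeric, logical(1))]
        columns <- setdiff(columns, "l_g")
    }
    for (col in columns) {
        v <- df[[col]]
        fin <- is.finite(v)
        if (sum(fin) < 2L)
            .stopf("fewer than 2 finite values for index %s", col)
        s <- .popSD(v[fin])
        if (s == 0)
            .stopf("index %s has zero standard deviation; Z undefined", col)
        df[[paste0("z_", col)]] <- (v - mean(v[fin])) / s
    }
    df
}

#' Per-gene adaptation index table
#'
#' One-stop computation of the per-gene indices from a validated CDS set:
#' CAI (against the corpus itself as reference, or a supplied weight vector),
#' Nc, CPB (against the corpus CPS table), and - when an adaptiveness vector
#' is supplied - tAI and AAtAI, plus Z-scores of every index over the gene
#' set.
#'
#' @param cds a [CDSSet-class] (or DNAStringSet of validated CDS).
#' @param adapt optional [AdaptivenessVector-class]; omit to skip tAI/AAtAI.
#' @param caiReference optional named weight vector (see [caiWeights()]);
#'   default: weights from the input corpus itself.
#' @param cps optional [CPSTable-class]; default: built from the input corpus
#'   with pseudocounts off (every pair of the corpus is observed in it, so
#'   strict scoring cannot fail).
#' @param code a [GeneticCode-class].
#' @return data.frame with columns \code{gene_id}, \code{l_g}, \code{cai},
#'   \code{nc}, \code{tai}, \code{aatai}, \code{cpb} and \code{z_*}
#'   standardizations.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "ATGGCTGAAGCCTAA", ">g2", "ATGGCCGAAGCCTAA"), fa)
#' computeGeneIndices(loadCDS(fa))
#' @export
computeGeneIndices <- function(cds, adapt = NULL, caiReference = NULL,
                               cps = NULL, code = standardGeneticCode()) {
    seqs <- .asDNAStringSet(cds)
    if (!length(seqs)) .stopf("no genes to score")
    counts <- countCodons(seqs, code)
    if (is.null(caiReference)) caiReference <- caiWeights(counts, code)
    if (is.null(cps)) {
        pairs <- countCodonPairs(seqs, code)
        cps <- buildCPSTable(pairs, counts, code)
    }
    df <- data.frame(gene_id = names(seqs),
                     l_g = unname(.geneLengths(seqs)),
                     cai = computeCAI(seqs, caiReference, code = code),
                     nc = unname(computeNc(seqs, code)),
                     stringsAsFactors = FALSE)
    if (!is.null(adapt)) {
        df$tai <- computeTAI(seqs, adapt, code)
        df$aatai <- computeAAtAI(seqs, adapt, code)
    }
    df$cpb <- suppressWarnings(unname(computeCPB(seqs, cps, code = code)))
    idx <- intersect(c("cai", "nc", "tai", "aatai", "cpb"), names(df))
    rownames(df) <- NULL
    zscoreIndices(df, idx)
}

#' Write a CPS table as TSV
#'
#' Columns: codonA, codonB, aaA, aaB, count, f_AB (per thousand pairs), cps.
#'
#' @param cps a [CPSTable-class].
#' @param pairs the [CodonPairStats-class] the table was built from.
#' @param path output path.
#' @param code a [GeneticCode-class].
#' @return the path, invisibly.
#' @export
writeCPSTable <- function(cps, pairs, path, code = standardGeneticCode()) {
    pn <- names(cps@cps)
    df <- data.frame(codonA = substring(pn, 1, 3), codonB = substring(pn, 4, 6))
    df$aaA <- unname(code@table[df$codonA])
    df$aaB <- unname(code@table[df$codonB])
    df$count <- unname(pairs@counts[pn])
    df$f_AB <- 1000 * df$count / sum(df$count)
    df$cps <- unname(cps@cps)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
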