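#' Simulation configuration
#'
#' Parameter container for the synthetic-data generator. The generator
#' emulates the three study inputs: a tRNA gene pool with heterogeneous,
#' long-tailed copy numbers; coding sequences whose synonymous-codon choice
#' is biased toward well-served codons with a per-gene selection strength
#' beta (codon probability proportional to exp(beta * w)); and a
#' two-condition expression table whose induced subset is drawn from the top
#' beta tertile. All randomness flows from \code{seed}; the same seed gives
#' byte-identical outputs.
#'
#' @slot params named list of generator parameters.
#' @export
setClass("SimulationConfig", slots = c(params = "list"),
    validity = function(object) {
        p <- object@params
        msg <- character()
        if (!is.numeric(p$seed) || length(p$seed) != 1L)
            msg <- c(msg, "seed must be a single integer")
        if (p$nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
        if (p$lengthMin < 2 || p$lengthMax < p$lengthMin)
            msg <- c(msg, "need 2 <= lengthMin <= lengthMax")
        if (p$betaMean < 0) msg <- c(msg, "betaMean must be >= 0")
        if (p$inducedFraction < 0 || p$inducedFraction >= 1)
            msg <- c(msg, "inducedFraction must lie in [0, 1)")
        if (p$repressedFraction < 0 || p$shiftedFraction < 0 ||
            p$repressedFraction + p$inducedFraction + p$shiftedFraction >= 1)
            msg <- c(msg,
                     "induced + repressed + shifted fractions must stay below 1")
        if (length(msg)) msg else TRUE
    })

#' @describeIn SimulationConfig-class constructor with the package defaults
#'   (2000 genes, log-normal lengths around ~350 codons clamped to
#'   [100, 1500], exponential selection strengths with mean 2, a 45-anticodon
#'   eukaryote-like pool with copy numbers 1 + NegBin, 15% of genes induced
#'   from the top selection-strength tertile at >= 2-fold with small
#'   p-values, 12% repressed, 12% significantly but sub-twofold shifted,
#'   background p ~ Uniform(0,1)). The repressed and shifted fractions keep
#'   every expression-response group at 200+ genes at the default size, the
#'   regime the group-comparison signature is asserted in; a large
#'   significant-but-small-change group mirrors the real two-condition data,
#'   where most significant genes change less than two-fold.
#'
#' @param seed integer seed driving every random draw.
#' @param nGenes number of genes to simulate.
#' @param lengthMin,lengthMax clamp on gene length in codons.
#' @param lengthMeanLog,lengthSdLog log-normal parameters of gene length.
#' @param betaMean mean of the exponential per-gene selection strength.
#' @param anticodons optional custom anticodon set for the tRNA pool
#'   (default: a built-in eukaryote-like set covering every amino acid).
#' @param copyMu,copySize negative-binomial parameters of tGCN - 1.
#' @param nScaffolds number of scaffolds tRNA genes are scattered over.
#' @param intronProb probability a tRNA gene carries an intron.
#' @param inducedFraction,repressedFraction fractions of genes induced /
#'   repressed at least two-fold in the second condition.
#' @param shiftedFraction fraction of genes with significant but sub-twofold
#'   expression changes (drawn beta-neutrally).
#' @param log2Effect,log2EffectSD mean and SD of the log2 induction effect
#'   (floored at 1, i.e. two-fold).
#' @param shiftedEffectSD SD of the sub-twofold log2 effects (clamped to
#'   (-0.9, 0.9)).
#' @param noiseSD SD of per-signal measurement noise (log2 scale).
#' @param baselineMean,baselineSD distribution of baseline log2 signals.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 2000L, lengthMin = 100L,
                             lengthMax = 1500L, lengthMeanLog = log(350),
                             lengthSdLog = 0.35, betaMean = 2,
                             anticodons = NULL, copyMu = 3.3, copySize = 1.3,
                             nScaffolds = 30L, intronProb = 0.7,
                             inducedFraction = 0.15,
                             repressedFraction = 0.12,
                             shiftedFraction = 0.12, log2Effect = 2,
                             log2EffectSD = 0.5, shiftedEffectSD = 0.4,
                             noiseSD = 0.25,
                             baselineMean = 10, baselineSD = 1.2) {
    new("SimulationConfig", params = list(
        seed = as.integer(seed), nGenes = as.integer(nGenes),
        lengthMin = as.integer(lengthMin), lengthMax = as.integer(lengthMax),
        lengthMeanLog = lengthMeanLog, lengthSdLog = lengthSdLog,
        betaMean = betaMean, anticodons = anticodons, copyMu = copyMu,
        copySize = copySize, nScaffolds = as.integer(nScaffolds),
        intronProb = intronProb, inducedFraction = inducedFraction,
        repressedFraction = repressedFraction,
        shiftedFraction = shiftedFraction, log2Effect = log2Effect,
        log2EffectSD = log2EffectSD, shiftedEffectSD = shiftedEffectSD,
        noiseSD = noiseSD,
        baselineMean = baselineMean, baselineSD = baselineSD))
}

setMethod("show", "SimulationConfig", function(object) {
    p <- object@params
    cat("SimulationConfig: seed", p$seed, "|", p$nGenes, "genes |",
        sprintf("%.0f%% induced, %.0f%% repressed\n",
                100 * p$inducedFraction, 100 * p$repressedFraction))
})

#' @describeIn SimulationConfig-class the parameter list
#' @param x a \code{SimulationConfig}
#' @export
configParams <- function(x) x@params

# built-in eukaryote-like anticodon set: one G34 anticodon per 2-fold
# pyrimidine family, C34+T34 per purine family, A34/C34/T34 per 4-fold box,
# A34+T34 for Ile, CAT for Met, CCA for Trp; covers every sense codon under
# the default wobble rules
.defaultAnticodons <- function(code = .defaultCode()) {
    out <- character()
    for (fam in code@families) {
        third <- substring(fam, 3L, 3L)
        boxes <- split(fam, substring(fam, 1L, 2L))
        for (box in boxes) {
            b3 <- substring(box, 3L, 3L)
            wc <- codonToAnticodon(box)
            if (length(box) == 1L) {
                out <- c(out, wc)
            } else if (all(b3 %in% c("T", "C"))) {
                out <- c(out, wc[b3 == "C"])  # G34 reads both
            } else if (all(b3 %in% c("A", "G"))) {
                out <- c(out, wc)             # T34 + C34
            } else {
                # 4-fold (or Ile ATT/ATC/ATA) box: A34, T34, C34 as present
                out <- c(out, wc[b3 %in% c("T", "A", "G")])
            }
        }
    }
    sort(unique(out))
}

#' Simulate a tRNA gene pool
#'
#' Draws anticodon gene copy numbers from a long-tailed discrete
#' distribution (1 + negative binomial), scatters the genes over scaffolds
#' with intron flags and plausible scores, and optionally writes a valid
#' tRNAscan-SE tabular file. Errors if the anticodon set leaves an amino
#' acid uncovered.
#'
#' @param config a [SimulationConfig-class].
#' @param path optional output path for a tRNAscan-SE-format file.
#' @param code a [GeneticCode-class].
#' @return A [TRNAGeneSet-class].
#' @export
simulateTrnaPool <- function(config, path = NULL,
                             code = standardGeneticCode()) {
    stopifnot(is(config, "SimulationConfig"))
    p <- config@params
    anticodons <- p$anticodons
    if (is.null(anticodons)) anticodons <- .defaultAnticodons(code)
    .checkTriplet(anticodons, "anticodon")
    aa1 <- translateCodon(anticodonToCodon(anticodons), code)
    if (any(aa1 == "*"))
        .stopf("anticodon(s) decoding stop codons are not allowed: %s",
               paste(anticodons[aa1 == "*"], collapse = ", "))
    missing <- setdiff(names(code@families), unique(aa1))
    if (length(missing))
        .stopf("anticodon set leaves amino acid(s) uncovered: %s",
               paste(missing, collapse = ", "))

    set.seed(p$seed)
    gcn <- 1L + rnbinom(length(anticodons), size = p$copySize,
                        mu = p$copyMu - 1)
    g <- data.frame(anticodon = rep(anticodons, gcn),
                    stringsAsFactors = FALSE)
    n <- nrow(g)
    g$scaffold <- paste0("scaffold_",
                         sort(sample.int(p$nScaffolds, n, replace = TRUE)))
    g$geneIndex <- stats::ave(seq_len(n), g$scaffold, FUN = seq_along)
    g$begin <- sample.int(5e5L, n, replace = TRUE)
    g$end <- g$begin + 71L
    g$hasIntron <- runif(n) < p$intronProb
    g$intronBegin <- ifelse(g$hasIntron, g$begin + 37L, 0)
    g$intronEnd <- ifelse(g$hasIntron, g$begin + 46L, 0)
    g$score <- round(runif(n, 40, 85), 1)
    g$aa <- unname(.AA1TO3[translateCodon(anticodonToCodon(g$anticodon),
                                          code)])
    g$discordant <- FALSE
    g <- g[, c("scaffold", "geneIndex", "begin", "end", "aa", "anticodon",
               "intronBegin", "intronEnd", "score", "hasIntron",
               "discordant")]
    set <- .newTRNAGeneSet(g)
    if (!is.null(path)) writeTRNAscan(set, path)
    set
}

#' Simulate codon-biased coding sequences
#'
#' Amino-acid sequences are i.i.d. uniform over the 20 amino acids; within
#' each synonymous family the codon c is chosen with probability
#' proportional to exp(beta_g * w_c), where w is the relative adaptiveness
#' of the supplied [AdaptivenessVector-class] and beta_g >= 0 is the gene's
#' selection strength (exponential across genes). beta = 0 gives uniform
#' synonymous usage; large beta approaches all-optimal codons. A terminal
#' stop codon is appended to every record (stripped again at load).
#'
#' @param config a [SimulationConfig-class].
#' @param adapt an [AdaptivenessVector-class] defining codon adaptiveness.
#' @param path optional FASTA output path.
#' @param truthPath optional path for the ground-truth sidecar TSV
#'   (gene_id, beta, l_g).
#' @param code a [GeneticCode-class].
#' @return list with \code{cds} (named \code{DNAStringSet}) and \code{truth}
#'   (data.frame gene_id, beta, l_g).
#' @export
simulateCds <- function(config, adapt, path = NULL, truthPath = NULL,
                        code = standardGeneticCode()) {
    stopifnot(is(config, "SimulationConfig"),
              is(adapt, "AdaptivenessVector"))
    p <- config@params
    w <- adapt@w[code@sense]
    if (any(!is.finite(w) | w <= 0))
        .stopf("adaptiveness vector has non-positive w values")
    set.seed(p$seed + 1L)
    n <- p$nGenes
    len <- pmin(pmax(round(rlnorm(n, p$lengthMeanLog, p$lengthSdLog)),
                     p$lengthMin), p$lengthMax)
    beta <- rexp(n, rate = 1 / p$betaMean)
    ids <- sprintf("gene_%05d", seq_len(n))
    aas <- names(code@families)
    stops <- sample(code@stops, n, replace = TRUE)
    seqs <- character(n)
    for (gidx in seq_len(n)) {
        aaSeq <- sample(aas, len[gidx], replace = TRUE)
        codonSeq <- character(len[gidx])
        for (aa in unique(aaSeq)) {
            fam <- code@families[[aa]]
            pos <- which(aaSeq == aa)
            # shift by the family max so large beta cannot overflow exp()
            prob <- exp(beta[gidx] * (w[fam] - max(w[fam])))
            codonSeq[pos] <- if (length(fam) == 1L) fam
                else sample(fam, length(pos), replace = TRUE, prob = prob)
        }
        seqs[gidx] <- paste0(paste(codonSeq, collapse = ""), stops[gidx])
    }
    cds <- Biostrings::DNAStringSet(setNames(seqs, ids))
    truth <- data.frame(gene_id = ids, beta = beta, l_g = len,
                        stringsAsFactors = FALSE)
    if (!is.null(path)) Biostrings::writeXStringSet(cds, path)
    if (!is.null(truthPath))
        write.table(truth, truthPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    list(cds = cds, truth = truth)
}

#' Simulate a two-condition expression table
#'
#' Baseline log2 signals are normal; a configured fraction of genes is
#' induced with a log2 effect floored at 1 (two-fold) and small p-values,
#' drawn preferentially from the top tertile of the true selection strength
#' beta, so induced genes are enriched for codon-adapted genes; a fraction
#' is repressed symmetrically and a fraction carries significant but
#' sub-twofold shifts (both drawn beta-neutrally); background genes get an
#' effect around 0 and p ~ Uniform(0, 1).
#'
#' @param config a [SimulationConfig-class].
#' @param truth ground-truth data.frame from [simulateCds()] (gene_id, beta).
#' @param path optional TSV output path (columns gene_id, log2_glucose,
#'   log2_bma, p_value).
#' @return data.frame with the four table columns plus a \code{status}
#'   column (\code{"induced"}, \code{"repressed"}, \code{"shifted"},
#'   \code{"background"}; not written to \code{path}).
#' @export
simulateExpression <- function(config, truth, path = NULL) {
    stopifnot(is(config, "SimulationConfig"),
              all(c("gene_id", "beta") %in% names(truth)))
    p <- config@params
    set.seed(p$seed + 2L)
    n <- nrow(truth)
    nInd <- round(n * p$inducedFraction)
    nRep <- round(n * p$repressedFraction)
    nShift <- round(n * p$shiftedFraction)
    status <- rep("background", n)
    if (nInd > 0) {
        top <- which(truth$beta >= quantile(truth$beta, 2 / 3))
        if (nInd > length(top))
            .stopf("induced fraction exceeds the top selection-strength tertile")
        status[sample(top, nInd)] <- "induced"
    }
    if (nRep > 0)
        status[sample(which(status == "background"), nRep)] <- "repressed"
    if (nShift > 0)
        status[sample(which(status == "background"), nShift)] <- "shifted"

    glu <- rnorm(n, p$baselineMean, p$baselineSD)
    effect <- rnorm(n, 0, p$noiseSD)
    ind <- status == "induced"
    rep_ <- status == "repressed"
    shf <- status == "shifted"
    effect[ind] <- pmax(1, rnorm(sum(ind), p$log2Effect, p$log2EffectSD))
    effect[rep_] <- pmin(-1, rnorm(sum(rep_), -p$log2Effect, p$log2EffectSD))
    effect[shf] <- pmin(pmax(rnorm(sum(shf), 0, p$shiftedEffectSD), -0.9),
                        0.9)
    bma <- glu + effect + rnorm(n, 0, p$noiseSD)
    pval <- runif(n)
    sig <- ind | rep_ | shf
    pval[sig] <- 10^(-runif(sum(sig), 1.34, 5))

    out <- data.frame(gene_id = truth$gene_id,
                      log2_glucose = round(glu, 3),
                      log2_bma = round(bma, 3),
                      p_value = signif(pval, 4),
                      status = status, stringsAsFactors = FALSE)
    if (!is.null(path))
        write.table(out[, c("gene_id", "log2_glucose", "log2_bma",
                            "p_value")],
                    path, sep = "\t", quote = FALSE, row.names = FALSE)
    out
}
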