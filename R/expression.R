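#' Load a two-condition expression table
#'
#' Reads a TSV of per-gene log2 microarray signals in a baseline condition
#' (glucose) and an induction condition (BMA, ball-milled aspen) with a
#' per-gene p-value, and derives the expression ratio
#' \code{ratio = 2^(log2_bma - log2_glucose)}. Rows with missing or
#' non-numeric values are rejected with reasons (attribute
#' \code{"rejected"}).
#'
#' @param path TSV with columns \code{id} (or \code{gene_id}),
#'   \code{log2_glucose}, \code{log2_bma}, \code{p_value}.
#' @return data.frame with columns \code{gene_id}, \code{log2_glucose},
#'   \code{log2_bma}, \code{ratio}, \code{p_value}.
#' @export
loadExpression <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    idCol <- intersect(c("gene_id", "id"), names(df))[1]
    need <- c("log2_glucose", "log2_bma", "p_value")
    if (is.na(idCol) || !all(need %in% names(df)))
        .stopf("expression table must have columns id/gene_id, log2_glucose, log2_bma, p_value")
    ids <- as.character(df[[idCol]])
    if (anyDuplicated(ids))
        .stopf("duplicate gene ids in expression table: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
    glu <- suppressWarnings(as.numeric(df$log2_glucose))
    bma <- suppressWarnings(as.numeric(df$log2_bma))
    p <- suppressWarnings(as.numeric(df$p_value))
    if (any(p < 0 | p > 1, na.rm = TRUE))
        .stopf("p-values outside [0, 1]")
    bad <- !is.finite(glu) | !is.finite(bma) | !is.finite(p)
    out <- data.frame(gene_id = ids[!bad], log2_glucose = glu[!bad],
                      log2_bma = bma[!bad],
                      ratio = 2^(bma[!bad] - glu[!bad]),
                      p_value = p[!bad], stringsAsFactors = FALSE)
    attr(out, "rejected") <- data.frame(
        id = ids[bad],
        reason = rep("missing or non-numeric value", sum(bad)),
        stringsAsFactors = FALSE)
    if (any(bad))
        .warnf("rejected %d malformed expression row(s)", sum(bad))
    out
}

#' Classify genes into expression-response groups A-D
#'
#' Fixed boundary policy: group A = repressed at least
#' \code{foldThreshold}-fold (ratio <= 1/foldThreshold) with
#' p < \code{alpha}; group B = induced at least \code{foldThreshold}-fold
#' (ratio >= foldThreshold) with p < \code{alpha}; group C = non-significant
#' (p >= \code{alpha}); group D = significant but under the fold threshold.
#' Every record receives exactly one label.
#'
#' @param records data.frame with columns \code{ratio} and \code{p_value}
#'   (e.g. from [loadExpression()]).
#' @param foldThreshold fold-change cutoff (default 2).
#' @param alpha significance cutoff (default 0.05); ties at exactly
#'   \code{alpha} go to group C.
#' @return \code{records} with an added factor column \code{group}.
#' @examples
#' df <- data.frame(ratio = c(6.5, 0.4, 0.7), p_value = c(0.009, 0.19, 0.006))
#' classifyGroups(df)$group  # B C D
#' @export
classifyGroups <- function(records, foldThreshold = 2, alpha = 0.05) {
    stopifnot(all(c("ratio", "p_value") %in% names(records)),
              foldThreshold > 1, alpha > 0, alpha < 1)
    r <- records$ratio
    p <- records$p_value
    grp <- ifelse(p >= alpha, "C",
           ifelse(r >= foldThreshold, "B",
           ifelse(r <= 1 / foldThreshold, "A", "D")))
    records$group <- factor(grp, levels = c("A", "B", "C", "D"))
    records
}

#' Rank-sum comparison of an index between group B and the other groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparisons of the induced
#' group B against each of A, C and D for one index, with the exact null
#' distribution at small n without ties and the normal approximation with
#' tie correction otherwise (the \code{stats::wilcox.test} contract). Empty
#' or singleton groups are skipped with a warning.
#'
#' @param df data.frame holding the index column and a \code{group} column.
#' @param indexName name of the index column to compare.
#' @param reference reference group (default \code{"B"}).
#' @return data.frame with one row per comparison: index, groups, per-group
#'   n and medians, rank-sum statistic W, two-sided p.
#' @export
compareIndexByGroup <- function(df, indexName, reference = "B") {
    stopifnot("group" %in% names(df), indexName %in% names(df))
    v <- df[[indexName]]
    g <- as.character(df$group)
    fin <- is.finite(v)
    ref <- v[fin & g == reference]
    out <- list()
    for (other in setdiff(c("A", "B", "C", "D"), reference)) {
        cmp <- v[fin & g == other]
        if (length(ref) < 2L || length(cmp) < 2L) {
            .warnf("comparison %s vs %s skipped for %s: group with n < 2",
                   reference, other, indexName)
            next
        }
        wt <- suppressWarnings(
            wilcox.test(ref, cmp, alternative = "two.sided"))
        out[[other]] <- data.frame(
            index = indexName, group1 = reference, group2 = other,
            n1 = length(ref), n2 = length(cmp),
            median1 = median(ref), median2 = median(cmp),
            W = unname(wt$statistic), p_value = wt$p.value,
            stringsAsFactors = FALSE)
    }
    if (!length(out)) return(NULL)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Spearman correlation of indices with expression, stratified by p-value
#'
#' Correlates each index with the baseline signal, the induction signal, and
#' their ratio, within p-value strata (default: p < 0.001, 0.001 <= p < 0.05,
#' p >= 0.05, plus the unstratified set). Spearman rank correlation with
#' average ranks for ties; Spearman is invariant to monotone transforms, so
#' log2 versus linear signals give identical results. Strata with fewer than
#' 3 paired observations, or with a constant vector, are flagged with NA.
#'
#' @param indices per-gene index data.frame (\code{gene_id} plus index
#'   columns).
#' @param expression data.frame from [loadExpression()].
#' @param indexNames index columns to correlate (default: the ones present
#'   among cai, nc, tai, aatai, cpb).
#' @param strataBreaks p-value cut points (default \code{c(0.001, 0.05)}).
#' @return data.frame with columns index, variable, stratum, n, rho, p_value.
#' @export
correlateIndexExpression <- function(indices, expression,
                                     indexNames = NULL,
                                     strataBreaks = c(0.001, 0.05)) {
    if (is.null(indexNames))
        indexNames <- intersect(c("cai", "nc", "tai", "aatai", "cpb"),
                                names(indices))
    m <- merge(indices, expression, by = "gene_id")
    if (!nrow(m)) .stopf("no overlapping gene ids")
    breaks <- c(0, strataBreaks, 1 + 1e-9)
    labs <- c(sprintf("p < %g", strataBreaks[1]),
              sprintf("%g <= p < %g", strataBreaks[1], strataBreaks[2]),
              sprintf("p >= %g", strataBreaks[2]))
    m$stratum <- cut(m$p_value, breaks = breaks, labels = labs, right = FALSE,
                     include.lowest = TRUE)
    vars <- c(glucose = "log2_glucose", bma = "log2_bma", ratio = "ratio")
    out <- list()
    for (idx in indexNames) {
        for (vn in names(vars)) {
            for (st in c("all", labs)) {
                sel <- if (st == "all") rep(TRUE, nrow(m))
                       else m$stratum == st
                xv <- m[[idx]][sel]
                yv <- m[[vars[vn]]][sel]
                ok <- is.finite(xv) & is.finite(yv)
                n <- sum(ok)
                if (n < 3L || length(unique(xv[ok])) < 2L ||
                    length(unique(yv[ok])) < 2L) {
                    rho <- NA_real_; pv <- NA_real_
                } else {
                    ct <- suppressWarnings(
                        cor.test(xv[ok], yv[ok], method = "spearman"))
                    rho <- unname(ct$estimate); pv <- ct$p.value
                }
                out[[length(out) + 1L]] <- data.frame(
                    index = idx, variable = vn, stratum = st, n = n,
                    rho = rho, p_value = pv, stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, out)
}
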