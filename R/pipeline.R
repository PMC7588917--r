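# run manifest: one per output directory; content hashes make reruns diffable
.writeManifest <- function(outDir, subcommand, inputs, config) {
    hashes <- if (length(inputs)) {
        h <- tools::md5sum(unlist(inputs))
        lapply(seq_along(inputs),
               function(i) list(path = unname(unlist(inputs)[i]),
                                md5 = unname(h[i])))
    } else list()
    names(hashes) <- names(inputs)
    manifest <- list(subcommand = subcommand,
                     tool = "codonAdapt",
                     version = as.character(packageVersion("codonAdapt")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     inputs = hashes, config = config)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(file.path(outDir, "manifest.json"))
}

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Generate a full synthetic input set
#'
#' Runs the three generators in sequence under one seed and writes a CDS
#' FASTA, a tRNAscan-SE-format tRNA table, an expression TSV, a ground-truth
#' sidecar (per-gene true selection strength and status), a YAML echo of the
#' configuration, and a run manifest. The files round-trip through
#' [loadCDS()], [parseTRNAscan()] and [loadExpression()] with zero rejected
#' records.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with the generated objects and file paths.
#' @examples
#' out <- runSimulate(simulationConfig(seed = 7, nGenes = 20), tempfile())
#' list.files(out$dir)
#' @export
runSimulate <- function(config, outDir) {
    stopifnot(is(config, "SimulationConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- config@params

    trnaPath <- file.path(outDir, "trna.tsv")
    pool <- simulateTrnaPool(config, path = trnaPath)
    adapt <- computeWi(pool, wobbleRules())

    cdsPath <- file.path(outDir, "cds.fasta")
    sim <- simulateCds(config, adapt, path = cdsPath)

    exprPath <- file.path(outDir, "expression.tsv")
    expr <- simulateExpression(config, sim$truth, path = exprPath)

    truth <- merge(sim$truth, expr[, c("gene_id", "status")], by = "gene_id")
    truthPath <- .writeTSV(truth, file.path(outDir, "truth.tsv"))

    cfg <- p[!vapply(p, is.null, logical(1))]
    yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
    .writeManifest(outDir, "simulate", list(), cfg)
    invisible(list(dir = outDir, pool = pool, adapt = adapt, cds = sim$cds,
                   truth = truth, expression = expr,
                   paths = list(cds = cdsPath, trna = trnaPath,
                                expression = exprPath, truth = truthPath)))
}

#' Compute per-gene adaptation indices from input files
#'
#' Loads and validates a CDS FASTA, builds the corpus codon and codon-pair
#' statistics, derives CAI weights (from the corpus itself unless a
#' reference table is supplied) and the CPS table, parses the tRNA gene
#' table and computes the adaptiveness vector when one is given, and writes:
#' the per-gene index table with Z-scores (\code{indices.tsv}), the CPS
#' table (\code{cps_table.tsv}), an EMBOSS-cusp-compatible codon usage
#' table (\code{codon_usage.tsv}), and - with tRNA input - the adaptiveness
#' vector (\code{adaptiveness.tsv}) and per-amino-acid tRNA summary
#' (\code{trna_summary.tsv}), plus a manifest. Without a tRNA table the
#' tAI/AAtAI columns are absent (with a warning); CAI, Nc and CPB are still
#' produced.
#'
#' @param cdsPath CDS FASTA path.
#' @param trnaPath optional tRNAscan-SE tabular path.
#' @param outDir output directory.
#' @param caiReference optional path to a cusp-style usage table to use as
#'   CAI reference instead of the input corpus.
#' @param pseudocount score unobserved codon pairs with a 0.5 count.
#' @param familyNormScale passed to [computeWi()].
#' @param sConstraints optional path to a wobble-constraint YAML.
#' @param organism passed to [wobbleRules()].
#' @param code a [GeneticCode-class].
#' @return invisibly, a list with the index data.frame and component objects.
#' @export
runIndices <- function(cdsPath, trnaPath = NULL, outDir,
                       caiReference = NULL, pseudocount = FALSE,
                       familyNormScale = "none", sConstraints = NULL,
                       organism = "eukaryote",
                       code = standardGeneticCode()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cds <- loadCDS(cdsPath, code)
    if (nrow(rejectedRecords(cds)))
        .warnf("%d CDS record(s) rejected: %s", nrow(rejectedRecords(cds)),
               paste(sprintf("%s (%s)", rejectedRecords(cds)$id,
                             rejectedRecords(cds)$reason), collapse = "; "))
    if (!length(cds)) .stopf("no valid coding sequences; nothing to score")

    counts <- countCodons(cds, code)
    pairs <- countCodonPairs(cds, code)
    cps <- buildCPSTable(pairs, counts, code, pseudocount = pseudocount)
    weights <- if (is.null(caiReference)) caiWeights(counts, code)
               else .readCuspWeights(caiReference, code)

    adapt <- NULL
    if (!is.null(trnaPath)) {
        pool <- parseTRNAscan(trnaPath, code)
        s <- if (is.null(sConstraints)) loadWobbleConstraints()
             else loadWobbleConstraints(sConstraints)
        adapt <- computeWi(pool, wobbleRules(code, s, organism),
                           familyNormScale = familyNormScale, code = code)
        writeAdaptiveness(adapt, file.path(outDir, "adaptiveness.tsv"), code)
        .writeTSV(summarizeTRNASet(pool),
                  file.path(outDir, "trna_summary.tsv"))
    } else {
        .warnf("no tRNA gene table supplied: tAI/AAtAI columns omitted")
    }

    indices <- computeGeneIndices(cds, adapt = adapt, caiReference = weights,
                                  cps = cps, code = code)
    .writeTSV(indices, file.path(outDir, "indices.tsv"))
    writeCPSTable(cps, pairs, file.path(outDir, "cps_table.tsv"), code)
    writeCusp(counts, file.path(outDir, "codon_usage.tsv"), code)
    inputs <- c(list(cds = cdsPath),
                if (!is.null(trnaPath)) list(trna = trnaPath))
    .writeManifest(outDir, "indices", inputs,
                   list(pseudocount = pseudocount,
                        familyNormScale = familyNormScale,
                        organism = organism,
                        caiReference = if (is.null(caiReference)) "corpus"
                                       else caiReference))
    invisible(list(indices = indices, counts = counts, pairs = pairs,
                   cps = cps, adapt = adapt, dir = outDir))
}

# read a cusp-style table back into CAI weights
.readCuspWeights <- function(path, code = .defaultCode()) {
    df <- read.table(path, header = FALSE, comment.char = "#",
                     col.names = c("codon", "aa", "fraction", "freq",
                                   "number"),
                     stringsAsFactors = FALSE)
    counts <- setNames(rep(0, length(code@sense)), code@sense)
    counts[df$codon] <- df$number
    caiWeights(new("CodonCountTable", counts = counts, nGenes = NA_real_,
                   codeId = code@id), code)
}

#' Integrate per-gene indices with two-condition expression data
#'
#' Joins an index table (from [runIndices()]) with an expression table on
#' gene id, classifies genes into response groups A-D, and writes the
#' group-annotated table (\code{groups.tsv}), the Mann-Whitney comparisons
#' of group B against A, C and D for every index (\code{comparisons.tsv}),
#' and the stratified Spearman correlations (\code{correlations.tsv}), plus
#' a manifest.
#'
#' @param indicesPath path to an indices TSV.
#' @param expressionPath path to an expression TSV (see [loadExpression()]).
#' @param outDir output directory.
#' @param alpha significance cutoff for the group rule.
#' @param foldThreshold fold-change cutoff for the group rule.
#' @return invisibly, a list with the annotated table, comparisons and
#'   correlations.
#' @export
runIntegrate <- function(indicesPath, expressionPath, outDir, alpha = 0.05,
                         foldThreshold = 2) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    indices <- read.delim(indicesPath, stringsAsFactors = FALSE)
    indices$gene_id <- as.character(indices$gene_id)
    expr <- loadExpression(expressionPath)
    joined <- merge(indices, expr, by = "gene_id")
    if (!nrow(joined))
        .stopf("no overlapping gene ids between indices and expression")
    joined <- classifyGroups(joined, foldThreshold = foldThreshold,
                             alpha = alpha)
    idx <- intersect(c("cai", "nc", "tai", "aatai", "cpb"), names(joined))
    comparisons <- do.call(rbind, lapply(idx, function(i)
        compareIndexByGroup(joined, i)))
    correlations <- correlateIndexExpression(
        indices[, c("gene_id", idx), drop = FALSE], expr, indexNames = idx)
    .writeTSV(joined, file.path(outDir, "groups.tsv"))
    .writeTSV(comparisons, file.path(outDir, "comparisons.tsv"))
    .writeTSV(correlations, file.path(outDir, "correlations.tsv"))
    .writeManifest(outDir, "integrate",
                   list(indices = indicesPath, expression = expressionPath),
                   list(alpha = alpha, foldThreshold = foldThreshold))
    invisible(list(groups = joined, comparisons = comparisons,
                   correlations = correlations, dir = outDir))
}
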