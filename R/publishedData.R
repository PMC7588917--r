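#' Published lignocellulolytic worked-example table
#'
#' Per-gene adaptation indices (CAI, AAtAI, tAI, CPB, Nc and their
#' genome-wide Z-scores) and two-condition microarray signals (log2 glucose,
#' log2 ball-milled aspen, their printed ratio and p-value) for the
#' lignocellulolytic gene set of the white-rot fungus
#' \emph{Ceriporiopsis subvermispora}, as published. Shipped as plain TSV in
#' \code{extdata} and used by the worked examples: the printed log2 signals
#' let the expression ratio and the group labels be recomputed and checked
#' against the printed columns, and the printed (CAI, Z-CAI) pairs pin down
#' the genome-wide affine standardization.
#'
#' @return data.frame with columns \code{category}, \code{transcript_id},
#'   \code{cai}, \code{aatai}, \code{tai}, \code{cpb}, \code{nc},
#'   \code{z_cai}, \code{z_aatai}, \code{z_cpb}, \code{z_tai},
#'   \code{putative_function}, \code{log2_glucose}, \code{log2_bma},
#'   \code{ratio}, \code{p_value}.
#' @examples
#' tab <- cersuLignocellulolyticGenes()
#' head(tab[, c("transcript_id", "cai", "nc", "ratio", "p_value")])
#' @export
cersuLignocellulolyticGenes <- function() {
    path <- system.file("extdata", "cersu_lignocellulolytic_genes.tsv",
                        package = "codonAdapt")
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    df$transcript_id <- as.character(df$transcript_id)
    df
}
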