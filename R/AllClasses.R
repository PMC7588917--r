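#' Validated coding sequences
#'
#' Container produced by [loadCDS()]: the accepted coding sequences (terminal
#' stop codons already stripped) plus a per-record rejection report.
#'
#' @slot sequences a \code{DNAStringSet} of validated CDS, names = gene ids.
#' @slot rejected data.frame with columns \code{id} and \code{reason}.
#' @slot codeId NCBI translation table id used for validation.
#' @export
setClass("CDSSet",
    slots = c(sequences = "ANY", rejected = "data.frame", codeId = "character"),
    validity = function(object) {
        msg <- character()
        if (!is(object@sequences, "DNAStringSet"))
            msg <- c(msg, "sequences must be a DNAStringSet")
        else {
            if (any(Biostrings::width(object@sequences) %% 3L != 0L))
                msg <- c(msg, "all sequence lengths must be multiples of 3")
            if (anyDuplicated(names(object@sequences)))
                msg <- c(msg, "gene ids must be unique")
        }
        if (!all(c("id", "reason") %in% names(object@rejected)))
            msg <- c(msg, "rejected must have columns id, reason")
        if (length(msg)) msg else TRUE
    })

#' @describeIn CDSSet-class the validated sequences as a DNAStringSet
#' @param x,object a \code{CDSSet}
#' @export
cdsSequences <- function(x) x@sequences

#' @describeIn CDSSet-class the rejection report (id, reason)
#' @export
rejectedRecords <- function(x) x@rejected

#' @describeIn CDSSet-class number of accepted genes
#' @export
setMethod("length", "CDSSet", function(x) length(x@sequences))

#' @describeIn CDSSet-class gene ids
#' @export
setMethod("names", "CDSSet", function(x) names(x@sequences))

setMethod("show", "CDSSet", function(object) {
    cat("CDSSet:", length(object@sequences), "coding sequences (",
        sum(Biostrings::width(object@sequences)) %/% 3L, "codons ),",
        nrow(object@rejected), "rejected records\n")
})

#' Genome-wide codon counts
#'
#' Counts of sense codons over a CDS corpus, with per-thousand frequencies
#' f(A) defined with respect to the total number of sense codons counted.
#'
#' @slot counts named numeric over the 61 sense codons.
#' @slot nGenes number of genes counted.
#' @slot codeId translation table id.
#' @export
setClass("CodonCountTable",
    slots = c(counts = "numeric", nGenes = "numeric", codeId = "character"),
    validity = function(object) {
        msg <- character()
        if (any(object@counts < 0) || any(is.na(object@counts)))
            msg <- c(msg, "counts must be non-negative and non-missing")
        if (is.null(names(object@counts)))
            msg <- c(msg, "counts must be named by codon")
        if (length(msg)) msg else TRUE
    })

#' @describeIn CodonCountTable-class raw codon counts (named numeric)
#' @param x,object a \code{CodonCountTable}
#' @export
codonCounts <- function(x) x@counts

#' @describeIn CodonCountTable-class frequencies per thousand codons;
#'   sums to 1000 over the sense codons
#' @export
freqPerThousand <- function(x) 1000 * x@counts / sum(x@counts)

setMethod("show", "CodonCountTable", function(object) {
    cat("CodonCountTable:", sum(object@counts), "codons over",
        length(object@counts), "sense codons from", object@nGenes, "genes\n")
})

#' Ordered codon-pair counts
#'
#' Counts of adjacent ordered sense-codon pairs (stored with hexamer names,
#' e.g. \code{"ATGGCC"} for the pair ATG->GCC). Pairs never span gene
#' boundaries and never involve stop codons.
#'
#' @slot counts named numeric over the 61 x 61 ordered sense pairs.
#' @slot nGenes number of genes contributing pairs.
#' @slot codeId translation table id.
#' @export
setClass("CodonPairStats",
    slots = c(counts = "numeric", nGenes = "numeric", codeId = "character"),
    validity = function(object) {
        msg <- character()
        if (any(object@counts < 0) || any(is.na(object@counts)))
            msg <- c(msg, "counts must be non-negative and non-missing")
        if (is.null(names(object@counts)) ||
            !all(nchar(names(object@counts)) == 6L))
            msg <- c(msg, "counts must be named by codon-pair hexamer")
        if (length(msg)) msg else TRUE
    })

#' @describeIn CodonPairStats-class raw pair counts (named by hexamer)
#' @param x,object a \code{CodonPairStats}
#' @export
codonPairCounts <- function(x) x@counts

#' @describeIn CodonPairStats-class pair frequencies per thousand pairs
#' @export
pairFreqPerThousand <- function(x) 1000 * x@counts / sum(x@counts)

setMethod("show", "CodonPairStats", function(object) {
    cat("CodonPairStats:", sum(object@counts), "ordered codon pairs (",
        sum(object@counts > 0), "of", length(object@counts),
        "distinct pairs observed ) from", object@nGenes, "genes\n")
})

#' tRNA gene set
#'
#' One row per tRNA gene as parsed from tRNAscan-SE tabular output (or
#' produced by the simulator), from which anticodon gene copy numbers (tGCN)
#' are derived.
#'
#' @slot genes data.frame with columns \code{scaffold}, \code{geneIndex},
#'   \code{aa} (predicted isotype, 3-letter), \code{anticodon},
#'   \code{hasIntron}, \code{score}.
#' @export
setClass("TRNAGeneSet",
    slots = c(genes = "data.frame"),
    validity = function(object) {
        need <- c("scaffold", "geneIndex", "aa", "anticodon", "hasIntron",
                  "score")
        msg <- character()
        if (!all(need %in% names(object@genes)))
            msg <- c(msg, paste("genes must have columns:",
                                paste(need, collapse = ", ")))
        else if (nrow(object@genes) &&
                 !all(grepl("^[ACGT]{3}$", object@genes$anticodon)))
            msg <- c(msg, "anticodons must be DNA 3-mers over ACGT")
        if (length(msg)) msg else TRUE
    })

#' @describeIn TRNAGeneSet-class the per-gene table
#' @param x,object a \code{TRNAGeneSet}
#' @export
trnaGenes <- function(x) x@genes

#' @describeIn TRNAGeneSet-class anticodon gene copy numbers: a named count
#'   vector (anticodon -> tGCN); the sum equals the number of retained genes
#' @export
tGCN <- function(x) {
    if (!nrow(x@genes)) return(setNames(numeric(0), character(0)))
    tab <- table(x@genes$anticodon)
    setNames(as.numeric(tab), names(tab))
}

#' @describeIn TRNAGeneSet-class number of tRNA genes
#' @export
setMethod("length", "TRNAGeneSet", function(x) nrow(x@genes))

setMethod("show", "TRNAGeneSet", function(object) {
    g <- object@genes
    cat("TRNAGeneSet:", nrow(g), "tRNA genes,",
        length(unique(g$anticodon)), "anticodons,",
        length(unique(g$scaffold)), "scaffolds,",
        sum(g$hasIntron), "with introns\n")
})

#' Wobble pairing rule set
#'
#' Codon -> anticodon recognition rules with selective constraints S in [0,1]
#' penalizing non-Watson-Crick third-position pairing. Watson-Crick entries
#' carry S = 0; every sense codon is matched by at least one rule.
#'
#' @slot rules data.frame with columns \code{codon}, \code{anticodon},
#'   \code{pairing} (label such as "WC", "G:U", "I:C"), \code{S}.
#' @slot organism \code{"eukaryote"} or \code{"prokaryote"} (lysidine ATA
#'   special case).
#' @slot sValues the named selective-constraint vector the rules were built
#'   from.
#' @export
setClass("WobbleRuleSet",
    slots = c(rules = "data.frame", organism = "character",
              sValues = "numeric"),
    validity = function(object) {
        r <- object@rules
        msg <- character()
        if (!all(c("codon", "anticodon", "pairing", "S") %in% names(r)))
            msg <- c(msg, "rules must have columns codon, anticodon, pairing, S")
        else {
            if (any(r$S < 0 | r$S > 1))
                msg <- c(msg, "constraints S must lie in [0, 1]")
            if (any(r$S[r$pairing == "WC"] != 0))
                msg <- c(msg, "Watson-Crick entries must have S = 0")
        }
        if (length(msg)) msg else TRUE
    })

#' @describeIn WobbleRuleSet-class the rule table
#' @param x,object a \code{WobbleRuleSet}
#' @export
wobbleRuleTable <- function(x) x@rules

setMethod("show", "WobbleRuleSet", function(object) {
    cat("WobbleRuleSet (", object@organism, "): ", nrow(object@rules),
        " rules over ", length(unique(object@rules$codon)), " codons; S = {",
        paste(sprintf("%s: %.4g", names(object@sValues), object@sValues),
              collapse = ", "), "}\n", sep = "")
})

#' Per-codon adaptiveness to the tRNA pool
#'
#' Absolute adaptiveness W of each sense codon under wobble rules
#' (W_i = sum over recognizing anticodons of (1 - S_ij) tGCN_ij), together
#' with three normalizations: w = W / max(W) (used by tAI), the
#' amino-acid-relative aaW = W / max(W within the codon's synonymous family)
#' (used by AAtAI), and the family-normalized famW = W / sum(W within family).
#' Codons with W = 0 receive the geometric mean of the non-zero values of the
#' corresponding normalized vector; the substitution is recorded.
#'
#' @slot W absolute adaptiveness, named over sense codons.
#' @slot w W / Wmax, zero-substituted.
#' @slot aaW W / W_AAmax, zero-substituted.
#' @slot famW family-normalized W.
#' @slot substituted codons whose w/aaW were geometric-mean substituted.
#' @slot provenance list (rule set organism, family normalization scale, ...).
#' @export
setClass("AdaptivenessVector",
    slots = c(W = "numeric", w = "numeric", aaW = "numeric", famW = "numeric",
              substituted = "character", provenance = "list"),
    validity = function(object) {
        msg <- character()
        eps <- 1e-12
        if (any(object@w < 0 - eps | object@w > 1 + eps))
            msg <- c(msg, "w must lie in [0, 1]")
        if (abs(max(object@w) - 1) > eps)
            msg <- c(msg, "max of w must be 1")
        if (any(object@aaW + eps < object@w))
            msg <- c(msg, "aaW must be >= w for every codon")
        if (length(msg)) msg else TRUE
    })

#' @describeIn AdaptivenessVector-class relative adaptiveness w = W/Wmax
#' @param x,object an \code{AdaptivenessVector}
#' @export
wValues <- function(x) x@w

#' @describeIn AdaptivenessVector-class absolute adaptiveness W
#' @export
absoluteW <- function(x) x@W

#' @describeIn AdaptivenessVector-class amino-acid-relative adaptiveness
#'   W / W_AAmax
#' @export
aaWValues <- function(x) x@aaW

#' @describeIn AdaptivenessVector-class family-normalized W
#' @export
famWValues <- function(x) x@famW

#' @describeIn AdaptivenessVector-class codons whose adaptiveness was
#'   geometric-mean substituted because W = 0
#' @export
substitutedCodons <- function(x) x@substituted

setMethod("show", "AdaptivenessVector", function(object) {
    cat("AdaptivenessVector over", length(object@W), "sense codons; Wmax =",
        max(object@W), "( codon", names(object@W)[which.max(object@W)], ");",
        length(object@substituted), "zero-W codons substituted\n")
})

#' Codon-pair score table
#'
#' Natural-log codon-pair scores for ordered sense-codon pairs:
#' CPS(AB) = ln( f(AB) / (f(A) f(B)) * (f(X) f(Y)) / f(XY) ), where X and Y
#' are the amino acids coded by A and B. Pairs unobserved in the reference
#' corpus are NA unless a 0.5-count pseudocount mode was requested.
#'
#' @slot cps named numeric over ordered pairs (hexamer names); NA = unobserved
#'   pair in strict mode.
#' @slot observed logical, pair observed in the reference corpus.
#' @slot pseudocount whether unobserved pairs were scored with a 0.5 count.
#' @slot provenance list describing the reference corpus.
#' @export
setClass("CPSTable",
    slots = c(cps = "numeric", observed = "logical", pseudocount = "logical",
              provenance = "list"),
    validity = function(object) {
        msg <- character()
        if (length(object@cps) != length(object@observed))
            msg <- c(msg, "cps and observed must have equal length")
        if (any(is.infinite(object@cps), na.rm = TRUE))
            msg <- c(msg, "CPS must be finite for scored pairs")
        if (length(msg)) msg else TRUE
    })

#' @describeIn CPSTable-class the CPS values (named by hexamer pair)
#' @param x,object a \code{CPSTable}
#' @export
cpsValues <- function(x) x@cps

setMethod("show", "CPSTable", function(object) {
    cat("CPSTable:", sum(object@observed), "observed pairs of",
        length(object@cps),
        if (object@pseudocount) "(pseudocount mode)\n" else "(strict mode)\n")
})
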