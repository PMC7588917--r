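#' @import methods
#' @importFrom stats cor.test median p.adjust rexp rlnorm rnbinom rnorm runif
#'   setNames wilcox.test quantile sd
#' @importFrom utils read.delim write.table packageVersion
NULL

# all 64 codons in alphabetical (ACGT) order; the package-wide canonical order
.allCodons <- local({
    b <- c("A", "C", "G", "T")
    sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
})

#' Genetic code with synonymous-family structure
#'
#' Wraps an NCBI translation table together with the derived sense/stop codon
#' partition and the synonymous-family map (amino acid to codon set) that the
#' codon-usage indices are defined over.
#'
#' @slot id NCBI translation table identifier.
#' @slot table named character vector of length 64 mapping codons to
#'   one-letter amino acids, \code{"*"} for stops.
#' @slot sense sense codons (codons not mapping to \code{"*"}).
#' @slot stops stop codons.
#' @slot families named list: amino acid -> character vector of its codons.
#'
#' @export
setClass("GeneticCode",
    slots = c(id = "character", table = "character", sense = "character",
              stops = "character", families = "list"),
    validity = function(object) {
        msg <- character()
        if (length(object@table) != 64L ||
            !identical(sort(names(object@table)), .allCodons))
            msg <- c(msg, "table must map exactly the 64 codons")
        if (!setequal(c(object@sense, object@stops), names(object@table)) ||
            length(intersect(object@sense, object@stops)))
            msg <- c(msg, "sense and stop codons must partition the 64 codons")
        fam <- unlist(object@families, use.names = FALSE)
        if (!setequal(fam, object@sense) || anyDuplicated(fam))
            msg <- c(msg, "families must partition the sense codons")
        if (length(msg)) msg else TRUE
    })

#' Construct a genetic code
#'
#' Builds a [GeneticCode-class] from an NCBI translation table via
#' \code{Biostrings::getGeneticCode}. Only the standard nuclear code
#' (\code{id = "1"}: 61 sense codons, 3 stops, family sizes 1/2/3/4/6) is
#' exercised by the package's validation suite; other table ids are accepted
#' but untested.
#'
#' @param id NCBI translation table id (character or integer), default "1".
#' @return A [GeneticCode-class] object.
#' @examples
#' gc <- standardGeneticCode()
#' length(senseCodons(gc))  # 61
#' @export
standardGeneticCode <- function(id = "1") {
    tab <- Biostrings::getGeneticCode(as.character(id))
    tab <- tab[.allCodons]
    sense <- names(tab)[tab != "*"]
    stops <- names(tab)[tab == "*"]
    families <- split(sense, tab[sense])
    new("GeneticCode", id = as.character(id), table = tab, sense = sense,
        stops = stops, families = families)
}

# cached default code (standard nuclear)
.codeCache <- new.env(parent = emptyenv())
.defaultCode <- function() {
    if (is.null(.codeCache$std)) .codeCache$std <- standardGeneticCode("1")
    .codeCache$std
}

#' @describeIn GeneticCode-class sense codons
#' @param code a [GeneticCode-class] object
#' @export
senseCodons <- function(code = standardGeneticCode()) code@sense

#' @describeIn GeneticCode-class stop codons
#' @export
stopCodons <- function(code = standardGeneticCode()) code@stops

#' @describeIn GeneticCode-class synonymous families (amino acid -> codons)
#' @export
codonFamilies <- function(code = standardGeneticCode()) code@families

setMethod("show", "GeneticCode", function(object) {
    cat("GeneticCode (NCBI table ", object@id, "): ",
        length(object@sense), " sense codons, ",
        length(object@stops), " stops, ",
        length(object@families), " amino acids\n", sep = "")
})

#' Translate codons
#'
#' Standard-nuclear-code translation of DNA codons to one-letter amino acids;
#' stop codons translate to \code{"*"}.
#'
#' @param codon character vector of uppercase DNA 3-mers.
#' @param code a [GeneticCode-class].
#' @return character vector of one-letter amino acids (\code{"*"} = stop).
#' @examples
#' translateCodon(c("ATG", "TAA"))  # "M" "*"
#' @export
translateCodon <- function(codon, code = .defaultCode()) {
    .checkTriplet(codon)
    unname(code@table[codon])
}

#' Decode an anticodon to its Watson-Crick codon
#'
#' The perfectly paired codon is the reverse complement of the anticodon
#' (e.g. the glycine anticodon GCC decodes codon GGC).
#'
#' @param anticodon character vector of uppercase DNA 3-mers (anticodons
#'   written 5'->3' in DNA alphabet, as reported by tRNAscan-SE).
#' @return character vector of codons.
#' @examples
#' anticodonToCodon("GCC")  # "GGC"
#' @export
anticodonToCodon <- function(anticodon) {
    .checkTriplet(anticodon, "anticodon")
    .revComp(anticodon)
}

#' @rdname anticodonToCodon
#' @param codon character vector of codons.
#' @export
codonToAnticodon <- function(codon) {
    .checkTriplet(codon)
    .revComp(codon)
}
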