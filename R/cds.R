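#' Load and validate coding sequences
#'
#' Reads a multi-FASTA of coding sequences (or takes a \code{DNAStringSet}
#' directly) and validates each record: the nucleotide length must be a
#' multiple of 3, the alphabet strictly ACGT, and the reading frame free of
#' internal stop codons. A terminal stop codon is stripped and never counted.
#' Records failing any check are rejected individually with a reason code so
#' the corpus stays maximal and auditable.
#'
#' @param x path to a FASTA file, or a \code{DNAStringSet} with unique names.
#' @param code a [GeneticCode-class]; default standard nuclear.
#' @return A [CDSSet-class]; rejected records are reported by
#'   [rejectedRecords()] with reasons \code{"invalid alphabet"},
#'   \code{"length not multiple of 3"}, \code{"empty after stop removal"},
#'   or \code{"internal stop"}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "ATGGCCTAA", ">g2", "ATGTAAGCC"), fa)
#' cds <- loadCDS(fa)
#' names(cds)            # "g1" (g2 has an internal stop)
#' rejectedRecords(cds)
#' @export
loadCDS <- function(x, code = standardGeneticCode()) {
    if (is.character(x) && length(x) == 1L) {
        seqs <- Biostrings::readDNAStringSet(x)
    } else if (is(x, "DNAStringSet")) {
        seqs <- x
    } else {
        .stopf("x must be a FASTA path or a DNAStringSet")
    }
    if (length(seqs) == 0L)
        .stopf("no sequence records found")
    ids <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(ids))
        .stopf("duplicate sequence ids: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(seqs) <- ids

    chr <- toupper(as.character(seqs))
    reason <- rep(NA_character_, length(seqs))

    ok <- grepl("^[ACGT]+$", chr)
    reason[!ok] <- "invalid alphabet"

    len3 <- nchar(chr) %% 3L == 0L & nchar(chr) > 0L
    reason[ok & !len3] <- "length not multiple of 3"
    keep <- ok & len3

    # strip one terminal stop codon where present
    last <- substring(chr, nchar(chr) - 2L, nchar(chr))
    hasTerm <- keep & last %in% code@stops
    chr[hasTerm] <- substring(chr[hasTerm], 1L, nchar(chr[hasTerm]) - 3L)
    empty <- keep & nchar(chr) == 0L
    reason[empty] <- "empty after stop removal"
    keep <- keep & !empty

    if (any(keep)) {
        kept <- Biostrings::DNAStringSet(chr[keep])
        stopCount <- rowSums(Biostrings::oligonucleotideFrequency(
            kept, width = 3L, step = 3L)[, code@stops, drop = FALSE])
        internal <- stopCount > 0
        reason[keep][internal] <- "internal stop"
        keep[keep] <- !internal
    }

    accepted <- Biostrings::DNAStringSet(setNames(chr[keep], ids[keep]))
    rejected <- data.frame(id = ids[!keep], reason = reason[!keep],
                           stringsAsFactors = FALSE)
    new("CDSSet", sequences = accepted, rejected = rejected, codeId = code@id)
}

# coerce the inputs the index functions accept into a DNAStringSet
.asDNAStringSet <- function(x) {
    if (is(x, "CDSSet")) return(x@sequences)
    if (is(x, "DNAStringSet")) return(x)
    if (is.character(x)) return(Biostrings::DNAStringSet(x))
    .stopf("expected a CDSSet, DNAStringSet, or character vector of sequences")
}

# per-gene codon count matrix (genes x 61 sense codons)
.codonCountMatrix <- function(x, code = .defaultCode()) {
    seqs <- .asDNAStringSet(x)
    m <- Biostrings::oligonucleotideFrequency(seqs, width = 3L, step = 3L)
    m <- m[, code@sense, drop = FALSE]
    rownames(m) <- names(seqs)
    m
}

# per-gene adjacent codon-pair (hexamer) count matrix (genes x 4096)
.pairCountMatrix <- function(x) {
    seqs <- .asDNAStringSet(x)
    m <- Biostrings::oligonucleotideFrequency(seqs, width = 6L, step = 3L)
    rownames(m) <- names(seqs)
    m
}

# hexamer names of the 61 x 61 ordered sense pairs, canonical order
.sensePairNames <- function(code = .defaultCode()) {
    as.vector(t(outer(code@sense, code@sense, paste0)))
}

#' Count codons over a CDS corpus
#'
#' Aggregates sense-codon counts over all genes; per-thousand frequencies
#' f(A) = 1000 * count / total are available through [freqPerThousand()].
#'
#' @param x a [CDSSet-class], \code{DNAStringSet}, or character vector of
#'   validated coding sequences (no stops, length divisible by 3).
#' @param code a [GeneticCode-class].
#' @return A [CodonCountTable-class].
#' @examples
#' counts <- countCodons(c(g = "ATGGCC"))
#' freqPerThousand(counts)[c("ATG", "GCC")]  # 500 500
#' @export
countCodons <- function(x, code = standardGeneticCode()) {
    m <- .codonCountMatrix(x, code)
    if (nrow(m) == 0L)
        .stopf("no coding sequences to count")
    new("CodonCountTable", counts = colSums(m), nGenes = nrow(m),
        codeId = code@id)
}

#' Count adjacent codon pairs over a CDS corpus
#'
#' Counts every ordered pair of adjacent sense codons within each gene
#' (l - 1 pairs for a gene of l codons). Pairs never span gene boundaries,
#' and stop codons never appear (terminal stops are stripped at load).
#'
#' @inheritParams countCodons
#' @return A [CodonPairStats-class].
#' @examples
#' ps <- countCodonPairs(c(g = "ATGGCCGAA"))
#' codonPairCounts(ps)[c("ATGGCC", "GCCGAA")]  # 1 1
#' @export
countCodonPairs <- function(x, code = standardGeneticCode()) {
    seqs <- .asDNAStringSet(x)
    if (all(Biostrings::width(seqs) < 6L))
        .stopf("no gene has two or more codons; no pairs to count")
    m <- .pairCountMatrix(seqs)
    counts <- colSums(m)[.sensePairNames(code)]
    new("CodonPairStats", counts = counts,
        nGenes = sum(Biostrings::width(seqs) >= 6L), codeId = code@id)
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c is its count divided by the mean count over its synonymous
#' family, so values sum to the family size within each family. Single-codon
#' families (Met, Trp) get RSCU = 1 when used. Families never observed in the
#' corpus are left NA and flagged, not zero-filled.
#'
#' @param counts a [CodonCountTable-class].
#' @param code a [GeneticCode-class].
#' @return data.frame with columns \code{codon}, \code{aa}, \code{count},
#'   \code{rscu}; attribute \code{"unobservedFamilies"} lists amino acids
#'   whose family had zero total usage.
#' @export
computeRSCU <- function(counts, code = standardGeneticCode()) {
    stopifnot(is(counts, "CodonCountTable"))
    n <- counts@counts[code@sense]
    rscu <- setNames(rep(NA_real_, length(n)), names(n))
    unobserved <- character()
    for (aa in names(code@families)) {
        fam <- code@families[[aa]]
        tot <- sum(n[fam])
        if (tot == 0) {
            unobserved <- c(unobserved, aa)
            next
        }
        rscu[fam] <- n[fam] / (tot / length(fam))
    }
    out <- data.frame(codon = code@sense,
                      aa = unname(code@table[code@sense]),
                      count = unname(n), rscu = unname(rscu),
                      stringsAsFactors = FALSE)
    attr(out, "unobservedFamilies") <- unobserved
    out
}

#' Write an EMBOSS-cusp-compatible codon usage table
#'
#' Columns: Codon, AA, Fraction (of its synonymous family), Frequency (per
#' thousand codons), Number.
#'
#' @param counts a [CodonCountTable-class].
#' @param path output file path.
#' @param code a [GeneticCode-class].
#' @return the path, invisibly.
#' @export
writeCusp <- function(counts, path, code = standardGeneticCode()) {
    stopifnot(is(counts, "CodonCountTable"))
    n <- counts@counts[code@sense]
    aa <- code@table[code@sense]
    famTot <- vapply(aa, function(a) sum(n[code@families[[a]]]), numeric(1))
    frac <- ifelse(famTot > 0, n / famTot, 0)
    freq <- 1000 * n / sum(n)
    lines <- c("#Codon AA Fraction Frequency Number",
               sprintf("%s %s %.3f %.3f %d", code@sense, aa, frac, freq,
                       as.integer(n)))
    writeLines(lines, path)
    invisible(path)
}
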