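# internal numeric helpers

# geometric mean via logs; x must be strictly positive
.geomMean <- function(x) exp(mean(log(x)))

# population standard deviation (n denominator)
.popSD <- function(x) {
    x <- x[is.finite(x)]
    sqrt(mean((x - mean(x))^2))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# strict DNA 3-mer check shared by codon-level operations
.checkTriplet <- function(x, what = "codon") {
    if (!is.character(x) || any(is.na(x)))
        .stopf("%s must be a character vector without NAs", what)
    bad <- !grepl("^[ACGT]{3}$", x)
    if (any(bad))
        .stopf("invalid %s(s): %s (must be uppercase DNA 3-mers over ACGT)",
               what, paste(x[bad], collapse = ", "))
    invisible(x)
}

# reverse complement of DNA strings, vectorized, no Biostrings round-trip
.revComp <- function(x) {
    comp <- chartr("ACGT", "TGCA", x)
    vapply(strsplit(comp, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), character(1))
}
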