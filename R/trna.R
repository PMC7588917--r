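# 3-letter -> 1-letter isotype map used for discordance checks
.AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
.AA1TO3 <- setNames(names(.AA3TO1), .AA3TO1)

#' Parse tRNAscan-SE tabular output
#'
#' Reads the standard tRNAscan-SE (v1/v2) tabular format: sequence name,
#' tRNA number, begin, end, isotype, anticodon, intron begin, intron end,
#' score (plus optional trailing note). Header/ruler lines are skipped.
#' Rows typed as pseudogenes or with an undetermined anticodon (\code{NNN},
#' \code{???}) are dropped with a warning. Genes whose predicted isotype
#' disagrees with the translation of their anticodon's Watson-Crick codon are
#' retained and flagged \code{discordant} (the anticodon governs gene copy
#' numbers), with a warning.
#'
#' @param path path to a tRNAscan-SE tabular file.
#' @param code a [GeneticCode-class] used for the discordance check.
#' @return A [TRNAGeneSet-class].
#' @export
parseTRNAscan <- function(path, code = standardGeneticCode()) {
    lines <- readLines(path)
    isHeader <- grepl("^(Sequence|Name|-{3,})", lines) |
        grepl("tRNA\\s*#", lines)
    body <- which(!isHeader & nzchar(trimws(lines)))
    if (!length(body)) {
        .warnf("no tRNA gene rows found in %s", path)
        return(.newTRNAGeneSet(.emptyTrnaFrame()))
    }
    rows <- vector("list", length(body))
    for (k in seq_along(body)) {
        i <- body[k]
        f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        if (length(f) < 9L)
            .stopf("malformed tRNAscan-SE row at line %d: expected >= 9 fields, got %d",
                   i, length(f))
        nums <- suppressWarnings(as.numeric(f[c(2, 3, 4, 7, 8, 9)]))
        if (any(is.na(nums)))
            .stopf("malformed tRNAscan-SE row at line %d: non-numeric coordinate or score",
                   i)
        rows[[k]] <- data.frame(scaffold = f[1], geneIndex = nums[1],
                                begin = nums[2], end = nums[3], aa = f[5],
                                anticodon = toupper(f[6]),
                                intronBegin = nums[4], intronEnd = nums[5],
                                score = nums[6],
                                note = if (length(f) >= 10L)
                                    paste(f[10:length(f)], collapse = " ")
                                else "",
                                stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, rows)

    drop <- g$aa %in% c("Pseudo", "pseudo") |
        grepl("pseudo", g$note, ignore.case = TRUE) |
        g$anticodon %in% c("NNN", "???") | !grepl("^[ACGT]{3}$", g$anticodon)
    if (any(drop))
        .warnf("dropped %d row(s): pseudogene or undetermined anticodon",
               sum(drop))
    g <- g[!drop, , drop = FALSE]

    g$hasIntron <- g$intronBegin != 0 | g$intronEnd != 0
    decoded <- translateCodon(anticodonToCodon(g$anticodon), code)
    g$discordant <- !is.na(.AA3TO1[g$aa]) & .AA3TO1[g$aa] != decoded
    # isotypes with no 1-letter mapping (SeC, Sup, ...) are left unflagged
    g$discordant[is.na(.AA3TO1[g$aa])] <- FALSE
    if (any(g$discordant))
        .warnf("%d gene(s) have an isotype discordant with their anticodon; anticodon retained for copy numbers",
               sum(g$discordant))
    g$note <- NULL
    rownames(g) <- NULL
    .newTRNAGeneSet(g)
}

.emptyTrnaFrame <- function() {
    data.frame(scaffold = character(), geneIndex = numeric(),
               begin = numeric(), end = numeric(), aa = character(),
               anticodon = character(), intronBegin = numeric(),
               intronEnd = numeric(), score = numeric(),
               hasIntron = logical(), discordant = logical(),
               stringsAsFactors = FALSE)
}

.newTRNAGeneSet <- function(g) new("TRNAGeneSet", genes = g)

#' Write a tRNAscan-SE-format tabular file
#'
#' Emits the three standard header lines followed by one row per gene, so the
#' output round-trips losslessly through [parseTRNAscan()].
#'
#' @param x a [TRNAGeneSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTRNAscan <- function(x, path) {
    stopifnot(is(x, "TRNAGeneSet"))
    g <- x@genes
    hdr <- c(paste("Sequence", "tRNA", "Bounds", "Bounds", "tRNA", "Anti",
                   "Intron", "Intron", "Inf", sep = "\t"),
             paste("Name", "tRNA #", "Begin", "End", "Type", "Codon",
                   "Begin", "End", "Score", sep = "\t"),
             paste("--------", "------", "-----", "---", "----", "-----",
                   "-----", "---", "-----", sep = "\t"))
    rows <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%.1f",
                    g$scaffold, as.integer(g$geneIndex), as.integer(g$begin),
                    as.integer(g$end), g$aa, g$anticodon,
                    as.integer(g$intronBegin), as.integer(g$intronEnd),
                    g$score)
    writeLines(c(hdr, rows), path)
    invisible(path)
}

#' Summarize a tRNA gene set by amino acid
#'
#' One row per predicted isotype with the gene count, anticodon frequencies
#' in superscript style (e.g. \code{"GCC^12, TCC^3"}), the scaffolds carrying
#' the genes, and the number of intron-containing genes.
#'
#' @param x a [TRNAGeneSet-class].
#' @return data.frame with columns \code{aa}, \code{n}, \code{anticodons},
#'   \code{scaffolds}, \code{nScaffolds}, \code{nIntron}.
#' @export
summarizeTRNASet <- function(x) {
    stopifnot(is(x, "TRNAGeneSet"))
    g <- x@genes
    if (!nrow(g)) .stopf("empty tRNA gene set")
    out <- lapply(split(g, g$aa), function(d) {
        tab <- table(d$anticodon)
        sc <- sort(unique(d$scaffold))
        data.frame(aa = d$aa[1], n = nrow(d),
                   anticodons = paste(sprintf("%s^%d", names(tab),
                                              as.integer(tab)),
                                      collapse = ", "),
                   scaffolds = paste(sc, collapse = ", "),
                   nScaffolds = length(sc), nIntron = sum(d$hasIntron),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out[order(out$aa), , drop = FALSE]
}

#' Load wobble selective constraints
#'
#' Reads the named selective-constraint vector S (one entry per non-WC
#' pairing geometry) from a YAML config. The shipped default follows the
#' reference tAI parameterization: G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68,
#' and lysidine L:A 0.89 for the prokaryotic ATA special case.
#'
#' @param path YAML file; defaults to the packaged constraint file.
#' @return named numeric vector of constraints in [0, 1].
#' @export
loadWobbleConstraints <- function(path = system.file("extdata",
        "wobble_constraints.yaml", package = "codonAdapt")) {
    s <- unlist(yaml::read_yaml(path))
    if (any(s < 0 | s > 1)) .stopf("constraints must lie in [0, 1]")
    s
}

#' Build the wobble recognition rule set
#'
#' For every sense codon, the Watson-Crick anticodon (S = 0) plus the wobble
#' isoacceptor implied by the codon's third base: codons ending T are also
#' read by the G34 anticodon (G:U), codons ending C and A by the A34
#' anticodon treated as inosine (I:C, I:A), and codons ending G by the T34
#' anticodon (U:G). ATG is read by its Watson-Crick anticodon only
#' (elongator Met); wobble partners whose Watson-Crick codon is a stop are
#' excluded (so TGG has no wobble partner). Under
#' \code{organism = "prokaryote"}, ATA is instead read by the
#' lysidine-modified CAT anticodon (L:A).
#'
#' @param code a [GeneticCode-class].
#' @param s named constraint vector, see [loadWobbleConstraints()].
#' @param organism \code{"eukaryote"} (default) or \code{"prokaryote"}.
#' @return A [WobbleRuleSet-class].
#' @export
wobbleRules <- function(code = standardGeneticCode(),
                        s = loadWobbleConstraints(),
                        organism = c("eukaryote", "prokaryote")) {
    organism <- match.arg(organism)
    need <- c("G:U", "I:C", "I:A", "U:G", "L:A")
    if (!all(need %in% names(s)))
        .stopf("constraint vector must name: %s", paste(need, collapse = ", "))
    codons <- code@sense
    wc <- codonToAnticodon(codons)
    third <- substring(codons, 3L, 3L)
    wobBase <- c(T = "G", C = "A", A = "A", G = "T")[third]
    wobPair <- c(T = "G:U", C = "I:C", A = "I:A", G = "U:G")[third]
    rules <- rbind(
        data.frame(codon = codons, anticodon = wc, pairing = "WC", S = 0,
                   stringsAsFactors = FALSE),
        data.frame(codon = codons,
                   anticodon = paste0(wobBase, substring(wc, 2L)),
                   pairing = wobPair, S = unname(s[wobPair]),
                   stringsAsFactors = FALSE))
    # elongator Met: no wobble reading of ATG
    rules <- rules[!(rules$codon == "ATG" & rules$pairing != "WC"), ]
    # no wobble contribution from anticodons that Watson-Crick decode a stop
    stopAnti <- codonToAnticodon(code@stops)
    rules <- rules[!(rules$pairing != "WC" & rules$anticodon %in% stopAnti), ]
    if (organism == "prokaryote") {
        rules <- rules[rules$codon != "ATA", ]
        rules <- rbind(rules,
                       data.frame(codon = "ATA", anticodon = "CAT",
                                  pairing = "L:A", S = unname(s["L:A"]),
                                  stringsAsFactors = FALSE))
    }
    rules <- rules[order(match(rules$codon, codons), rules$pairing != "WC"), ]
    rownames(rules) <- NULL
    new("WobbleRuleSet", rules = rules, organism = organism, sValues = s)
}

#' Anticodons recognizing a codon
#'
#' Lists the isoacceptors that read a sense codon under a rule set, with
#' their pairing geometry, selective constraint, and gene copy number in a
#' tRNA gene set. Anticodons absent from the gene set are retained with
#' tGCN = 0 (zero weight contribution).
#'
#' @param codon a single sense codon.
#' @param rules a [WobbleRuleSet-class].
#' @param genes a [TRNAGeneSet-class].
#' @param code a [GeneticCode-class].
#' @return data.frame with columns \code{anticodon}, \code{pairing},
#'   \code{S}, \code{tGCN}.
#' @export
codonRecognizers <- function(codon, rules, genes, code = standardGeneticCode()) {
    .checkTriplet(codon)
    stopifnot(length(codon) == 1L)
    if (codon %in% code@stops)
        .stopf("%s is a stop codon; stop codons are not decoded", codon)
    r <- rules@rules[rules@rules$codon == codon, , drop = FALSE]
    if (!nrow(r))
        .stopf("rule set has no entry for codon %s", codon)
    tg <- tGCN(genes)
    r$tGCN <- ifelse(r$anticodon %in% names(tg), tg[r$anticodon], 0)
    rownames(r) <- NULL
    r[, c("anticodon", "pairing", "S", "tGCN")]
}

#' Absolute and relative codon adaptiveness to the tRNA pool
#'
#' Computes, for every sense codon i, the absolute adaptiveness
#' \deqn{W_i = \sum_{j=1}^{n_i} (1 - S_{ij})\, tGCN_{ij}}
#' over the anticodons j that recognize it, then three normalizations:
#' \code{w = W / Wmax} (the tAI weight), the amino-acid-relative
#' \code{aaW = W / W_AAmax} with W_AAmax the largest W within the codon's
#' synonymous family (the AAtAI weight), and the family-normalized
#' \code{famW = W / sum(W over the family)} (optionally multiplied by the
#' family size). Codons with W = 0 receive the geometric mean of the non-zero
#' values of w (respectively aaW) so that a single unserved codon does not
#' annihilate the downstream geometric means; the substitution is recorded in
#' the object.
#'
#' @param genes a [TRNAGeneSet-class].
#' @param rules a [WobbleRuleSet-class].
#' @param familyNormScale \code{"none"} (default; famW = W / family total) or
#'   \code{"family_size"} (multiplied by the family size).
#' @param code a [GeneticCode-class].
#' @return An [AdaptivenessVector-class].
#' @examples
#' genes <- simulateTrnaPool(simulationConfig(seed = 1))
#' adapt <- computeWi(genes, wobbleRules())
#' head(wValues(adapt))
#' @export
computeWi <- function(genes, rules, familyNormScale = c("none", "family_size"),
                      code = standardGeneticCode()) {
    familyNormScale <- match.arg(familyNormScale)
    stopifnot(is(genes, "TRNAGeneSet"), is(rules, "WobbleRuleSet"))
    r <- rules@rules
    covered <- unique(r$codon)
    if (!all(code@sense %in% covered))
        .stopf("rule set does not cover all sense codons")
    tg <- tGCN(genes)
    contrib <- (1 - r$S) * ifelse(r$anticodon %in% names(tg),
                                  tg[r$anticodon], 0)
    W <- vapply(split(contrib, r$codon)[code@sense], sum, numeric(1))
    if (all(W == 0))
        .stopf("all W are zero: the tRNA gene set serves no codon")

    w <- W / max(W)
    zero <- W == 0
    if (any(zero)) w[zero] <- .geomMean(w[!zero])

    aaW <- setNames(rep(NA_real_, length(W)), names(W))
    famW <- aaW
    for (aa in names(code@families)) {
        fam <- code@families[[aa]]
        famMax <- max(W[fam])
        famSum <- sum(W[fam])
        if (famMax > 0) aaW[fam] <- W[fam] / famMax
        if (famSum > 0) {
            famW[fam] <- W[fam] / famSum
            if (familyNormScale == "family_size")
                famW[fam] <- famW[fam] * length(fam)
        }
    }
    aaZero <- zero | is.na(aaW)
    if (any(aaZero)) aaW[aaZero] <- .geomMean(aaW[!aaZero & aaW > 0])

    new("AdaptivenessVector", W = W, w = w, aaW = aaW, famW = famW,
        substituted = names(W)[zero],
        provenance = list(organism = rules@organism, sValues = rules@sValues,
                          familyNormScale = familyNormScale,
                          nTRNAGenes = length(genes)))
}

#' Write an adaptiveness vector as TSV
#'
#' Columns: codon, aa, W, w, aaW, famW, substituted.
#'
#' @param adapt an [AdaptivenessVector-class].
#' @param path output path.
#' @param code a [GeneticCode-class].
#' @return the path, invisibly.
#' @export
writeAdaptiveness <- function(adapt, path, code = standardGeneticCode()) {
    df <- data.frame(codon = names(adapt@W),
                     aa = unname(code@table[names(adapt@W)]),
                     W = unname(adapt@W), w = unname(adapt@w),
                     aaW = unname(adapt@aaW), famW = unname(adapt@famW),
                     substituted = names(adapt@W) %in% adapt@substituted)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
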