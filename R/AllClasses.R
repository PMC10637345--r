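#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabet used throughout for CDR3 and antigen sequences. Ambiguity
#' codes and stop symbols are rejected everywhere.
#'
#' @export
AA_STANDARD20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' ChemicalScales: per-residue charge and hydropathy used by all scoring
#'
#' Holds a signed unitless charge q per residue (in \[-1, 1\]), a
#' normalized hydropathy h per residue (in \[0, 1\], higher = more
#' hydrophobic), and the shift-attenuation weight w (in \[0, 1\]) applied
#' to one-position-shifted partner terms. Objects are value-immutable in
#' the usual R sense: scoring the same pair twice with the same object
#' yields identical results.
#'
#' @slot charge named numeric, one signed charge per standard residue.
#' @slot hydropathy named numeric, one value in \[0, 1\] per residue.
#' @slot shiftWeight numeric(1) in \[0, 1\].
#'
#' @seealso [chemicalScales()], [loadScales()]
#' @export
setClass("ChemicalScales",
         slots = c(charge = "numeric",
                   hydropathy = "numeric",
                   shiftWeight = "numeric"))

setValidity("ChemicalScales", function(object) {
    msgs <- character(0)
    for (sl in c("charge", "hydropathy")) {
        v <- slot(object, sl)
        missing <- setdiff(AA_STANDARD20, names(v))
        if (length(missing))
            msgs <- c(msgs, sprintf("%s table missing residue(s): %s",
                                    sl, paste(missing, collapse = ", ")))
    }
    q <- object@charge
    bad <- names(q)[!is.na(q) & (q < -1 | q > 1)]
    if (length(bad))
        msgs <- c(msgs, sprintf("charge outside [-1, 1] for residue(s): %s",
                                paste(bad, collapse = ", ")))
    h <- object@hydropathy
    bad <- names(h)[!is.na(h) & (h < 0 | h > 1)]
    if (length(bad))
        msgs <- c(msgs, sprintf("hydropathy outside [0, 1] for residue(s): %s",
                                paste(bad, collapse = ", ")))
    if (anyNA(q) || anyNA(h))
        msgs <- c(msgs, "NA values in scale tables")
    w <- object@shiftWeight
    if (length(w) != 1L || is.na(w) || w < 0 || w > 1)
        msgs <- c(msgs, "shiftWeight must be a single value in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' GeneSegmentSet: a validated V/J gene-segment reference
#'
#' A `DataFrame` subclass with one row per TCR V or J gene segment and
#' columns `name`, `locus` (TRA/TRB), `kind` (V/J), `nt_sequence`,
#' `anchor` (0-based start of the conserved-motif codon: the Cys codon
#' for V segments, the Phe/Trp codon of the F/W-G-x-G motif for J
#' segments) and `frame` (reading-frame offset of the anchor codon).
#'
#' Validity enforces the nucleotide alphabet, that the anchor codon lies
#' inside the sequence, and that it translates to C (V) or F/W (J).
#'
#' @seealso [geneSegmentSet()], [toySegmentLibrary()], [readSegmentFasta()]
#' @export
setClass("GeneSegmentSet", contains = "DFrame")

setValidity("GeneSegmentSet", function(object) {
    req <- c("name", "locus", "kind", "nt_sequence", "anchor", "frame")
    missing <- setdiff(req, colnames(object))
    if (length(missing))
        return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    if (nrow(object) == 0L) return(TRUE)
    msgs <- character(0)
    if (!all(object$locus %in% c("TRA", "TRB")))
        msgs <- c(msgs, "locus must be TRA or TRB")
    if (!all(object$kind %in% c("V", "J")))
        msgs <- c(msgs, "kind must be V or J")
    if (any(grepl("[^ACGT]", object$nt_sequence)))
        msgs <- c(msgs, "nt_sequence alphabet must be A/C/G/T")
    len <- nchar(object$nt_sequence)
    if (any(object$anchor < 0L | object$anchor + 3L > len))
        msgs <- c(msgs, "anchor codon must lie within nt_sequence")
    aa <- vapply(seq_len(nrow(object)), function(i) {
        codon <- substr(object$nt_sequence[i], object$anchor[i] + 1L,
                        object$anchor[i] + 3L)
        translateCodon(codon)
    }, character(1))
    isV <- object$kind == "V"
    if (any(isV & aa != "C"))
        msgs <- c(msgs, sprintf("V anchor codon must encode C (offending: %s)",
                                paste(object$name[isV & aa != "C"], collapse = ", ")))
    isJ <- object$kind == "J"
    if (any(isJ & !aa %in% c("F", "W")))
        msgs <- c(msgs, sprintf("J anchor codon must encode F or W (offending: %s)",
                                paste(object$name[isJ & !aa %in% c("F", "W")],
                                      collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' CohortReport: structured results of the cohort analysis
#'
#' Produced by [runCohortAnalysis()]. Mirrors the report shape of a
#' median-split survival study: per-group Kaplan-Meier summaries and
#' logrank test, univariate and bivariate Cox fits, the zero-expression
#' odds ratio, the methylation t-test and per-gene Pearson correlations
#' between the complementarity score and expression.
#'
#' @slot samples joined per-sample table including the `group` column.
#' @slot km list: per-group n, events, median survival, logrank chisq + p.
#' @slot coxUnivariate data.frame: term, exp_beta, p, n.
#' @slot coxBivariate data.frame: one row per term of each bivariate fit.
#' @slot oddsRatio list: 2x2 table, per-group zero proportions, OR, p.
#' @slot methylation list: group means, t, df, p.
#' @slot correlations data.frame: gene, r, p, p_bh, n.
#' @slot missingSections character: names of sections skipped for lack
#'   of input (e.g. "methylation").
#' @export
setClass("CohortReport",
         slots = c(samples = "data.frame",
                   km = "list",
                   coxUnivariate = "data.frame",
                   coxBivariate = "data.frame",
                   oddsRatio = "list",
                   methylation = "list",
                   correlations = "data.frame",
                   missingSections = "character"))

setValidity("CohortReport", function(object) {
    ps <- c(object@km$logrank_p, object@coxUnivariate$p,
            object@coxBivariate$p, object@oddsRatio$p,
            object@methylation$p, object@correlations$p)
    ps <- ps[!is.na(ps)]
    if (length(ps) && any(ps < 0 | ps > 1))
        return("all p-values must lie in [0, 1]")
    hr <- c(object@coxUnivariate$exp_beta, object@coxBivariate$exp_beta)
    hr <- hr[!is.na(hr)]
    if (length(hr) && any(hr <= 0))
        return("Exp(beta) must be positive")
    TRUE
})
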