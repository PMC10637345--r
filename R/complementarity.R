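## CDR3-antigen chemical complementarity scoring.
##
## The score of a CDR3 placed ungapped at a given offset in an antigen is
## the sum of per-residue pair terms with its direct partners plus
## w times the terms with the two one-position-shifted partners
## (neighbors falling off the antigen contribute nothing). The reported
## CS for a pair is the maximum over all full-overlap offsets.

#' Electrostatic pair term
#'
#' Attraction term `-q(a) * q(b)`: positive for oppositely charged
#' residues, negative for like charges, zero when either is neutral.
#'
#' @param a,b single residues (one-letter code).
#' @param scales a [ChemicalScales-class] object.
#' @return numeric(1) unitless term.
#' @examples
#' electroPairTerm("K", "E", chemicalScales())  # +1
#' @export
electroPairTerm <- function(a, b, scales = chemicalScales()) {
    q <- charges(scales)
    aaResidues(a, "residue a"); aaResidues(b, "residue b")
    unname(-q[[a]] * q[[b]])
}

#' Hydropathy pair term
#'
#' Product `h(a) * h(b)` of normalized hydropathies: both-hydrophobic
#' pairs score high, any hydrophilic partner pulls the term toward 0.
#'
#' @inheritParams electroPairTerm
#' @return numeric(1) unitless term.
#' @export
hydroPairTerm <- function(a, b, scales = chemicalScales()) {
    h <- hydropathies(scales)
    aaResidues(a, "residue a"); aaResidues(b, "residue b")
    unname(h[[a]] * h[[b]])
}

## Per-residue numeric encodings for a sequence.
.encode <- function(res, map) unname(map[res])

## Cross-correlation C(m) = sum_i term(c_i, t_{m+i}) for m in
## [-1, La-Lc+1], computed on a zero-padded antigen encoding so that
## out-of-bounds partners contribute nothing. `sign` is -1 for the
## electrostatic term (attraction) and +1 for hydropathy.
.crossCorr <- function(cv, tv, sign) {
    Lc <- length(cv); La <- length(tv)
    tpad <- c(0, 0, tv, 0, 0)  # index m+i maps to tpad[m+i+3] (m from -2)
    ms <- seq(-1L, La - Lc + 1L)
    out <- numeric(length(ms))
    for (i in seq_len(Lc)) {
        out <- out + cv[i] * tpad[ms + i + 2L]
    }
    sign * out
}

## Per-offset score profile S(off), off = 0..La-Lc (returned 1-indexed).
## S(off) = C(off) + w * (C(off-1) + C(off+1)).
.offsetProfile <- function(cv, tv, sign, w) {
    cc <- .crossCorr(cv, tv, sign)          # indices: m = -1 .. La-Lc+1
    n <- length(cc) - 2L                    # number of admissible offsets
    idx <- seq_len(n) + 1L                  # position of m = 0..La-Lc in cc
    cc[idx] + w * (cc[idx - 1L] + cc[idx + 1L])
}

.pairProfiles <- function(cdr3, antigenSeq, scales) {
    cres <- aaResidues(cdr3, "cdr3")
    tres <- aaResidues(antigenSeq, "antigen")
    if (length(cres) > length(tres))
        stop("cdr3 is longer than the antigen: full overlap of the CDR3 ",
             "within the antigen is required", call. = FALSE)
    w <- shiftWeight(scales)
    list(electro = .offsetProfile(.encode(cres, charges(scales)),
                                  .encode(tres, charges(scales)), -1, w),
         hydro = .offsetProfile(.encode(cres, hydropathies(scales)),
                                .encode(tres, hydropathies(scales)), 1, w))
}

#' Per-offset complementarity score
#'
#' Score of placing `cdr3` at a single 0-based `offset` within the
#' antigen: the direct-partner terms plus `shiftWeight(scales)` times
#' the terms against the two one-position-shifted partners, with
#' neighbor terms skipped where the neighbor index falls outside the
#' antigen.
#'
#' @param cdr3 CDR3 amino-acid string.
#' @param antigen antigen amino-acid string (or named length-1 vector).
#' @param offset 0-based offset, in `[0, nchar(antigen) - nchar(cdr3)]`.
#' @param term `"electro"` or `"hydro"`.
#' @param scales a [ChemicalScales-class] object.
#' @return numeric(1) unitless per-offset score.
#' @examples
#' perOffsetScore("K", "AEA", 1, "electro")  # +1
#' perOffsetScore("K", "EKE", 1, "electro")  # 0: -1 direct, +1 from shifts
#' @export
perOffsetScore <- function(cdr3, antigen, offset,
                           term = c("electro", "hydro"),
                           scales = chemicalScales()) {
    term <- match.arg(term)
    antigen <- asAntigenVector(antigen)[[1]]
    maxOff <- nchar(antigen) - nchar(cdr3)
    if (length(offset) != 1L || is.na(offset) || offset < 0 || offset > maxOff)
        stop(sprintf("offset must lie in [0, %d]", maxOff), call. = FALSE)
    prof <- .pairProfiles(cdr3, antigen, scales)[[term]]
    prof[[offset + 1L]]
}

## z-standardize a profile given batch mean/sd; a degenerate batch
## (sd = 0 or a single value) standardizes to all-zero.
.zstd <- function(x, mu, sdev) {
    if (!is.finite(sdev) || sdev == 0) return(rep(0, length(x)))
    (x - mu) / sdev
}

.bestOffset <- function(prof) which.max(prof) - 1L  # ties -> smallest offset

#' Score one CDR3-antigen pair
#'
#' Evaluates the per-offset electrostatic and hydropathy scores at every
#' admissible offset and retains the best of each. The Combo CS is the
#' maximum over offsets of `z_e(offset) + z_h(offset)`, where the two
#' per-offset profiles are z-standardized by the batch mean and standard
#' deviation — here the batch is this pair's own offsets; in
#' [scoreRepertoire()] it is the pooled profiles of the whole batch.
#' `comboMethod = "sum"` instead maximizes the unstandardized sum.
#' Offset ties break toward the smallest offset.
#'
#' @inheritParams perOffsetScore
#' @param antigen antigen sequence; a named character of length 1, a
#'   one-element `AAStringSet`, or a plain string.
#' @param comboMethod `"zscore"` (default) or `"sum"`.
#' @return one-row data.frame: `cdr3`, `antigen_id`, `electro_cs`,
#'   `hydro_cs`, `combo_cs`, and the 0-based `best_offset_electro`,
#'   `best_offset_hydro`, `best_offset_combo`.
#' @examples
#' scorePair("CASSLKGF", ddx53Fragment())
#' @export
scorePair <- function(cdr3, antigen, scales = chemicalScales(),
                      comboMethod = c("zscore", "sum")) {
    comboMethod <- match.arg(comboMethod)
    antigen <- asAntigenVector(antigen)
    if (length(antigen) != 1L)
        stop("scorePair expects a single antigen; use scoreRepertoire ",
             "for batches", call. = FALSE)
    prof <- .pairProfiles(cdr3, antigen[[1]], scales)
    combo <- if (comboMethod == "zscore")
        .zstd(prof$electro, mean(prof$electro), stats::sd(prof$electro)) +
            .zstd(prof$hydro, mean(prof$hydro), stats::sd(prof$hydro))
    else prof$electro + prof$hydro
    data.frame(cdr3 = cdr3,
               antigen_id = names(antigen),
               electro_cs = max(prof$electro),
               hydro_cs = max(prof$hydro),
               combo_cs = max(combo),
               best_offset_electro = .bestOffset(prof$electro),
               best_offset_hydro = .bestOffset(prof$hydro),
               best_offset_combo = .bestOffset(combo),
               stringsAsFactors = FALSE)
}

#' Score a CDR3 repertoire against a panel of antigens
#'
#' One result per (CDR3, antigen) pair in input order (CDR3-major).
#' Raw `electro_cs`/`hydro_cs` equal the single-pair [scorePair()]
#' values; the Combo CS standardizes the per-offset profiles by the
#' mean and standard deviation pooled over all per-offset scores in the
#' batch, so Combo values are comparable across pairs. CDR3s longer
#' than an antigen are skipped with a warning rather than aborting the
#' batch.
#'
#' @param cdr3s data.frame with columns `sample_id`, `chain`, `cdr3_aa`
#'   (as read by [readCdr3Csv()]), or a character vector of CDR3s.
#' @param antigens named character vector, `AAStringSet`, or data.frame
#'   with `antigen_id`/`sequence`.
#' @inheritParams scorePair
#' @return data.frame with one row per scored pair: the CDR3 columns,
#'   `antigen_id`, the three CS values and their best offsets.
#' @export
scoreRepertoire <- function(cdr3s, antigens, scales = chemicalScales(),
                            comboMethod = c("zscore", "sum")) {
    comboMethod <- match.arg(comboMethod)
    if (is.character(cdr3s))
        cdr3s <- data.frame(sample_id = "sample1", chain = NA_character_,
                            cdr3_aa = cdr3s, stringsAsFactors = FALSE)
    if (!is.data.frame(cdr3s) || !"cdr3_aa" %in% colnames(cdr3s))
        stop("cdr3s must be a data.frame with a cdr3_aa column", call. = FALSE)
    if (nrow(cdr3s) == 0L)
        stop("empty CDR3 input", call. = FALSE)
    antigens <- asAntigenVector(antigens)
    if (length(antigens) == 0L)
        stop("empty antigen input", call. = FALSE)

    rows <- list(); profs <- list(); k <- 0L
    for (i in seq_len(nrow(cdr3s))) {
        for (j in seq_along(antigens)) {
            if (nchar(cdr3s$cdr3_aa[i]) > nchar(antigens[[j]])) {
                warning(sprintf("skipping CDR3 '%s' (longer than antigen '%s')",
                                cdr3s$cdr3_aa[i], names(antigens)[j]),
                        call. = FALSE)
                next
            }
            k <- k + 1L
            profs[[k]] <- .pairProfiles(cdr3s$cdr3_aa[i], antigens[[j]], scales)
            rows[[k]] <- cbind(cdr3s[i, , drop = FALSE],
                               data.frame(antigen_id = names(antigens)[j],
                                          stringsAsFactors = FALSE))
        }
    }
    if (k == 0L)
        stop("no scoreable CDR3-antigen pairs in the batch", call. = FALSE)
    allE <- unlist(lapply(profs, `[[`, "electro"))
    allH <- unlist(lapply(profs, `[[`, "hydro"))
    muE <- mean(allE); sdE <- stats::sd(allE)
    muH <- mean(allH); sdH <- stats::sd(allH)
    out <- do.call(rbind, lapply(seq_len(k), function(m) {
        p <- profs[[m]]
        combo <- if (comboMethod == "zscore")
            .zstd(p$electro, muE, sdE) + .zstd(p$hydro, muH, sdH)
        else p$electro + p$hydro
        cbind(rows[[m]],
              data.frame(electro_cs = max(p$electro),
                         hydro_cs = max(p$hydro),
                         combo_cs = max(combo),
                         best_offset_electro = .bestOffset(p$electro),
                         best_offset_hydro = .bestOffset(p$hydro),
                         best_offset_combo = .bestOffset(combo),
                         stringsAsFactors = FALSE))
    }))
    rownames(out) <- NULL
    out
}

#' Collapse pair-level scores to one CS per sample
#'
#' Summarizes `combo_cs` across each sample's CDR3s for a single
#' antigen. The default summary is the mean; `max` and `sum` are
#' available. Mixing antigens in one call is an error — aggregate per
#' antigen.
#'
#' @param results data.frame from [scoreRepertoire()] restricted to one
#'   antigen.
#' @param method `"mean"`, `"max"` or `"sum"`.
#' @param value column to aggregate (default `"combo_cs"`).
#' @return data.frame: `sample_id`, `antigen_id`, `cs`, `n_cdr3`.
#' @export
aggregateSampleCS <- function(results, method = c("mean", "max", "sum"),
                              value = "combo_cs") {
    method <- match.arg(method)
    if (!is.data.frame(results) || nrow(results) == 0L)
        stop("empty results input", call. = FALSE)
    if (length(unique(results$antigen_id)) != 1L)
        stop("results mix multiple antigens; aggregate one antigen at a time",
             call. = FALSE)
    f <- switch(method, mean = mean, max = max, sum = sum)
    agg <- stats::aggregate(results[[value]],
                            by = list(sample_id = results$sample_id),
                            FUN = f)
    n <- stats::aggregate(results[[value]],
                          by = list(sample_id = results$sample_id),
                          FUN = length)
    out <- data.frame(sample_id = agg$sample_id,
                      antigen_id = results$antigen_id[1],
                      cs = agg$x,
                      n_cdr3 = n$x,
                      stringsAsFactors = FALSE)
    out[order(out$sample_id), , drop = FALSE]
}

#' The published DDX53 peptide fragment
#'
#' The 60-residue DDX53 (CAGE) peptide fragment used as the default
#' antigen throughout examples and the synthetic cohort.
#'
#' @return a named character vector of length 1 (`DDX53_fragment`).
#' @export
ddx53Fragment <- function() {
    c(DDX53_fragment =
      "MNNSVNLRSITYLVIDEADKMLDMEFEPQIRKILLDVRPDRQTVMTSATWPDTVRQLALS")
}
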