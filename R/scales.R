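## Chemical scales: residue charges, normalized hydropathy, shift weight.

## Kyte-Doolittle hydropathy, the canonical table.
KD_HYDROPATHY <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
                   L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

DEFAULT_CHARGE <- c(A = 0, R = 1, N = 0, D = -1, C = 0,
                    Q = 0, E = -1, G = 0, H = 0.5, I = 0,
                    L = 0, K = 1, M = 0, F = 0, P = 0,
                    S = 0, T = 0, W = 0, Y = 0, V = 0)

#' Construct a ChemicalScales object
#'
#' Defaults encode the conventions used throughout the package: unit
#' charges for D/E (-1) and K/R (+1), +0.5 for histidine (partially
#' protonated at physiologic pH), zero otherwise; hydropathy is the
#' Kyte-Doolittle table min-max rescaled to \[0, 1\] (so I = 1, R = 0),
#' i.e. a normalized scale in which higher values mean more hydrophobic;
#' and shift weight w = 0.5 for the one-position-shifted partner terms.
#'
#' @param charge named numeric over the 20 standard residues, in \[-1, 1\].
#' @param hydropathy named numeric over the 20 standard residues, in \[0, 1\].
#' @param shiftWeight numeric(1) in \[0, 1\]; weight of the +/-1-offset terms.
#' @return a validated [ChemicalScales-class] object.
#' @examples
#' sc <- chemicalScales()
#' charges(sc)[c("K", "E", "A")]
#' hydropathies(sc)[c("I", "R")]
#' @export
chemicalScales <- function(charge = DEFAULT_CHARGE,
                           hydropathy = normalizeHydropathy(KD_HYDROPATHY),
                           shiftWeight = 0.5) {
    new("ChemicalScales",
        charge = charge[AA_STANDARD20],
        hydropathy = hydropathy[AA_STANDARD20],
        shiftWeight = as.numeric(shiftWeight))
}

#' Min-max normalize a raw hydropathy table to \[0, 1\]
#'
#' @param x named numeric of raw hydropathy values.
#' @return named numeric rescaled so the minimum maps to 0 and the
#'   maximum to 1.
#' @export
normalizeHydropathy <- function(x) {
    (x - min(x)) / (max(x) - min(x))
}

#' Load chemical scales from a key-value text file
#'
#' The file format is whitespace-separated lines of the form
#' `charge <residue> <value>`, `hydropathy <residue> <value>` or
#' `shift_weight <value>`; blank lines and lines starting with `#` are
#' ignored. A supplied charge or hydropathy table must cover all 20
#' standard residues. With `path = NULL` the defaults of
#' [chemicalScales()] are returned.
#'
#' @param path path to a scale file, or `NULL` for defaults.
#' @return a [ChemicalScales-class] object.
#' @export
loadScales <- function(path = NULL) {
    if (is.null(path)) return(chemicalScales())
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    charge <- DEFAULT_CHARGE
    hydro <- normalizeHydropathy(KD_HYDROPATHY)
    sawCharge <- sawHydro <- FALSE
    chargeIn <- hydroIn <- c()
    w <- 0.5
    for (ln in lines) {
        tok <- strsplit(ln, "[[:space:],]+")[[1]]
        key <- tolower(tok[1])
        if (key == "shift_weight") {
            w <- as.numeric(tok[2])
        } else if (key %in% c("charge", "hydropathy")) {
            res <- toupper(tok[2])
            val <- as.numeric(tok[3])
            if (!res %in% AA_STANDARD20)
                stop("scale file: unknown residue '", res, "'", call. = FALSE)
            if (is.na(val))
                stop("scale file: non-numeric value for residue '", res, "'",
                     call. = FALSE)
            if (key == "charge") {
                if (val < -1 || val > 1)
                    stop("scale file: charge for residue '", res,
                         "' outside [-1, 1]", call. = FALSE)
                sawCharge <- TRUE; chargeIn[res] <- val
            } else {
                if (val < 0 || val > 1)
                    stop("scale file: hydropathy for residue '", res,
                         "' outside [0, 1]", call. = FALSE)
                sawHydro <- TRUE; hydroIn[res] <- val
            }
        } else {
            stop("scale file: unrecognized key '", tok[1], "'", call. = FALSE)
        }
    }
    if (sawCharge) {
        missing <- setdiff(AA_STANDARD20, names(chargeIn))
        if (length(missing))
            stop("scale file: charge table missing residue(s): ",
                 paste(missing, collapse = ", "), call. = FALSE)
        charge <- chargeIn
    }
    if (sawHydro) {
        missing <- setdiff(AA_STANDARD20, names(hydroIn))
        if (length(missing))
            stop("scale file: hydropathy table missing residue(s): ",
                 paste(missing, collapse = ", "), call. = FALSE)
        hydro <- hydroIn
    }
    chemicalScales(charge = charge, hydropathy = hydro, shiftWeight = w)
}

#' @describeIn chemicalScales charge map accessor (named numeric).
#' @param scales a [ChemicalScales-class] object.
#' @export
charges <- function(scales) scales@charge

#' @describeIn chemicalScales hydropathy map accessor (named numeric).
#' @export
hydropathies <- function(scales) scales@hydropathy

#' @describeIn chemicalScales shift-attenuation weight accessor.
#' @export
shiftWeight <- function(scales) scales@shiftWeight

setMethod("show", "ChemicalScales", function(object) {
    cat("ChemicalScales\n")
    cat("  charged residues:",
        paste(sprintf("%s=%+.2g", names(object@charge)[object@charge != 0],
                      object@charge[object@charge != 0]), collapse = " "), "\n")
    cat(sprintf("  hydropathy: [%.2f, %.2f], max at %s\n",
                min(object@hydropathy), max(object@hydropathy),
                names(object@hydropathy)[which.max(object@hydropathy)]))
    cat(sprintf("  shift weight w = %g\n", object@shiftWeight))
})
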