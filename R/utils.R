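## Internal helpers shared across modules.

#' @importFrom Biostrings GENETIC_CODE
translateCodon <- function(codon) {
    aa <- Biostrings::GENETIC_CODE[[codon]]
    if (is.null(aa)) "X" else aa
}

## Translate an in-frame nucleotide string via the standard genetic code.
## Stops become "*"; codons with N become "X". Length must be divisible by 3.
translateNt <- function(nt) {
    stopifnot(nchar(nt) %% 3 == 0)
    if (nchar(nt) == 0L) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                       if.fuzzy.codon = "X"))
}

## Split an amino-acid string into residues, erroring on non-standard ones.
aaResidues <- function(seq, what = "sequence") {
    if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
        stop(what, " must be a non-empty character string", call. = FALSE)
    res <- strsplit(seq, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(res), AA_STANDARD20)
    if (length(bad))
        stop(what, " contains non-standard residue(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    res
}

isValidCdr3 <- function(aa, minLen = 5L, maxLen = 35L) {
    n <- nchar(aa)
    n >= minLen && n <= maxLen &&
        !grepl(sprintf("[^%s]", paste(AA_STANDARD20, collapse = "")), aa) &&
        substr(aa, 1L, 1L) == "C" &&
        substr(aa, n, n) %in% c("F", "W")
}

## Coerce a single-antigen argument (character, named character, AAStringSet,
## or data.frame with antigen_id/sequence) to a named character vector.
asAntigenVector <- function(antigens) {
    if (is(antigens, "AAStringSet")) {
        out <- as.character(antigens)
        if (is.null(names(out)))
            names(out) <- paste0("antigen", seq_along(out))
    } else if (is.data.frame(antigens)) {
        if (!all(c("antigen_id", "sequence") %in% colnames(antigens)))
            stop("antigen table must have columns antigen_id and sequence",
                 call. = FALSE)
        out <- antigens$sequence
        names(out) <- antigens$antigen_id
    } else if (is.character(antigens)) {
        out <- antigens
        if (is.null(names(out)))
            names(out) <- paste0("antigen", seq_along(out))
    } else {
        stop("unsupported antigen representation: ", class(antigens)[1],
             call. = FALSE)
    }
    for (i in seq_along(out)) aaResidues(out[[i]], sprintf("antigen '%s'", names(out)[i]))
    out
}

reverseComplement1 <- function(nt) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}
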