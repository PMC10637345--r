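## V/J gene-segment reference handling.

#' Construct a GeneSegmentSet
#'
#' @param name segment names.
#' @param locus `"TRA"` or `"TRB"` per segment.
#' @param kind `"V"` or `"J"` per segment.
#' @param nt_sequence nucleotide sequences (A/C/G/T).
#' @param anchor 0-based start of the conserved-motif codon (Cys for V,
#'   Phe/Trp for J).
#' @param frame reading-frame offset of the anchor codon (0 in the
#'   bundled toy library; kept for references whose anchor annotation is
#'   relative to a larger frame).
#' @return a validated [GeneSegmentSet-class].
#' @export
geneSegmentSet <- function(name, locus, kind, nt_sequence, anchor, frame = 0L) {
    new("GeneSegmentSet",
        DataFrame(name = as.character(name),
                  locus = as.character(locus),
                  kind = as.character(kind),
                  nt_sequence = toupper(as.character(nt_sequence)),
                  anchor = as.integer(anchor),
                  frame = as.integer(rep_len(frame, length(name)))))
}

#' Bundled toy V/J reference library
#'
#' Four V and four J segments per locus (TRA, TRB) with realistic
#' conserved anchors: each V ends in a Cys codon three nucleotides
#' before its 3' end; each J starts its anchor Phe/Trp codon at
#' position 3 (0-based), followed by a G-G-x-G-G run echoing the
#' F/W-G-x-G motif. Anchor seed windows were chosen mutually distant
#' (and distant from their reverse complements) so low-stringency seeds
#' do not cross-match between V and J. Not real IMGT alleles — a
#' deterministic synthetic stand-in for toy-scale work; load a real
#' reference with [readSegmentFasta()].
#'
#' @return a [GeneSegmentSet-class] with 16 segments.
#' @export
toySegmentLibrary <- function() {
    rows <- list(
        list("TRAV-toy-1", "TRA", "V", "AGAAGTCTTGGAGCGTCATGACTGGCAAGGTGTTAT", 30L),
        list("TRAV-toy-2", "TRA", "V", "CAGTTCGCTTTTTGAGTGCTAACTATCGGTTGTTAG", 30L),
        list("TRAV-toy-3", "TRA", "V", "GGGCGATCTTAAAGTGTCTTATATTGACCTTGCGAG", 30L),
        list("TRAV-toy-4", "TRA", "V", "TAAAGCCGTCATAGTTTGGTTGTGTCGTCGTGTACC", 30L),
        list("TRAJ-toy-1", "TRA", "J", "TAGTTTGGCGGTTAATTATTTGTGCGTCAACAC", 3L),
        list("TRAJ-toy-2", "TRA", "J", "CAATGGGGTGGTCCAGATGGTGCAAGTATATCA", 3L),
        list("TRAJ-toy-3", "TRA", "J", "CCGTTCGGGGGATAACCCGCTTGTTTCGGGCCC", 3L),
        list("TRAJ-toy-4", "TRA", "J", "AGGTGGGGTGGGTATACGCGCAGTGTAGTCCAA", 3L),
        list("TRBV-toy-1", "TRB", "V", "GATATGATAGCGGGTCCAACAAAGGCCGACTGTTGA", 30L),
        list("TRBV-toy-2", "TRB", "V", "GTGTAACGGGCTATTATTGTTAAAAGGCTCTGTGAT", 30L),
        list("TRBV-toy-3", "TRB", "V", "CCTTTGGCGCCTAACGCCATTTTACCTAATTGTACC", 30L),
        list("TRBV-toy-4", "TRB", "V", "TTTAGTTAAGGTGGTGCGCAACGACATGCTTGTCGT", 30L),
        list("TRBJ-toy-1", "TRB", "J", "TGGTTCGGTGGACAATCGAAAACATTGCGGATA", 3L),
        list("TRBJ-toy-2", "TRB", "J", "AGATGGGGAGGCAGTTGCAATGCGGATCGAGAA", 3L),
        list("TRBJ-toy-3", "TRB", "J", "GCATTTGGCGGTTCATCTAAGCCGCTTTGAGGT", 3L),
        list("TRBJ-toy-4", "TRB", "J", "GTGTGGGGCGGACCGTTATCTCCGTATAAGAAC", 3L))
    geneSegmentSet(name = vapply(rows, `[[`, "", 1),
                   locus = vapply(rows, `[[`, "", 2),
                   kind = vapply(rows, `[[`, "", 3),
                   nt_sequence = vapply(rows, `[[`, "", 4),
                   anchor = vapply(rows, function(r) r[[5]], 1L))
}

#' Read a V/J segment reference from FASTA
#'
#' Header convention: `name|locus|kind|anchor|frame` with `anchor` the
#' 0-based start of the conserved-motif codon.
#'
#' @param path FASTA file path.
#' @return a [GeneSegmentSet-class].
#' @export
readSegmentFasta <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0L)
        stop("empty segment reference: ", path, call. = FALSE)
    fields <- strsplit(names(seqs), "|", fixed = TRUE)
    bad <- which(lengths(fields) < 4L)
    if (length(bad))
        stop("segment FASTA header must be name|locus|kind|anchor[|frame] ",
             "(record ", bad[1], ")", call. = FALSE)
    geneSegmentSet(name = vapply(fields, `[[`, "", 1),
                   locus = vapply(fields, `[[`, "", 2),
                   kind = vapply(fields, `[[`, "", 3),
                   nt_sequence = as.character(seqs),
                   anchor = as.integer(vapply(fields, `[[`, "", 4)),
                   frame = as.integer(vapply(fields, function(f)
                       if (length(f) >= 5L) f[[5]] else "0", "")))
}

#' Write a V/J segment reference to FASTA
#'
#' Inverse of [readSegmentFasta()].
#'
#' @param segments a [GeneSegmentSet-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeSegmentFasta <- function(segments, path) {
    seqs <- Biostrings::DNAStringSet(segments$nt_sequence)
    names(seqs) <- sprintf("%s|%s|%s|%d|%d", segments$name, segments$locus,
                           segments$kind, segments$anchor, segments$frame)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

## The anchor seed window of one segment: for V the k nucleotides ending
## at the anchor codon's 3' end; for J the k nucleotides starting at the
## anchor codon. Errors if the segment is too short for k.
segmentAnchorWindow <- function(seg, k) {
    len <- nchar(seg$nt_sequence)
    if (seg$kind == "V") {
        start <- seg$anchor + 3L - k + 1L      # 1-based
        if (start < 1L)
            stop(sprintf("seed length k=%d exceeds usable length of segment %s",
                         k, seg$name), call. = FALSE)
        list(window = substr(seg$nt_sequence, start, seg$anchor + 3L),
             anchorInWindow = k - 3L)          # 0-based anchor codon start
    } else {
        if (seg$anchor + k > len)
            stop(sprintf("seed length k=%d exceeds usable length of segment %s",
                         k, seg$name), call. = FALSE)
        list(window = substr(seg$nt_sequence, seg$anchor + 1L, seg$anchor + k),
             anchorInWindow = 0L)
    }
}
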