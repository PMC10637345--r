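## CDR3 recovery: low-stringency V/J seed scan, same-read V-J
## recombination calling, productivity filtering.

#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is chosen by extension (`.fastq`/`.fq` vs anything else);
#' qualities are ignored.
#'
#' @param path reads file.
#' @return a `DNAStringSet` named by read id.
#' @export
readReads <- function(path) {
    if (!file.exists(path))
        stop("cannot read input file: ", path, call. = FALSE)
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
        "fastq" else "fasta"
    reads <- tryCatch(Biostrings::readDNAStringSet(path, format = fmt),
                      error = function(e)
                          stop("failed to parse ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    names(reads) <- sub("\\s.*$", "", names(reads))
    reads
}

.asReadSet <- function(reads) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        return(readReads(reads))
    if (is.character(reads)) {
        out <- Biostrings::DNAStringSet(reads)
        if (is.null(names(out)) && length(out))
            names(out) <- paste0("read", seq_along(out))
        return(out)
    }
    if (is(reads, "DNAStringSet")) {
        if (is.null(names(reads)) && length(reads))
            names(reads) <- paste0("read", seq_along(reads))
        return(reads)
    }
    stop("reads must be a file path, character vector or DNAStringSet",
         call. = FALSE)
}

#' Low-stringency seed scan of reads against V/J anchor windows
#'
#' Matches each segment's length-`k` anchor window (the `k` nucleotides
#' ending at the Cys codon for V segments, starting at the Phe/Trp codon
#' for J segments) against every read on both strands, tolerating up to
#' `maxMismatch` mismatches. `N` never counts as a match. Hit
#' coordinates are reported on the forward read (0-based half-open);
#' `oanchor` gives the anchor-codon start on the read in the hit's own
#' orientation, which is what recombination calling consumes.
#'
#' @param reads file path, character vector or `DNAStringSet`.
#' @param segments a [GeneSegmentSet-class].
#' @param k seed window length (>= 8).
#' @param maxMismatch maximum mismatches tolerated in the window.
#' @return data.frame: `read_id`, `segment`, `locus`, `kind`, `strand`
#'   (+/-), `start`, `end` (forward read, 0-based half-open),
#'   `mismatches`, `oanchor`.
#' @export
seedScan <- function(reads, segments, k = 15L, maxMismatch = 3L) {
    reads <- .asReadSet(reads)
    if (!is(segments, "GeneSegmentSet") || nrow(segments) == 0L)
        stop("empty or invalid segment reference", call. = FALSE)
    if (k < 8L)
        stop("seed length k must be >= 8", call. = FALSE)
    empty <- data.frame(read_id = character(0), segment = character(0),
                        locus = character(0), kind = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), mismatches = integer(0),
                        oanchor = integer(0), stringsAsFactors = FALSE)
    if (length(reads) == 0L) return(empty)
    rcReads <- Biostrings::reverseComplement(reads)
    readLen <- Biostrings::width(reads)
    hits <- list(); h <- 0L
    for (i in seq_len(nrow(segments))) {
        seg <- as.list(segments[i, ])
        win <- segmentAnchorWindow(seg, k)
        pat <- Biostrings::DNAString(win$window)
        for (strand in c("+", "-")) {
            subj <- if (strand == "+") reads else rcReads
            ## cheap count pass first; position extraction only on the
            ## (rare) reads that carry a hit
            cnt <- Biostrings::vcountPattern(pat, subj,
                                             max.mismatch = maxMismatch,
                                             fixed = TRUE)
            cand <- which(cnt > 0L)
            if (!length(cand)) next
            m <- Biostrings::vmatchPattern(pat, subj[cand],
                                           max.mismatch = maxMismatch,
                                           fixed = TRUE)
            idx <- cand[rep(seq_along(cand), lengths(m))]
            if (!length(idx)) next
            starts1 <- unlist(lapply(m, IRanges::start))  # 1-based, oriented
            keep <- starts1 >= 1L & starts1 + k - 1L <= readLen[idx]
            idx <- idx[keep]; starts1 <- starts1[keep]
            if (!length(idx)) next
            mm <- vapply(seq_along(idx), function(j)
                Biostrings::neditStartingAt(pat, subj[[idx[j]]],
                                            starting.at = starts1[j]),
                integer(1))
            ostart <- starts1 - 1L                        # 0-based, oriented
            fstart <- if (strand == "+") ostart else readLen[idx] - (ostart + k)
            h <- h + 1L
            hits[[h]] <- data.frame(
                read_id = names(reads)[idx],
                segment = seg$name, locus = seg$locus, kind = seg$kind,
                strand = strand,
                start = fstart, end = fstart + k,
                mismatches = mm,
                oanchor = ostart + win$anchorInWindow,
                stringsAsFactors = FALSE)
        }
    }
    if (h == 0L) return(empty)
    out <- do.call(rbind, hits)
    out <- out[order(match(out$read_id, names(reads)), out$kind,
                     out$segment, out$strand, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Call a V-J recombination on one read
#'
#' Given a V hit and a J hit on the same read, same locus and same
#' orientation with the V anchor upstream of the J anchor, extracts the
#' nucleotide span from the V Cys codon through the J Phe/Trp codon
#' inclusive and translates it in the V frame. The call is productive
#' when the span length is divisible by 3 and the translation contains
#' no stop (and no ambiguous codon); `cdr3_aa` is set only then.
#'
#' @param read forward-read nucleotide string (or `DNAString`).
#' @param vHit,jHit one-row data.frames (or lists) as returned by
#'   [seedScan()].
#' @return one-row data.frame: `read_id`, `v_name`, `j_name`, `locus`,
#'   `strand`, `v_end`, `j_start` (0-based half-open window coordinates
#'   on the read in V->J orientation), `junction_nt`, `cdr3_aa`
#'   (NA unless productive), `productive`, `reason`.
#' @export
callRecombination <- function(read, vHit, jHit) {
    vHit <- as.list(vHit); jHit <- as.list(jHit)
    if (vHit$kind != "V" || jHit$kind != "J")
        stop("vHit must be a V hit and jHit a J hit", call. = FALSE)
    if (vHit$locus != jHit$locus)
        stop("cross-locus V-J pair: ", vHit$locus, " vs ", jHit$locus,
             call. = FALSE)
    if (vHit$strand != jHit$strand)
        stop("V and J hits lie on opposite strands", call. = FALSE)
    read <- as.character(read)
    oread <- if (vHit$strand == "+") read else reverseComplement1(read)
    vA <- vHit$oanchor; jA <- jHit$oanchor
    if (jA < vA + 3L)
        stop("malformed junction: V and J anchors overlap", call. = FALSE)
    span <- substr(oread, vA + 1L, jA + 3L)
    junction <- substr(oread, vA + 4L, jA)
    productive <- FALSE; aa <- NA_character_; reason <- "productive"
    if (nchar(span) %% 3 != 0) {
        reason <- "out-of-frame junction"
    } else {
        tr <- translateNt(span)
        if (grepl("*", tr, fixed = TRUE)) {
            reason <- "stop codon"
        } else if (grepl("X", tr, fixed = TRUE)) {
            reason <- "ambiguous codon"
        } else {
            productive <- TRUE
            aa <- tr
        }
    }
    k <- vHit$end - vHit$start
    ovstart <- if (vHit$strand == "+") vHit$start
               else nchar(read) - vHit$end
    ojstart <- if (jHit$strand == "+") jHit$start
               else nchar(read) - jHit$end
    data.frame(read_id = if (!is.null(vHit$read_id)) vHit$read_id else NA_character_,
               v_name = vHit$segment, j_name = jHit$segment,
               locus = vHit$locus, strand = vHit$strand,
               v_end = ovstart + k, j_start = ojstart,
               junction_nt = junction,
               cdr3_aa = aa, productive = productive, reason = reason,
               stringsAsFactors = FALSE)
}

#' Recover a productive CDR3 repertoire from reads
#'
#' Full pipeline: [seedScan()] of all reads against the reference, then
#' [callRecombination()] on every same-locus, same-orientation V-J hit
#' pair with V upstream of J, keeping calls that are productive and
#' satisfy the CDR3 contract (starts with C, ends with F/W, no stop,
#' length within `[minLen, maxLen]`). When one read supports several
#' valid calls the longest CDR3 is kept (ties broken lexicographically,
#' then by segment names) so each read contributes at most one record.
#'
#' Sample ids are taken from read names as the prefix before
#' `sampleDelim` when present, else `sampleId`.
#'
#' @inheritParams seedScan
#' @param minLen,maxLen CDR3 amino-acid length bounds.
#' @param sampleDelim delimiter separating sample id from read id in
#'   read names.
#' @param sampleId fallback sample id for unprefixed read names.
#' @return list with `cdr3` (data.frame: `sample_id`, `chain`,
#'   `cdr3_aa`, `source_read`) and `counts` (named integer summary).
#' @export
recoverRepertoire <- function(reads, segments, k = 15L, maxMismatch = 3L,
                              minLen = 5L, maxLen = 35L,
                              sampleDelim = "|", sampleId = "sample1") {
    reads <- .asReadSet(reads)
    if (!is(segments, "GeneSegmentSet") || nrow(segments) == 0L)
        stop("empty segment reference", call. = FALSE)
    if (!any(segments$kind == "V") || !any(segments$kind == "J"))
        stop("segment reference must contain at least one V and one J",
             call. = FALSE)
    emptyCdr3 <- data.frame(sample_id = character(0), chain = character(0),
                            cdr3_aa = character(0), source_read = character(0),
                            stringsAsFactors = FALSE)
    counts <- c(reads_scanned = length(reads), reads_with_hits = 0L,
                candidate_pairs = 0L, calls = 0L, productive_calls = 0L,
                cdr3_records = 0L)
    if (length(reads) == 0L)
        return(list(cdr3 = emptyCdr3, counts = counts))
    hits <- seedScan(reads, segments, k = k, maxMismatch = maxMismatch)
    byRead <- split(hits, hits$read_id)
    counts["reads_with_hits"] <- length(byRead)
    recs <- list(); r <- 0L
    readChar <- as.character(reads)
    for (rid in names(reads)) {
        h <- byRead[[rid]]
        if (is.null(h)) next
        vs <- h[h$kind == "V", , drop = FALSE]
        js <- h[h$kind == "J", , drop = FALSE]
        if (nrow(vs) == 0L || nrow(js) == 0L) next
        best <- NULL
        for (iv in seq_len(nrow(vs))) {
            for (ij in seq_len(nrow(js))) {
                vh <- vs[iv, ]; jh <- js[ij, ]
                if (vh$locus != jh$locus || vh$strand != jh$strand) next
                if (jh$oanchor < vh$oanchor + 3L) next
                counts["candidate_pairs"] <- counts["candidate_pairs"] + 1L
                call <- callRecombination(readChar[[rid]], vh, jh)
                counts["calls"] <- counts["calls"] + 1L
                if (!call$productive) next
                counts["productive_calls"] <- counts["productive_calls"] + 1L
                if (!isValidCdr3(call$cdr3_aa, minLen, maxLen)) next
                if (is.null(best) ||
                    nchar(call$cdr3_aa) > nchar(best$cdr3_aa) ||
                    (nchar(call$cdr3_aa) == nchar(best$cdr3_aa) &&
                     (call$cdr3_aa < best$cdr3_aa ||
                      (call$cdr3_aa == best$cdr3_aa &&
                       paste(call$v_name, call$j_name) <
                       paste(best$v_name, best$j_name)))))
                    best <- call
            }
        }
        if (!is.null(best)) {
            r <- r + 1L
            sid <- if (grepl(sampleDelim, rid, fixed = TRUE))
                strsplit(rid, sampleDelim, fixed = TRUE)[[1]][1] else sampleId
            recs[[r]] <- data.frame(sample_id = sid, chain = best$locus,
                                    cdr3_aa = best$cdr3_aa, source_read = rid,
                                    stringsAsFactors = FALSE)
        }
    }
    cdr3 <- if (r) do.call(rbind, recs) else emptyCdr3
    cdr3 <- cdr3[order(match(cdr3$source_read, names(reads))), , drop = FALSE]
    rownames(cdr3) <- NULL
    counts["cdr3_records"] <- nrow(cdr3)
    list(cdr3 = cdr3, counts = counts)
}
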