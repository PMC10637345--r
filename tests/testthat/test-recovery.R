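segs <- toySegmentLibrary()

## Build a read around a V-J join with a chosen junction (in the V frame).
buildJoin <- function(v, j, junctionNt, leftPad = "", rightPad = "") {
    vSeq <- segs$nt_sequence[segs$name == v]
    vAnchor <- segs$anchor[segs$name == v]
    jSeq <- segs$nt_sequence[segs$name == j]
    jAnchor <- segs$anchor[segs$name == j]
    paste0(leftPad, substr(vSeq, 1, vAnchor + 3), junctionNt,
           substr(jSeq, jAnchor + 1, nchar(jSeq)), rightPad)
}

test_that("the toy library satisfies the anchor contract", {
    expect_true(validObject(segs))
    expect_equal(sum(segs$kind == "V" & segs$locus == "TRA"), 4L)
    expect_equal(sum(segs$kind == "J" & segs$locus == "TRB"), 4L)
})

test_that("seed scan finds planted anchor windows on both strands", {
    read <- buildJoin("TRAV-toy-1", "TRAJ-toy-1", "GCAAGCAGC")
    hits <- seedScan(read, segs)
    vhit <- hits[hits$segment == "TRAV-toy-1", ]
    jhit <- hits[hits$segment == "TRAJ-toy-1", ]
    expect_equal(nrow(vhit), 1L)
    expect_equal(vhit$mismatches, 0L)
    expect_equal(vhit$strand, "+")
    expect_equal(nrow(jhit), 1L)
    ## reverse-complemented read: same windows on the minus strand,
    ## coordinates still on the forward read
    rcHits <- seedScan(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(read)), segs)
    rcV <- rcHits[rcHits$segment == "TRAV-toy-1", ]
    expect_equal(rcV$strand, "-")
    expect_equal(rcV$start, nchar(read) - vhit$end)
    ## all-N read yields nothing
    expect_equal(nrow(seedScan(strrep("N", 100), segs)), 0L)
    expect_error(seedScan(read, segs, k = 40L), "k=40")
})

test_that("seed hits grow monotonically with the mismatch allowance", {
    set.seed(31)
    cfg <- simulationConfig(read_depth = 60, planted_productive = 40,
                            planted_frameshift = 0, planted_stop = 0,
                            window_mismatches = 2L)
    rd <- genReads(cfg, segs)
    key <- function(h) paste(h$read_id, h$segment, h$strand, h$start)
    h2 <- seedScan(rd$reads, segs, maxMismatch = 2L)
    h3 <- seedScan(rd$reads, segs, maxMismatch = 3L)
    h4 <- seedScan(rd$reads, segs, maxMismatch = 4L)
    expect_true(all(key(h2) %in% key(h3)))
    expect_true(all(key(h3) %in% key(h4)))
})

test_that("seed scan recalls every planted window at <= max mismatches", {
    cfg <- simulationConfig(read_depth = 500, planted_productive = 200,
                            planted_frameshift = 0, planted_stop = 0,
                            window_mismatches = 3L, seed = 5L)
    rd <- genReads(cfg, segs)
    planted <- rd$truth[rd$truth$category == "productive", ]
    hits <- seedScan(rd$reads, segs, maxMismatch = 3L)
    vFound <- hits$read_id[hits$kind == "V"]
    jFound <- hits$read_id[hits$kind == "J"]
    expect_true(all(planted$read_id %in% vFound))
    expect_true(all(planted$read_id %in% jFound))
})

test_that("recombination calls translate the junction span in the V frame", {
    junction <- "GCAAGCAGC"  # ASS
    read <- buildJoin("TRBV-toy-1", "TRBJ-toy-1", junction)
    hits <- seedScan(read, segs)
    vh <- hits[hits$segment == "TRBV-toy-1", ]
    jh <- hits[hits$segment == "TRBJ-toy-1", ]
    call <- callRecombination(read, vh, jh)
    expect_true(call$productive)
    ## oracle: direct standard-genetic-code translation of the span
    vSeq <- segs$nt_sequence[segs$name == "TRBV-toy-1"]
    jSeq <- segs$nt_sequence[segs$name == "TRBJ-toy-1"]
    jAnchor <- segs$anchor[segs$name == "TRBJ-toy-1"]
    span <- paste0(substr(vSeq, 31, 33), junction,
                   substr(jSeq, jAnchor + 1, jAnchor + 3))
    expect_equal(call$cdr3_aa, handTranslate(span))
    expect_match(call$cdr3_aa, "^C")
    expect_match(call$cdr3_aa, "[FW]$")
    expect_equal(call$junction_nt, junction)
    expect_lte(call$v_end, call$j_start)

    ## one inserted junction nucleotide: frameshift
    fs <- buildJoin("TRBV-toy-1", "TRBJ-toy-1", paste0("G", junction))
    hitsFs <- seedScan(fs, segs)
    callFs <- callRecombination(fs, hitsFs[hitsFs$segment == "TRBV-toy-1", ],
                                hitsFs[hitsFs$segment == "TRBJ-toy-1", ])
    expect_false(callFs$productive)
    expect_equal(callFs$reason, "out-of-frame junction")
    expect_true(is.na(callFs$cdr3_aa))

    ## in-frame TAA: stop codon
    st <- buildJoin("TRBV-toy-1", "TRBJ-toy-1", paste0("TAA", junction))
    hitsSt <- seedScan(st, segs)
    callSt <- callRecombination(st, hitsSt[hitsSt$segment == "TRBV-toy-1", ],
                                hitsSt[hitsSt$segment == "TRBJ-toy-1", ])
    expect_false(callSt$productive)
    expect_equal(callSt$reason, "stop codon")

    ## cross-locus pairing is an error, not a call
    xl <- buildJoin("TRAV-toy-1", "TRBJ-toy-1", junction)
    hitsXl <- seedScan(xl, segs)
    expect_error(callRecombination(xl,
                                   hitsXl[hitsXl$segment == "TRAV-toy-1", ],
                                   hitsXl[hitsXl$segment == "TRBJ-toy-1", ]),
                 "cross-locus")
})

test_that("repertoire recovery returns exactly the planted productive CDR3s", {
    cfg <- simulationConfig(read_depth = 800, planted_productive = 30,
                            planted_frameshift = 8, planted_stop = 8,
                            seed = 17L)
    rd <- genReads(cfg, segs)
    res <- recoverRepertoire(rd$reads, segs)
    planted <- rd$truth[rd$truth$category == "productive", ]
    expect_equal(sort(res$cdr3$cdr3_aa), sort(planted$cdr3_aa))
    expect_equal(sort(res$cdr3$source_read), sort(planted$read_id))
    ## every emitted record satisfies the CDR3 contract
    expect_true(all(grepl("^C", res$cdr3$cdr3_aa)))
    expect_true(all(grepl("[FW]$", res$cdr3$cdr3_aa)))
    expect_true(all(!grepl("\\*", res$cdr3$cdr3_aa)))
    expect_true(all(nchar(res$cdr3$cdr3_aa) >= 5))
    ## chain assignment matches the planted locus
    expect_equal(res$cdr3$chain[match(planted$read_id, res$cdr3$source_read)],
                 substr(planted$v_name, 1, 3))
})

test_that("zero reads give an empty repertoire with zero counts", {
    res <- recoverRepertoire(Biostrings::DNAStringSet(), segs)
    expect_equal(nrow(res$cdr3), 0L)
    expect_equal(unname(res$counts["reads_scanned"]), 0L)
    expect_error(recoverRepertoire("ACGT", segs[segs$kind == "V", ]),
                 "at least one V and one J")
})

test_that("background reads add nothing and strand flips change nothing", {
    cfg <- simulationConfig(read_depth = 400, planted_productive = 15,
                            planted_frameshift = 4, planted_stop = 4,
                            seed = 23L)
    rd <- genReads(cfg, segs)
    base <- recoverRepertoire(rd$reads, segs)
    ## doubling background-only reads leaves the CDR3 multiset unchanged
    bg <- rd$reads[grepl("^BG", names(rd$reads))]
    bg2 <- bg; names(bg2) <- sub("^BG", "BG2", names(bg2))
    more <- recoverRepertoire(c(rd$reads, bg2), segs)
    expect_equal(sort(base$cdr3$cdr3_aa), sort(more$cdr3$cdr3_aa))
    ## strand closure: reverse-complementing every read preserves CDR3s
    flipped <- recoverRepertoire(Biostrings::reverseComplement(rd$reads), segs)
    expect_equal(sort(base$cdr3$cdr3_aa), sort(flipped$cdr3$cdr3_aa))
})

test_that("recovery output is byte-identical across reruns", {
    cfg <- simulationConfig(read_depth = 200, planted_productive = 10,
                            planted_frameshift = 2, planted_stop = 2,
                            seed = 29L)
    rd <- genReads(cfg, segs)
    f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
    writeCdr3Csv(recoverRepertoire(rd$reads, segs)$cdr3, f1)
    writeCdr3Csv(recoverRepertoire(rd$reads, segs)$cdr3, f2)
    expect_identical(readLines(f1), readLines(f2))
})
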