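sc <- chemicalScales()

test_that("pair terms follow the attraction conventions", {
    expect_equal(electroPairTerm("K", "E", sc), 1)   # opposite charges attract
    expect_equal(electroPairTerm("K", "K", sc), -1)  # like charges repel
    expect_equal(electroPairTerm("A", "E", sc), 0)   # neutral partner
    expect_equal(hydroPairTerm("I", "I", sc), 1)     # both at rescaled max
    for (x in c("A", "K", "W", "P"))
        expect_equal(hydroPairTerm("R", x, sc), 0)   # h(R) = 0
    ## product symmetry
    set.seed(11)
    for (i in 1:20) {
        ab <- sample(AA_STANDARD20, 2)
        expect_equal(hydroPairTerm(ab[1], ab[2], sc),
                     hydroPairTerm(ab[2], ab[1], sc))
        expect_equal(electroPairTerm(ab[1], ab[2], sc),
                     electroPairTerm(ab[2], ab[1], sc))
    }
    expect_error(electroPairTerm("B", "E", sc), "non-standard")
})

test_that("per-offset score applies shift attenuation with edge clipping", {
    expect_equal(perOffsetScore("K", "AEA", 1, "electro", sc), 1)
    expect_equal(perOffsetScore("K", "EKE", 1, "electro", sc), 0)
    ## neutral CDR3: zero at every offset
    for (off in 0:3)
        expect_equal(perOffsetScore("AGS", "EKEKEK", off, "electro", sc), 0)
    expect_error(perOffsetScore("K", "AEA", 3, "electro", sc), "offset")
    expect_error(perOffsetScore("K", "AEA", -1, "electro", sc), "offset")
})

test_that("score_pair matches the exhaustive brute-force enumerator", {
    set.seed(101)
    for (i in 1:40) {
        cdr3 <- randomAA(sample(8:20, 1))
        antigen <- randomAA(sample(20:80, 1))
        p <- scorePair(cdr3, antigen, sc)
        expect_equal(p$electro_cs, bruteForceCS(cdr3, antigen, sc, "electro"),
                     tolerance = 1e-12)
        expect_equal(p$hydro_cs, bruteForceCS(cdr3, antigen, sc, "hydro"),
                     tolerance = 1e-12)
    }
})

test_that("charge-flip antisymmetry holds exactly at every offset", {
    flip <- c(K = "D", R = "E", D = "K", E = "R", A = "A", G = "G", S = "S")
    set.seed(7)
    for (i in 1:25) {
        cdr3 <- paste(sample(names(flip), 8, TRUE), collapse = "")
        flipped <- paste(flip[strsplit(cdr3, "")[[1]]], collapse = "")
        antigen <- randomAA(30)
        for (off in c(0, 5, 22)) {
            expect_identical(perOffsetScore(cdr3, antigen, off, "electro", sc),
                             -perOffsetScore(flipped, antigen, off, "electro",
                                             sc))
        }
    }
})

test_that("score is affine in the shift weight; w = 0 keeps direct terms only", {
    set.seed(13)
    sc0 <- chemicalScales(shiftWeight = 0)
    sc1 <- chemicalScales(shiftWeight = 1)
    scw <- chemicalScales(shiftWeight = 0.7)
    for (i in 1:15) {
        cdr3 <- randomAA(6); antigen <- randomAA(25)
        for (off in c(0, 9, 19)) {
            s0 <- perOffsetScore(cdr3, antigen, off, "electro", sc0)
            s1 <- perOffsetScore(cdr3, antigen, off, "electro", sc1)
            sw <- perOffsetScore(cdr3, antigen, off, "electro", scw)
            ## direct-partner sum alone at w = 0
            direct <- sum(vapply(1:6, function(j)
                electroPairTerm(substr(cdr3, j, j),
                                substr(antigen, off + j, off + j), sc),
                numeric(1)))
            expect_equal(s0, direct, tolerance = 1e-12)
            expect_equal(sw, s0 + 0.7 * (s1 - s0), tolerance = 1e-12)
        }
    }
})

test_that("gaining an opposite charge never lowers the electro score there", {
    set.seed(19)
    neutral <- c("A", "G", "S", "T", "P")
    for (i in 1:25) {
        antigen <- randomAA(30)
        cdr3 <- paste(sample(neutral, 8, TRUE), collapse = "")
        off <- sample(0:22, 1)
        pos <- sample(1:8, 1)
        partner <- substr(antigen, off + pos, off + pos)
        q <- charges(sc)[[partner]]
        if (q == 0) next
        repl <- if (q > 0) "D" else "K"
        mutated <- cdr3
        substr(mutated, pos, pos) <- repl
        expect_gte(perOffsetScore(mutated, antigen, off, "electro", sc),
                   perOffsetScore(cdr3, antigen, off, "electro", sc))
    }
})

test_that("hydro per-offset scores respect the [0, L(1+2w)] bound", {
    set.seed(23)
    for (i in 1:30) {
        L <- sample(5:15, 1)
        cdr3 <- randomAA(L); antigen <- randomAA(40)
        prof <- vapply(0:(40 - L), function(off)
            perOffsetScore(cdr3, antigen, off, "hydro", sc), numeric(1))
        expect_true(all(prof >= 0))
        expect_true(all(prof <= L * (1 + 2 * shiftWeight(sc)) + 1e-12))
    }
})

test_that("reported CS dominates every admissible per-offset score", {
    set.seed(29)
    for (i in 1:15) {
        cdr3 <- randomAA(sample(8:14, 1))
        antigen <- randomAA(sample(25:50, 1))
        p <- scorePair(cdr3, antigen, sc)
        nOff <- nchar(antigen) - nchar(cdr3)
        for (off in c(0, sample(0:nOff, 5), nOff)) {
            expect_gte(p$electro_cs + 1e-12,
                       perOffsetScore(cdr3, antigen, off, "electro", sc))
            expect_gte(p$hydro_cs + 1e-12,
                       perOffsetScore(cdr3, antigen, off, "hydro", sc))
        }
        expect_equal(p$electro_cs,
                     perOffsetScore(cdr3, antigen, p$best_offset_electro,
                                    "electro", sc))
    }
})

test_that("a CDR3 as long as the antigen leaves a single alignment", {
    cdr3 <- "CKDEF"
    p <- scorePair(cdr3, c(tiny = "AKDEA"), sc)
    expect_equal(p$best_offset_electro, 0)
    expect_equal(p$electro_cs,
                 perOffsetScore(cdr3, "AKDEA", 0, "electro", sc))
    expect_equal(p$combo_cs, 0)  # degenerate one-offset batch standardizes to 0
    expect_error(scorePair("CKDEAF", c(tiny = "AKDEA"), sc), "overlap")
})

test_that("batch scoring is a cartesian, deterministic driver", {
    cdr3s <- data.frame(sample_id = c("s1", "s1", "s2"),
                        chain = "TRB",
                        cdr3_aa = c("CASSF", "CKKKF", "CASSF"),
                        stringsAsFactors = FALSE)
    antigens <- c(a1 = "MNNSVNLRSITYLVIDEADK", a2 = "QTVMTSATWPDTVRQLALS")
    res <- scoreRepertoire(cdr3s, antigens, sc)
    expect_equal(nrow(res), 6L)
    expect_equal(res$antigen_id, rep(c("a1", "a2"), 3))  # CDR3-major order
    ## identical CDR3s score identically
    same <- res[res$cdr3_aa == "CASSF" & res$antigen_id == "a1", ]
    expect_equal(same$combo_cs[1], same$combo_cs[2])
    expect_equal(same$electro_cs[1], same$electro_cs[2])
    ## raw components match single-pair scoring
    for (r in seq_len(nrow(res))) {
        single <- scorePair(res$cdr3_aa[r], antigens[res$antigen_id[r]], sc)
        expect_equal(res$electro_cs[r], single$electro_cs)
        expect_equal(res$hydro_cs[r], single$hydro_cs)
        expect_equal(res$best_offset_electro[r], single$best_offset_electro)
    }
    expect_error(scoreRepertoire(cdr3s[0, ], antigens, sc), "empty")
    ## too-long CDR3s are skipped with a warning, not an abort
    long <- rbind(cdr3s,
                  data.frame(sample_id = "s3", chain = "TRB",
                             cdr3_aa = paste0("C", strrep("A", 18), "F"),
                             stringsAsFactors = FALSE))
    expect_warning(res2 <- scoreRepertoire(long, antigens, sc), "skipping")
    ## the length-20 CDR3 still scores against the length-20 antigen a1
    ## but is skipped for the shorter a2
    expect_equal(nrow(res2), 7L)
    expect_false(any(res2$cdr3_aa == long$cdr3_aa[4] &
                     res2$antigen_id == "a2"))
})

test_that("per-sample aggregation honors the chosen summary", {
    res <- data.frame(sample_id = c("s1", "s1", "s2"),
                      antigen_id = "a1",
                      combo_cs = c(1, 3, 2), stringsAsFactors = FALSE)
    expect_equal(aggregateSampleCS(res, "mean")$cs, c(2, 2))
    expect_equal(aggregateSampleCS(res, "max")$cs, c(3, 2))
    expect_equal(aggregateSampleCS(res, "sum")$cs, c(4, 2))
    ## a singleton equals its own CS under every method
    one <- res[3, ]
    for (m in c("mean", "max", "sum"))
        expect_equal(aggregateSampleCS(one, m)$cs, 2)
    res$antigen_id <- c("a1", "a2", "a1")
    expect_error(aggregateSampleCS(res), "antigen")
})
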