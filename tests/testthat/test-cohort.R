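test_that("median split respects the tie-alternation and size contract", {
    s <- data.frame(sample_id = c("a", "b", "c", "d"), cs = c(1, 2, 3, 4))
    g <- medianSplit(s)
    expect_equal(as.character(g), c("lower", "lower", "upper", "upper"))
    ## ties at the median alternate deterministically
    s2 <- data.frame(sample_id = c("a", "b", "c", "d"), cs = c(5, 5, 5, 1))
    g2 <- medianSplit(s2)
    expect_equal(as.character(g2[4]), "lower")
    expect_equal(abs(sum(g2 == "upper") - sum(g2 == "lower")), 0)
    expect_identical(g2, medianSplit(s2))
    ## odd n: sizes differ by at most one
    set.seed(37)
    for (i in 1:10) {
        n <- sample(c(5, 9, 15), 1)
        s3 <- data.frame(sample_id = sprintf("s%02d", 1:n),
                         cs = sample(1:4, n, TRUE))
        g3 <- medianSplit(s3)
        expect_lte(abs(sum(g3 == "upper") - sum(g3 == "lower")), 1)
    }
    expect_error(medianSplit(data.frame(sample_id = letters[1:5],
                                        cs = rep(2, 5))), "degenerate")
    expect_error(medianSplit(data.frame(sample_id = c("a", "b"),
                                        cs = c(1, 2))), ">= 4")
})

test_that("KM medians and logrank match hand calculations", {
    ## identical groups: no separation at all
    km0 <- kmLogrank(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1),
                     rep(c("x", "y"), each = 3))
    expect_equal(km0$chisq, 0, tolerance = 1e-12)
    expect_equal(km0$logrank_p, 1, tolerance = 1e-12)
    ## all events, no censoring: medians from the 3-point product limit
    km1 <- kmLogrank(c(1, 2, 3, 4, 5, 6), rep(1, 6), rep(c("g1", "g2"), each = 3))
    expect_equal(km1$groups$median_months[km1$groups$group == "g1"], 2)
    expect_equal(km1$groups$median_months[km1$groups$group == "g2"], 5)
    expect_equal(handKMMedian(c(1, 2, 3), c(1, 1, 1)), 2)
    expect_error(kmLogrank(1:3, rep(1, 3), rep("x", 3)), "two")
})

test_that("KM estimator agrees with the hand product-limit on a censored fixture", {
    time <- c(2, 4, 4, 7, 9, 11)
    event <- c(1, 1, 0, 1, 0, 1)
    hand <- handKM(time, event)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    atEvents <- summary(fit, times = hand$time)
    expect_equal(atEvents$surv, hand$surv, tolerance = 1e-12)
    ## median: earliest time where survival <= 0.5
    grp <- kmLogrank(c(time, 100, 100), c(event, 0, 0),
                     rep(c("a", "b"), c(6, 2)))
    expect_equal(grp$groups$median_months[grp$groups$group == "a"],
                 handKMMedian(time, event))
    expect_true(is.na(grp$groups$median_months[grp$groups$group == "b"]))
})

test_that("Cox fits report per-term hazard ratios and refuse degenerate terms", {
    set.seed(41)
    group <- rep(c(1, 0), each = 150)
    mkData <- function()
        data.frame(sample_id = sprintf("s%03d", 1:300),
                   group_upper = group,
                   dfs_months = rexp(300, 0.02 * ifelse(group == 1, 3, 1)),
                   event = 1L)
    d <- mkData()
    fit <- coxFit(d, "group_upper")
    expect_equal(nrow(fit$coefficients), 1L)
    expect_true(fit$coefficients$p < 0.001)
    ## mean log-HR over replicates recovered with < 10% bias at n=300
    logHR <- replicate(10, log(coxFit(mkData(), "group_upper")$coefficients$exp_beta))
    expect_lt(abs(mean(logHR) - log(3)) / log(3), 0.10)
    d$flat <- 1
    expect_error(coxFit(d, "flat"), "constant")
    d$extra <- rbinom(300, 1, 0.5)
    biv <- coxFit(d, c("group_upper", "extra"))
    expect_equal(nrow(biv$coefficients), 2L)
    ## listwise deletion is logged in the counts
    d$extra[1:10] <- NA
    biv2 <- coxFit(d, c("group_upper", "extra"))
    expect_equal(biv2$n_dropped, 10L)
})

test_that("zero-expression odds ratio matches the hypergeometric oracle", {
    mk <- function(a, b, c_, d) {
        list(expr = c(rep(0, a), rep(5, b), rep(0, c_), rep(9, d)),
             grp = rep(c("upper", "lower"), c(a + b, c_ + d)))
    }
    x <- mk(10, 10, 10, 10)
    r <- zeroExpressionOdds(x$expr, x$grp)
    expect_equal(r$odds_ratio, 1)
    expect_equal(r$p, 1)
    ## the spec's worked table
    x <- mk(29, 6, 23, 14)
    r <- zeroExpressionOdds(x$expr, x$grp)
    expect_equal(r$p, fisherOracleP(29, 6, 23, 14), tolerance = 1e-9)
    expect_equal(r$odds_ratio, (29 * 14) / (6 * 23))
    expect_equal(unname(r$prop_zero["upper"]), 29 / 35)
    ## Haldane-Anscombe correction with an empty cell
    x <- mk(12, 0, 5, 7)
    r <- zeroExpressionOdds(x$expr, x$grp)
    expect_true(r$corrected)
    expect_equal(r$odds_ratio, (12.5 * 7.5) / (0.5 * 5.5))
    ## all-zero expression: degenerate, OR undefined but flagged
    x <- mk(10, 0, 10, 0)
    r <- zeroExpressionOdds(x$expr, x$grp)
    expect_true(r$degenerate)
    expect_true(is.na(r$odds_ratio))
})

test_that("methylation t-test equals the pooled-variance hand formula", {
    id <- methylationTTest(rep(c(0.2, 0.4, 0.6), 2),
                           rep(c("upper", "lower"), each = 3))
    expect_equal(id$t, 0, tolerance = 1e-12)
    expect_equal(id$p, 1, tolerance = 1e-12)
    b <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
    g <- rep(c("upper", "lower"), each = 3)
    r <- methylationTTest(b, g)
    sp2 <- (var(b[1:3]) + var(b[4:6])) / 2
    tHand <- (mean(b[1:3]) - mean(b[4:6])) / sqrt(sp2 * (2 / 3))
    expect_equal(r$t, tHand, tolerance = 1e-12)
    expect_equal(r$p, 2 * pt(-abs(tHand), df = 4), tolerance = 1e-12)
    expect_equal(unname(r$means), c(0.2, 0.5))
    expect_error(methylationTTest(c(0.1, 0.2, 0.3),
                                  c("upper", "lower", "lower")), ">= 2")
})

test_that("CS-expression correlation handles exact, absent and flat genes", {
    cs <- c(1, 2, 3, 4, 5)
    ex <- data.frame(G1 = 2 * cs + 1, G2 = rep(3, 5))
    r <- csExpressionCorrelation(cs, ex)
    expect_equal(r$r[r$gene == "G1"], 1, tolerance = 1e-12)
    expect_true(r$undefined[r$gene == "G2"])
    expect_error(csExpressionCorrelation(cs, ex, "NOPE"), "NOPE")
})

test_that("the cohort driver joins, reports all sections, and is order-invariant", {
    co <- genCohort(simulationConfig(seed = 43, n_samples = 40))
    rep1 <- runCohortAnalysis(co$sample_cs, co$survival, co$expression,
                              co$methylation, co$covariates,
                              markerGenes = c("POLG", "EIF2AK3"))
    expect_s4_class(rep1, "CohortReport")
    expect_true(validObject(rep1))
    expect_length(rep1@missingSections, 0L)
    expect_equal(nrow(rep1@correlations), 2L)
    expect_true(all(is.finite(rep1@coxUnivariate$exp_beta)))
    expect_gte(nrow(rep1@coxBivariate), 2L)
    ## shuffling input row order changes nothing
    shuffle <- function(d) d[sample(nrow(d)), , drop = FALSE]
    set.seed(47)
    rep2 <- runCohortAnalysis(shuffle(co$sample_cs), shuffle(co$survival),
                              shuffle(co$expression), shuffle(co$methylation),
                              shuffle(co$covariates),
                              markerGenes = c("POLG", "EIF2AK3"))
    expect_equal(rep1@km, rep2@km)
    expect_equal(rep1@coxUnivariate, rep2@coxUnivariate)
    expect_equal(rep1@oddsRatio$odds_ratio, rep2@oddsRatio$odds_ratio)
    expect_equal(rep1@correlations, rep2@correlations)
    ## dropping methylation marks that section absent, others unchanged
    rep3 <- runCohortAnalysis(co$sample_cs, co$survival, co$expression,
                              covariates = co$covariates,
                              markerGenes = c("POLG", "EIF2AK3"))
    expect_true("methylation" %in% rep3@missingSections)
    expect_equal(rep3@km, rep1@km)
    ## too-small joins abort
    expect_error(runCohortAnalysis(co$sample_cs[1:4, ], co$survival),
                 "too small")
})
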