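## Cohort-level analyses: median CS split, KM/logrank, Cox, zero-
## expression odds ratio, methylation t-test, CS-expression correlation.

#' @importFrom survival Surv survfit survdiff coxph
NULL

#' Split samples at the median of a field
#'
#' Samples above the median go to the `upper` group, below to `lower`.
#' Samples exactly at the median are assigned alternately (in sample_id
#' sort order, each to the currently smaller group) so group sizes
#' differ by at most one — a deterministic rule for a choice the data do
#' not make by themselves.
#'
#' @param samples data.frame with `sample_id` and the split field.
#' @param by name of the numeric field to split on (default `"cs"`).
#' @return factor of `"upper"`/`"lower"` aligned with `samples` rows.
#' @export
medianSplit <- function(samples, by = "cs") {
    v <- samples[[by]]
    if (is.null(v)) stop("no field '", by, "' in sample table", call. = FALSE)
    ok <- !is.na(v)
    if (sum(ok) < 4L)
        stop("need >= 4 samples with non-missing '", by, "'", call. = FALSE)
    if (length(unique(v[ok])) == 1L)
        stop("degenerate split: all '", by, "' values identical", call. = FALSE)
    med <- stats::median(v[ok])
    grp <- rep(NA_character_, length(v))
    grp[ok & v > med] <- "upper"
    grp[ok & v < med] <- "lower"
    ties <- which(ok & v == med)
    if (length(ties)) {
        ties <- ties[order(samples$sample_id[ties])]
        for (i in ties) {
            nUp <- sum(grp == "upper", na.rm = TRUE)
            nLo <- sum(grp == "lower", na.rm = TRUE)
            grp[i] <- if (nUp <= nLo) "upper" else "lower"
        }
    }
    factor(grp, levels = c("lower", "upper"))
}

#' Kaplan-Meier curves and logrank test for two groups
#'
#' Product-limit estimator per group with median survival defined as the
#' earliest time at which the survival curve is <= 0.5 (NA when the
#' curve never crosses 0.5, i.e. median not reached), plus the
#' two-sided logrank test.
#'
#' @param time survival times (months), >= 0.
#' @param event 1 = event (recurrence/progression), 0 = censored.
#' @param group two-level factor/character of group labels.
#' @return list: `groups` (data.frame with n, events, median), `chisq`,
#'   `logrank_p`, and the `survfit` object in `fit`.
#' @export
kmLogrank <- function(time, event, group) {
    group <- as.factor(droplevels(as.factor(group)))
    if (nlevels(group) != 2L)
        stop("kmLogrank requires exactly two non-empty groups", call. = FALSE)
    if (any(table(group) == 0L))
        stop("a group has zero subjects", call. = FALSE)
    stopifnot(length(time) == length(event), length(time) == length(group))
    fit <- survival::survfit(survival::Surv(time, event) ~ group)
    tab <- summary(fit)$table
    if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                         dimnames = list("all", names(tab)))
    groups <- data.frame(group = sub("^group=", "", rownames(tab)),
                         n = tab[, "records"],
                         events = tab[, "events"],
                         median_months = tab[, "median"],
                         stringsAsFactors = FALSE, row.names = NULL)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
    list(groups = groups, chisq = unname(sd$chisq), logrank_p = unname(p),
         fit = fit)
}

#' Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ terms` with listwise deletion of samples
#' missing any term, reporting the hazard ratio Exp(beta) and Wald p per
#' coefficient. A term that is constant after deletion, or a fit that
#' fails to converge, raises an error naming the term.
#'
#' @param samples data.frame with `dfs_months`, `event` and the term
#'   columns.
#' @param terms character vector of covariate column names (one term
#'   for the univariate fit, two for a bivariate fit).
#' @return list: `coefficients` (data.frame term / exp_beta / p),
#'   `n_used`, `n_dropped`.
#' @export
coxFit <- function(samples, terms) {
    need <- c("dfs_months", "event", terms)
    missingCols <- setdiff(need, colnames(samples))
    if (length(missingCols))
        stop("missing column(s): ", paste(missingCols, collapse = ", "),
             call. = FALSE)
    use <- stats::complete.cases(samples[, need, drop = FALSE])
    dat <- samples[use, , drop = FALSE]
    for (tm in terms) {
        v <- dat[[tm]]
        if (length(unique(v)) < 2L)
            stop("covariate '", tm, "' is constant after listwise deletion",
                 call. = FALSE)
    }
    fml <- stats::as.formula(paste("survival::Surv(dfs_months, event) ~",
                                   paste(sprintf("`%s`", terms),
                                         collapse = " + ")))
    fit <- tryCatch(
        survival::coxph(fml, data = dat),
        warning = function(w) {
            if (grepl("converge|infinite|singular", conditionMessage(w)))
                stop("Cox fit failed for terms ",
                     paste(terms, collapse = " + "), ": ",
                     conditionMessage(w), call. = FALSE)
            suppressWarnings(survival::coxph(fml, data = dat))
        })
    s <- summary(fit)$coefficients
    if (anyNA(s[, "coef"]))
        stop("Cox fit produced undefined coefficient(s) for term(s): ",
             paste(rownames(s)[is.na(s[, "coef"])], collapse = ", "),
             call. = FALSE)
    list(coefficients = data.frame(term = rownames(s),
                                   exp_beta = unname(s[, "exp(coef)"]),
                                   p = unname(s[, "Pr(>|z|)"]),
                                   stringsAsFactors = FALSE, row.names = NULL),
         n_used = sum(use), n_dropped = sum(!use))
}

#' Odds ratio for zero antigen expression between CS groups
#'
#' Builds the 2x2 table of zero vs nonzero expression (zero means value
#' <= `zeroThreshold`, default exactly 0) against upper vs lower group,
#' and reports per-group zero proportions, the odds ratio (with the
#' Haldane-Anscombe 0.5 continuity correction when any cell is zero)
#' and the two-sided Fisher exact p-value.
#'
#' @param expression numeric expression values (RSEM-like, >= 0).
#' @param group factor of `"upper"`/`"lower"` per sample.
#' @param zeroThreshold values <= this count as zero expression.
#' @return list: `table` (2x2), `prop_zero` (named: upper, lower),
#'   `odds_ratio` (NA when undefined), `p`, `corrected` (logical),
#'   `degenerate` (logical).
#' @export
zeroExpressionOdds <- function(expression, group, zeroThreshold = 0) {
    ok <- !is.na(expression) & !is.na(group)
    expression <- expression[ok]
    group <- factor(as.character(group)[ok], levels = c("upper", "lower"))
    if (any(table(group) == 0L))
        stop("both groups need at least one sample with expression",
             call. = FALSE)
    zero <- factor(ifelse(expression <= zeroThreshold, "zero", "nonzero"),
                   levels = c("zero", "nonzero"))
    tab <- table(group, zero)
    prop <- tab[, "zero"] / rowSums(tab)
    degenerate <- any(colSums(tab) == 0L)
    a <- tab["upper", "zero"]; b <- tab["upper", "nonzero"]
    c_ <- tab["lower", "zero"]; d <- tab["lower", "nonzero"]
    corrected <- any(tab == 0L)
    or <- if (degenerate) NA_real_ else if (corrected)
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
    list(table = tab,
         prop_zero = c(upper = unname(prop["upper"]),
                       lower = unname(prop["lower"])),
         odds_ratio = or, p = p, corrected = corrected,
         degenerate = degenerate)
}

#' Two-sample t-test on methylation beta values
#'
#' Classical pooled-variance (Student's) two-tailed t-test by default;
#' `welch = TRUE` drops the equal-variance assumption.
#'
#' @param beta methylation beta values in \[0, 1\].
#' @param group factor of `"upper"`/`"lower"` per sample.
#' @param welch use the Welch correction instead of pooled variance.
#' @return list: `means` (named: upper, lower), `t`, `df`, `p`, `n`.
#' @export
methylationTTest <- function(beta, group, welch = FALSE) {
    ok <- !is.na(beta) & !is.na(group)
    beta <- beta[ok]
    group <- factor(as.character(group)[ok], levels = c("upper", "lower"))
    n <- table(group)
    if (any(n < 2L))
        stop("each group needs >= 2 methylation values", call. = FALSE)
    tt <- stats::t.test(beta[group == "upper"], beta[group == "lower"],
                        var.equal = !welch)
    list(means = c(upper = mean(beta[group == "upper"]),
                   lower = mean(beta[group == "lower"])),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, n = c(upper = unname(n["upper"]),
                               lower = unname(n["lower"])))
}

#' Pearson correlation between sample CS and gene expression
#'
#' For each gene, the Pearson correlation of (cs, expression) over
#' samples with both values, with the two-sided p from the t-transform
#' of r. Zero-variance series yield an NA correlation flagged in
#' `undefined`. A Benjamini-Hochberg column is added for transparency;
#' the per-gene p-values themselves are not adjusted.
#'
#' @param cs numeric sample-level CS, aligned with rows of `expression`.
#' @param expression data.frame/matrix of expression, one column per
#'   gene.
#' @param genes gene columns to test (default: all columns).
#' @return data.frame: `gene`, `r`, `p`, `p_bh`, `n`, `undefined`.
#' @export
csExpressionCorrelation <- function(cs, expression, genes = colnames(expression)) {
    missing <- setdiff(genes, colnames(expression))
    if (length(missing))
        stop("gene(s) absent from expression table: ",
             paste(missing, collapse = ", "), call. = FALSE)
    rows <- lapply(genes, function(g) {
        x <- cs; y <- expression[[g]]
        ok <- !is.na(x) & !is.na(y)
        x <- x[ok]; y <- y[ok]
        if (length(x) < 3L)
            stop("gene '", g, "': need >= 3 paired observations", call. = FALSE)
        if (stats::sd(x) == 0 || stats::sd(y) == 0)
            return(data.frame(gene = g, r = NA_real_, p = NA_real_,
                              n = length(x), undefined = TRUE,
                              stringsAsFactors = FALSE))
        ct <- stats::cor.test(x, y, method = "pearson")
        data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value,
                   n = length(x), undefined = FALSE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_bh <- stats::p.adjust(out$p, method = "BH")
    out[, c("gene", "r", "p", "p_bh", "n", "undefined")]
}

#' Run the full cohort analysis
#'
#' Joins the per-sample CS table with survival, expression, methylation
#' and covariate tables on `sample_id` (unmatched ids are dropped with a
#' message), median-splits on CS, and runs every section: KM + logrank,
#' univariate Cox on the group indicator (or continuous CS with
#' `csTerm = "continuous"`), one bivariate Cox per covariate,
#' zero-expression odds ratio for `antigenGene`, methylation t-test and
#' CS-expression Pearson correlations for `markerGenes`. Sections whose
#' inputs are absent are skipped and listed in `missingSections`.
#'
#' @param cs data.frame from [aggregateSampleCS()] (`sample_id`, `cs`).
#' @param survivalData data.frame: `sample_id`, `dfs_months`, `dfs_event`.
#' @param expression optional data.frame: `sample_id` plus gene columns.
#' @param methylation optional data.frame: `sample_id`, `beta`.
#' @param covariates optional data.frame: `sample_id` plus covariate
#'   columns.
#' @param antigenGene expression column tested for zero expression.
#' @param markerGenes expression columns for the correlation section.
#' @param csTerm `"group"` (median-split indicator, default) or
#'   `"continuous"` for the Cox fits.
#' @param zeroThreshold passed to [zeroExpressionOdds()].
#' @param minSamples minimum joined cohort size (default 8).
#' @return a [CohortReport-class].
#' @export
runCohortAnalysis <- function(cs, survivalData, expression = NULL,
                              methylation = NULL, covariates = NULL,
                              antigenGene = "DDX53",
                              markerGenes = NULL,
                              csTerm = c("group", "continuous"),
                              zeroThreshold = 0, minSamples = 8L) {
    csTerm <- match.arg(csTerm)
    samples <- merge(cs[, c("sample_id", "cs")],
                     survivalData[, c("sample_id", "dfs_months", "dfs_event")],
                     by = "sample_id")
    dropped <- setdiff(union(cs$sample_id, survivalData$sample_id),
                       samples$sample_id)
    if (length(dropped))
        message(length(dropped), " sample(s) dropped at the CS-survival join")
    samples <- samples[order(samples$sample_id), , drop = FALSE]
    if (nrow(samples) < minSamples)
        stop("cohort too small after join: ", nrow(samples), " samples (need >= ",
             minSamples, ")", call. = FALSE)
    if (any(samples$dfs_months < 0, na.rm = TRUE))
        stop("negative dfs_months in survival table", call. = FALSE)
    samples$event <- as.integer(samples$dfs_event)
    samples$group <- medianSplit(samples, by = "cs")
    samples$group_upper <- as.integer(samples$group == "upper")

    km <- kmLogrank(samples$dfs_months, samples$event, samples$group)
    km$fit <- NULL  # keep the report plain-data

    term <- if (csTerm == "group") "group_upper" else "cs"
    coxUni <- coxFit(samples, term)
    coxUniDf <- cbind(coxUni$coefficients, n = coxUni$n_used)

    missingSections <- character(0)
    coxBiv <- data.frame(comparison = character(0), term = character(0),
                         exp_beta = numeric(0), p = numeric(0),
                         n = integer(0), stringsAsFactors = FALSE)
    if (!is.null(covariates)) {
        samples <- merge(samples, covariates, by = "sample_id", all.x = TRUE)
        covNames <- setdiff(colnames(covariates), "sample_id")
        biv <- lapply(covNames, function(cv) {
            fit <- tryCatch(coxFit(samples, c(term, cv)),
                            error = function(e) NULL)
            if (is.null(fit)) return(NULL)
            cbind(comparison = cv, fit$coefficients, n = fit$n_used)
        })
        biv <- biv[!vapply(biv, is.null, logical(1))]
        if (length(biv)) coxBiv <- do.call(rbind, biv)
    } else missingSections <- c(missingSections, "covariates")

    oddsRes <- list()
    corrDf <- data.frame(gene = character(0), r = numeric(0), p = numeric(0),
                         p_bh = numeric(0), n = integer(0),
                         undefined = logical(0), stringsAsFactors = FALSE)
    if (!is.null(expression)) {
        expr <- merge(samples[, c("sample_id", "cs", "group")], expression,
                      by = "sample_id")
        if (!antigenGene %in% colnames(expr))
            stop("gene '", antigenGene, "' absent from expression table",
                 call. = FALSE)
        oddsRes <- zeroExpressionOdds(expr[[antigenGene]], expr$group,
                                      zeroThreshold = zeroThreshold)
        if (is.null(markerGenes))
            markerGenes <- setdiff(colnames(expression),
                                   c("sample_id", antigenGene))
        if (length(markerGenes))
            corrDf <- csExpressionCorrelation(expr$cs, expr, markerGenes)
    } else missingSections <- c(missingSections, "expression")

    methRes <- list()
    if (!is.null(methylation)) {
        meth <- merge(samples[, c("sample_id", "group")], methylation,
                      by = "sample_id")
        if (any(meth$beta < 0 | meth$beta > 1, na.rm = TRUE))
            stop("methylation beta values must lie in [0, 1]", call. = FALSE)
        methRes <- methylationTTest(meth$beta, meth$group)
    } else missingSections <- c(missingSections, "methylation")

    new("CohortReport", samples = samples, km = km,
        coxUnivariate = coxUniDf, coxBivariate = coxBiv,
        oddsRatio = oddsRes, methylation = methRes,
        correlations = corrDf, missingSections = missingSections)
}

#' Plot Kaplan-Meier curves for a cohort report
#'
#' Upper-percentile group in black, lower in gray, censoring ticks
#' shown — the conventional two-arm DFS display.
#'
#' @param report a [CohortReport-class].
#' @param main plot title.
#' @return invisibly, the refitted `survfit` object.
#' @export
plotKM <- function(report, main = "Disease-free survival by CS group") {
    s <- report@samples
    fit <- survival::survfit(survival::Surv(dfs_months, event) ~ group,
                             data = s)
    graphics::plot(fit, col = c("gray60", "black"), lwd = 2, mark.time = TRUE,
                   xlab = "Months", ylab = "Survival probability", main = main)
    graphics::legend("topright", bty = "n", lwd = 2, col = c("black", "gray60"),
                     legend = c("upper 50th percentile CS",
                                "lower 50th percentile CS"))
    invisible(fit)
}

setMethod("show", "CohortReport", function(object) {
    cat("CohortReport —", nrow(object@samples), "samples\n")
    g <- object@km$groups
    if (!is.null(g)) {
        for (i in seq_len(nrow(g)))
            cat(sprintf("  %s: n=%d, events=%d, median DFS=%s months\n",
                        g$group[i], g$n[i], g$events[i],
                        ifelse(is.na(g$median_months[i]), "not reached",
                               format(g$median_months[i]))))
        cat(sprintf("  logrank p = %.4g\n", object@km$logrank_p))
    }
    if (nrow(object@coxUnivariate))
        cat(sprintf("  Cox (univariate): Exp(beta) = %.3g, p = %.4g\n",
                    object@coxUnivariate$exp_beta[1],
                    object@coxUnivariate$p[1]))
    if (length(object@oddsRatio))
        cat(sprintf("  zero expression: %.1f%% vs %.1f%%, OR = %.3g, p = %.4g\n",
                    100 * object@oddsRatio$prop_zero["upper"],
                    100 * object@oddsRatio$prop_zero["lower"],
                    object@oddsRatio$odds_ratio, object@oddsRatio$p))
    if (length(object@methylation))
        cat(sprintf("  methylation beta: %.3f vs %.3f, p = %.4g\n",
                    object@methylation$means["upper"],
                    object@methylation$means["lower"], object@methylation$p))
    if (nrow(object@correlations))
        for (i in seq_len(nrow(object@correlations)))
            cat(sprintf("  CS~%s: r = %.3f, p = %.4g\n",
                        object@correlations$gene[i], object@correlations$r[i],
                        object@correlations$p[i]))
    if (length(object@missingSections))
        cat("  sections absent:",
            paste(object@missingSections, collapse = ", "), "\n")
})
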