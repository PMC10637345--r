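## Independent oracles used to cross-check the implementation. These
## deliberately re-derive every quantity with naive enumeration rather
## than calling the package's scoring/statistics code paths.

## Exhaustive per-offset complementarity enumeration: nested loops over
## offsets, CDR3 positions and the -1/0/+1 shifts.
bruteForceProfile <- function(cdr3, antigen, scales, type = "electro") {
    q <- charges(scales); h <- hydropathies(scales); w <- shiftWeight(scales)
    term <- function(a, b) {
        if (type == "electro") -q[[a]] * q[[b]] else h[[a]] * h[[b]]
    }
    cres <- strsplit(cdr3, "")[[1]]
    tres <- strsplit(antigen, "")[[1]]
    nOff <- length(tres) - length(cres) + 1L
    out <- numeric(nOff)
    for (off in seq_len(nOff) - 1L) {
        s <- 0
        for (i in seq_along(cres)) {
            s <- s + term(cres[i], tres[off + i])
            for (d in c(-1L, 1L)) {
                j <- off + i + d
                if (j >= 1L && j <= length(tres))
                    s <- s + w * term(cres[i], tres[j])
            }
        }
        out[off + 1L] <- s
    }
    out
}

bruteForceCS <- function(cdr3, antigen, scales, type = "electro") {
    max(bruteForceProfile(cdr3, antigen, scales, type))
}

## Standard-genetic-code translation by direct codon lookup.
handTranslate <- function(nt) {
    stopifnot(nchar(nt) %% 3 == 0)
    codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    paste(vapply(codons, function(cd) Biostrings::GENETIC_CODE[[cd]], ""),
          collapse = "")
}

## Two-sided Fisher exact p by exhaustive hypergeometric summation over
## all tables with the observed margins.
fisherOracleP <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    lo <- max(0L, k - n); hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

## Hand product-limit estimator: returns step-function values at event
## times.
handKM <- function(time, event) {
    ord <- order(time)
    time <- time[ord]; event <- event[ord]
    atRisk <- length(time)
    s <- 1
    times <- sort(unique(time[event == 1]))
    surv <- numeric(length(times))
    for (i in seq_along(times)) {
        t <- times[i]
        d <- sum(time == t & event == 1)
        nRisk <- sum(time >= t)
        s <- s * (1 - d / nRisk)
        surv[i] <- s
    }
    data.frame(time = times, surv = surv)
}

handKMMedian <- function(time, event) {
    km <- handKM(time, event)
    cross <- which(km$surv <= 0.5)
    if (!length(cross)) NA_real_ else km$time[min(cross)]
}

## Random sequence helpers (draw from the 20 standard residues).
randomAA <- function(n) paste(sample(AA_STANDARD20, n, TRUE), collapse = "")
randomCdr3 <- function(len) {
    paste0("C", paste(sample(AA_STANDARD20, len - 2L, TRUE), collapse = ""),
           sample(c("F", "W"), 1L))
}
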