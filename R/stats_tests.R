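## Statistical layer: two-sided Mann-Whitney, Kruskal-Wallis + Dunn,
## two-way ANOVA + Sidak pairwise comparisons, Wilcoxon signed-rank,
## Pearson correlation and ROUT outlier flagging. All results come back
## as plain data.frames with a common column set.

.testResult <- function(test, statistic, p, adjusted = NA_real_,
                        group1 = NA, group2 = NA, n1 = NA, n2 = NA) {
    data.frame(test = test, statistic = statistic,
               p_value = p, adjusted_p = adjusted,
               group1 = as.character(group1), group2 = as.character(group2),
               n1 = n1, n2 = n2, stringsAsFactors = FALSE)
}

.midranks <- function(x) rank(x, ties.method = "average")

#' Two-sided Mann-Whitney U test
#'
#' U with midrank tie handling. The p-value is exact (full enumeration
#' of rank assignments) when both groups have at most \code{exactMax}
#' observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction is used (logged).
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exactMax largest per-group n for the exact method (default 8).
#' @return one-row data.frame (test, statistic = U of group a, p_value, ...).
#' @export
mannWhitneyTwoSided <- function(a, b, exactMax = 8L) {
    if (!length(a) || !length(b)) .stopInput("both groups must be non-empty")
    n1 <- length(a); n2 <- length(b)
    pooled <- c(a, b)
    r <- .midranks(pooled)
    u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- anyDuplicated(pooled) > 0L
    if (!ties && n1 <= exactMax && n2 <= exactMax) {
        p <- .mwExactP(n1, n2, u1)
    } else {
        if (ties) .log("mannWhitneyTwoSided: ties present, using approximation")
        n <- n1 + n2
        mu <- n1 * n2 / 2
        tt <- table(pooled)
        tieTerm <- sum(tt^3 - tt) / (n * (n - 1))
        sig2 <- n1 * n2 / 12 * ((n + 1) - tieTerm)
        z <- u1 - mu
        z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)   # continuity corr.
        p <- min(1, 2 * stats::pnorm(-abs(z)))
        if (sig2 == 0) p <- 1
    }
    .testResult("mann_whitney_two_sided", u1, p, group1 = "a", group2 = "b",
                n1 = n1, n2 = n2)
}

## exact two-sided p for U (no ties): enumerate all C(n, n1) assignments
.mwExactP <- function(n1, n2, u) {
    sets <- utils::combn(n1 + n2, n1)
    us <- colSums(sets) - n1 * (n1 + 1) / 2
    pLow <- mean(us <= u + 1e-9)
    pHigh <- mean(us >= u - 1e-9)
    min(1, 2 * min(pLow, pHigh))
}

#' Kruskal-Wallis test with Dunn's multiple comparisons
#'
#' Kruskal-Wallis H (tie-corrected, via \code{stats::kruskal.test})
#' followed by Dunn's pairwise z statistics on pooled midranks. Adjusted
#' p-values use a Sidak-style family-wise correction over the compared
#' pairs by default (\code{"sidak"}), with \code{"bonferroni"} and
#' \code{"none"} as options.
#'
#' @param groups named list of at least three numeric vectors (each n >= 2).
#' @param adjust \code{"sidak"}, \code{"bonferroni"} or \code{"none"}.
#' @return list with \code{omnibus} (one-row data.frame, statistic = H)
#'   and \code{pairwise} (one row per pair).
#' @export
kruskalDunn <- function(groups, adjust = c("sidak", "bonferroni", "none")) {
    adjust <- match.arg(adjust)
    if (length(groups) < 3L)
        .stopInput("need >= 3 groups; use mannWhitneyTwoSided for two")
    if (any(vapply(groups, length, 1L) < 2L))
        .stopInput("every group needs n >= 2")
    if (is.null(names(groups)))
        names(groups) <- paste0("g", seq_along(groups))
    kw <- stats::kruskal.test(groups)
    omnibus <- .testResult("kruskal_wallis", unname(kw$statistic),
                           kw$p.value,
                           n1 = sum(lengths(groups)))

    x <- unlist(groups, use.names = FALSE)
    g <- rep(names(groups), lengths(groups))
    n <- length(x)
    r <- .midranks(x)
    rbar <- tapply(r, g, mean)
    ni <- tapply(r, g, length)
    tt <- table(x)
    tieT <- sum(tt^3 - tt) / (12 * (n - 1))
    pairs <- utils::combn(names(groups), 2L)
    m <- ncol(pairs)
    pw <- do.call(rbind, lapply(seq_len(m), function(k) {
        i <- pairs[1L, k]; j <- pairs[2L, k]
        se <- sqrt((n * (n + 1) / 12 - tieT) * (1 / ni[[i]] + 1 / ni[[j]]))
        z <- (rbar[[i]] - rbar[[j]]) / se
        p <- min(1, 2 * stats::pnorm(-abs(z)))
        .testResult("dunn", z, p, group1 = i, group2 = j,
                    n1 = ni[[i]], n2 = ni[[j]])
    }))
    pw$adjusted_p <- .adjustFamily(pw$p_value, adjust)
    list(omnibus = omnibus, pairwise = pw)
}

.adjustFamily <- function(p, adjust) {
    m <- length(p)
    switch(adjust,
           sidak = pmin(1, 1 - (1 - p)^m),
           bonferroni = pmin(1, p * m),
           none = p)
}

#' Two-way ANOVA with Sidak's multiple comparisons
#'
#' Fits \code{value ~ A * B} and reports type-II F tests for both main
#' effects and the interaction (type II handles the unbalanced designs
#' that arise when disc counts differ between conditions), then compares
#' the levels of factor A within each level of factor B using pooled-MSE
#' t tests with Sidak family-wise adjustment
#' \eqn{p_{adj} = 1 - (1 - p)^m} over the m comparisons.
#'
#' Degenerate noise-free data are reported with the convention
#' SS = 0 => F = 0, p = 1.
#'
#' @param values numeric vector.
#' @param factorA,factorB factor labels, same length as \code{values}.
#' @return list with \code{anova} (rows A, B, A:B) and \code{pairwise}.
#' @export
twowayAnovaSidak <- function(values, factorA, factorB) {
    A <- factor(factorA); B <- factor(factorB)
    if (nlevels(A) < 2L || nlevels(B) < 2L)
        .stopInput("each factor needs >= 2 levels")
    cells <- table(A, B)
    if (any(cells == 0L)) {
        bad <- which(cells == 0L, arr.ind = TRUE)
        .stopInput("empty cell(s): %s",
                   paste(sprintf("(%s, %s)", rownames(cells)[bad[, 1L]],
                                 colnames(cells)[bad[, 2L]]), collapse = ", "))
    }
    d <- data.frame(value = values, A = A, B = B)
    fit <- stats::lm(value ~ A * B, data = d)
    ## type-II sums of squares from nested model comparisons (each main
    ## effect adjusted for the other; interaction adjusted for both)
    rss <- function(fm) sum(stats::residuals(stats::lm(fm, data = d))^2)
    rssAB <- rss(value ~ A + B)
    ss <- c(factor_a = rss(value ~ B) - rssAB,
            factor_b = rss(value ~ A) - rssAB,
            interaction = rssAB - sum(stats::residuals(fit)^2))
    df <- c(nlevels(A) - 1L, nlevels(B) - 1L,
            (nlevels(A) - 1L) * (nlevels(B) - 1L))
    dfe <- stats::df.residual(fit)
    mse <- sum(stats::residuals(fit)^2)
    msePer <- if (dfe > 0) mse / dfe else 0
    tol <- .Machine$double.eps^0.5 * max(1, sum(values^2))
    fstat <- numeric(3); pval <- numeric(3)
    for (k in 1:3) {
        if (ss[k] < tol) {                       # no effect at all
            fstat[k] <- 0; pval[k] <- 1
        } else if (msePer <= tol / max(1, dfe)) { # perfect fit, real effect
            fstat[k] <- Inf; pval[k] <- 0
        } else {
            fstat[k] <- (ss[k] / df[k]) / msePer
            pval[k] <- stats::pf(fstat[k], df[k], dfe, lower.tail = FALSE)
        }
    }
    eff <- data.frame(test = "twoway_anova_typeII",
                      effect = names(ss),
                      sum_sq = unname(ss), df = df,
                      statistic = fstat, p_value = pval,
                      stringsAsFactors = FALSE)
    cmean <- tapply(d$value, list(d$A, d$B), mean)
    pairsA <- utils::combn(levels(A), 2L)
    comp <- list()
    for (bl in levels(B)) for (k in seq_len(ncol(pairsA))) {
        a1 <- pairsA[1L, k]; a2 <- pairsA[2L, k]
        n1 <- cells[a1, bl]; n2 <- cells[a2, bl]
        diff <- cmean[a1, bl] - cmean[a2, bl]
        se <- sqrt(msePer * (1 / n1 + 1 / n2))
        if (se == 0) {
            t <- if (abs(diff) < .Machine$double.eps^0.5) 0 else Inf
        } else t <- diff / se
        p <- if (dfe > 0 && is.finite(t))
            min(1, 2 * stats::pt(-abs(t), dfe)) else if (t == 0) 1 else 0
        comp[[length(comp) + 1L]] <-
            .testResult("sidak_pairwise", t, p,
                        group1 = sprintf("%s|%s", a1, bl),
                        group2 = sprintf("%s|%s", a2, bl),
                        n1 = n1, n2 = n2)
    }
    pw <- do.call(rbind, comp)
    pw$adjusted_p <- .adjustFamily(pw$p_value, "sidak")
    list(anova = eff, pairwise = pw)
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped (with a warning when all are zero, in
#' which case p = 1). For n <= \code{exactMax} the two-sided p is exact,
#' by enumeration of all 2^n sign patterns on the midranks of |d| (valid
#' under the symmetry null also with ties); larger n use the normal
#' approximation with tie and continuity correction.
#'
#' @param pairedDiffs numeric vector of paired differences.
#' @param exactMax largest n for the exact method (default 15).
#' @return one-row data.frame (statistic = V, the positive-rank sum).
#' @export
wilcoxonSignedRank <- function(pairedDiffs, exactMax = 15L) {
    d <- pairedDiffs[is.finite(pairedDiffs)]
    if (!length(d)) .stopInput("no finite differences")
    nz <- d[d != 0]
    if (!length(nz)) {
        warning("all differences are zero; degenerate test, p = 1")
        return(.testResult("wilcoxon_signed_rank", 0, 1, n1 = 0L))
    }
    n <- length(nz)
    r <- .midranks(abs(nz))
    v <- sum(r[nz > 0])
    if (n <= exactMax) {
        signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
        vs <- as.vector(signs %*% r)
        p <- min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
    } else {
        mu <- n * (n + 1) / 4
        tt <- table(abs(nz))
        sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
        z <- v - mu
        z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    .testResult("wilcoxon_signed_rank", v, p, n1 = n)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors of equal length (n >= 3), both with nonzero
#'   variance.
#' @return one-row data.frame (statistic = r).
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3L)
        .stopInput("x and y must have equal length >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        .stopInput("zero variance in x or y")
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    .testResult("pearson", unname(ct$estimate), ct$p.value, n1 = length(x))
}

#' ROUT outlier flagging (one-sample)
#'
#' Robust location/scale fit followed by FDR-controlled flagging of
#' extreme residuals, for a univariate measurement set: residuals from
#' the median are scaled by the robust standard deviation of the
#' residuals (the 68.27th percentile of |residuals|, inflated by
#' sqrt(n/(n-1))); candidates are examined from the most extreme
#' inwards and flagged while the two-sided t probability (df = n - 1)
#' stays below the stepwise threshold q * (n - i + 1) / n.
#' Deterministic for fixed input and invariant under affine
#' transformations of the data.
#'
#' @param values numeric vector, n >= 3.
#' @param q false-discovery rate, in (0, 0.5]; default 0.01.
#' @return list(flags = logical vector, q = q, method = "ROUT").
#' @export
routOutliers <- function(values, q = 0.01) {
    n <- length(values)
    if (n < 3L) .stopInput("need n >= 3")
    if (q <= 0 || q > 0.5) .stopInput("q must be in (0, 0.5]")
    res <- values - stats::median(values)
    rsdr <- stats::quantile(abs(res), 0.6827, names = FALSE) *
        sqrt(n / (n - 1))
    flags <- logical(n)
    if (rsdr == 0) {
        flags[abs(res) > 0] <- TRUE   # residuals from exact consensus
        return(list(flags = flags, q = q, method = "ROUT"))
    }
    ord <- order(abs(res), decreasing = TRUE)
    for (i in seq_len(n)) {
        t <- abs(res[ord[i]]) / rsdr
        p <- 2 * stats::pt(-t, df = n - 1)
        alpha <- q * (n - i + 1) / n
        if (p < alpha) flags[ord[i]] <- TRUE else break
    }
    list(flags = flags, q = q, method = "ROUT")
}
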