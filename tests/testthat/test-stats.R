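test_that("Mann-Whitney: spec fixtures and exact enumeration", {
    ## disjoint groups {1,2,3} vs {4,5,6}: U = 0, exact p = 2/20
    r <- mannWhitneyTwoSided(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$statistic, 0)
    expect_equal(r$p_value, 0.1, tolerance = 1e-12)
    ## identical samples -> p = 1
    expect_equal(mannWhitneyTwoSided(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
    ## exact p equals the enumeration oracle for random small samples
    set.seed(31)
    for (k in 1:10) {
        a <- round(rnorm(sample(3:7, 1)), 4)
        b <- round(rnorm(sample(3:7, 1)) + runif(1, -1, 1), 4)
        expect_equal(mannWhitneyTwoSided(a, b)$p_value,
                     oracleMannWhitneyExact(a, b), tolerance = 1e-12,
                     label = sprintf("draw %d", k))
    }
    ## cross-check against the standard library implementation
    set.seed(5)
    a <- rnorm(6); b <- rnorm(7) + 0.4
    expect_equal(mannWhitneyTwoSided(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
    expect_error(mannWhitneyTwoSided(numeric(0), 1),
                 class = "discRim_input_error")
})

test_that("Mann-Whitney type-I error sits at the nominal level", {
    set.seed(2024)
    rej <- mean(replicate(2000, {
        mannWhitneyTwoSided(rnorm(10), rnorm(10))$p_value < 0.05
    }))
    expect_gte(rej, 0.035)
    expect_lte(rej, 0.065)
})

test_that("Kruskal-Wallis + Dunn: null case, H formula, shifted group", {
    g0 <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
    r0 <- kruskalDunn(g0)
    expect_lt(r0$omnibus$statistic, 1e-9)
    expect_true(all(r0$pairwise$adjusted_p > 0.99))
    ## H matches a direct rank-formula computation on a fixed 3x4 table
    gt <- list(a = c(2.1, 3.5, 1.2, 4.4), b = c(5.0, 6.1, 5.5, 7.2),
               c = c(1.1, 2.2, 2.9, 3.3))
    expect_equal(kruskalDunn(gt)$omnibus$statistic, oracleKruskalH(gt),
                 tolerance = 1e-12)
    ## one strongly shifted group is detected in >= 95% of 200 seeds
    hits <- vapply(1:200, function(s) {
        set.seed(s)
        g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 4)
        pw <- kruskalDunn(g)$pairwise
        min(pw$adjusted_p[pw$group1 == "a" & pw$group2 == "c" |
                          pw$group1 == "b" & pw$group2 == "c"]) < 0.05
    }, TRUE)
    expect_gte(mean(hits), 0.95)
    ## adjusted p >= raw p always; relabelling permutes but preserves results
    pw <- kruskalDunn(gt)$pairwise
    expect_true(all(pw$adjusted_p >= pw$p_value - 1e-15))
    expect_true(all(pw$adjusted_p <= 1))
    perm <- kruskalDunn(gt[c(3, 1, 2)])$pairwise
    expect_equal(sort(perm$p_value), sort(pw$p_value), tolerance = 1e-12)
    expect_error(kruskalDunn(gt[1:2]), class = "discRim_input_error")
})

test_that("two-way ANOVA: degenerate null, Sidak identity, closed-form SS", {
    ## all cells equal constants, no noise -> all F = 0 by convention
    d0 <- expand.grid(A = c("wt", "mut"), B = c("ctl", "drug"), rep = 1:3)
    r0 <- twowayAnovaSidak(rep(5, nrow(d0)), d0$A, d0$B)
    expect_true(all(r0$anova$statistic == 0))
    expect_true(all(r0$anova$p_value == 1))
    ## Sidak with m = 1 leaves p unchanged: single pair within one level
    expect_equal(discRim:::.adjustFamily(0.03, "sidak"), 0.03)
    ## balanced 2x2 with additive effects, no noise: closed-form decomposition
    d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:4)
    alpha <- ifelse(d$A == "a1", -1.5, 1.5)
    beta <- ifelse(d$B == "b1", -2, 2)
    v <- 10 + alpha + beta
    r <- twowayAnovaSidak(v, d$A, d$B)
    n <- nrow(d)
    expect_equal(r$anova$sum_sq[r$anova$effect == "factor_a"],
                 n * 1.5^2, tolerance = 1e-9)
    expect_equal(r$anova$sum_sq[r$anova$effect == "factor_b"],
                 n * 2^2, tolerance = 1e-9)
    expect_equal(r$anova$sum_sq[r$anova$effect == "interaction"], 0,
                 tolerance = 1e-9)
    ## pairwise table: adjusted >= raw, and strong effects detected with noise
    set.seed(9)
    vn <- v + rnorm(n, 0, 0.5)
    rn <- twowayAnovaSidak(vn, d$A, d$B)
    expect_true(all(rn$pairwise$adjusted_p >= rn$pairwise$p_value - 1e-15))
    expect_true(all(rn$pairwise$adjusted_p < 0.01))
    ## unbalanced noisy design: type-II table matches the car reference
    set.seed(40)
    du <- data.frame(A = rep(c("a1", "a2"), c(9, 6)),
                     B = sample(c("b1", "b2"), 15, TRUE))
    du$v <- rnorm(15) + (du$A == "a2") * 1.2 + (du$B == "b2") * 0.7
    ru <- twowayAnovaSidak(du$v, du$A, du$B)
    ca <- car::Anova(lm(v ~ A * B, data = du), type = 2)
    expect_equal(ru$anova$sum_sq, ca[c("A", "B", "A:B"), "Sum Sq"],
                 tolerance = 1e-9)
    expect_equal(ru$anova$p_value, ca[c("A", "B", "A:B"), "Pr(>F)"],
                 tolerance = 1e-9)
    expect_error(twowayAnovaSidak(1:3, c("a", "a", "b"), c("x", "x", "x")),
                 class = "discRim_input_error")
    expect_error(
        twowayAnovaSidak(1:3, c("a", "a", "b"), c("x", "y", "x")),
        class = "discRim_input_error")   # empty (b, y) cell
})

test_that("Wilcoxon signed-rank: spec fixtures and exact enumeration", {
    ## symmetric pair -> p = 1
    expect_equal(wilcoxonSignedRank(c(-1, 1))$p_value, 1)
    ## all-positive {1..5} -> 2/32
    r <- wilcoxonSignedRank(c(1, 2, 3, 4, 5))
    expect_equal(r$statistic, 15)
    expect_equal(r$p_value, 0.0625, tolerance = 1e-12)
    ## random n <= 10 match the sign-pattern enumeration oracle
    set.seed(17)
    for (k in 1:10) {
        d <- round(rnorm(sample(4:10, 1), 0.3), 4)
        expect_equal(wilcoxonSignedRank(d)$p_value, oracleSignedRankExact(d),
                     tolerance = 1e-12, label = sprintf("draw %d", k))
    }
    ## cross-check against the standard library implementation (no ties)
    set.seed(33); d <- rnorm(9, 0.5)
    expect_equal(wilcoxonSignedRank(d)$p_value,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
    expect_warning(z <- wilcoxonSignedRank(c(0, 0, 0)), "zero")
    expect_equal(z$p_value, 1)
})

test_that("Pearson correlation: affine cases and the covariance formula", {
    x <- c(1, 2, 4, 7, 11)
    expect_equal(pearsonR(x, x)$statistic, 1)
    expect_equal(pearsonR(x, -2 * x + 7)$statistic, -1)
    y <- c(2.3, 1.9, 4.4, 6.0, 9.1)
    expect_equal(pearsonR(x, y)$statistic, oraclePearsonR(x, y),
                 tolerance = 1e-12)
    expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)),
                 class = "discRim_input_error")
    expect_error(pearsonR(1:2, 1:2), class = "discRim_input_error")
})

test_that("ROUT flags the planted outlier and respects affine equivariance", {
    ## constant data -> nothing flagged
    expect_false(any(routOutliers(rep(3, 6))$flags))
    ## classic fixture: only the wild value is flagged at Q = 1%
    v <- c(1, 1.1, 0.9, 1.05, 50)
    fl <- routOutliers(v, q = 0.01)$flags
    expect_identical(fl, c(FALSE, FALSE, FALSE, FALSE, TRUE))
    ## affine transformation leaves the flag set unchanged
    for (tr in list(c(3, 10), c(-2, 0.5), c(0.01, -7)))
        expect_identical(routOutliers(tr[1] * v + tr[2], q = 0.01)$flags, fl)
    ## deterministic
    expect_identical(routOutliers(v, 0.01), routOutliers(v, 0.01))
    expect_error(routOutliers(c(1, 2)), class = "discRim_input_error")
    expect_error(routOutliers(v, q = 0.8), class = "discRim_input_error")
})
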