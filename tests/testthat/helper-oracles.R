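## Independent brute-force oracles used to validate the pipeline's
## implementations. These deliberately use naive exhaustive computations
## and share no code with the package internals.

options(discRim.verbose = FALSE)

## exhaustive per-pixel Euclidean distance to the nearest background pixel
oracleDistToBackground <- function(mask) {
    H <- nrow(mask); W <- ncol(mask)
    bg <- which(!mask)
    yb <- ((bg - 1L) %% H) + 1L
    xb <- ((bg - 1L) %/% H) + 1L
    out <- matrix(0, H, W)
    for (i in which(mask)) {
        y <- ((i - 1L) %% H) + 1L
        x <- ((i - 1L) %/% H) + 1L
        out[i] <- sqrt(min((yb - y)^2 + (xb - x)^2))
    }
    out
}

## exhaustive minimum pairwise distance between two pixel sets
oracleMinPairDist <- function(maskA, maskB) {
    H <- nrow(maskA)
    ia <- which(maskA); ib <- which(maskB)
    ya <- ((ia - 1L) %% H) + 1L; xa <- ((ia - 1L) %/% H) + 1L
    yb <- ((ib - 1L) %% H) + 1L; xb <- ((ib - 1L) %/% H) + 1L
    best <- Inf
    for (k in seq_along(ia))
        best <- min(best, min((yb - ya[k])^2 + (xb - xa[k])^2))
    sqrt(best)
}

## rim/centre normalized ratio straight from masked sums
oracleRimCentreRatio <- function(mark, ref, rim, centre) {
    (sum(mark[rim]) / sum(ref[rim])) / (sum(mark[centre]) / sum(ref[centre]))
}

## exact two-sided Mann-Whitney p by enumeration of group assignments;
## U computed by pair counting, not rank sums
oracleMannWhitneyExact <- function(a, b) {
    pooled <- c(a, b)
    n1 <- length(a); n <- length(pooled)
    uOf <- function(idx) {
        ga <- pooled[idx]; gb <- pooled[-idx]
        sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
    }
    uObs <- uOf(seq_len(n1))
    us <- apply(utils::combn(n, n1), 2L, uOf)
    min(1, 2 * min(mean(us <= uObs + 1e-9), mean(us >= uObs - 1e-9)))
}

## exact two-sided Wilcoxon signed-rank p by sign-pattern enumeration
oracleSignedRankExact <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    vObs <- sum(r[d > 0])
    vs <- vapply(0:(2^n - 1), function(bits) {
        sum(r[bitwAnd(bits, 2^(seq_len(n) - 1)) > 0])
    }, 1)
    min(1, 2 * min(mean(vs <= vObs + 1e-9), mean(vs >= vObs - 1e-9)))
}

## hand computation of the tie-corrected Kruskal-Wallis H
oracleKruskalH <- function(groups) {
    x <- unlist(groups)
    g <- rep(seq_along(groups), lengths(groups))
    n <- length(x)
    r <- rank(x)
    h <- 12 / (n * (n + 1)) *
        sum(tapply(r, g, function(ri) length(ri) *
                       (mean(ri) - (n + 1) / 2)^2))
    tt <- table(x)
    h / (1 - sum(tt^3 - tt) / (n^3 - n))
}

## plain quotient-of-sums Pearson r
oraclePearsonR <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

makePlane <- function(values, px = 0.5) {
    discRim:::.newPlane(values, px, "test fixture")
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
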