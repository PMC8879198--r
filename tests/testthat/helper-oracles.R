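# Shared independent oracles and fixture helpers for the suite.

# random profile with distinct gaussian-scored columns
randomProfile <- function(L, seed = NULL, label = "p") {
    if (!is.null(seed)) set.seed(seed)
    sequenceProfile(paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
                    matrix(rnorm(L * 20), L, 20), label = label)
}

profileScoreMatrix <- function(q, t) {
    A <- profileColumns(q); B <- profileColumns(t)
    matrix(sapply(seq_len(nrow(B)), function(j)
        sapply(seq_len(nrow(A)), function(i) columnScore(A[i, ], B[j, ]))),
        nrow(A), nrow(B))
}

# affine gap cost of a gap block of length g
gapCost <- function(g, go, ge) ifelse(g <= 0, 0, go + (g - 1) * ge)

# free-end-gap semantics: a double overhang at a terminus pays for the
# cheaper side only (the other side is the free end gap)
endCost <- function(a, b, go, ge) {
    ifelse(a == 0 | b == 0, 0, pmin(gapCost(a, go, ge), gapCost(b, go, ge)))
}

# score one monotone alignment (pair index vectors) under glocal scoring
alignmentPathScore <- function(S, qi, ti, go, ge) {
    k <- length(qi)
    if (k == 0) return(0)
    sc <- sum(S[cbind(qi, ti)])
    if (k > 1)
        sc <- sc - sum(gapCost(diff(qi) - 1, go, ge)) -
            sum(gapCost(diff(ti) - 1, go, ge))
    sc - endCost(qi[1] - 1, ti[1] - 1, go, ge) -
        endCost(nrow(S) - qi[k], ncol(S) - ti[k], go, ge)
}

# exhaustive enumeration of every monotone alignment (tiny inputs only)
bruteForceAlignScore <- function(S, go, ge) {
    n <- nrow(S); m <- ncol(S)
    best <- 0
    combs <- function(v, k) if (k == 0) list(integer(0)) else
        combn(v, k, simplify = FALSE)
    for (k in seq_len(min(n, m))) {
        for (qi in combs(seq_len(n), k)) for (ti in combs(seq_len(m), k)) {
            sc <- alignmentPathScore(S, qi, ti, go, ge)
            if (sc > best) best <- sc
        }
    }
    best
}

# brute-force circular cross-correlation numerator at a given voxel shift
bruteShiftNumerator <- function(ev, sv, shift) {
    d <- dim(ev)
    idx <- lapply(1:3, function(k) (((seq_len(d[k]) - 1) - shift[k]) %% d[k]) + 1)
    sum(ev * sv[idx[[1]], idx[[2]], idx[[3]]])
}

# dense-rotation-grid + polish oracle for minimal superposition RMSD
gridSearchMinRmsd <- function(P, Q, stepDeg = 15) {
    rmsd_of <- function(R) {
        Pm <- P %*% t(R)
        Pm <- sweep(Pm, 2, colMeans(Q) - colMeans(Pm), "+")
        sqrt(mean(rowSums((Pm - Q)^2)))
    }
    best <- Inf; bestAngles <- c(0, 0, 0)
    d2r <- pi / 180
    rotzyz <- function(a, b, g) {
        Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                                   0, 0, 1), 3, 3)
        Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                                   sin(t), 0, cos(t)), 3, 3)
        Rz(a) %*% Ry(b) %*% Rz(g)
    }
    for (a in seq(0, 360 - stepDeg, by = stepDeg) * d2r)
        for (b in seq(0, 180, by = stepDeg) * d2r)
            for (g in seq(0, 360 - stepDeg, by = stepDeg) * d2r) {
                v <- rmsd_of(rotzyz(a, b, g))
                if (v < best) { best <- v; bestAngles <- c(a, b, g) }
            }
    opt <- optim(bestAngles, function(p) rmsd_of(rotzyz(p[1], p[2], p[3])),
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    opt$value
}

# brute-force O(n^2) contact enumeration under the restraint rule
bruteContactCount <- function(model, cutoff) {
    a <- atoms(model)
    ca <- a[a$elety == "CA", ]
    n <- nrow(ca)
    cnt <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        same <- ca$chain[i] == ca$chain[j]
        if (same && abs(ca$resno[j] - ca$resno[i]) < 3) next
        d <- sqrt(sum((ca[i, c("x", "y", "z")] - ca[j, c("x", "y", "z")])^2))
        if (d <= cutoff) cnt <- cnt + 1
    }
    cnt
}
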