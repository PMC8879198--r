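#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation of \code{mobile} minimizing the
#' RMSD to \code{reference} over a set of paired atoms, via SVD of the
#' cross-covariance matrix with the usual reflection correction.
#'
#' @param mobile,reference \code{AtomicModel}s or n x 3 coordinate matrices.
#' @param pairing two-column integer matrix of (mobile index, reference
#'   index) atom pairs; default pairs atoms 1:n of both.
#' @return list with \code{transform} (a \code{RigidTransform} to apply to
#'   \code{mobile}) and \code{rmsd} (\enc{Å}{Angstrom}).
#' @export
superposeKabsch <- function(mobile, reference, pairing = NULL) {
    X <- if (is(mobile, "AtomicModel")) coords(mobile) else as.matrix(mobile)
    Y <- if (is(reference, "AtomicModel")) coords(reference) else as.matrix(reference)
    if (is.null(pairing)) {
        n <- min(nrow(X), nrow(Y))
        pairing <- cbind(seq_len(n), seq_len(n))
    }
    pairing <- as.matrix(pairing)
    if (nrow(pairing) < 3) stop("superposition needs at least 3 paired points")
    P <- X[pairing[, 1], , drop = FALSE]
    Q <- Y[pairing[, 2], , drop = FALSE]
    pc <- colMeans(P); qc <- colMeans(Q)
    P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
    # collinearity check: rank of the centered point set
    if (sum(svd(P0)$d > 1e-9 * max(1, max(abs(P0)))) < 2)
        stop("degenerate superposition: paired points are collinear")
    H <- crossprod(P0, Q0)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    tr <- qc - as.vector(R %*% pc)
    moved <- sweep(P %*% t(R), 2, tr, "+")
    rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
    list(transform = rigidTransform(R, tr), rmsd = rmsd)
}

#' RMSD between paired coordinates without superposition
#' @param a,b \code{AtomicModel}s or coordinate matrices with equal rows.
#' @return root-mean-square deviation in \enc{Å}{Angstrom}.
#' @export
rmsd <- function(a, b) {
    A <- if (is(a, "AtomicModel")) coords(a) else as.matrix(a)
    B <- if (is(b, "AtomicModel")) coords(b) else as.matrix(b)
    stopifnot(nrow(A) == nrow(B))
    sqrt(mean(rowSums((A - B)^2)))
}

#' TM-score between two structures under a fixed residue pairing
#'
#' Length-normalized structure similarity in (0, 1]:
#' \deqn{TM = \max_{superposition} \frac{1}{L_{ref}} \sum_i \frac{1}{1 + (d_i/d_0)^2}}
#' with \eqn{d_0 = 1.24 (L_{ref} - 15)^{1/3} - 1.8}. The maximization is
#' approximated by the standard heuristic: Kabsch superpositions seeded from
#' the full pairing and from contiguous fragments, each refined by iterating
#' Kabsch on the subset of pairs with \eqn{d_i < 2 d_0}. Exactness is
#' guaranteed only for rigid copies (where the optimum is attained); for
#' general pairs the result is a lower bound on the true optimum.
#'
#' @param model,reference \code{AtomicModel}s or coordinate matrices.
#' @param pairing two-column index matrix (model, reference); default
#'   identity over the shorter length. Must have >= 16 pairs.
#' @return TM-score in (0, 1].
#' @export
tmScore <- function(model, reference, pairing = NULL) {
    X <- if (is(model, "AtomicModel")) coords(caTrace(model)) else as.matrix(model)
    Y <- if (is(reference, "AtomicModel")) coords(caTrace(reference)) else as.matrix(reference)
    if (is.null(pairing)) {
        n <- min(nrow(X), nrow(Y))
        pairing <- cbind(seq_len(n), seq_len(n))
    }
    pairing <- as.matrix(pairing)
    L <- nrow(pairing)
    if (L < 16) stop("TM-score requires at least 16 paired residues (d0 validity)")
    d0 <- 1.24 * (L - 15)^(1/3) - 1.8
    P <- X[pairing[, 1], , drop = FALSE]
    Q <- Y[pairing[, 2], , drop = FALSE]
    tm_of <- function(Pm) mean(1 / (1 + rowSums((Pm - Q)^2) / d0^2))
    seeds <- list(seq_len(L))
    for (fl in unique(pmin(L, c(4, L %/% 2)))) {
        if (fl >= 3) {
            starts <- unique(round(seq(1, L - fl + 1, length.out = min(8, L - fl + 1))))
            for (s in starts) seeds <- c(seeds, list(seq(s, s + fl - 1)))
        }
    }
    best <- 0
    for (sub in seeds) {
        idx <- sub
        for (iter in 1:20) {
            if (length(idx) < 3) break
            sp <- tryCatch(superposeKabsch(P[idx, , drop = FALSE],
                                           Q[idx, , drop = FALSE]),
                           error = function(e) NULL)
            if (is.null(sp)) break
            Pm <- applyTransform(P, sp$transform)
            best <- max(best, tm_of(Pm))
            d <- sqrt(rowSums((Pm - Q)^2))
            new_idx <- which(d < 2 * d0)
            if (length(new_idx) < 3 || identical(new_idx, idx)) break
            idx <- new_idx
        }
    }
    best
}
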