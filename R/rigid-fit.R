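#' Configuration for exhaustive rigid-body docking
#'
#' @param simParams \code{DensitySimParams} used to simulate candidate
#'   densities (its sigma should match the experimental map resolution).
#' @param angularStep Euler-lattice step in degrees, in (0, 90] (default 20).
#' @param topKRescore number of translation-scan candidates re-scored with
#'   the exact CCC (default 20).
#' @param peakMinSeparation minimum voxel separation between translation
#'   peaks kept per rotation (default 2).
#' @param peaksPerRotation translation peaks retained per rotation (default 2).
#' @param refine locally refine the best candidates over the 6 rigid degrees
#'   of freedom by derivative-free CCC maximization (default TRUE).
#' @return list of class \code{"RigidSearchConfig"}.
#' @export
rigidSearchConfig <- function(simParams, angularStep = 20, topKRescore = 20,
                              peakMinSeparation = 2, peaksPerRotation = 2,
                              refine = TRUE) {
    if (angularStep <= 0 || angularStep > 90)
        stop("angularStep must be in (0, 90]")
    if (topKRescore < 1) stop("topKRescore must be >= 1")
    structure(list(simParams = simParams, angularStep = angularStep,
                   topKRescore = topKRescore,
                   peakMinSeparation = peakMinSeparation,
                   peaksPerRotation = peaksPerRotation, refine = refine),
              class = "RigidSearchConfig")
}

.rotZ <- function(a) {
    ca <- cos(a); sa <- sin(a)
    matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}
.rotY <- function(a) {
    ca <- cos(a); sa <- sin(a)
    matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Deterministic covering of rotation space by a z-y-z Euler lattice
#'
#' Rotations \code{Rz(alpha) Ry(beta) Rz(gamma)} with all three angles on a
#' lattice of the stated step; the gimbal-degenerate rings at beta = 0 and
#' 180 degrees keep a single gamma. The list always contains the identity.
#'
#' @param angularStep lattice step in degrees, in (0, 90].
#' @return list of 3x3 rotation matrices.
#' @export
enumerateRotations <- function(angularStep) {
    if (angularStep <= 0 || angularStep > 90)
        stop("angularStep must be in (0, 90]")
    d2r <- pi / 180
    alphas <- seq(0, 360 - angularStep, by = angularStep) * d2r
    betas <- seq(0, 180, by = angularStep) * d2r
    if (max(betas) < pi) betas <- c(betas, pi)
    gammas <- alphas
    out <- vector("list", 0)
    for (b in betas) {
        Ry_b <- .rotY(b)
        gs <- if (abs(b) < 1e-12 || abs(b - pi) < 1e-12) 0 else gammas
        for (a in alphas) for (g in gs)
            out[[length(out) + 1L]] <- .rotZ(a) %*% Ry_b %*% .rotZ(g)
    }
    out
}

#' FFT translation scan of a simulated map against an experimental map
#'
#' Computes the cross-correlation numerator
#' \eqn{\sum_v \rho_{exp}(v)\, \rho_{sim}(v - s)} for every integer voxel
#' shift s (circularly, via 3-D FFT after zero-padding the simulated map to
#' the experimental grid). The best shift is the argmax, reported in the
#' signed range; ties are broken by smallest shift norm, then
#' lexicographically.
#'
#' @param expMap,simMap \code{DensityMap}s with equal spacing;
#'   \code{simMap} dims must not exceed \code{expMap} dims.
#' @return list with \code{scores} (array of numerators indexed by shift +
#'   1, modulo dims), \code{bestShift} (signed integer 3-vector) and
#'   \code{bestScore}.
#' @export
translationScan <- function(expMap, simMap) {
    if (max(abs(mapSpacing(expMap) - mapSpacing(simMap))) > 1e-6)
        stop("translation scan requires equal voxel spacing")
    de <- mapDims(expMap); ds <- mapDims(simMap)
    if (any(ds > de)) stop("simulated map dims must not exceed experimental dims")
    sim <- array(0, de)
    sim[seq_len(ds[1]), seq_len(ds[2]), seq_len(ds[3])] <- mapValues(simMap)
    num <- Re(stats::fft(stats::fft(mapValues(expMap)) * Conj(stats::fft(sim)),
                         inverse = TRUE)) / prod(de)
    best <- which(num == max(num))
    sh <- arrayInd(best, de) - 1L
    signed <- sh - de[col(sh)] * (sh > de[col(sh)] / 2)
    if (nrow(signed) > 1) {
        ord <- order(rowSums(signed^2), signed[, 1], signed[, 2], signed[, 3])
        signed <- signed[ord, , drop = FALSE]
    }
    list(scores = num, bestShift = as.integer(signed[1, ]),
         bestScore = max(num))
}

# greedy extraction of up to k peak shifts separated by >= sep voxels
.topPeaks <- function(num, k, sep) {
    d <- dim(num)
    peaks <- matrix(integer(0), 0, 3)
    vals <- numeric(0)
    work <- num
    for (p in seq_len(k)) {
        i <- which.max(work)
        if (!is.finite(work[i])) break
        ind <- arrayInd(i, d)
        peaks <- rbind(peaks, ind - 1L)
        vals <- c(vals, num[i])
        # mask a cube of half-width sep around the peak (circular)
        rng <- lapply(1:3, function(ax)
            ((ind[ax] - 1 + (-sep):sep) %% d[ax]) + 1)
        work[rng[[1]], rng[[2]], rng[[3]]] <- -Inf
    }
    list(shifts = peaks, values = vals)
}

#' Exhaustive rigid-body docking of a model into a density map
#'
#' For each rotation of a z-y-z Euler lattice the model is centered,
#' rotated, placed at the grid center and its simulated density is scanned
#' over all integer voxel translations by FFT (the cross-correlation
#' numerator; the denominator term \eqn{\sum \rho_{sim}^2} is nearly
#' translation-invariant, so numerator ranking approximates CCC ranking).
#' The globally best candidates are re-scored with the exact CCC, the given
#' input pose is always included as a candidate (so the top placement never
#' scores below the unfitted pose), and the best candidates are optionally
#' polished by local derivative-free maximization of the CCC over the six
#' rigid degrees of freedom.
#'
#' @param expMap experimental \code{DensityMap}.
#' @param model an \code{AtomicModel}.
#' @param config a \code{RigidSearchConfig}.
#' @return list of \code{Placement}, ranked by non-increasing ccc. Each
#'   transform maps the input model into the map.
#' @export
rigidFit <- function(expMap, model, config) {
    stopifnot(inherits(config, "RigidSearchConfig"))
    params <- config$simParams
    xyz <- coords(model)
    mu <- colMeans(xyz)
    centered <- sweep(xyz, 2, mu)
    d <- mapDims(expMap)
    sp <- mapSpacing(expMap)
    c0 <- mapOrigin(expMap) + (d - 1) / 2 * sp
    rots <- enumerateRotations(config$angularStep)
    geom <- list(origin = mapOrigin(expMap), spacing = sp, dims = d)
    fexp <- stats::fft(mapValues(expMap))
    nvox <- prod(d)
    cand <- vector("list", 0)
    for (ri in seq_along(rots)) {
        R <- rots[[ri]]
        pos <- sweep(centered %*% t(R), 2, c0, "+")
        sim <- .cppSimDensity(pos, geom$origin, geom$spacing,
                              as.integer(geom$dims), params$sigma,
                              params$truncationRadius)
        num <- Re(stats::fft(fexp * Conj(stats::fft(array(sim, d))),
                             inverse = TRUE)) / nvox
        pk <- .topPeaks(num, config$peaksPerRotation, config$peakMinSeparation)
        for (p in seq_len(nrow(pk$shifts)))
            cand[[length(cand) + 1L]] <- list(rot = ri, shift = pk$shifts[p, ],
                                              num = pk$values[p])
    }
    if (length(cand) == 0) stop("rigid fit search produced no candidates")
    ord <- order(vapply(cand, `[[`, numeric(1), "num"), decreasing = TRUE)
    cand <- cand[ord[seq_len(min(config$topKRescore, length(cand)))]]
    eval_pose <- function(R, tvec) {
        pos <- sweep(xyz %*% t(R), 2, tvec, "+")
        sim <- .cppSimDensity(pos, geom$origin, geom$spacing,
                              as.integer(geom$dims), params$sigma,
                              params$truncationRadius)
        tryCatch(.cccRaw(as.numeric(mapValues(expMap)), sim),
                 error = function(e) NA_real_)
    }
    scored <- lapply(cand, function(cc) {
        R <- rots[[cc$rot]]
        shift <- cc$shift - d * (cc$shift > d / 2)  # wrap to signed
        tvec <- c0 + shift * sp - as.vector(R %*% mu)
        list(R = R, t = tvec, ccc = eval_pose(R, tvec))
    })
    # the as-given pose is always a candidate
    scored[[length(scored) + 1L]] <- list(R = diag(3), t = c(0, 0, 0),
                                          ccc = eval_pose(diag(3), c(0, 0, 0)))
    keep <- vapply(scored, function(s) is.finite(s$ccc), logical(1))
    scored <- scored[keep]
    if (length(scored) == 0) stop("rigid fit failed: no candidate with finite ccc")
    sort_dedup <- function(sc) {
        ord <- order(vapply(sc, `[[`, numeric(1), "ccc"), decreasing = TRUE)
        sc <- sc[ord]
        kept <- list()
        for (s in sc) {
            dup <- any(vapply(kept, function(u)
                rotationAngle(s$R %*% t(u$R)) < config$angularStep / 2 &&
                sqrt(sum((s$t - u$t)^2)) <
                    config$peakMinSeparation * max(sp), logical(1)))
            if (!dup) kept[[length(kept) + 1L]] <- s
        }
        kept
    }
    scored <- sort_dedup(scored)
    if (isTRUE(config$refine)) {
        nref <- min(3L, length(scored))
        for (k in seq_len(nref)) {
            s0 <- scored[[k]]
            obj <- function(p) {
                Rd <- .axisAngleRotation(p[1:3])
                -eval_pose(Rd %*% s0$R, as.vector(Rd %*% s0$t) + p[4:6])
            }
            par <- rep(0, 6)
            for (round in 1:2) {  # Nelder-Mead with one restart
                opt <- stats::optim(par, obj, method = "Nelder-Mead",
                                    control = list(maxit = 400, reltol = 1e-9))
                par <- opt$par
            }
            if (-opt$value > s0$ccc) {
                Rd <- .axisAngleRotation(par[1:3])
                scored[[k]] <- list(R = Rd %*% s0$R,
                                    t = as.vector(Rd %*% s0$t) + par[4:6],
                                    ccc = -opt$value)
            }
        }
        scored <- sort_dedup(scored)
    }
    lapply(seq_along(scored), function(k)
        new("Placement",
            transform = rigidTransform(scored[[k]]$R, scored[[k]]$t),
            ccc = scored[[k]]$ccc, rank = as.integer(k)))
}

# rotation matrix from a rotation vector (axis * angle, radians)
.axisAngleRotation <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

setMethod("show", "Placement", function(object) {
    cat(sprintf("Placement rank %d: ccc = %.4f\n", object@rank, object@ccc))
    show(object@transform)
})

#' Tabulate a list of placements
#' @param placements list of \code{Placement} from \code{\link{rigidFit}}.
#' @return data.frame with rank, ccc and rotation angle / translation norm.
#' @export
placementTable <- function(placements) {
    do.call(rbind, lapply(placements, function(p) data.frame(
        rank = p@rank, ccc = p@ccc,
        rotationDeg = rotationAngle(p@transform),
        translationA = sqrt(sum(p@transform@translation^2)))))
}
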