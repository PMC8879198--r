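# centered Pearson over a voxel subset; errors on zero variance
.pearsonSubset <- function(a, b, idx) {
    x <- a[idx]; y <- b[idx]
    if (length(x) < 2) stop("metric region has fewer than 2 voxels")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        stop("degenerate metric region: zero variance")
    stats::cor(x, y)
}

.modelSim <- function(expMap, model, sigma, truncationRadius = 4) {
    params <- densitySimParams(sigma, truncationRadius = truncationRadius)
    as.numeric(mapValues(simulateDensity(model, expMap, params)))
}

.maskIdx <- function(expMap, model, radius) {
    xyz <- if (is(model, "AtomicModel")) coords(model) else as.matrix(model)
    m <- .cppAtomMask(xyz, mapOrigin(expMap), mapSpacing(expMap),
                      as.integer(mapDims(expMap)), radius)
    which(m)
}

#' CCmask: map-model correlation inside an atom-centered mask
#'
#' Centered Pearson correlation between the experimental map and the
#' model's simulated density over voxels whose centers lie within
#' \code{maskRadius} of any model atom. Measures the fit at atomic centers.
#'
#' @param expMap experimental \code{DensityMap} covering the model.
#' @param model an \code{AtomicModel}.
#' @param sigma simulation kernel width = nominal resolution,
#'   \enc{Å}{Angstrom}.
#' @param maskRadius fixed mask radius, \enc{Å}{Angstrom} (default 3).
#' @return correlation in [-1, 1].
#' @export
ccMask <- function(expMap, model, sigma, maskRadius = 3) {
    idx <- .maskIdx(expMap, model, maskRadius)
    if (length(idx) == 0) stop("empty mask: no voxel within maskRadius of model")
    .pearsonSubset(as.numeric(mapValues(expMap)),
                   .modelSim(expMap, model, sigma), idx)
}

# indices of the v highest-valued voxels of a vector (full sort, determinate)
.topVoxels <- function(vals, v) {
    v <- min(v, length(vals))
    order(vals, decreasing = TRUE)[seq_len(v)]
}

#' CCvolume and CCpeaks: correlations over highest-density regions
#'
#' Let v be the size of the atom mask used by \code{\link{ccMask}}.
#' \code{ccVolume} correlates over the v highest-valued voxels of the model
#' map (the molecular envelope); \code{ccPeaks} over the union of the v
#' highest voxels of the model map and the v highest of the experimental
#' map (the strongest peaks of both).
#'
#' @inheritParams ccMask
#' @return correlation in [-1, 1].
#' @export
ccVolume <- function(expMap, model, sigma, maskRadius = 3) {
    v <- length(.maskIdx(expMap, model, maskRadius))
    sim <- .modelSim(expMap, model, sigma)
    if (v > length(sim)) { warning("mask larger than grid; clipped"); v <- length(sim) }
    .pearsonSubset(as.numeric(mapValues(expMap)), sim, .topVoxels(sim, v))
}

#' @rdname ccVolume
#' @export
ccPeaks <- function(expMap, model, sigma, maskRadius = 3) {
    v <- length(.maskIdx(expMap, model, maskRadius))
    sim <- .modelSim(expMap, model, sigma)
    exp_v <- as.numeric(mapValues(expMap))
    if (v > length(sim)) { warning("mask larger than grid; clipped"); v <- length(sim) }
    idx <- union(.topVoxels(sim, v), .topVoxels(exp_v, v))
    .pearsonSubset(exp_v, sim, idx)
}

#' CCbox: correlation over the whole grid
#'
#' Centered Pearson correlation between the experimental map and the model
#' map over every voxel of the (possibly cropped) grid.
#'
#' @inheritParams ccMask
#' @return correlation in [-1, 1].
#' @export
ccBox <- function(expMap, model, sigma) {
    sim <- .modelSim(expMap, model, sigma)
    .pearsonSubset(as.numeric(mapValues(expMap)), sim,
                   seq_along(sim))
}

#' All four global CC metrics at once
#'
#' @inheritParams ccMask
#' @return a \code{MapModelScores}.
#' @export
mapModelCC <- function(expMap, model, sigma, maskRadius = 3) {
    idx <- .maskIdx(expMap, model, maskRadius)
    if (length(idx) == 0) stop("empty mask: no voxel within maskRadius of model")
    exp_v <- as.numeric(mapValues(expMap))
    sim <- .modelSim(expMap, model, sigma)
    v <- length(idx)
    new("MapModelScores",
        ccMask = .pearsonSubset(exp_v, sim, idx),
        ccVolume = .pearsonSubset(exp_v, sim, .topVoxels(sim, v)),
        ccPeaks = .pearsonSubset(exp_v, sim,
                                 union(.topVoxels(sim, v), .topVoxels(exp_v, v))),
        ccBox = .pearsonSubset(exp_v, sim, seq_along(sim)),
        maskVoxels = as.integer(v))
}

setMethod("show", "MapModelScores", function(object) {
    cat(sprintf("MapModelScores: CCmask %.3f  CCvolume %.3f  CCpeaks %.3f  CCbox %.3f (mask %d voxels)\n",
                object@ccMask, object@ccVolume, object@ccPeaks, object@ccBox,
                object@maskVoxels))
})

#' SMOC: per-residue segment-based Manders overlap coefficient
#'
#' For each residue a segment of \code{window} residues centered on it
#' (clipped at chain termini; chains shorter than the window use the whole
#' chain) defines a mask of voxels within \code{radius} of any segment
#' atom. The score is the non-centered Manders overlap
#' \eqn{\sum \rho_{exp}\rho_{sim} / \sqrt{\sum \rho_{exp}^2 \sum
#' \rho_{sim}^2}} over that mask — 1 when the local densities are
#' proportional, and in [0, 1] for non-negative maps.
#'
#' @inheritParams ccMask
#' @param window segment length in residues, odd (default 11).
#' @param radius mask radius around segment atoms, \enc{Å}{Angstrom}
#'   (default 3).
#' @return a \code{SmocProfile}; residues whose mask is empty get NA.
#' @export
smoc <- function(expMap, model, sigma, window = 11, radius = 3) {
    window <- as.integer(window)
    if (window %% 2L != 1L) stop("window must be odd")
    exp_v <- as.numeric(mapValues(expMap))
    sim <- .modelSim(expMap, model, sigma)
    a <- atoms(model)
    res <- unique(a[, c("chain", "resno")])
    rownames(res) <- NULL
    half <- window %/% 2L
    out <- res
    out$smoc <- NA_real_
    for (ch in unique(res$chain)) {
        rr <- which(res$chain == ch)
        nr <- length(rr)
        for (p in seq_len(nr)) {
            lo <- max(1, p - half); hi <- min(nr, p + half)
            seg_res <- res$resno[rr[lo:hi]]
            rows <- which(a$chain == ch & a$resno %in% seg_res)
            xyz <- as.matrix(a[rows, c("x", "y", "z")])
            idx <- .maskIdx(expMap, xyz, radius)
            if (length(idx) == 0) next
            se <- sum(exp_v[idx]^2); ss <- sum(sim[idx]^2)
            if (se == 0 || ss == 0) next
            out$smoc[rr[p]] <- sum(exp_v[idx] * sim[idx]) / sqrt(se * ss)
        }
    }
    new("SmocProfile", scores = out, window = window, radius = radius)
}

#' @rdname smoc
#' @param x a \code{SmocProfile}.
#' @export
smocScores <- function(x) x@scores

setMethod("show", "SmocProfile", function(object) {
    s <- object@scores$smoc
    cat(sprintf("SmocProfile: %d residues, window %d, radius %.1f A; mean %.3f, min %.3f\n",
                nrow(object@scores), object@window, object@radius,
                mean(s, na.rm = TRUE), min(s, na.rm = TRUE)))
})
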