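#' Parameters for simulating density from an atomic model
#'
#' The model density is a sum over heavy atoms of the isotropic Gaussian
#' kernel \eqn{g_n(r) = \exp(-\frac{3}{2\sigma^2} |r - r_n|^2)}, integrated
#' exactly over each voxel. \code{sigma} equals the nominal map resolution
#' in \enc{Å}{Angstrom} verbatim (no FWHM or half-resolution conversion; see
#' the package vignette — conventions differ between tools). Each voxel
#' integral is the product of three 1-D error-function differences;
#' contributions are truncated outside the rectangular box
#' \code{truncationRadius * sigma} around each atom.
#'
#' @param sigma kernel width = nominal resolution, \enc{Å}{Angstrom} (> 0).
#' @param truncationRadius truncation in units of sigma (>= 3, default 4).
#' @param margin \enc{Å}{Angstrom} added around the model bounding box when
#'   auto-gridding (default \code{truncationRadius * sigma}).
#' @param spacing voxel size used when auto-gridding (default
#'   \code{sigma / 2}).
#' @return a list of class \code{"DensitySimParams"}.
#' @export
densitySimParams <- function(sigma, truncationRadius = 4,
                             margin = truncationRadius * sigma,
                             spacing = sigma / 2) {
    if (sigma <= 0) stop("sigma must be > 0")
    if (truncationRadius < 3) stop("truncationRadius must be >= 3")
    structure(list(sigma = sigma, truncationRadius = truncationRadius,
                   margin = margin, spacing = spacing),
              class = "DensitySimParams")
}

# grid geometry covering the model bounding box plus margin
.autoGrid <- function(xyz, params) {
    lo <- apply(xyz, 2, min) - params$margin
    hi <- apply(xyz, 2, max) + params$margin
    sp <- rep(params$spacing, 3)
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / sp)) + 1L)
    list(origin = lo, spacing = sp, dims = dims)
}

#' Simulate a density map from an atomic model
#'
#' Computes \eqn{\rho_{sim}(i,j,k) = \sum_n \int_{V_{ijk}} g_n(r)\, dr}
#' (sum over heavy atoms of the Gaussian kernel integrated over each voxel;
#' see \code{\link{densitySimParams}}). The total over an ample grid
#' approaches \eqn{N (2\pi\sigma^2/3)^{3/2}}.
#'
#' @param model an \code{AtomicModel}.
#' @param grid \code{"auto"} (bounding box + margin) or a \code{DensityMap}
#'   whose geometry (origin/spacing/dims) is reused.
#' @param params a \code{DensitySimParams}.
#' @return a \code{DensityMap}.
#' @export
simulateDensity <- function(model, grid = "auto", params) {
    stopifnot(inherits(params, "DensitySimParams"))
    xyz <- if (is(model, "AtomicModel")) coords(model) else as.matrix(model)
    if (nrow(xyz) < 1) stop("model must contain at least one atom")
    if (is(grid, "DensityMap")) {
        g <- list(origin = mapOrigin(grid), spacing = mapSpacing(grid),
                  dims = mapDims(grid))
    } else if (identical(grid, "auto")) {
        g <- .autoGrid(xyz, params)
    } else {
        g <- grid  # list(origin, spacing, dims)
    }
    v <- .cppSimDensity(xyz, g$origin, g$spacing, as.integer(g$dims),
                        params$sigma, params$truncationRadius)
    densityMap(array(v, dim = g$dims), origin = g$origin, spacing = g$spacing,
               metadata = list(sigma = params$sigma))
}

#' @rdname ccc
#' @export
setMethod("ccc", signature("DensityMap", "DensityMap"), function(a, b) {
    if (!.sameGrid(a, b)) stop("ccc requires identical grid geometry")
    .cccRaw(as.numeric(a@values), as.numeric(b@values))
})

#' @rdname ccc
#' @export
setMethod("ccc", signature("numeric", "numeric"), function(a, b) {
    stopifnot(length(a) == length(b))
    .cccRaw(a, b)
})

.cccRaw <- function(a, b) {
    sa <- sum(a * a); sb <- sum(b * b)
    if (sa == 0 || sb == 0) stop("degenerate map: all-zero values")
    sum(a * b) / sqrt(sa * sb)
}

#' Zero a map outside spherical zones around anchor points
#'
#' Voxels whose centers lie farther than \code{radius} from every anchor
#' point are set to zero; the grid is unchanged. Used to split a complex's
#' map into subunit-sized fragments around a placed subunit model.
#'
#' @param map a \code{DensityMap}.
#' @param anchor an \code{AtomicModel} or an n x 3 matrix of points.
#' @param radius zone radius in \enc{Å}{Angstrom} (> 0).
#' @return a \code{DensityMap} with \code{metadata$retainedVoxels} set.
#' @export
segmentMapZone <- function(map, anchor, radius) {
    if (radius <= 0) stop("radius must be > 0")
    pts <- if (is(anchor, "AtomicModel")) coords(anchor) else as.matrix(anchor)
    keep <- .cppAtomMask(pts, mapOrigin(map), mapSpacing(map),
                         as.integer(mapDims(map)), radius)
    if (!any(keep)) stop("empty segment: no voxel center within radius of any anchor")
    v <- as.numeric(map@values)
    v[!keep] <- 0
    md <- map@metadata
    md$retainedVoxels <- sum(keep)
    densityMap(array(v, mapDims(map)), mapOrigin(map), mapSpacing(map),
               metadata = md)
}

#' Crop a map to an index box
#'
#' @param map a \code{DensityMap}.
#' @param box list or matrix giving 1-based inclusive index ranges per axis:
#'   \code{list(c(i0, i1), c(j0, j1), c(k0, k1))}.
#' @return a \code{DensityMap} over the sub-grid, origin shifted accordingly.
#' @export
cropMap <- function(map, box) {
    if (is.matrix(box)) box <- lapply(1:3, function(k) box[k, ])
    d <- mapDims(map)
    for (k in 1:3) {
        if (box[[k]][1] < 1 || box[[k]][2] > d[k] || box[[k]][1] > box[[k]][2])
            stop("crop box outside map dimensions on axis ", k)
    }
    v <- map@values[box[[1]][1]:box[[1]][2],
                    box[[2]][1]:box[[2]][2],
                    box[[3]][1]:box[[3]][2], drop = FALSE]
    origin <- mapOrigin(map) +
        (vapply(box, `[`, numeric(1), 1) - 1) * mapSpacing(map)
    densityMap(v, origin, mapSpacing(map), metadata = map@metadata)
}
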