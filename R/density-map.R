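#' Construct a DensityMap
#'
#' @param values 3-D numeric array of voxel intensities.
#' @param origin world coordinate (\enc{Å}{Angstrom}) of the center of voxel
#'   (1,1,1).
#' @param spacing voxel size per axis (\enc{Å}{Angstrom}); scalar recycled.
#' @param metadata free-form list.
#' @export
densityMap <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                       metadata = list()) {
    if (length(spacing) == 1) spacing <- rep(spacing, 3)
    new("DensityMap", values = values, origin = as.numeric(origin),
        spacing = as.numeric(spacing), metadata = metadata)
}

#' Accessors for DensityMap
#'
#' \code{mapValues} returns the voxel array, \code{mapOrigin} the world
#' coordinate of the first voxel center, \code{mapSpacing} the voxel size,
#' \code{mapDims} the grid dimensions and \code{voxelVolume} the constant
#' per-voxel volume in \enc{Å}{Angstrom}^3.
#'
#' @param x a \code{DensityMap}.
#' @name DensityMap-accessors
#' @aliases mapValues mapOrigin mapSpacing mapDims voxelVolume
NULL

#' @rdname DensityMap-accessors
#' @export
setMethod("mapValues", "DensityMap", function(x) x@values)

#' @rdname DensityMap-accessors
#' @export
setMethod("mapOrigin", "DensityMap", function(x) x@origin)

#' @rdname DensityMap-accessors
#' @export
setMethod("mapSpacing", "DensityMap", function(x) x@spacing)

#' @rdname DensityMap-accessors
#' @export
setMethod("mapDims", "DensityMap", function(x) dim(x@values))

#' @rdname DensityMap-accessors
#' @export
setMethod("voxelVolume", "DensityMap", function(x) prod(x@spacing))

setMethod("show", "DensityMap", function(object) {
    d <- dim(object@values)
    cat(sprintf("DensityMap %d x %d x %d, spacing (%.2f, %.2f, %.2f) A\n",
                d[1], d[2], d[3], object@spacing[1], object@spacing[2],
                object@spacing[3]))
    cat(sprintf("  origin (%.2f, %.2f, %.2f) A, range [%.4g, %.4g]\n",
                object@origin[1], object@origin[2], object@origin[3],
                min(object@values), max(object@values)))
})

.sameGrid <- function(a, b, tol = 1e-6) {
    all(mapDims(a) == mapDims(b)) &&
        max(abs(mapSpacing(a) - mapSpacing(b))) < tol &&
        max(abs(mapOrigin(a) - mapOrigin(b))) < tol
}

#' Read a density map from an MRC/CCP4 (2014) file
#'
#' Supports mode-2 (float32) maps with orthogonal cells. The stored axis
#' order (MAPC/MAPR/MAPS) is normalized so the returned array is indexed
#' x-fastest; the origin is taken from the ORIGIN header words when any is
#' non-zero, otherwise from the NC/NR/NS start fields times the spacing.
#'
#' @param path MRC/CCP4 file path.
#' @return a \code{DensityMap}.
#' @export
readMap <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
    if (length(hdr_int) < 10) stop("truncated MRC file: ", path)
    nxyz <- hdr_int[1:3]
    mode <- hdr_int[4]
    nstart <- hdr_int[5:7]
    mxyz <- hdr_int[8:10]
    cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
    cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
    mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
    invisible(readBin(con, "numeric", n = 3, size = 4, endian = "little")) # dmin/dmax/dmean
    invisible(readBin(con, "integer", n = 2, size = 4, endian = "little")) # ispg, nsymbt
    invisible(readBin(con, "integer", n = 25, size = 4, endian = "little")) # extra
    orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
    magic <- readChar(con, 4, useBytes = TRUE)
    if (!identical(substr(magic, 1, 3), "MAP"))
        stop("not an MRC 2014 file (missing MAP magic): ", path)
    if (mode != 2) stop("unsupported MRC mode ", mode, " (only float32 mode 2)")
    if (max(abs(cellb - 90)) > 1e-3)
        stop("unsupported non-orthogonal cell (angles must be 90 degrees)")
    if (any(nxyz < 1) || any(mxyz < 1)) stop("invalid MRC header dimensions")
    seek(con, 1024 + 0) # skip machst/rms/labels; no extended header support
    n <- prod(nxyz)
    vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
    if (length(vals) < n) stop("truncated MRC data section: ", path)
    a <- array(vals, dim = nxyz)
    if (any(sort(mapcrs) != 1:3)) stop("invalid MAPC/MAPR/MAPS fields")
    perm <- match(1:3, mapcrs)  # stored slot holding world axis 1, 2, 3
    a <- aperm(a, perm)
    spacing <- cella / mxyz
    start_world <- nstart[perm]
    origin <- if (any(abs(orig) > 0)) as.numeric(orig) else start_world * spacing
    densityMap(a, origin = origin, spacing = spacing,
               metadata = list(source = path))
}

#' Write a density map to an MRC/CCP4 (2014) file
#'
#' Mode-2 float32, axis order x-fastest (MAPC/MAPR/MAPS = 1/2/3), origin in
#' the ORIGIN header words.
#'
#' @param map a \code{DensityMap}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeMap <- function(map, path) {
    stopifnot(is(map, "DensityMap"))
    d <- mapDims(map)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
             endian = "little")
    writeBin(as.numeric(c(d * mapSpacing(map), 90, 90, 90)), con, size = 4,
             endian = "little")
    writeBin(1:3, con, size = 4, endian = "little")
    v <- mapValues(map)
    writeBin(as.numeric(c(min(v), max(v), mean(v))), con, size = 4,
             endian = "little")
    writeBin(c(1L, 0L), con, size = 4, endian = "little")  # ispg, nsymbt
    writeBin(integer(25), con, size = 4, endian = "little")
    writeBin(as.numeric(mapOrigin(map)), con, size = 4, endian = "little")
    writeChar("MAP ", con, nchars = 4, eos = NULL)
    writeBin(as.integer(0x00004144), con, size = 4, endian = "little") # machst LE
    rms <- stats::sd(v)
    writeBin(as.numeric(ifelse(is.finite(rms), rms, 0)), con, size = 4,
             endian = "little")
    writeBin(1L, con, size = 4, endian = "little")  # nlabl
    lab <- sprintf("%-80s", "mapfitr")
    writeChar(paste(rep(lab, 1), collapse = ""), con, nchars = 80, eos = NULL)
    writeChar(paste(rep(sprintf("%-80s", ""), 9), collapse = ""), con,
              nchars = 720, eos = NULL)
    writeBin(as.numeric(v), con, size = 4, endian = "little")
    invisible(path)
}

#' World coordinates of voxel centers along each axis
#' @param map a \code{DensityMap}.
#' @return list of three numeric vectors (x, y, z centers).
#' @export
voxelAxes <- function(map) {
    d <- mapDims(map)
    lapply(1:3, function(k)
        mapOrigin(map)[k] + (seq_len(d[k]) - 1) * mapSpacing(map)[k])
}
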