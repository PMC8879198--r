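#' @rdname AtomicModel-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname AtomicModel-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname AtomicModel-accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname AtomicModel-accessors
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname AtomicModel-accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname AtomicModel-accessors
#' @export
setGeneric("modelMetadata", function(x) standardGeneric("modelMetadata"))

#' @rdname DensityMap-accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname DensityMap-accessors
#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))

#' @rdname DensityMap-accessors
#' @export
setGeneric("mapSpacing", function(x) standardGeneric("mapSpacing"))

#' @rdname DensityMap-accessors
#' @export
setGeneric("mapDims", function(x) standardGeneric("mapDims"))

#' @rdname DensityMap-accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' Cross-correlation coefficient between two density maps
#'
#' Non-centered overlap measure
#' \eqn{\sum \rho_a \rho_b / \sqrt{\sum \rho_a^2 \sum \rho_b^2}} over all
#' voxels of two maps on an identical grid. Scale-invariant; 1 for
#' proportional maps.
#'
#' @param a,b \code{DensityMap} objects on the same grid.
#' @return numeric in [-1, 1].
#' @export
setGeneric("ccc", function(a, b) standardGeneric("ccc"))

#' @rdname SequenceProfile-accessors
#' @export
setGeneric("profileColumns", function(x) standardGeneric("profileColumns"))

#' @rdname SequenceProfile-accessors
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))

#' @rdname SequenceProfile-accessors
#' @export
setGeneric("profileSequence", function(x) standardGeneric("profileSequence"))

#' @rdname ProfileAlignment-accessors
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))

#' @rdname ProfileAlignment-accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' Apply a rigid transform to a model or coordinate matrix
#'
#' @param x an \code{AtomicModel} or an n x 3 coordinate matrix.
#' @param transform a \code{RigidTransform}.
#' @return object of the same class as \code{x}, transformed.
#' @export
setGeneric("applyTransform", function(x, transform) standardGeneric("applyTransform"))
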