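#' @useDynLib mapfitr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetical ordering used for all profile columns.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' AtomicModel: an ordered set of atoms with chain/residue structure
#'
#' Atoms are stored as a data.frame in file order with columns
#' \code{chain}, \code{resno}, \code{resid} (3-letter residue name),
#' \code{elety} (atom name), \code{elesy} (element), \code{x}, \code{y},
#' \code{z} (\enc{Å}{Angstrom}) and \code{b} (B-factor). Chains occupy
#' contiguous blocks of rows.
#'
#' @slot atoms data.frame of atom records.
#' @slot metadata free-form list (provenance, flags, fixture seeds).
#' @exportClass AtomicModel
setClass("AtomicModel",
         representation(atoms = "data.frame", metadata = "list"),
         prototype(metadata = list()))

setValidity("AtomicModel", function(object) {
    a <- object@atoms
    req <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z", "b")
    if (!all(req %in% names(a)))
        return(paste("atoms must have columns:", paste(req, collapse = ", ")))
    if (nrow(a) < 1) return("model must contain at least one atom")
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
        return("atom coordinates must be finite")
    r <- rle(as.character(a$chain))
    if (anyDuplicated(r$values)) return("chains must be contiguous blocks")
    TRUE
})

#' RigidTransform: a proper rotation plus translation
#'
#' Maps a coordinate row-vector x to \code{x \%*\% t(rotation) + translation}.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric, \enc{Å}{Angstrom}.
#' @exportClass RigidTransform
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
    if (length(object@translation) != 3) return("translation must be length 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-8) return("rotation not orthonormal")
    if (abs(det(R) - 1) > 1e-8) return("rotation must have determinant +1")
    TRUE
})

#' DensityMap: a 3-D intensity grid with world-space placement
#'
#' \code{values[i, j, k]} is the intensity of the voxel whose center is at
#' \code{origin + (c(i, j, k) - 1) * spacing} (the origin is the world
#' coordinate of the center of the first voxel); voxel (i,j,k) spans
#' half a spacing either side of its center on each axis.
#'
#' @slot values 3-D numeric array.
#' @slot origin world coordinate (\enc{Å}{Angstrom}) of the first voxel center.
#' @slot spacing voxel edge lengths (\enc{Å}{Angstrom}) per axis, all > 0.
#' @slot metadata free-form list.
#' @exportClass DensityMap
setClass("DensityMap",
         representation(values = "array", origin = "numeric",
                        spacing = "numeric", metadata = "list"),
         prototype(metadata = list()))

setValidity("DensityMap", function(object) {
    if (length(dim(object@values)) != 3) return("values must be a 3-D array")
    if (length(object@origin) != 3) return("origin must be length 3")
    if (length(object@spacing) != 3) return("spacing must be length 3")
    if (any(object@spacing <= 0)) return("spacing must be positive on every axis")
    if (any(dim(object@values) < 1)) return("dims must be >= 1")
    TRUE
})

#' SequenceProfile: per-position 20-dimensional score columns
#'
#' @slot sequence consensus/query sequence (one-letter codes), length L.
#' @slot columns L x 20 numeric matrix of position-specific scores; column
#'   order follows \code{AA_ALPHABET}.
#' @slot label identifier used in alignments and reports.
#' @slot metadata list; may carry \code{ss} (H/E/C string) and \code{offset}
#'   (0-based start of a fragment within its parent profile).
#' @exportClass SequenceProfile
setClass("SequenceProfile",
         representation(sequence = "character", columns = "matrix",
                        label = "character", metadata = "list"),
         prototype(label = "profile", metadata = list()))

setValidity("SequenceProfile", function(object) {
    if (ncol(object@columns) != 20) return("columns must have 20 columns")
    if (nrow(object@columns) < 1) return("profile length must be >= 1")
    if (nchar(object@sequence) != nrow(object@columns))
        return("sequence length must equal number of profile positions")
    v <- apply(object@columns, 1, stats::var)
    if (any(v <= 0)) return("every profile column must have non-zero variance")
    TRUE
})

#' ProfileAlignment: result of profile-profile dynamic programming
#'
#' @slot pairs integer matrix with columns \code{query}, \code{template};
#'   strictly increasing in both coordinates.
#' @slot score raw alignment score S (sum of column correlations minus gap
#'   penalties along the path).
#' @slot zScore calibrated Z-score (NA until calibrated).
#' @slot queryLabel,templateLabel profile labels.
#' @slot mode alignment mode used ("glocal" or "local").
#' @exportClass ProfileAlignment
setClass("ProfileAlignment",
         representation(pairs = "matrix", score = "numeric", zScore = "numeric",
                        queryLabel = "character", templateLabel = "character",
                        mode = "character"),
         prototype(zScore = NA_real_, mode = "glocal"))

setValidity("ProfileAlignment", function(object) {
    p <- object@pairs
    if (nrow(p) > 1) {
        if (any(diff(p[, 1]) <= 0) || any(diff(p[, 2]) <= 0))
            return("pairs must be strictly increasing in both coordinates")
    }
    TRUE
})

#' ZScoreCalibration: log-length regression of library alignment scores
#'
#' Models the expected raw score of an unrelated query/template pair as
#' \code{intercept + slope * log(Lq * Lt)}; Z-scores standardise observed
#' scores by \code{residualSd}.
#'
#' @slot slope,intercept coefficients of the linear model.
#' @slot residualSd residual standard deviation (n - 2 denominator), > 0.
#' @slot nPoints number of library hits used.
#' @exportClass ZScoreCalibration
setClass("ZScoreCalibration",
         representation(slope = "numeric", intercept = "numeric",
                        residualSd = "numeric", nPoints = "integer"))

setValidity("ZScoreCalibration", function(object) {
    if (object@residualSd <= 0) return("residualSd must be > 0")
    if (object@nPoints < 10L) return("calibration needs at least 10 points")
    TRUE
})

#' Placement: one ranked rigid-body docking solution
#'
#' @slot transform RigidTransform taking the input model into the map.
#' @slot ccc cross-correlation coefficient of the placed model's simulated
#'   density with the experimental map.
#' @slot rank 1-based rank by non-increasing ccc.
#' @exportClass Placement
setClass("Placement",
         representation(transform = "RigidTransform", ccc = "numeric",
                        rank = "integer"))

setValidity("Placement", function(object) {
    if (abs(object@ccc) > 1 + 1e-9) return("ccc must lie in [-1, 1]")
    TRUE
})

#' RestraintSet: structure-based bonded and contact restraints
#'
#' @slot bonds data.frame(i, j, d0, k): consecutive-residue virtual bonds.
#' @slot contacts data.frame(i, j, d0, k): native-contact distance restraints.
#' @slot contactCutoff \enc{Å}{Angstrom} cutoff used to define contacts.
#' @slot delta flat-bottom half-width (\enc{Å}{Angstrom}) of the contact term.
#' @exportClass RestraintSet
setClass("RestraintSet",
         representation(bonds = "data.frame", contacts = "data.frame",
                        contactCutoff = "numeric", delta = "numeric"))

#' SmocProfile: per-residue local map-model agreement
#'
#' @slot scores data.frame(chain, resno, smoc); \code{smoc} is NA where the
#'   residue's segment mask was empty.
#' @slot window sliding window length in residues (odd).
#' @slot radius mask radius in \enc{Å}{Angstrom}.
#' @exportClass SmocProfile
setClass("SmocProfile",
         representation(scores = "data.frame", window = "integer",
                        radius = "numeric"))

setValidity("SmocProfile", function(object) {
    if (object@window %% 2L != 1L) return("window must be odd")
    TRUE
})

#' MapModelScores: the global CC metric suite for one map/model pair
#'
#' @slot ccMask,ccVolume,ccPeaks,ccBox centered Pearson correlations over,
#'   respectively, the atom mask, the model map's top-density region of the
#'   mask's size, the union of both maps' top regions, and the whole grid.
#' @slot maskVoxels number of voxels in the atom mask.
#' @exportClass MapModelScores
setClass("MapModelScores",
         representation(ccMask = "numeric", ccVolume = "numeric",
                        ccPeaks = "numeric", ccBox = "numeric",
                        maskVoxels = "integer"))
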