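#' Construct an AtomicModel
#'
#' @param atoms data.frame with columns chain, resno, resid, elety, elesy,
#'   x, y, z and optionally b (defaults to 0).
#' @param metadata free-form list.
#' @return an \code{AtomicModel}.
#' @examples
#' m <- atomicModel(data.frame(chain = "A", resno = 1, resid = "ALA",
#'                             elety = "CA", elesy = "C",
#'                             x = 0, y = 0, z = 0))
#' nAtoms(m)
#' @export
atomicModel <- function(atoms, metadata = list()) {
    atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
    if (is.null(atoms$b)) atoms$b <- 0
    if (is.null(atoms$elesy)) atoms$elesy <- substr(atoms$elety, 1, 1)
    atoms$chain <- as.character(atoms$chain)
    atoms$resno <- as.integer(atoms$resno)
    rownames(atoms) <- NULL
    new("AtomicModel", atoms = atoms, metadata = metadata)
}

#' Accessors for AtomicModel
#'
#' \code{atoms} returns the atom table; \code{coords} the n x 3 coordinate
#' matrix (replaceable); \code{chainIds} the unique chain identifiers in
#' order of appearance; \code{nAtoms} the atom count.
#'
#' @param x an \code{AtomicModel}.
#' @param value n x 3 numeric matrix of replacement coordinates.
#' @name AtomicModel-accessors
#' @aliases atoms nAtoms coords coords<- chainIds modelMetadata
NULL

#' @rdname AtomicModel-accessors
#' @export
setMethod("atoms", "AtomicModel", function(x) x@atoms)

#' @rdname AtomicModel-accessors
#' @export
setMethod("nAtoms", "AtomicModel", function(x) nrow(x@atoms))

#' @rdname AtomicModel-accessors
#' @export
setMethod("coords", "AtomicModel", function(x)
    unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @rdname AtomicModel-accessors
#' @export
setReplaceMethod("coords", "AtomicModel", function(x, value) {
    stopifnot(is.matrix(value), nrow(value) == nrow(x@atoms), ncol(value) == 3)
    x@atoms$x <- value[, 1]
    x@atoms$y <- value[, 2]
    x@atoms$z <- value[, 3]
    x
})

#' @rdname AtomicModel-accessors
#' @export
setMethod("chainIds", "AtomicModel", function(x) unique(as.character(x@atoms$chain)))

#' @rdname AtomicModel-accessors
#' @export
setMethod("modelMetadata", "AtomicModel", function(x) x@metadata)

setMethod("show", "AtomicModel", function(object) {
    a <- object@atoms
    cat("AtomicModel with", nrow(a), "atoms in", length(unique(a$chain)),
        "chain(s):", paste(unique(a$chain), collapse = ", "), "\n")
    cat("  residues:", length(unique(paste(a$chain, a$resno))),
        "  heavy-atom types:", paste(utils::head(unique(a$elety), 6), collapse = " "),
        "\n")
})

#' Construct a RigidTransform
#'
#' @param rotation 3x3 orthonormal matrix, det +1. Default identity.
#' @param translation length-3 numeric (\enc{Å}{Angstrom}). Default zero.
#' @return a \code{RigidTransform} mapping x to \code{rotation \%*\% x + translation}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
    new("RigidTransform", rotation = unname(as.matrix(rotation)),
        translation = as.numeric(translation))
}

setMethod("show", "RigidTransform", function(object) {
    ang <- rotationAngle(object@rotation)
    cat(sprintf("RigidTransform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) A\n",
                ang, object@translation[1], object@translation[2],
                object@translation[3]))
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "matrix", function(x, transform) {
    sweep(x %*% t(transform@rotation), 2, transform@translation, "+")
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "AtomicModel", function(x, transform) {
    coords(x) <- applyTransform(coords(x), transform)
    x
})

#' Compose and invert rigid transforms
#'
#' \code{composeTransforms(a, b)} applies \code{b} first, then \code{a};
#' \code{invertTransform(a)} returns the inverse motion.
#' @param a,b \code{RigidTransform} objects.
#' @export
composeTransforms <- function(a, b) {
    rigidTransform(a@rotation %*% b@rotation,
                   as.vector(a@rotation %*% b@translation) + a@translation)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(a) {
    rigidTransform(t(a@rotation), -as.vector(t(a@rotation) %*% a@translation))
}

#' Geodesic rotation angle (degrees) of a rotation matrix
#'
#' @param R 3x3 rotation matrix (or a \code{RigidTransform}).
#' @return angle in degrees in [0, 180].
#' @export
rotationAngle <- function(R) {
    if (is(R, "RigidTransform")) R <- R@rotation
    ct <- (sum(diag(R)) - 1) / 2
    acos(min(1, max(-1, ct))) * 180 / pi
}

#' Read an atomic model from a PDB file
#'
#' Parsing is delegated to \code{bio3d::read.pdb} (fixed-column PDB format;
#' coordinates from columns 31-54). Hydrogens are dropped, only the first
#' alternate location is kept, and insertion codes are ignored. HETATM
#' records are retained and flagged in \code{metadata$het} (row indices).
#'
#' @param path path to a PDB file with at least one ATOM/HETATM record.
#' @return an \code{AtomicModel}; atoms in file order.
#' @export
readPDB <- function(path) {
    if (!file.exists(path)) stop("cannot read PDB file: ", path)
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = TRUE),
                    error = function(e) stop("failed to parse PDB file '", path,
                                             "': ", conditionMessage(e)))
    a <- pdb$atom
    if (is.null(a) || nrow(a) == 0) stop("no ATOM/HETATM records in ", path)
    keep <- is.na(a$elesy) | toupper(a$elesy) != "H"
    a <- a[keep, , drop = FALSE]
    if (nrow(a) == 0) stop("no heavy-atom records in ", path)
    chain <- ifelse(is.na(a$chain), "A", a$chain)
    atoms <- data.frame(chain = chain, resno = a$resno, resid = a$resid,
                        elety = a$elety,
                        elesy = ifelse(is.na(a$elesy), substr(a$elety, 1, 1), a$elesy),
                        x = a$x, y = a$y, z = a$z,
                        b = ifelse(is.na(a$b), 0, a$b),
                        stringsAsFactors = FALSE)
    atomicModel(atoms, metadata = list(source = path,
                                       het = which(a$type == "HETATM")))
}

#' Write an atomic model to a PDB file
#'
#' Fixed-column PDB output; coordinates rounded to 3 decimals; a TER record
#' follows each chain.
#'
#' @param model a non-empty \code{AtomicModel}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePDB <- function(model, path) {
    stopifnot(is(model, "AtomicModel"))
    a <- model@atoms
    if (max(abs(as.matrix(a[, c("x", "y", "z")]))) >= 10000)
        stop("coordinate magnitude >= 10000 A does not fit the PDB field width")
    het <- modelMetadata(model)$het
    rec <- rep("ATOM  ", nrow(a))
    if (length(het)) rec[het] <- "HETATM"
    # atom-name column convention: 1-3 character names start in column 14
    nm <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                 sprintf(" %-3s", a$elety))
    lines <- character(0)
    serial <- 0L
    for (ch in chainIds(model)) {
        idx <- which(a$chain == ch)
        serial_block <- serial + seq_along(idx)
        lines <- c(lines, sprintf(
            "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec[idx], serial_block, nm[idx], a$resid[idx], ch, a$resno[idx],
            a$x[idx], a$y[idx], a$z[idx], 1.00, a$b[idx],
            toupper(a$elesy[idx])))
        serial <- serial + length(idx) + 1L
        lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                                  serial, a$resid[idx[length(idx)]], ch,
                                  a$resno[idx[length(idx)]]))
    }
    writeLines(c(lines, "END"), path)
    invisible(path)
}

#' Restrict a model to its C-alpha trace
#'
#' @param model an \code{AtomicModel}.
#' @return an \code{AtomicModel} containing only CA atoms, in order.
#' @export
caTrace <- function(model) {
    a <- model@atoms
    idx <- which(a$elety == "CA")
    if (length(idx) == 0) stop("model has no CA atoms")
    atomicModel(a[idx, , drop = FALSE], metadata = model@metadata)
}

# residue table of a CA trace: one row per residue, in atom order
.caResidues <- function(model) {
    a <- model@atoms
    idx <- which(a$elety == "CA")
    data.frame(row = idx, chain = a$chain[idx], resno = a$resno[idx],
               stringsAsFactors = FALSE)
}

#' Centroid of a model
#' @param model an \code{AtomicModel}.
#' @return length-3 numeric.
#' @export
centroid <- function(model) colMeans(coords(model))
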