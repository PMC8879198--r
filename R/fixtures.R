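# Synthetic structure/map/MSA generator: every test fixture in the package
# is produced here from a pinned seed, so the whole suite runs without any
# external downloads.

# ideal CA helix: 1.5 A rise and 100 deg twist per residue; the radius is
# chosen so consecutive CA atoms are exactly 3.8 A apart
.helixPoints <- function(n, base = c(0, 0, 0), axis = c(0, 0, 1), phase = 0) {
    twist <- 100 * pi / 180
    rise <- 1.5
    r <- sqrt(3.8^2 - rise^2) / (2 * sin(twist / 2))
    i <- seq_len(n) - 1
    local <- cbind(r * cos(i * twist + phase), r * sin(i * twist + phase),
                   i * rise)
    axis <- axis / sqrt(sum(axis^2))
    # rotate +z onto axis
    z <- c(0, 0, 1)
    v <- c(z[2] * axis[3] - z[3] * axis[2],
           z[3] * axis[1] - z[1] * axis[3],
           z[1] * axis[2] - z[2] * axis[1])
    s <- sqrt(sum(v^2)); cth <- sum(z * axis)
    R <- if (s < 1e-12) {
        if (cth > 0) diag(3) else diag(c(1, -1, -1))
    } else {
        K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
        diag(3) + K + K %*% K * ((1 - cth) / s^2)
    }
    sweep(local %*% t(R), 2, base, "+")
}

# two intermediate points connecting A to B with all three segments 3.8 A;
# solvable whenever |A - B| <= 11.4
.linkerPoints <- function(A, B, up = c(0, 0, 1)) {
    D <- sqrt(sum((B - A)^2))
    if (D > 3 * 3.8 - 1e-9) stop("linker span too long: ", round(D, 2), " A")
    e <- (B - A) / D
    u <- up - sum(up * e) * e
    if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0, 0) - e[1] * e
    u <- u / sqrt(sum(u^2))
    ca <- max(-1, min(1, (D - 3.8) / 7.6))
    sa <- sqrt(1 - ca^2)
    l1 <- A + 3.8 * (ca * e + sa * u)
    l2 <- B - 3.8 * ca * e + 3.8 * sa * u
    rbind(l1, l2)
}

# chain of helices connected by exact-3.8 linkers. lateral[[k]] gives the
# (x, y) position of helix k's axis; dir = +1 up / -1 down along z. Each
# helix after the first starts at the height of the previous chain end and
# is phased so its first atom faces that end, keeping the linker span well
# inside the reach of two 3.8 A segments.
.helixChain <- function(lengths, lateral, dirs) {
    pts <- NULL
    for (k in seq_along(lengths)) {
        axy <- lateral[[k]]
        if (is.null(pts)) {
            base <- c(axy, 0)
            phase <- 0
        } else {
            E <- pts[nrow(pts), ]
            base <- c(axy, E[3])
            phase <- atan2(E[2] - axy[2], E[1] - axy[1])
        }
        seg <- .helixPoints(lengths[k], base = base, axis = c(0, 0, dirs[k]),
                            phase = phase)
        if (!is.null(pts)) pts <- rbind(pts, .linkerPoints(pts[nrow(pts), ],
                                                           seg[1, ]))
        pts <- rbind(pts, seg)
    }
    pts
}

.caModelFromPoints <- function(pts, chain = "A", resnoStart = 1L,
                               metadata = list()) {
    n <- nrow(pts)
    atomicModel(data.frame(chain = chain, resno = resnoStart + seq_len(n) - 1L,
                           resid = "ALA", elety = "CA", elesy = "C",
                           x = pts[, 1], y = pts[, 2], z = pts[, 3], b = 0,
                           stringsAsFactors = FALSE),
                metadata = metadata)
}

#' Generate an idealized synthetic CA structure
#'
#' Deterministic toy structures with exact 3.8 \enc{Å}{Angstrom} CA-CA
#' spacing built from ideal helices (1.5 \enc{Å}{Angstrom} rise, 100
#' degrees twist per residue) and exactly solvable two-residue linkers:
#' \describe{
#'   \item{helix}{one straight helix of \code{nResidues}.}
#'   \item{three-helix-bundle}{three helices of unequal lengths arranged on
#'     a triangle (up/down/up), one chain.}
#'   \item{c2-dimer}{an asymmetric two-helix hairpin protomer (chain A) and
#'     its exact copy under a 180-degree rotation about z (chain B).}
#'   \item{two-domain-hinge}{two helical domains joined by a linker in an
#'     L-shape; the natural substrate for hinge perturbations.}
#' }
#'
#' @param kind one of "helix", "three-helix-bundle", "c2-dimer",
#'   "two-domain-hinge".
#' @param nResidues total residue count (>= 10; >= 20 for multi-segment
#'   kinds).
#' @param seed recorded in the output metadata (the geometry itself is
#'   deterministic).
#' @return an \code{AtomicModel} with \code{metadata$kind} and
#'   \code{metadata$seed}.
#' @export
makeStructure <- function(kind = c("helix", "three-helix-bundle", "c2-dimer",
                                   "two-domain-hinge"),
                          nResidues, seed = 1L) {
    kind <- match.arg(kind)
    if (nResidues < 10) stop("nResidues must be >= 10")
    md <- list(kind = kind, seed = as.integer(seed), nResidues = nResidues)
    if (kind == "helix") {
        pts <- .helixPoints(nResidues)
        return(.caModelFromPoints(pts, metadata = md))
    }
    if (kind == "three-helix-bundle") {
        if (nResidues < 20) stop("bundle needs >= 20 residues")
        nh <- (nResidues - 4) %/% 3
        lens <- c(nh - 2, nh, nResidues - 4 - (nh - 2) - nh)
        pts <- .helixChain(lens, list(c(0, 0), c(10, 0), c(5, 8.66)),
                           dirs = c(1, -1, 1))
        return(.caModelFromPoints(pts, metadata = md))
    }
    if (kind == "c2-dimer") {
        if (nResidues < 24) stop("dimer needs >= 24 residues")
        nprot <- nResidues %/% 2
        nh <- (nprot - 2) %/% 2
        lens <- c(nh - 2, nprot - 2 - (nh - 2))
        pts <- .helixChain(lens, list(c(0, 0), c(9, 0)), dirs = c(1, -1))
        pts <- sweep(pts, 2, c(9, 3, 0), "+")  # protomer offset from the C2 axis
        Rz <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3)
        ptsB <- pts %*% t(Rz)
        a <- .caModelFromPoints(pts, chain = "A")@atoms
        b <- .caModelFromPoints(ptsB, chain = "B")@atoms
        md$symmetryRotation <- Rz
        return(atomicModel(rbind(a, b), metadata = md))
    }
    # two-domain-hinge
    if (nResidues < 20) stop("hinge fixture needs >= 20 residues")
    n1 <- (nResidues - 2) %/% 2
    n2 <- nResidues - 2 - n1
    d1 <- .helixPoints(n1)
    A <- d1[nrow(d1), ]
    d2 <- .helixPoints(n2, base = A + c(6.5, 0, 2.5), axis = c(1, 0, 0))
    link <- .linkerPoints(A, d2[1, ], up = c(0, 1, 0))
    pts <- rbind(d1, link, d2)
    md$hingeAfter <- n1 + 1L  # hinge bond: linker atom 1 -> linker atom 2
    .caModelFromPoints(pts, metadata = md)
}

#' Perturb a structure (hinge rotation, jitter, or rigid offset)
#'
#' \describe{
#'   \item{hinge}{rotates the second half of the chain about the axis along
#'     the hinge bond (between atoms \code{m} and \code{m+1}, where m is
#'     \code{metadata$hingeAfter} or the chain midpoint) by \code{angle}
#'     degrees. The atom m+1 lies on the axis, so applying the opposite
#'     angle restores the input exactly. Errors on single-domain (helix)
#'     fixtures.}
#'   \item{jitter}{adds isotropic Gaussian noise of standard deviation
#'     \code{sd} \enc{Å}{Angstrom} per coordinate, seeded.}
#'   \item{rigid}{applies a seeded random rotation of \code{angle} degrees
#'     about a random axis through the centroid plus a random translation
#'     of norm \code{shift} \enc{Å}{Angstrom}.}
#' }
#' The RMSD to the input is recorded in \code{metadata$rmsdToInput}.
#'
#' @param model an \code{AtomicModel}.
#' @param perturbation list with \code{kind} ("hinge", "jitter", "rigid")
#'   and its parameter (\code{angle}, \code{sd}, or \code{angle}/
#'   \code{shift}).
#' @param seed RNG seed for the stochastic kinds.
#' @return the perturbed \code{AtomicModel}.
#' @export
perturbModel <- function(model, perturbation, seed = 1L) {
    kind <- perturbation$kind
    xyz <- coords(model)
    n <- nrow(xyz)
    if (kind == "hinge") {
        if (identical(modelMetadata(model)$kind, "helix"))
            stop("hinge perturbation undefined for a single-domain fixture")
        m <- modelMetadata(model)$hingeAfter
        if (is.null(m)) m <- n %/% 2
        axis <- xyz[m + 1, ] - xyz[m, ]
        axis <- axis / sqrt(sum(axis^2))
        R <- .axisAngleRotation(axis * perturbation$angle * pi / 180)
        idx <- (m + 1):n
        xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, xyz[m, ]) %*% t(R),
                            2, xyz[m, ], "+")
    } else if (kind == "jitter") {
        withr::with_seed(seed, {
            xyz <- xyz + matrix(stats::rnorm(3 * n, sd = perturbation$sd), n, 3)
        })
    } else if (kind == "rigid") {
        withr::with_seed(seed, {
            ax <- stats::rnorm(3)
            ax <- ax / sqrt(sum(ax^2))
            R <- .axisAngleRotation(ax * perturbation$angle * pi / 180)
            tdir <- stats::rnorm(3)
            tdir <- tdir / sqrt(sum(tdir^2))
            mu <- colMeans(xyz)
            shift <- if (is.null(perturbation$shift)) 0 else perturbation$shift
            xyz <- sweep(sweep(xyz, 2, mu) %*% t(R), 2,
                         mu + shift * tdir, "+")
        })
    } else stop("unknown perturbation kind: ", kind)
    out <- model
    coords(out) <- xyz
    out@metadata$rmsdToInput <- rmsd(xyz, coords(model))
    out@metadata$perturbation <- perturbation
    out
}

# fixed residue exchange table used by the MSA sampler: a letter mutates to
# itself with probability 0.3, within its physicochemical group with total
# probability 0.5, and anywhere else with total probability 0.2
.exchangeTable <- function() {
    groups <- list(c("A", "V", "I", "L", "M", "C"), c("F", "W", "Y"),
                   c("S", "T", "N", "Q"), c("D", "E", "K", "R", "H"),
                   c("G", "P"))
    E <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    for (g in groups) {
        for (a in g) {
            E[a, a] <- 0.3
            others <- setdiff(g, a)
            E[a, others] <- 0.5 / length(others)
            out <- setdiff(AA_ALPHABET, g)
            E[a, out] <- 0.2 / length(out)
        }
    }
    E
}

#' Sample a synthetic multiple sequence alignment around a query
#'
#' Each of the \code{nSequences - 1} homolog records mutates every position
#' independently with probability \code{rate}; a mutated letter is drawn
#' from a fixed physicochemical exchange table (self-probability 0.3). The
#' query is kept intact as record 1. No gaps are introduced, so the MSA is
#' trivially aligned.
#'
#' @param query amino-acid sequence string (20-letter alphabet).
#' @param nSequences total records including the query.
#' @param rate per-position substitution probability in [0, 1].
#' @param seed RNG seed.
#' @return named character vector of aligned sequences (record 1 = query).
#' @export
sampleMSA <- function(query, nSequences, rate, seed = 1L) {
    if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
    q <- strsplit(query, "")[[1]]
    stopifnot(all(q %in% AA_ALPHABET))
    E <- .exchangeTable()
    withr::with_seed(seed, {
        out <- vapply(seq_len(max(0, nSequences - 1)), function(s) {
            r <- q
            mut <- stats::runif(length(q)) < rate
            if (any(mut))
                r[mut] <- vapply(which(mut), function(i)
                    sample(AA_ALPHABET, 1, prob = E[q[i], ]), character(1))
            paste(r, collapse = "")
        }, character(1))
    })
    stats::setNames(c(query, out),
                    c("query", sprintf("seq%03d", seq_len(length(out)))))
}

#' Decoy model library around a reference structure
#'
#' Builds the ten-candidate library used to exercise the selection pipeline
#' end to end: one near-native model (0.1 \enc{Å}{Angstrom} jitter), three
#' quaternary-perturbed models (hinge rotations of 15/25/35 degrees, which
#' keep secondary structure intact but degrade the fit), three wrong-fold
#' models (a long helix, a three-helix bundle and a short helix, which dock
#' poorly), and three heavily jittered models (2.5/3/4 \enc{Å}{Angstrom},
#' which still dock as blobs but lose their secondary structure). Only the
#' near-native and hinge decoys are built to survive the standard selection
#' thresholds (CCC > 0.75 and secondary-structure similarity > 0.75).
#'
#' @param reference the reference \code{AtomicModel} (a multi-domain
#'   fixture; the hinge decoys need \code{metadata$kind} != "helix").
#' @param seed base RNG seed for the jittered decoys.
#' @return list with \code{models} (named list of \code{AtomicModel}) and
#'   \code{expectedPass} (names of the decoys built to pass).
#' @export
decoyLibrary <- function(reference, seed = 1L) {
    n <- nAtoms(reference)
    models <- list(
        near = perturbModel(reference, list(kind = "jitter", sd = 0.1),
                            seed = seed + 1L),
        hinge15 = perturbModel(reference, list(kind = "hinge", angle = 15)),
        hinge25 = perturbModel(reference, list(kind = "hinge", angle = 25)),
        hinge35 = perturbModel(reference, list(kind = "hinge", angle = 35)),
        fold_helix = makeStructure("helix", n),
        fold_bundle = makeStructure("three-helix-bundle", n),
        fold_short = makeStructure("helix", max(10, n - 12)),
        melt25 = perturbModel(reference, list(kind = "jitter", sd = 2.5),
                              seed = seed + 4L),
        melt30 = perturbModel(reference, list(kind = "jitter", sd = 3.0),
                              seed = seed + 5L),
        melt40 = perturbModel(reference, list(kind = "jitter", sd = 4.0),
                              seed = seed + 6L))
    list(models = models,
         expectedPass = c("near", "hinge15", "hinge25", "hinge35"))
}

#' Add seeded white Gaussian noise to a density map
#'
#' @param map a \code{DensityMap}.
#' @param noiseSd noise standard deviation as a fraction of the map maximum
#'   (>= 0).
#' @param seed RNG seed.
#' @param clampNegative set negative voxels to zero after adding noise
#'   (default FALSE).
#' @return a \code{DensityMap}.
#' @export
makeNoisyMap <- function(map, noiseSd, seed = 1L, clampNegative = FALSE) {
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    v <- mapValues(map)
    if (noiseSd > 0) {
        withr::with_seed(seed, {
            v <- v + array(stats::rnorm(length(v), sd = noiseSd * max(v)),
                           dim(v))
        })
    }
    if (clampNegative) v[v < 0] <- 0
    densityMap(v, mapOrigin(map), mapSpacing(map),
               metadata = c(map@metadata, list(noiseSd = noiseSd,
                                               seed = as.integer(seed))))
}
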