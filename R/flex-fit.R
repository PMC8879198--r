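#' Build structure-based restraints from a starting model
#'
#' Harmonic virtual bonds link consecutive C-alpha atoms within each chain
#' at their initial lengths; Go-like contact restraints link C-alpha pairs
#' with sequence separation >= 3 (any chain pair) whose initial distance is
#' within \code{contactCutoff}, with targets equal to the initial distances.
#' Together they preserve local geometry and the native contact network
#' while the map bias deforms the model.
#'
#' @param model an \code{AtomicModel} with >= 2 residues per chain (chains
#'   with a single residue contribute no bonds and raise a warning).
#' @param contactCutoff contact distance cutoff, \enc{Å}{Angstrom}
#'   (default 8).
#' @param kBond,kContact force constants (reduced units; defaults 10, 0.2).
#' @param delta flat-bottom half-width of the contact term,
#'   \enc{Å}{Angstrom} (default 0.5).
#' @return a \code{RestraintSet}; indices refer to CA rows of the model.
#' @export
buildRestraints <- function(model, contactCutoff = 8, kBond = 10,
                            kContact = 0.2, delta = 0.5) {
    res <- .caResidues(model)
    xyz <- coords(model)[res$row, , drop = FALSE]
    n <- nrow(res)
    if (n < 2) stop("need at least 2 residues to build restraints")
    bonds <- NULL
    for (ch in unique(res$chain)) {
        idx <- which(res$chain == ch)
        if (length(idx) < 2) {
            warning("chain ", ch, " has a single residue: no bonds built")
            next
        }
        i <- idx[-length(idx)]; j <- idx[-1]
        d0 <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
        bonds <- rbind(bonds, data.frame(i = i, j = j, d0 = d0, k = kBond))
    }
    if (is.null(bonds)) bonds <- data.frame(i = integer(0), j = integer(0),
                                            d0 = numeric(0), k = numeric(0))
    # contacts: |residue separation| >= 3 within a chain; all inter-chain pairs
    contacts <- data.frame(i = integer(0), j = integer(0), d0 = numeric(0),
                           k = numeric(0))
    if (contactCutoff > 0 && n >= 2) {
        pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        sep_ok <- res$chain[pr[, 1]] != res$chain[pr[, 2]] |
            abs(res$resno[pr[, 2]] - res$resno[pr[, 1]]) >= 3
        pr <- pr[sep_ok, , drop = FALSE]
        if (nrow(pr)) {
            dd <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                                xyz[pr[, 2], , drop = FALSE])^2))
            keep <- dd <= contactCutoff
            if (any(keep))
                contacts <- data.frame(i = pr[keep, 1], j = pr[keep, 2],
                                       d0 = dd[keep], k = kContact)
        }
    }
    new("RestraintSet", bonds = bonds, contacts = contacts,
        contactCutoff = contactCutoff, delta = delta)
}

setMethod("show", "RestraintSet", function(object) {
    cat(sprintf("RestraintSet: %d bonds, %d contacts (cutoff %.1f A, delta %.2f A)\n",
                nrow(object@bonds), nrow(object@contacts),
                object@contactCutoff, object@delta))
})

#' Restraint energy and gradient
#'
#' Bonds contribute \eqn{\frac{1}{2} k_b (d - d_0)^2}; contacts contribute a
#' flat-bottomed harmonic \eqn{\frac{1}{2} k_c (\max(0, |d - d_0| -
#' \delta))^2}. Gradients are exact.
#'
#' @param xyz n x 3 coordinate matrix (CA order used by the restraints).
#' @param restraints a \code{RestraintSet}.
#' @return list with \code{energy} and \code{gradient} (n x 3).
#' @export
restraintEnergy <- function(xyz, restraints) {
    xyz <- as.matrix(xyz)
    grad <- matrix(0, nrow(xyz), 3)
    e <- 0
    pair_term <- function(tab, flat) {
        if (nrow(tab) == 0) return(invisible())
        dvec <- xyz[tab$i, , drop = FALSE] - xyz[tab$j, , drop = FALSE]
        d <- sqrt(rowSums(dvec^2))
        if (any(d < 1e-8)) stop("singular geometry: coincident restrained atoms")
        if (flat > 0) {
            ex <- pmax(0, abs(d - tab$d0) - flat)
            e <<- e + sum(0.5 * tab$k * ex^2)
            f <- tab$k * ex * sign(d - tab$d0)  # dE/dd
        } else {
            e <<- e + sum(0.5 * tab$k * (d - tab$d0)^2)
            f <- tab$k * (d - tab$d0)
        }
        gpair <- dvec * (f / d)
        for (c3 in 1:3) {
            gi <- tapply(gpair[, c3], tab$i, sum)
            gj <- tapply(gpair[, c3], tab$j, sum)
            ii <- as.integer(names(gi)); jj <- as.integer(names(gj))
            grad[ii, c3] <<- grad[ii, c3] + gi
            grad[jj, c3] <<- grad[jj, c3] - gj
        }
        invisible()
    }
    pair_term(restraints@bonds, 0)
    pair_term(restraints@contacts, restraints@delta)
    list(energy = e, gradient = grad)
}

#' Map-bias energy and gradient
#'
#' The bias toward the experimental map is \eqn{E_{EM} = N k (1 - CCC)}
#' where N is the number of (heavy) atoms, k the bias strength and CCC the
#' cross-correlation of the experimental map with the density simulated
#' from the current coordinates. The gradient is exact: the CCC quotient
#' rule composed with the derivative of the voxel integrals (differences of
#' face Gaussians).
#'
#' @param xyz n x 3 coordinate matrix.
#' @param expMap experimental \code{DensityMap}.
#' @param params \code{DensitySimParams} (simulation on the map's grid).
#' @param k bias strength (> 0).
#' @return list with \code{energy}, \code{gradient} (n x 3) and \code{ccc}.
#' @export
emEnergy <- function(xyz, expMap, params, k = 1) {
    xyz <- as.matrix(xyz)
    n <- nrow(xyz)
    g <- list(origin = mapOrigin(expMap), spacing = mapSpacing(expMap),
              dims = as.integer(mapDims(expMap)))
    sim <- .cppSimDensity(xyz, g$origin, g$spacing, g$dims, params$sigma,
                          params$truncationRadius)
    a <- as.numeric(mapValues(expMap))
    sb <- sum(sim * sim)
    if (sb == 0) stop("degenerate simulated density: model outside the map")
    sa <- sum(a * a)
    if (sa == 0) stop("degenerate experimental map: all zeros")
    sab <- sum(a * sim)
    cc <- sab / sqrt(sa * sb)
    # d ccc / d sim_v  (quotient rule)
    w <- a / sqrt(sa * sb) - cc * sim / sb
    wg <- .cppDensityGradDot(xyz, g$origin, g$spacing, g$dims, params$sigma,
                             params$truncationRadius, w)
    list(energy = n * k * (1 - cc), gradient = -n * k * wg, ccc = cc)
}

#' Configuration for flexible fitting
#'
#' @param sigma map resolution passed to the density simulation,
#'   \enc{Å}{Angstrom}.
#' @param k bias strength of the EM term (default 1).
#' @param maxSteps maximum minimizer steps (default 2000).
#' @param stepRule "gradient-descent" (deterministic, backtracking line
#'   search, monotone total energy) or "langevin" (seeded BAOAB dynamics).
#' @param temperature reduced temperature, langevin only (default 0.1).
#' @param timestep langevin timestep, reduced units (default 0.05).
#' @param friction langevin friction constant (default 1).
#' @param seed RNG seed, langevin only.
#' @param convergenceWindow steps over which the CCC change is monitored
#'   (default 50).
#' @param convergenceDccc stop when the CCC change over the window falls
#'   below this (default 1e-6).
#' @param truncationRadius kernel truncation in sigmas (default 4).
#' @return list of class \code{"FlexFitConfig"}.
#' @export
flexFitConfig <- function(sigma, k = 1, maxSteps = 2000,
                          stepRule = c("gradient-descent", "langevin"),
                          temperature = 0.1, timestep = 0.05, friction = 1,
                          seed = 1L, convergenceWindow = 50,
                          convergenceDccc = 1e-6, truncationRadius = 4) {
    stepRule <- match.arg(stepRule)
    if (k <= 0) stop("k must be > 0")
    if (maxSteps < 1) stop("maxSteps must be >= 1")
    structure(list(sigma = sigma, k = k, maxSteps = maxSteps,
                   stepRule = stepRule, temperature = temperature,
                   timestep = timestep, friction = friction,
                   seed = as.integer(seed),
                   convergenceWindow = convergenceWindow,
                   convergenceDccc = convergenceDccc,
                   truncationRadius = truncationRadius),
              class = "FlexFitConfig")
}

#' Flexible fitting of a model into a density map
#'
#' Minimizes \code{restraint energy + E_EM} over the model's CA coordinates.
#' The default gradient-descent mode uses a backtracking line search and is
#' deterministic with monotone non-increasing total energy; the langevin
#' mode runs seeded BAOAB dynamics (reproducible bit-for-bit for a fixed
#' seed) and returns the lowest-energy visited conformation. The run stops
#' at \code{maxSteps} or when the CCC change over
#' \code{convergenceWindow} steps falls below \code{convergenceDccc}.
#'
#' @param model starting \code{AtomicModel}; its CA trace is fitted. The
#'   initial pose must overlap the map (initial ccc > 0) — rigid-fit first
#'   otherwise.
#' @param expMap experimental \code{DensityMap}.
#' @param config a \code{FlexFitConfig}.
#' @param restraints optional \code{RestraintSet}; default built from the
#'   starting model with \code{\link{buildRestraints}} defaults.
#' @return list with \code{model} (fitted), \code{trajectory} (data.frame
#'   step, eRestraint, eEM, ccc) and \code{restraints}.
#' @export
flexibleFit <- function(model, expMap, config, restraints = NULL) {
    stopifnot(inherits(config, "FlexFitConfig"))
    if (is.null(restraints)) restraints <- buildRestraints(model)
    ca <- caTrace(model)
    xyz <- coords(ca)
    n <- nrow(xyz)
    params <- densitySimParams(config$sigma,
                               truncationRadius = config$truncationRadius)
    em0 <- emEnergy(xyz, expMap, params, config$k)
    if (!is.finite(em0$ccc) || em0$ccc <= 0)
        stop("initial ccc <= 0: run a rigid fit before flexible fitting")
    energies <- function(x) {
        r <- restraintEnergy(x, restraints)
        m <- emEnergy(x, expMap, params, config$k)
        list(e = r$energy + m$energy, grad = r$gradient + m$gradient,
             eR = r$energy, eM = m$energy, ccc = m$ccc)
    }
    traj <- vector("list", config$maxSteps + 1)
    cur <- energies(xyz)
    traj[[1]] <- data.frame(step = 0L, eRestraint = cur$eR, eEM = cur$eM,
                            ccc = cur$ccc)
    cccs <- cur$ccc
    run_gd <- function() {
        step_size <- 0.1
        for (s in seq_len(config$maxSteps)) {
            gnorm <- sqrt(sum(cur$grad^2))
            if (gnorm < 1e-10) break
            accepted <- FALSE
            for (bt in 1:30) {
                trial <- xyz - step_size * cur$grad
                cand <- tryCatch(energies(trial), error = function(e) NULL)
                if (!is.null(cand) && is.finite(cand$e) && cand$e <= cur$e) {
                    xyz <<- trial
                    cur <<- cand
                    accepted <- TRUE
                    break
                }
                step_size <- step_size / 2
            }
            if (!accepted) break
            step_size <- min(step_size * 1.5, 10)
            traj[[s + 1]] <<- data.frame(step = s, eRestraint = cur$eR,
                                         eEM = cur$eM, ccc = cur$ccc)
            cccs <<- c(cccs, cur$ccc)
            w <- config$convergenceWindow
            if (length(cccs) > w &&
                abs(cccs[length(cccs)] - cccs[length(cccs) - w]) <
                config$convergenceDccc) break
        }
    }
    run_langevin <- function() {
        withr::with_seed(config$seed, {
            dt <- config$timestep
            gamma <- config$friction
            kT <- config$temperature
            cfac <- exp(-gamma * dt)
            nfac <- sqrt(kT * (1 - cfac^2))
            vel <- matrix(0, n, 3)
            best <- list(xyz = xyz, e = cur$e)
            for (s in seq_len(config$maxSteps)) {
                vel <- vel - 0.5 * dt * cur$grad              # B
                xyz <<- xyz + 0.5 * dt * vel                  # A
                vel <- cfac * vel + nfac * matrix(stats::rnorm(3 * n), n, 3) # O
                xyz <<- xyz + 0.5 * dt * vel                  # A
                cand <- energies(xyz)
                vel <- vel - 0.5 * dt * cand$grad             # B
                cur <<- cand
                if (cand$e < best$e) best <- list(xyz = xyz, e = cand$e)
                traj[[s + 1]] <<- data.frame(step = s, eRestraint = cur$eR,
                                             eEM = cur$eM, ccc = cur$ccc)
                cccs <<- c(cccs, cur$ccc)
                w <- config$convergenceWindow
                if (length(cccs) > w &&
                    abs(cccs[length(cccs)] - cccs[length(cccs) - w]) <
                    config$convergenceDccc) break
            }
            xyz <<- best$xyz
        })
    }
    if (config$stepRule == "gradient-descent") run_gd() else run_langevin()
    out <- model
    a <- out@atoms
    cares <- .caResidues(model)
    a$x[cares$row] <- xyz[, 1]
    a$y[cares$row] <- xyz[, 2]
    a$z[cares$row] <- xyz[, 3]
    out@atoms <- a
    list(model = out, trajectory = do.call(rbind, traj[!vapply(traj, is.null,
                                                               logical(1))]),
         restraints = restraints)
}

#' Fraction of contacts preserved by a fitted model
#'
#' A contact is preserved when its current distance lies within
#' \code{delta + tol} of its target.
#'
#' @param model fitted \code{AtomicModel}.
#' @param restraints the \code{RestraintSet} the fit used.
#' @param tol tolerance beyond the flat bottom, \enc{Å}{Angstrom}
#'   (default 0.5).
#' @return fraction in [0, 1] (1 when there are no contacts).
#' @export
contactPreservation <- function(model, restraints, tol = 0.5) {
    tab <- restraints@contacts
    if (nrow(tab) == 0) return(1)
    xyz <- coords(caTrace(model))
    d <- sqrt(rowSums((xyz[tab$i, , drop = FALSE] -
                       xyz[tab$j, , drop = FALSE])^2))
    mean(abs(d - tab$d0) <= restraints@delta + tol)
}
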