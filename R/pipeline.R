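#' Fraction of matching secondary-structure states
#'
#' @param ssModel,ssPredicted H/E/C strings of equal length.
#' @return fraction of positions with identical state, in [0, 1].
#' @export
ssSimilarity <- function(ssModel, ssPredicted) {
    a <- strsplit(ssModel, "")[[1]]
    b <- strsplit(ssPredicted, "")[[1]]
    if (length(a) != length(b))
        stop("secondary-structure strings must have equal length")
    mean(a == b)
}

#' Assign secondary structure from a C-alpha trace
#'
#' P-SEA-style distance rules on the CA trace, per chain: residue i starts
#' a helix when d(i, i+3) lies in [4.4, 5.8] \enc{Å}{Angstrom} and
#' d(i, i+4) in [5.5, 6.9] \enc{Å}{Angstrom} (residues i..i+4 marked H);
#' it starts a strand when d(i, i+2) >= 6.4 \enc{Å}{Angstrom} (residues
#' i..i+2 marked E unless already H); everything else is coil. Chains of
#' fewer than 5 residues are all coil.
#'
#' @param model an \code{AtomicModel} with a CA trace.
#' @return H/E/C string, one state per residue in model order.
#' @export
assignSSFromCA <- function(model) {
    res <- .caResidues(model)
    xyz <- coords(model)[res$row, , drop = FALSE]
    out <- character(0)
    for (ch in unique(res$chain)) {
        idx <- which(res$chain == ch)
        n <- length(idx)
        ss <- rep("C", n)
        if (n >= 5) {
            p <- xyz[idx, , drop = FALSE]
            dist_k <- function(k) c(sqrt(rowSums((p[seq_len(n - k), , drop = FALSE] -
                                                  p[(k + 1):n, , drop = FALSE])^2)),
                                    rep(NA, k))
            d2 <- dist_k(2); d3 <- dist_k(3); d4 <- dist_k(4)
            for (i in seq_len(n - 4)) {
                if (!is.na(d3[i]) && !is.na(d4[i]) &&
                    d3[i] >= 4.4 && d3[i] <= 5.8 &&
                    d4[i] >= 5.5 && d4[i] <= 6.9)
                    ss[i:(i + 4)] <- "H"
            }
            for (i in seq_len(n - 2)) {
                if (!is.na(d2[i]) && d2[i] >= 6.4 && all(ss[i:(i + 2)] == "C"))
                    ss[i:(i + 2)] <- "E"
            }
        }
        out <- c(out, ss)
    }
    paste(out, collapse = "")
}

#' Rigid-fit a set of candidate models and tabulate their scores
#'
#' Each model is docked into the map with \code{\link{rigidFit}} and its
#' best CCC recorded. When a predicted secondary-structure string is given,
#' each model's CA-derived secondary structure is compared to it
#' (\code{ss_similarity} column). External per-model quality scores (e.g.
#' verify3d, ddfire, zscore columns) are merged by \code{model_id} and
#' passed through untouched. Models whose rigid fit fails are flagged
#' (\code{fit_ok = FALSE}, ccc NA), not dropped. Rows are ordered by
#' \code{model_id}; the procedure is deterministic.
#'
#' @param models named list of \code{AtomicModel}s (names = model ids).
#' @param expMap experimental \code{DensityMap}.
#' @param config a \code{RigidSearchConfig}.
#' @param predictedSS optional H/E/C string for the target.
#' @param externalScores optional data.frame with a \code{model_id} column.
#' @return data.frame of candidate records.
#' @export
scoreCandidates <- function(models, expMap, config, predictedSS = NULL,
                            externalScores = NULL) {
    if (length(models) < 1) stop("need at least one candidate model")
    if (is.null(names(models)))
        names(models) <- sprintf("model_%03d", seq_along(models))
    ids <- sort(names(models))
    rows <- lapply(ids, function(id) {
        m <- models[[id]]
        pl <- tryCatch(rigidFit(expMap, m, config), error = function(e) NULL)
        rec <- data.frame(model_id = id,
                          ccc = if (is.null(pl)) NA_real_ else pl[[1]]@ccc,
                          fit_ok = !is.null(pl), stringsAsFactors = FALSE)
        if (!is.null(predictedSS)) {
            ssm <- assignSSFromCA(m)
            # a model of the wrong length cannot match the prediction
            rec$ss_similarity <- if (nchar(ssm) == nchar(predictedSS))
                ssSimilarity(ssm, predictedSS) else 0
        }
        rec
    })
    tab <- do.call(rbind, rows)
    if (!is.null(externalScores)) {
        stopifnot("model_id" %in% names(externalScores))
        tab <- merge(tab, externalScores, by = "model_id", all.x = TRUE,
                     sort = TRUE)
    }
    tab$selected <- NA
    rownames(tab) <- NULL
    tab
}

#' Specify threshold filters and a ranking key for candidate tables
#'
#' @param ... predicates as named two-element lists or strings of the form
#'   \code{"ccc > 0.75"}; comparators among >, >=, <, <=.
#' @param rankKey column used to sort selected records (default "ccc").
#' @return list of class \code{"FilterSpec"}.
#' @examples
#' filterSpec("ccc > 0.75", "ss_similarity > 0.75", "verify3d > 80")
#' @export
filterSpec <- function(..., rankKey = "ccc") {
    preds <- lapply(list(...), function(p) {
        if (is.character(p)) {
            m <- regmatches(p, regexec("^\\s*(\\S+)\\s*(>=|<=|>|<)\\s*(\\S+)\\s*$", p))[[1]]
            if (length(m) != 4) stop("cannot parse predicate: ", p)
            list(score = m[2], cmp = m[3], threshold = as.numeric(m[4]))
        } else {
            stopifnot(all(c("score", "cmp", "threshold") %in% names(p)))
            p
        }
    })
    structure(list(predicates = preds, rankKey = rankKey), class = "FilterSpec")
}

#' Filter and rank candidate records by score thresholds
#'
#' Records satisfying ALL predicates are marked \code{selected}; the table
#' is returned sorted by the ranking key, descending, with ties broken by
#' \code{model_id}. Applying the same filter twice is idempotent.
#'
#' @param table candidate data.frame (from \code{\link{scoreCandidates}} or
#'   any table with a \code{model_id} column).
#' @param spec a \code{FilterSpec}.
#' @return the table with a logical \code{selected} column, sorted.
#' @export
filterCandidates <- function(table, spec) {
    stopifnot(inherits(spec, "FilterSpec"))
    for (p in spec$predicates)
        if (!p$score %in% names(table))
            stop("filter references unknown column: ", p$score)
    if (!spec$rankKey %in% names(table))
        stop("unknown ranking column: ", spec$rankKey)
    sel <- rep(TRUE, nrow(table))
    for (p in spec$predicates) {
        v <- table[[p$score]]
        ok <- switch(p$cmp,
                     ">" = v > p$threshold, ">=" = v >= p$threshold,
                     "<" = v < p$threshold, "<=" = v <= p$threshold,
                     stop("unknown comparator: ", p$cmp))
        ok[is.na(ok)] <- FALSE
        sel <- sel & ok
    }
    table$selected <- sel
    if (!any(sel)) warning("no candidate passes all filters")
    ord <- order(-xtfrm(table[[spec$rankKey]]), table$model_id)
    table <- table[ord, , drop = FALSE]
    rownames(table) <- NULL
    table
}

#' Assemble placed subunit models into one complex
#'
#' Applies each component's rigid transform, relabels chains uniquely
#' (A-Z, a-z, 0-9), concatenates the atoms and reports inter-component
#' CA-CA clashes closer than \code{clashCutoff}.
#'
#' @param placed list of components, each either an \code{AtomicModel}
#'   (already placed) or \code{list(model =, transform =)}.
#' @param clashCutoff clash distance in \enc{Å}{Angstrom} (default 3).
#' @return list with \code{model} (the assembly) and \code{clashes}
#'   (data.frame component_a, component_b, chain_a, chain_b, resno_a,
#'   resno_b, distance) plus \code{nClashes}.
#' @export
assembleModels <- function(placed, clashCutoff = 3) {
    if (length(placed) < 2) stop("assembly needs at least 2 components")
    mods <- lapply(placed, function(p) {
        if (is(p, "AtomicModel")) return(p)
        applyTransform(p$model, p$transform)
    })
    pool <- c(LETTERS, letters, as.character(0:9))
    total_chains <- sum(vapply(mods, function(m) length(chainIds(m)), integer(1)))
    if (total_chains > length(pool))
        stop("cannot relabel more than ", length(pool), " chains uniquely")
    next_chain <- 1L
    tabs <- vector("list", length(mods))
    comp_of <- integer(0)
    for (k in seq_along(mods)) {
        a <- atoms(mods[[k]])
        old <- unique(a$chain)
        map <- stats::setNames(pool[next_chain + seq_along(old) - 1L], old)
        next_chain <- next_chain + length(old)
        a$chain <- unname(map[a$chain])
        tabs[[k]] <- a
        comp_of <- c(comp_of, rep(k, nrow(a)))
    }
    all_atoms <- do.call(rbind, tabs)
    assembly <- atomicModel(all_atoms, metadata = list(components = length(mods)))
    ca <- which(all_atoms$elety == "CA")
    xyz <- as.matrix(all_atoms[ca, c("x", "y", "z")])
    comp <- comp_of[ca]
    clashes <- NULL
    for (i in seq_len(length(mods) - 1)) for (j in (i + 1):length(mods)) {
        ai <- which(comp == i); aj <- which(comp == j)
        if (!length(ai) || !length(aj)) next
        d2 <- outer(rowSums(xyz[ai, , drop = FALSE]^2),
                    rowSums(xyz[aj, , drop = FALSE]^2), "+") -
            2 * xyz[ai, , drop = FALSE] %*% t(xyz[aj, , drop = FALSE])
        hit <- which(d2 < clashCutoff^2, arr.ind = TRUE)
        if (nrow(hit)) {
            ra <- ca[ai[hit[, 1]]]; rb <- ca[aj[hit[, 2]]]
            clashes <- rbind(clashes, data.frame(
                component_a = i, component_b = j,
                chain_a = all_atoms$chain[ra], chain_b = all_atoms$chain[rb],
                resno_a = all_atoms$resno[ra], resno_b = all_atoms$resno[rb],
                distance = sqrt(pmax(0, d2[hit]))))
        }
    }
    if (is.null(clashes))
        clashes <- data.frame(component_a = integer(0), component_b = integer(0),
                              chain_a = character(0), chain_b = character(0),
                              resno_a = integer(0), resno_b = integer(0),
                              distance = numeric(0))
    list(model = assembly, clashes = clashes, nClashes = nrow(clashes))
}
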