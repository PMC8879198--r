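#' Construct a SequenceProfile
#'
#' @param sequence consensus/query amino-acid sequence (one string).
#' @param columns L x 20 numeric matrix, column order \code{AA_ALPHABET}.
#' @param label identifier.
#' @param metadata list; \code{ss} may hold an H/E/C string, \code{offset}
#'   a 0-based fragment offset.
#' @export
sequenceProfile <- function(sequence, columns, label = "profile",
                            metadata = list()) {
    columns <- unname(as.matrix(columns))
    colnames(columns) <- AA_ALPHABET
    new("SequenceProfile", sequence = sequence, columns = columns,
        label = label, metadata = metadata)
}

#' Accessors for SequenceProfile
#' @param x a \code{SequenceProfile}.
#' @name SequenceProfile-accessors
#' @aliases profileColumns profileLength profileSequence
NULL

#' @rdname SequenceProfile-accessors
#' @export
setMethod("profileColumns", "SequenceProfile", function(x) x@columns)

#' @rdname SequenceProfile-accessors
#' @export
setMethod("profileLength", "SequenceProfile", function(x) nrow(x@columns))

#' @rdname SequenceProfile-accessors
#' @export
setMethod("profileSequence", "SequenceProfile", function(x) x@sequence)

setMethod("show", "SequenceProfile", function(object) {
    cat(sprintf("SequenceProfile '%s': %d positions x 20 scores\n",
                object@label, nrow(object@columns)))
})

#' Build a sequence profile from a multiple sequence alignment
#'
#' The first record is taken as the query; alignment columns where the query
#' has a gap are dropped, so the profile length equals the query's ungapped
#' length. Each retained column holds log-odds scores
#' \code{log(20 * (count_a + pseudocount) / (n_nongap + 20 * pseudocount))}
#' of the residue frequencies among non-gap letters against the uniform
#' background 1/20.
#'
#' @param msa an \code{\link[Biostrings]{AAStringSet}}, a character vector of
#'   aligned sequences (equal lengths, gaps as \code{-} or \code{.}), or the
#'   path of an aligned FASTA file.
#' @param pseudocount additive pseudocount, >= 0 (default 1; with 0, columns
#'   may contain \code{-Inf} log-odds and zero variance).
#' @param label profile label; defaults to the first record's name.
#' @return a \code{SequenceProfile}.
#' @export
buildProfileFromMSA <- function(msa, pseudocount = 1, label = NULL) {
    if (is.character(msa) && length(msa) == 1 && file.exists(msa))
        msa <- Biostrings::readAAStringSet(msa)
    if (is(msa, "XStringSet")) {
        nms <- names(msa)
        msa <- as.character(msa)
        if (!is.null(nms)) names(msa) <- nms
    }
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    if (length(unique(nchar(msa))) != 1)
        stop("ragged MSA: aligned sequences must all have equal length")
    if (is.null(label)) label <- if (!is.null(names(msa))) names(msa)[1] else "query"
    mat <- do.call(rbind, strsplit(toupper(msa), ""))
    gap <- mat %in% c("-", ".")
    dim(gap) <- dim(mat)
    keep <- !gap[1, ]
    if (!any(keep)) stop("query sequence is all gaps")
    mat <- mat[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
    L <- ncol(mat)
    cols <- matrix(NA_real_, L, 20)
    drop_cols <- logical(L)
    for (j in seq_len(L)) {
        letters_j <- mat[!gap[, j], j]
        letters_j <- letters_j[letters_j %in% AA_ALPHABET]
        if (length(letters_j) == 0) { drop_cols[j] <- TRUE; next }
        cnt <- table(factor(letters_j, levels = AA_ALPHABET))
        # pseudocount on the relative frequencies, so column scores do not
        # depend on alignment depth
        rf <- as.numeric(cnt) / length(letters_j)
        f <- (rf + pseudocount) / (1 + 20 * pseudocount)
        cols[j, ] <- log(20 * f)
    }
    if (any(drop_cols)) {
        warning(sum(drop_cols), " all-gap column(s) dropped from the profile")
        cols <- cols[!drop_cols, , drop = FALSE]
    }
    qseq <- paste(mat[1, !drop_cols], collapse = "")
    sequenceProfile(qseq, cols, label = label)
}

#' Correlation score between two profile columns
#'
#' Pearson correlation coefficient of two 20-dimensional column score
#' vectors; the match score of profile-profile alignment.
#'
#' @param colA,colB numeric vectors of length 20 with non-zero variance.
#' @return correlation in [-1, 1].
#' @export
columnScore <- function(colA, colB) {
    if (stats::var(colA) == 0 || stats::var(colB) == 0)
        stop("degenerate profile column: zero variance")
    stats::cor(colA, colB)
}

# full L1 x L2 column-correlation matrix (rows standardised once)
.scoreMatrix <- function(query, template) {
    A <- profileColumns(query)
    B <- profileColumns(template)
    std <- function(M) {
        M <- M - rowMeans(M)
        s <- sqrt(rowSums(M^2))
        if (any(s == 0)) stop("degenerate profile column: zero variance")
        M / s
    }
    tcrossprod(std(A), std(B))
}

#' Profile-profile alignment by affine-gap dynamic programming
#'
#' Aligns two profiles over the column-correlation score matrix with affine
#' gap penalties (first gapped position costs \code{gapOpen}, each further
#' position \code{gapExtend}). In \code{"glocal"} mode (global with free end
#' gaps, the template-detection default) terminal gaps in either profile are
#' unpenalized; \code{"local"} is Smith-Waterman. Traceback ties prefer
#' match over gap-in-template over gap-in-query, giving a deterministic
#' optimum path.
#'
#' @param query,template \code{SequenceProfile}s.
#' @param gapOpen,gapExtend positive gap penalties on the correlation scale.
#' @param mode "glocal" or "local".
#' @return a \code{ProfileAlignment}.
#' @export
alignProfiles <- function(query, template, gapOpen = 1.0, gapExtend = 0.1,
                          mode = c("glocal", "local")) {
    mode <- match.arg(mode)
    if (gapOpen <= 0 || gapExtend <= 0)
        stop("gap penalties must be positive")
    S <- .scoreMatrix(query, template)
    n <- nrow(S); m <- ncol(S)
    NEG <- -Inf
    local <- mode == "local"
    M <- matrix(NEG, n + 1, m + 1)   # ends in a match at (i, j)
    Ix <- matrix(NEG, n + 1, m + 1)  # ends with query i unmatched (gap in template)
    Iy <- matrix(NEG, n + 1, m + 1)  # ends with template j unmatched (gap in query)
    M[1, ] <- 0; M[, 1] <- 0         # free leading gaps (and local zero-start)
    # traceback codes: 1 diag-from-M, 2 diag-from-Ix, 3 diag-from-Iy, 0 fresh start
    tbM <- matrix(0L, n + 1, m + 1)
    tbX <- matrix(0L, n + 1, m + 1)  # 1 from M, 2 from Ix, 3 from Iy
    tbY <- matrix(0L, n + 1, m + 1)
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            # gap states consume query i (Ix) or template j (Iy)
            cx <- c(M[i, j + 1] - gapOpen, Ix[i, j + 1] - gapExtend,
                    Iy[i, j + 1] - gapOpen)
            kx <- which.max(cx)
            Ix[i + 1, j + 1] <- cx[kx]; tbX[i + 1, j + 1] <- kx
            cy <- c(M[i + 1, j] - gapOpen, Iy[i + 1, j] - gapExtend,
                    Ix[i + 1, j] - gapOpen)
            ky <- which.max(cy)
            Iy[i + 1, j + 1] <- cy[ky]
            tbY[i + 1, j + 1] <- c(1L, 3L, 2L)[ky]
            cm <- c(M[i, j], Ix[i, j], Iy[i, j])
            km <- which.max(cm)
            val <- cm[km] + S[i, j]
            if (local && val < S[i, j]) { val <- S[i, j]; km <- 0L }
            M[i + 1, j + 1] <- val
            tbM[i + 1, j + 1] <- if (local && km == 0L) 0L else km
        }
    }
    # terminus: glocal = best M on last row/column (trailing gaps free);
    # local = best M anywhere
    if (local) {
        best <- which(M == max(M), arr.ind = TRUE)
        best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
        score <- M[best[1], best[2]]
        ei <- best[1]; ej <- best[2]
    } else {
        cand <- rbind(cbind(n + 1, seq_len(m + 1)), cbind(seq_len(n + 1), m + 1))
        vals <- M[cand]
        k <- which.max(vals)
        score <- vals[k]
        ei <- cand[k, 1]; ej <- cand[k, 2]
    }
    pairs <- matrix(integer(0), 0, 2)
    i <- ei; j <- ej; state <- 1L
    while (i > 1 && j > 1) {
        if (state == 1L) {
            prev <- tbM[i, j]
            pairs <- rbind(c(i - 1L, j - 1L), pairs)
            if (prev == 0L) break  # local fresh start
            state <- prev; i <- i - 1L; j <- j - 1L
        } else if (state == 2L) {
            prev <- tbX[i, j]; state <- prev; i <- i - 1L
        } else {
            prev <- tbY[i, j]; state <- prev; j <- j - 1L
        }
    }
    colnames(pairs) <- c("query", "template")
    new("ProfileAlignment", pairs = pairs, score = score,
        queryLabel = query@label, templateLabel = template@label, mode = mode)
}

#' @rdname ProfileAlignment-accessors
#' @export
setMethod("alignedPairs", "ProfileAlignment", function(x) x@pairs)

#' @rdname ProfileAlignment-accessors
#' @export
setMethod("alignmentScore", "ProfileAlignment", function(x) x@score)

setMethod("show", "ProfileAlignment", function(object) {
    cat(sprintf("ProfileAlignment %s vs %s (%s): %d pairs, S = %.3f, Z = %s\n",
                object@queryLabel, object@templateLabel, object@mode,
                nrow(object@pairs), object@score,
                ifelse(is.na(object@zScore), "uncalibrated",
                       sprintf("%.2f", object@zScore))))
})

#' Calibrate alignment Z-scores by log-length regression
#'
#' Fits the library raw scores S by least squares on \code{log(Lq * Lt)};
#' the residual standard deviation (n - 2 denominator) standardises
#' subsequent scores. With no length variation the fit falls back to a
#' constant model (slope 0) with a warning.
#'
#' @param hits data.frame (or matrix) with columns \code{S}, \code{Lq},
#'   \code{Lt}; at least 10 rows.
#' @return a \code{ZScoreCalibration}.
#' @export
calibrateZScores <- function(hits) {
    hits <- as.data.frame(hits)
    stopifnot(all(c("S", "Lq", "Lt") %in% names(hits)))
    n <- nrow(hits)
    if (n < 10) stop("Z-score calibration needs at least 10 library hits")
    x <- log(hits$Lq * hits$Lt)
    if (length(unique(x)) < 2) {
        warning("all length products identical: constant calibration model")
        res <- hits$S - mean(hits$S)
        sdres <- sqrt(sum(res^2) / (n - 2))
        return(new("ZScoreCalibration", slope = 0, intercept = mean(hits$S),
                   residualSd = max(sdres, .Machine$double.eps),
                   nPoints = as.integer(n)))
    }
    fit <- stats::lm(hits$S ~ x)
    sdres <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
    new("ZScoreCalibration", slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        residualSd = max(sdres, .Machine$double.eps),
        nPoints = as.integer(n))
}

setMethod("show", "ZScoreCalibration", function(object) {
    cat(sprintf("ZScoreCalibration: S ~ %.3f + %.3f log(Lq*Lt), sd %.3g (n = %d)\n",
                object@intercept, object@slope, object@residualSd, object@nPoints))
})

#' Z-score of a raw alignment score
#'
#' \code{(S - (intercept + slope * log(Lq * Lt))) / residualSd}.
#'
#' @param S raw alignment score (or a \code{ProfileAlignment}).
#' @param Lq,Lt query and template profile lengths.
#' @param calib a \code{ZScoreCalibration}.
#' @return numeric Z-score (or, for an alignment input, the alignment with
#'   its \code{zScore} slot filled).
#' @export
zScore <- function(S, Lq, Lt, calib) {
    if (is(S, "ProfileAlignment")) {
        aln <- S
        aln@zScore <- zScore(aln@score, Lq, Lt, calib)
        return(aln)
    }
    (S - (calib@intercept + calib@slope * log(Lq * Lt))) / calib@residualSd
}

#' Split a query profile into overlapping fragments
#'
#' Sliding windows of \code{fragmentLength} positions advancing by
#' \code{fragmentLength - overlap}; the final window is anchored at the end
#' so coverage is complete. Each fragment records its 0-based offset in
#' \code{metadata$offset}.
#'
#' @param profile a \code{SequenceProfile}.
#' @param fragmentLength window length (> overlap).
#' @param overlap positions shared by successive windows (>= 0).
#' @return list of \code{SequenceProfile} fragments.
#' @export
splitQuery <- function(profile, fragmentLength, overlap = 0) {
    stopifnot(fragmentLength > overlap, overlap >= 0)
    L <- profileLength(profile)
    if (fragmentLength >= L)
        return(list(sequenceProfile(profile@sequence, profile@columns,
                                    label = profile@label,
                                    metadata = c(profile@metadata, offset = 0))))
    step <- fragmentLength - overlap
    offs <- seq(0, L - fragmentLength, by = step)
    if (offs[length(offs)] != L - fragmentLength)
        offs <- c(offs, L - fragmentLength)
    lapply(seq_along(offs), function(k) {
        o <- offs[k]
        idx <- (o + 1):(o + fragmentLength)
        sequenceProfile(substr(profile@sequence, o + 1, o + fragmentLength),
                        profile@columns[idx, , drop = FALSE],
                        label = sprintf("%s_frag%d", profile@label, k),
                        metadata = c(profile@metadata, offset = o))
    })
}
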