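test_that("MSA profiles carry the stated pseudocounted log-odds", {
    prof <- buildProfileFromMSA(c(q = "ACD"), pseudocount = 1)
    expect_equal(profileLength(prof), 3)
    # single observation of A with pseudocount 1: f = (1+1)/(1+20), score
    # log(20 f)
    expect_equal(profileColumns(prof)[1, "A"], log(2 / 21 * 20),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(profileColumns(prof)[1, "C"], log(1 / 21 * 20),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # five identical sequences give the same profile as one
    prof5 <- buildProfileFromMSA(rep("ACD", 5), pseudocount = 1)
    expect_equal(profileColumns(prof5), profileColumns(prof))
})

test_that("query gap columns are dropped so length equals ungapped query", {
    msa <- c(q = "AC-D", h1 = "ACWD", h2 = "GC-D")
    prof <- buildProfileFromMSA(msa)
    expect_equal(profileLength(prof), 3)
    expect_equal(profileSequence(prof), "ACD")
    expect_error(buildProfileFromMSA(c("ACD", "AC")), "ragged")
})

test_that("aligned FASTA files feed the profile builder", {
    tf <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">q", "ACDE", ">h1", "ACDG", ">h2", "AVDE"), tf)
    prof <- buildProfileFromMSA(tf)
    expect_equal(profileLength(prof), 4)
    expect_equal(prof@label, "q")
})

test_that("column score is the Pearson correlation of 20-vectors", {
    set.seed(3)
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(columnScore(a, a), 1.0)
    expect_equal(columnScore(a, -a + 7), -1.0)
    # independent textbook evaluation
    hand <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(columnScore(a, b), hand, tolerance = 1e-12)
    expect_error(columnScore(rep(1, 20), a), "variance")
})

test_that("a profile aligned to itself yields the identity pairing", {
    q <- randomProfile(12, seed = 5)
    aln <- alignProfiles(q, q)
    p <- alignedPairs(aln)
    expect_equal(nrow(p), 12)
    expect_true(all(p[, 1] == p[, 2]))
    expect_equal(alignmentScore(aln), 12, tolerance = 1e-9)
})

test_that("an inserted block is aligned as a single gap", {
    set.seed(8)
    cols <- matrix(rnorm(400), 20, 20)
    q <- sequenceProfile(strrep("A", 20), cols)
    t <- sequenceProfile(strrep("A", 23),
                         rbind(cols[1:10, ], matrix(rnorm(60), 3, 20),
                               cols[11:20, ]))
    p <- alignedPairs(alignProfiles(q, t))
    expect_equal(nrow(p), 20)
    gaps <- diff(p[, 2]) - 1
    expect_equal(sum(gaps > 0), 1)
    expect_equal(max(gaps), 3)
})

test_that("dynamic programming equals exhaustive enumeration on tiny profiles", {
    set.seed(99)
    for (rep in 1:12) {
        n <- sample(2:5, 1); m <- sample(2:5, 1)
        q <- randomProfile(n); t <- randomProfile(m)
        S <- profileScoreMatrix(q, t)
        aln <- alignProfiles(q, t, gapOpen = 0.6, gapExtend = 0.2)
        expect_equal(alignmentScore(aln), bruteForceAlignScore(S, 0.6, 0.2),
                     tolerance = 1e-9)
    }
})

test_that("the optimum dominates random monotone alignments", {
    set.seed(17)
    q <- randomProfile(12); t <- randomProfile(10)
    S <- profileScoreMatrix(q, t)
    best <- alignmentScore(alignProfiles(q, t, 0.6, 0.2))
    for (r in 1:100) {
        k <- sample(1:10, 1)
        qi <- sort(sample(1:12, k)); ti <- sort(sample(1:10, k))
        expect_lte(alignmentPathScore(S, qi, ti, 0.6, 0.2), best + 1e-9)
    }
})

test_that("glocal score is symmetric under swapping query and template", {
    set.seed(21)
    for (r in 1:5) {
        q <- randomProfile(sample(6:15, 1)); t <- randomProfile(sample(6:15, 1))
        expect_equal(alignmentScore(alignProfiles(q, t)),
                     alignmentScore(alignProfiles(t, q)), tolerance = 1e-9)
    }
})

test_that("local mode finds a high-identity island and penalties are validated", {
    set.seed(30)
    core <- matrix(rnorm(120), 6, 20)
    q <- sequenceProfile(strrep("A", 14),
                         rbind(matrix(rnorm(80), 4, 20), core,
                               matrix(rnorm(80), 4, 20)))
    t <- sequenceProfile(strrep("A", 10),
                         rbind(matrix(rnorm(40), 2, 20), core,
                               matrix(rnorm(40), 2, 20)))
    aln <- alignProfiles(q, t, mode = "local")
    p <- alignedPairs(aln)
    expect_true(all((p[, 1] - p[, 2]) == 2))  # the shared core register
    expect_gte(alignmentScore(aln), 6 - 1e-9)
    expect_error(alignProfiles(q, t, gapOpen = 0), "positive")
})

test_that("Z-score calibration recovers exact and noisy linear models", {
    set.seed(11)
    hits <- data.frame(Lq = sample(50:500, 40, TRUE),
                       Lt = sample(50:500, 40, TRUE))
    hits$S <- 2 + 3 * log(hits$Lq * hits$Lt)
    cal <- calibrateZScores(hits)
    expect_equal(cal@slope, 3, tolerance = 1e-9)
    expect_equal(cal@intercept, 2, tolerance = 1e-9)
    # noisy: recovered slope within 3 standard errors
    set.seed(12)
    big <- data.frame(Lq = sample(50:500, 1000, TRUE),
                      Lt = sample(50:500, 1000, TRUE))
    x <- log(big$Lq * big$Lt)
    big$S <- 2 + 3 * x + rnorm(1000)
    calN <- calibrateZScores(big)
    se <- calN@residualSd / sqrt(sum((x - mean(x))^2))
    expect_lt(abs(calN@slope - 3), 3 * se)
})

test_that("degenerate libraries fall back to a constant model", {
    hits <- data.frame(S = rep(5, 12), Lq = 100, Lt = 200)
    expect_warning(cal <- calibrateZScores(hits), "constant")
    expect_equal(cal@slope, 0)
    expect_equal(zScore(5, 100, 200, cal), 0)
    expect_error(calibrateZScores(hits[1:5, ]), "10")
})

test_that("Z-scores standardise against the regression line", {
    set.seed(40)
    hits <- data.frame(Lq = sample(50:400, 30, TRUE),
                       Lt = sample(50:400, 30, TRUE))
    hits$S <- 1 + 0.5 * log(hits$Lq * hits$Lt) + rnorm(30, sd = 0.3)
    cal <- calibrateZScores(hits)
    online <- cal@intercept + cal@slope * log(120 * 300)
    expect_equal(zScore(online, 120, 300, cal), 0, tolerance = 1e-12)
    expect_equal(zScore(online + cal@residualSd, 120, 300, cal), 1,
                 tolerance = 1e-12)
})

test_that("Z-scores are invariant to affine rescaling of the library", {
    set.seed(41)
    hits <- data.frame(Lq = sample(50:400, 30, TRUE),
                       Lt = sample(50:400, 30, TRUE))
    hits$S <- 1 + 0.5 * log(hits$Lq * hits$Lt) + rnorm(30, sd = 0.3)
    cal <- calibrateZScores(hits)
    resc <- hits; resc$S <- 2.5 * hits$S + 7
    cal2 <- calibrateZScores(resc)
    z1 <- zScore(hits$S[1], hits$Lq[1], hits$Lt[1], cal)
    z2 <- zScore(resc$S[1], resc$Lq[1], resc$Lt[1], cal2)
    expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("the true template attains the top Z-score in a decoy library", {
    set.seed(1234)
    qseq <- paste(sample(AA_ALPHABET, 60, TRUE), collapse = "")
    qp <- buildProfileFromMSA(sampleMSA(qseq, 20, 0.3, seed = 1234))
    lib <- list(true = buildProfileFromMSA(sampleMSA(qseq, 20, 0.35, seed = 99),
                                           label = "true"))
    for (i in 1:15) {
        rseq <- paste(sample(AA_ALPHABET, sample(40:90, 1), TRUE), collapse = "")
        lib[[paste0("decoy", i)]] <-
            buildProfileFromMSA(sampleMSA(rseq, 20, 0.3, seed = i))
    }
    hits <- data.frame(
        S = vapply(lib, function(t) alignmentScore(alignProfiles(qp, t)),
                   numeric(1)),
        Lq = 60, Lt = vapply(lib, profileLength, numeric(1)))
    cal <- calibrateZScores(hits)
    z <- mapply(function(S, Lt) zScore(S, 60, Lt, cal), hits$S, hits$Lt)
    expect_equal(names(lib)[which.max(z)], "true")
})

test_that("query splitting covers the profile with anchored windows", {
    prof <- randomProfile(100, seed = 55)
    fr <- splitQuery(prof, 50, 10)
    offs <- vapply(fr, function(f) f@metadata$offset, numeric(1))
    expect_equal(offs, c(0, 40, 50))
    covered <- sort(unique(unlist(lapply(offs, function(o) (o + 1):(o + 50)))))
    expect_equal(covered, 1:100)
    expect_equal(profileColumns(fr[[2]]), profileColumns(prof)[41:90, ],
                 ignore_attr = TRUE)
    # short profile: one fragment identical to the input
    short <- randomProfile(30, seed = 56)
    fr1 <- splitQuery(short, 50)
    expect_length(fr1, 1)
    expect_equal(profileColumns(fr1[[1]]), profileColumns(short))
    frL <- splitQuery(short, 30, 0)
    expect_length(frL, 1)
    expect_error(splitQuery(short, 10, 10))
})
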