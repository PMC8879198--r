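test_that("MRC write/read round trip preserves the grid", {
    m <- simulateDensity(makeStructure("helix", 20), "auto",
                         densitySimParams(4))
    tf <- withr::local_tempfile(fileext = ".mrc")
    writeMap(m, tf)
    m2 <- readMap(tf)
    expect_equal(mapDims(m2), mapDims(m))
    # values pass through float32
    expect_lt(max(abs(mapValues(m2) - mapValues(m))),
              1e-6 * max(abs(mapValues(m))) + 1e-6)
    expect_lt(max(abs(mapOrigin(m2) - mapOrigin(m))), 1e-4)
    expect_lt(max(abs(mapSpacing(m2) - mapSpacing(m))), 1e-6)
})

test_that("permuted-axis MRC headers read to the same world-space density", {
    vals <- array(seq_len(3 * 4 * 5) / 10, c(3, 4, 5))
    m <- densityMap(vals, origin = c(1, 2, 3), spacing = c(2, 2, 2))
    tf <- withr::local_tempfile(fileext = ".mrc")
    writeMap(m, tf)
    ref <- readMap(tf)
    # hand-build a file with storage order (y, z, x): MAPC/MAPR/MAPS = 2,3,1
    tp <- withr::local_tempfile(fileext = ".mrc")
    con <- file(tp, "wb")
    perm_vals <- aperm(vals, c(2, 3, 1))
    writeBin(as.integer(c(dim(perm_vals), 2L, 0L, 0L, 0L, dim(vals))), con,
             size = 4, endian = "little")
    writeBin(as.numeric(c(dim(vals) * 2, 90, 90, 90)), con, size = 4,
             endian = "little")
    writeBin(c(2L, 3L, 1L), con, size = 4, endian = "little")
    writeBin(as.numeric(c(min(vals), max(vals), mean(vals))), con, size = 4,
             endian = "little")
    writeBin(c(1L, 0L), con, size = 4, endian = "little")
    writeBin(integer(25), con, size = 4, endian = "little")
    writeBin(c(1, 2, 3), con, size = 4, endian = "little")
    writeChar("MAP ", con, nchars = 4, eos = NULL)
    writeBin(as.integer(0x00004144), con, size = 4, endian = "little")
    writeBin(0, con, size = 4, endian = "little")
    writeBin(0L, con, size = 4, endian = "little")
    writeChar(paste(rep(sprintf("%-80s", ""), 10), collapse = ""), con,
              nchars = 800, eos = NULL)
    writeBin(as.numeric(perm_vals), con, size = 4, endian = "little")
    close(con)
    permuted <- readMap(tp)
    expect_equal(mapValues(permuted), mapValues(ref), tolerance = 1e-6)
    expect_equal(mapOrigin(permuted), mapOrigin(ref), tolerance = 1e-6)
})

test_that("truncated or malformed map files raise format errors", {
    tf <- withr::local_tempfile(fileext = ".mrc")
    writeBin(raw(100), tf)
    expect_error(readMap(tf))
    tf2 <- withr::local_tempfile(fileext = ".mrc")
    writeBin(as.integer(rep(1, 256)), tf2, size = 4)
    suppressWarnings(expect_error(readMap(tf2), "MAP"))
})

test_that("total simulated density obeys the closed-form Gaussian integral", {
    # single atom: sum over voxels -> (2 pi sigma^2 / 3)^(3/2)
    for (sigma in c(4, 6)) {
        p <- densitySimParams(sigma)
        one <- simulateDensity(matrix(c(0.3, -0.2, 0.1), 1, 3), "auto", p)
        expect_equal(sum(mapValues(one)), (2 * pi * sigma^2 / 3)^1.5,
                     tolerance = 1e-3)
    }
    # every fixture kind at 4 sigma margin: relative error < 0.1 %
    p <- densitySimParams(5)
    for (kind in c("helix", "three-helix-bundle", "c2-dimer",
                   "two-domain-hinge")) {
        mdl <- makeStructure(kind, 40)
        tot <- sum(mapValues(simulateDensity(mdl, "auto", p)))
        expect_equal(tot, nAtoms(mdl) * (2 * pi * 25 / 3)^1.5,
                     tolerance = 1e-3)
    }
})

test_that("density is additive over atoms", {
    p <- densitySimParams(4)
    two <- matrix(c(0, 0, 0, 60, 0, 0), 2, 3, byrow = TRUE)
    m2 <- simulateDensity(two, "auto", p)
    m1 <- simulateDensity(two[1, , drop = FALSE], "auto", p)
    expect_equal(sum(mapValues(m2)), 2 * sum(mapValues(m1)), tolerance = 1e-6)
})

test_that("voxel values equal adaptive quadrature of the triple integral", {
    sigma <- 4
    atom <- c(1.3, -0.7, 2.1)
    m <- simulateDensity(matrix(atom, 1, 3),
                         list(origin = c(0, 0, 0), spacing = c(2, 2, 2),
                              dims = c(4L, 4L, 4L)),
                         densitySimParams(sigma))
    g1 <- function(x, mu) exp(-(3 / (2 * sigma^2)) * (x - mu)^2)
    for (vox in list(c(1, 1, 1), c(2, 3, 2), c(3, 2, 4))) {
        ctr <- (vox - 1) * 2
        I <- prod(vapply(1:3, function(k)
            integrate(g1, ctr[k] - 1, ctr[k] + 1, mu = atom[k],
                      rel.tol = 1e-12)$value, numeric(1)))
        expect_equal(mapValues(m)[vox[1], vox[2], vox[3]], I,
                     tolerance = 1e-8)
    }
})

test_that("simulation is equivariant under integer-voxel translations", {
    p <- densitySimParams(4)
    mdl <- coords(makeStructure("helix", 15))
    g <- list(origin = c(-20, -20, -20), spacing = c(2, 2, 2),
              dims = c(30L, 30L, 32L))
    a <- mapValues(simulateDensity(mdl, g, p))
    b <- mapValues(simulateDensity(sweep(mdl, 2, c(2, 0, 2), "+"), g, p))
    # interior comparison: map shifted by one voxel on x and z
    expect_lt(max(abs(b[5:28, 5:28, 5:28] - a[4:27, 5:28, 4:27])), 1e-10)
})

test_that("CCC satisfies its algebraic identities", {
    m <- simulateDensity(makeStructure("helix", 20), "auto",
                         densitySimParams(4))
    expect_equal(ccc(m, m), 1.0, tolerance = 1e-12)
    scaled <- densityMap(mapValues(m) * 2.5, mapOrigin(m), mapSpacing(m))
    expect_equal(ccc(m, scaled), 1.0, tolerance = 1e-12)
    noisy <- makeNoisyMap(m, 0.5, seed = 4)
    expect_equal(ccc(m, noisy), ccc(noisy, m), tolerance = 1e-15)
    expect_lte(abs(ccc(m, noisy)), 1)
    # hand example on a 3-voxel grid
    a <- densityMap(array(c(1, 2, 3), c(3, 1, 1)))
    b <- densityMap(array(c(3, 2, 1), c(3, 1, 1)))
    expect_equal(ccc(a, b), 10 / 14, tolerance = 1e-12)
})

test_that("CCC rejects degenerate or mismatched grids", {
    a <- densityMap(array(1:8 / 8, c(2, 2, 2)))
    z <- densityMap(array(0, c(2, 2, 2)))
    expect_error(ccc(a, z), "zero")
    b <- densityMap(array(1:8 / 8, c(2, 2, 2)), origin = c(5, 0, 0))
    expect_error(ccc(a, b), "grid")
    d <- densityMap(array(1, c(2, 2, 1)))
    expect_error(ccc(a, d), "grid")
})

test_that("zone segmentation keeps spheres around anchors", {
    m <- simulateDensity(makeStructure("helix", 20), "auto",
                         densitySimParams(4))
    whole <- segmentMapZone(m, makeStructure("helix", 20), 1e4)
    expect_equal(mapValues(whole), mapValues(m))
    # radius of half a voxel around one voxel center keeps exactly 1 voxel
    ctr <- matrix(mapOrigin(m) + 5 * mapSpacing(m), 1, 3)
    one <- segmentMapZone(m, ctr, 0.5 * mapSpacing(m)[1])
    expect_equal(one@metadata$retainedVoxels, 1L)
    # disjoint anchors: retained count is additive
    ctr2 <- matrix(mapOrigin(m) + 12 * mapSpacing(m), 1, 3)
    r <- 1.2 * mapSpacing(m)[1]
    n1 <- segmentMapZone(m, ctr, r)@metadata$retainedVoxels
    n2 <- segmentMapZone(m, ctr2, r)@metadata$retainedVoxels
    nu <- segmentMapZone(m, rbind(ctr, ctr2), r)@metadata$retainedVoxels
    expect_equal(nu, n1 + n2)
    expect_error(segmentMapZone(m, matrix(c(1e6, 1e6, 1e6), 1, 3), 2),
                 "empty")
    expect_error(segmentMapZone(m, ctr, 0), "radius")
})

test_that("cropping shifts the origin and restricts correlations", {
    m <- simulateDensity(makeStructure("helix", 20), "auto",
                         densitySimParams(4))
    d <- mapDims(m)
    full <- cropMap(m, list(c(1, d[1]), c(1, d[2]), c(1, d[3])))
    expect_equal(mapValues(full), mapValues(m))
    expect_equal(mapOrigin(full), mapOrigin(m))
    one <- cropMap(m, list(c(3, 3), c(4, 4), c(5, 5)))
    expect_equal(mapDims(one), c(1L, 1L, 1L))
    expect_equal(mapOrigin(one),
                 mapOrigin(m) + c(2, 3, 4) * mapSpacing(m))
    expect_error(cropMap(m, list(c(0, 2), c(1, 2), c(1, 2))), "box")
    # ccc of identical crops equals ccc restricted to the region
    n <- makeNoisyMap(m, 0.3, seed = 9)
    box <- list(c(2, 8), c(2, 8), c(3, 9))
    sub_a <- mapValues(cropMap(m, box)); sub_b <- mapValues(cropMap(n, box))
    expect_equal(ccc(cropMap(m, box), cropMap(n, box)),
                 sum(sub_a * sub_b) / sqrt(sum(sub_a^2) * sum(sub_b^2)),
                 tolerance = 1e-12)
})
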