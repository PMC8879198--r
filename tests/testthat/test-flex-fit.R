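test_that("restraints follow the bonded-chain and contact rules", {
    h <- makeStructure("helix", 10)
    rs <- buildRestraints(h, contactCutoff = 8)
    expect_equal(nrow(rs@bonds), 9)
    expect_equal(rs@bonds$d0, rep(3.8, 9), tolerance = 0.01)
    expect_equal(nrow(rs@contacts), bruteContactCount(h, 8))
    expect_true(all(abs(atoms(h)$resno[rs@contacts$j] -
                        atoms(h)$resno[rs@contacts$i]) >= 3))
    # zero cutoff: no contacts
    expect_equal(nrow(buildRestraints(h, contactCutoff = 0)@contacts), 0)
})

test_that("chains are bonded separately but share contacts", {
    dm <- makeStructure("c2-dimer", 48)
    rs <- buildRestraints(dm, contactCutoff = 10)
    a <- atoms(dm)
    expect_true(all(a$chain[rs@bonds$i] == a$chain[rs@bonds$j]))
    expect_equal(nrow(rs@bonds), nAtoms(dm) - 2)  # one chain break
    expect_equal(nrow(rs@contacts), bruteContactCount(dm, 10))
})

test_that("restraint energy is zero at the construction pose with exact gradients", {
    hg <- makeStructure("two-domain-hinge", 30)
    rs <- buildRestraints(hg)
    at0 <- restraintEnergy(coords(hg), rs)
    expect_equal(at0$energy, 0)
    expect_equal(max(abs(at0$gradient)), 0)
    # one bond stretched by 1 A with kb = 1 scores 1/2
    two <- atomicModel(data.frame(chain = "A", resno = 1:2, resid = "ALA",
                                  elety = "CA", elesy = "C",
                                  x = c(0, 3.8), y = 0, z = 0, b = 0))
    rs2 <- buildRestraints(two, contactCutoff = 0, kBond = 1)
    stretched <- matrix(c(0, 4.8, 0, 0, 0, 0), 2, 3)
    expect_equal(restraintEnergy(stretched, rs2)$energy, 0.5,
                 tolerance = 1e-12)
    # finite-difference gradient check off the minimum
    set.seed(2)
    xyz <- coords(hg) + matrix(rnorm(90, sd = 0.3), 30, 3)
    an <- restraintEnergy(xyz, rs)
    h <- 1e-6
    for (pick in list(c(1, 1), c(12, 2), c(30, 3))) {
        xp <- xyz; xp[pick[1], pick[2]] <- xp[pick[1], pick[2]] + h
        xm <- xyz; xm[pick[1], pick[2]] <- xm[pick[1], pick[2]] - h
        num <- (restraintEnergy(xp, rs)$energy -
                restraintEnergy(xm, rs)$energy) / (2 * h)
        expect_equal(an$gradient[pick[1], pick[2]], num, tolerance = 1e-6)
    }
    expect_error(restraintEnergy(xyz * 0, rs), "singular")
})

test_that("the EM bias energy follows N k (1 - CCC) with an exact gradient", {
    h5 <- makeStructure("helix", 12)
    p <- densitySimParams(4)
    map <- simulateDensity(h5, "auto", p)
    # simulated map equal to the target (up to scale) gives zero energy
    scaled <- densityMap(mapValues(map) * 3.7, mapOrigin(map), mapSpacing(map))
    em <- emEnergy(coords(h5), scaled, p, k = 2)
    expect_equal(em$energy, 0, tolerance = 1e-9)
    expect_equal(em$ccc, 1, tolerance = 1e-12)
    # displaced pose: energy identity and finite differences
    xyz <- coords(h5) + 0.5
    em <- emEnergy(xyz, map, p, k = 2)
    expect_equal(em$energy, 12 * 2 * (1 - em$ccc), tolerance = 1e-12)
    hstep <- 1e-4
    num <- matrix(0, 3, 3)
    for (n in 1:3) for (i in 1:3) {
        xp <- xyz; xp[n, i] <- xp[n, i] + hstep
        xm <- xyz; xm[n, i] <- xm[n, i] - hstep
        num[n, i] <- (emEnergy(xp, map, p, 2)$energy -
                      emEnergy(xm, map, p, 2)$energy) / (2 * hstep)
    }
    expect_lt(max(abs(num - em$gradient[1:3, ])) / max(abs(em$gradient)),
              1e-4)
    # model fully outside the map is degenerate
    expect_error(emEnergy(xyz + 1e4, map, p, 2), "degenerate")
})

test_that("flexible fitting recovers a hinge-bent fixture", {
    ref <- makeStructure("two-domain-hinge", 40)
    p <- densitySimParams(6)
    expMap <- simulateDensity(ref, "auto", p)
    start <- perturbModel(ref, list(kind = "hinge", angle = 25), seed = 11)
    cfg <- flexFitConfig(sigma = 6, k = 5, maxSteps = 600)
    ff <- flexibleFit(start, expMap, cfg)
    tr <- ff$trajectory
    expect_gt(tr$ccc[nrow(tr)], tr$ccc[1])
    expect_lt(rmsd(ff$model, ref), rmsd(start, ref))
    expect_gte(contactPreservation(ff$model, ff$restraints), 0.9)
    # energy is monotone non-increasing and the E_EM record is consistent
    etot <- tr$eRestraint + tr$eEM
    expect_true(all(diff(etot) <= 1e-9))
    expect_equal(tr$eEM, 40 * 5 * (1 - tr$ccc), tolerance = 1e-9)
})

test_that("the k -> 0 limit leaves the start essentially unchanged", {
    ref <- makeStructure("two-domain-hinge", 30)
    p <- densitySimParams(6)
    expMap <- simulateDensity(ref, "auto", p)
    start <- perturbModel(ref, list(kind = "hinge", angle = 20), seed = 11)
    ff <- flexibleFit(start, expMap, flexFitConfig(sigma = 6, k = 1e-12,
                                                   maxSteps = 200))
    expect_lt(rmsd(ff$model, start), 1e-3)
})

test_that("stronger map bias never lowers the final CCC on the hinge fixture", {
    ref <- makeStructure("two-domain-hinge", 40)
    p <- densitySimParams(6)
    expMap <- simulateDensity(ref, "auto", p)
    start <- perturbModel(ref, list(kind = "hinge", angle = 25), seed = 11)
    finals <- vapply(c(0.1, 1, 10), function(k) {
        tr <- flexibleFit(start, expMap,
                          flexFitConfig(sigma = 6, k = k,
                                        maxSteps = 400))$trajectory
        tr$ccc[nrow(tr)]
    }, numeric(1))
    expect_true(all(diff(finals) >= -1e-6))
})

test_that("langevin fitting is bitwise reproducible for a fixed seed", {
    ref <- makeStructure("two-domain-hinge", 30)
    p <- densitySimParams(6)
    expMap <- simulateDensity(ref, "auto", p)
    start <- perturbModel(ref, list(kind = "hinge", angle = 20), seed = 11)
    cfg <- flexFitConfig(sigma = 6, k = 2, maxSteps = 40,
                         stepRule = "langevin", seed = 42)
    f1 <- flexibleFit(start, expMap, cfg)
    f2 <- flexibleFit(start, expMap, cfg)
    expect_identical(f1$trajectory, f2$trajectory)
    expect_identical(coords(f1$model), coords(f2$model))
    # a different seed takes a different path
    f3 <- flexibleFit(start, expMap,
                      flexFitConfig(sigma = 6, k = 2, maxSteps = 40,
                                    stepRule = "langevin", seed = 43))
    expect_false(identical(f1$trajectory, f3$trajectory))
})

test_that("fitting refuses a non-overlapping start", {
    ref <- makeStructure("two-domain-hinge", 30)
    p <- densitySimParams(6)
    expMap <- simulateDensity(ref, "auto", p)
    away <- ref
    coords(away) <- coords(ref) + 500
    expect_error(flexibleFit(away, expMap, flexFitConfig(sigma = 6)))
})
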