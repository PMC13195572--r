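test_that("the fraying landscape is an anchored zipper with a tether penalty", {
    d <- defaultDesign()
    m <- energyModel()
    fl <- frayingLandscape(d, m)

    expect_identical(nStates(fl), 8L)  # 7-bp retained segment -> s = 0..7
    expect_identical(stateCoordinates(fl), 0:7)
    dG <- stateEnergies(fl)
    expect_identical(dG[8L], 0)           # fully bound reference
    expect_gt(dG[1L], 0)                  # bound state more stable than open
    ## the 0 -> 1 closing step pays exactly the tether initiation penalty
    ## on top of losing no stack (state 1 has no internal stack)
    expect_equal(dG[2L] - dG[1L], m@tetherInitDG, tolerance = 1e-9)

    ## hand-assembled zipper from the same retained duplex
    s4 <- rnaStrand(d); s1 <- designStrand(d, "S1")
    ret <- pairStrands(s4, c(14, 20), s1, c(45, 51))
    st <- vapply(1:6, function(j) stackDG(ret, j, s4, s1, m), numeric(1))
    EL <- m@tetherInitDG + sum(st)
    for (s in 0:7) {
        Es <- if (s == 0) 0 else m@tetherInitDG +
            (if (s >= 2) sum(st[(7 - s + 1):6]) else 0)
        expect_equal(dG[s + 1L], Es - EL, tolerance = 1e-9)
    }
})

test_that("a zeroed energy model gives a flat landscape", {
    d <- defaultDesign()
    fl <- frayingLandscape(d, zeroEnergyModel())
    expect_true(all(abs(stateEnergies(fl)) < 1e-12))
})

test_that("fraying hand-sum oracle holds on a 3-bp toy segment", {
    m <- energyModel()
    r3 <- modifiedStrand("r3", "AAA", sugars = "RNA")
    d3 <- modifiedStrand("d3", "TTT")
    dup <- pairStrands(r3, c(1, 3), d3, c(1, 3))
    fl <- gapmerTDN:::.frayingFromSegment(dup, r3, d3, m)
    st <- handDG(-7.8, -21.9)  # rAA/dTT hybrid stack, both steps
    expected <- c(0,
                  m@tetherInitDG,
                  m@tetherInitDG + st,
                  m@tetherInitDG + 2 * st)
    expect_equal(stateEnergies(fl), expected - expected[4L], tolerance = 1e-9)
})

test_that("two-state availability matches the closed form", {
    m <- energyModel()
    occ <- toeholdAvailability(twoStateLandscape(3), m)
    analytic <- exp(-3 / RT310) / (1 + exp(-3 / RT310))
    expect_equal(occ@openFraction, analytic, tolerance = 1e-12)
    expect_lt(occ@openFraction, 0.01)
    expect_equal(occ@deltaGOpen, 3)

    ## deltaG = 0: symmetry
    occ0 <- toeholdAvailability(twoStateLandscape(0), m)
    expect_equal(occ0@openFraction, 0.5, tolerance = 1e-12)

    ## probabilities always sum to 1 within 1e-12
    d <- defaultDesign()
    fl <- frayingLandscape(d, m)
    expect_equal(sum(toeholdAvailability(fl, m)@probabilities), 1,
                 tolerance = 1e-12)
})

test_that("open fraction is monotone in deltaG, temperature and increments", {
    m <- energyModel()
    ## strictly decreasing in deltaGOpen
    fr <- vapply(seq(0, 6, by = 0.5), function(g)
        toeholdAvailability(twoStateLandscape(g), m)@openFraction, numeric(1))
    expect_true(all(diff(fr) < 0))

    ## strictly increasing in temperature for fixed deltaG > 0
    frT <- vapply(c(290, 310, 330, 350), function(tt) {
        mt <- energyModel(temperature = tt)
        toeholdAvailability(twoStateLandscape(3), mt)@openFraction
    }, numeric(1))
    expect_true(all(diff(frT) > 0))

    ## stabilizing the retained segment never opens the toehold more
    d <- defaultDesign()
    frMod <- vapply(c(0, 0.5, 1, 1.5, 2), function(f) {
        mf <- energyModel(modIncrements = c(LNA = -1.0 * f, OME = -0.2 * f,
                                            PS = 0.1))
        toeholdAvailability(frayingLandscape(d, mf), mf)@openFraction
    }, numeric(1))
    expect_true(all(diff(frMod) <= 0))
})

test_that("calibration hits a requested opening free energy exactly", {
    d <- defaultDesign()
    m <- energyModel()
    cal <- calibrateToeholdModel(d, m, targetDeltaGOpen = 3)
    occ <- toeholdAvailability(frayingLandscape(d, cal), cal)
    expect_equal(occ@deltaGOpen, 3, tolerance = 1e-9)
    expect_false(is.null(attr(cal, "calibrationFactor")))
})

test_that("displacement landscapes zipper, plateau and commit", {
    m <- energyModel()
    d <- defaultDesign()
    tg <- generateTarget(d, seed = 1)
    dl <- displacementLandscape(d, tg, m)

    ## 21 pair states (m = 0..20) + 13 branch-migration plateaus
    expect_identical(nStates(dl), 34L)
    expect_identical(sum(dl@stateLabels == "plateau"), 13L)
    ## global minimum at full displacement (m = 20, coordinate 40)
    expect_identical(stateCoordinates(dl)[which.min(stateEnergies(dl))], 40L)
    ## thermodynamic drive: final below initial
    expect_lt(stateEnergies(dl)[nStates(dl)], stateEnergies(dl)[1L])

    ## the first barrier out of the toehold-bound state is the plateau height
    co <- stateCoordinates(dl)
    expect_equal(stateEnergies(dl)[match(15L, co)] -
                 stateEnergies(dl)[match(14L, co)],
                 m@bmPlateauDG, tolerance = 1e-9)
})

test_that("identical chemistries and zero plateau flatten branch migration", {
    m <- zeroEnergyModel()
    st <- rep(-1.0, 9)  # uniform invader stacks, T = 4, I = 6
    dl <- displacementLandscapeFromStacks(
        invaderStacks = st, incumbentStacks = rep(-1.0, 5),
        toeholdLen = 4L, model = m, invaderInitDG = 1.5, incumbentInitDG = 1.5)
    co <- stateCoordinates(dl); dG <- stateEnergies(dl)
    bm <- dG[co %in% (2L * (4:9))]  # pair states m = 4..9
    expect_true(all(abs(bm - bm[1L]) < 1e-12))
    ## the final state credits the incumbent dissociation entropy once
    final <- dG[co == 2L * 10L]
    expect_equal(final - bm[1L], -1.5 + (-1.0), tolerance = 1e-12)
})

test_that("profile reports are stable and anchored", {
    d <- defaultDesign()
    m <- energyModel()
    fl <- frayingLandscape(d, m)
    tab <- deltaGProfileReport(fl)
    expect_identical(nrow(tab), 8L)
    expect_identical(tab$dG[fl@referenceIndex], 0)

    flat <- frayingLandscape(d, zeroEnergyModel())
    expect_true(all(deltaGProfileReport(flat)$dG == 0))

    f1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    deltaGProfileReport(fl, f1); deltaGProfileReport(fl, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
})
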