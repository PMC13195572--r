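test_that("exact occupancy reproduces hand-computed Boltzmann sums", {
    m <- energyModel()
    ## fixed toy 8-state landscape
    dG <- c(4.2, 3.1, 2.5, 1.7, 1.2, 0.8, 0.3, 0)
    ls <- landscape1D(0:7, dG)
    occ <- exactOccupancy(ls, m)
    w <- exp(-dG / RT310)
    expect_equal(unname(occ@probabilities), w / sum(w), tolerance = 1e-12)
    expect_equal(sum(occ@probabilities), 1, tolerance = 1e-12)
    expect_equal(occ@openFraction, (w / sum(w))[1L], tolerance = 1e-12)

    occ2 <- exactOccupancy(twoStateLandscape(0), m)
    expect_equal(unname(occ2@probabilities), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("metropolis sampling is deterministic per seed and uniform on flat", {
    m <- energyModel()
    flat <- landscape1D(0:4, rep(0, 5), referenceIndex = 1L)
    h1 <- metropolisSample(flat, m, nSteps = 2e5, seed = 42)
    h2 <- metropolisSample(flat, m, nSteps = 2e5, seed = 42)
    expect_identical(h1@counts, h2@counts)
    expect_identical(h1@transitionsUp, h2@transitionsUp)

    ## flat landscape: uniform within 3 standard errors (conservative SE
    ## that ignores the favourable negative correlation of a reflected walk)
    p <- h1@counts / h1@nSteps
    se <- sqrt(0.2 * 0.8 / (h1@nSteps / 5))  # ~5-step decorrelation
    expect_true(all(abs(p - 0.2) < 3 * se + 0.01))
})

test_that("unbiased sampling converges to the exact occupancies", {
    d <- defaultDesign()
    m <- energyModel()
    fl <- frayingLandscape(d, m)
    ex <- exactOccupancy(fl, m)
    h <- metropolisSample(fl, m, nSteps = 2e5, seed = 9)
    expect_lt(totalVariation(h, ex), 0.05)
})

test_that("empirical transitions satisfy detailed balance", {
    m <- energyModel()
    dG <- c(0.8, 0.3, 0, 0.5)
    ls <- landscape1D(0:3, dG, referenceIndex = 3L)
    h <- metropolisSample(ls, m, nSteps = 3e5, seed = 5)
    ## net flux across each adjacent bond is zero in equilibrium: accepted
    ## up- and down-crossings match closely
    for (i in 1:3) {
        up <- h@transitionsUp[i]; dn <- h@transitionsDown[i]
        expect_lt(abs(up - dn) / sqrt(up + dn), 4)
    }
    ## occupancy ratios reproduce exp(-ddG/RT)
    p <- h@counts / h@nSteps
    for (i in 1:3) {
        expect_equal(unname(log(p[i + 1L] / p[i])),
                     -(dG[i + 1L] - dG[i]) / RT310, tolerance = 0.1)
    }
})

test_that("umbrella machinery reduces to unbiased sampling at zero bias", {
    m <- energyModel()
    ls <- landscape1D(0:3, c(1.2, 0.4, 0.1, 0), referenceIndex = 4L)
    w0 <- umbrellaWindow(rep(0, 4), label = "null")
    h <- umbrellaSample(ls, m, list(w0), nStepsPerWindow = 5e4, seed = 31)[[1L]]
    href <- metropolisSample(ls, m, nSteps = 5e4, seed = 31)
    expect_identical(h@counts, href@counts)
})

test_that("biased sampling matches the analytic biased Boltzmann weights", {
    m <- energyModel()
    ls <- twoStateLandscape(2)
    b <- umbrellaWindow(c(0, 1.2), label = "push")
    h <- metropolisSample(ls, m, nSteps = 2e5, seed = 13, bias = b)
    E <- stateEnergies(ls) + b@bias
    pth <- exp(-(E - min(E)) / RT310); pth <- pth / sum(pth)
    pobs <- h@counts / h@nSteps
    ## two-state chains decorrelate in a few steps; 3 SE with a safety floor
    se <- sqrt(pth[1L] * pth[2L] / (h@nSteps / 5))
    expect_true(all(abs(pobs - pth) < 3 * se + 0.01))
})

test_that("harmonic windows cover all states and reweighting round-trips", {
    d <- defaultDesign()
    m <- energyModel()
    fl <- frayingLandscape(d, m)
    wins <- harmonicWindows(fl, kappa = 1)
    expect_identical(length(wins), nStates(fl))

    hs <- umbrellaSample(fl, m, wins, nStepsPerWindow = 2e4, seed = 17)
    ## every state well visited somewhere
    tot <- Reduce(`+`, lapply(hs, function(h) h@counts))
    expect_true(all(tot >= 100))

    rw <- reweight(hs, wins, m, fl)
    expect_lt(max(abs(stateEnergies(rw) - stateEnergies(fl))), 0.15)

    ## reweighted open fraction close to the exact one (loose unit-level
    ## bound; the acceptance suite runs the full-budget check)
    ex <- exactOccupancy(fl, m)
    est <- sampledOpenFraction(rw, m)
    expect_lt(abs(est - ex@openFraction) / ex@openFraction, 0.5)
})

test_that("single-window reweighting equals the log-ratio estimator", {
    m <- energyModel()
    ls <- twoStateLandscape(1.5)
    w0 <- umbrellaWindow(c(0, 0))
    h <- metropolisSample(ls, m, nSteps = 1e5, seed = 3, bias = w0)
    rw <- reweight(list(h), list(w0), m, ls)
    direct <- -RT310 * log(h@counts / h@nSteps)
    direct <- direct - direct[2L]
    expect_equal(stateEnergies(rw), unname(direct), tolerance = 1e-9)
})

test_that("non-overlapping windows are refused", {
    m <- energyModel()
    ls <- landscape1D(0:3, c(0.5, 0.2, 0.1, 0), referenceIndex = 4L)
    wa <- umbrellaWindow(c(0, 0, 200, 200), label = "low")
    wb <- umbrellaWindow(c(200, 200, 0, 0), label = "high")
    hs <- umbrellaSample(ls, m, list(wa, wb), nStepsPerWindow = 2e4, seed = 2)
    expect_error(reweight(hs, list(wa, wb), m, ls), "do not overlap")
})
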