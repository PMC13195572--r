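## mc_sampling: Metropolis Monte Carlo on discrete landscapes, umbrella
## biasing, and multi-histogram reweighting. The exact Boltzmann sum
## (exactOccupancy) is the oracle every sampler is verified against.

#' Construct an umbrella window
#'
#' @param bias per-state bias energies, kcal/mol.
#' @param label window label.
#' @return an [UmbrellaWindow-class].
#' @export
umbrellaWindow <- function(bias, label = "window") {
    new("UmbrellaWindow", bias = as.numeric(bias), label = label)
}

#' Harmonic-equivalent discrete umbrella windows
#'
#' One window per chosen center: window centered on state index \eqn{c}
#' biases state \eqn{i} by \eqn{\kappa (i - c)^2 / 2} kcal/mol, the discrete
#' analogue of a harmonic restraint on the reaction coordinate.
#'
#' @param landscape the [Landscape1D-class] to be sampled.
#' @param kappa restraint stiffness, kcal/mol per state-index squared.
#' @param spacing center-to-center spacing in state indices.
#' @return list of [UmbrellaWindow-class] objects spanning all states.
#' @export
harmonicWindows <- function(landscape, kappa = 1.0, spacing = 1L) {
    S <- nStates(landscape)
    centers <- unique(c(seq.int(1L, S, by = spacing), S))
    lapply(centers, function(cc)
        umbrellaWindow(0.5 * kappa * (seq_len(S) - cc)^2,
                       label = sprintf("w%02d", cc)))
}

#' Metropolis sampling of a discrete landscape
#'
#' Single-state-increment Metropolis Monte Carlo: proposals move the current
#' state by one position left or right with equal probability; moves past the
#' ends are rejected (the chain stays put), which preserves detailed balance
#' with respect to \eqn{\exp(-(dG + bias)/RT)}. Every step (accepted or not)
#' is recorded in the histogram. Accepted transitions between adjacent states
#' are counted separately so detailed balance can be checked empirically.
#'
#' @param landscape a [Landscape1D-class].
#' @param model an [EnergyModel-class] (temperature).
#' @param nSteps number of Monte Carlo steps.
#' @param seed RNG seed (recorded in the result).
#' @param bias optional [UmbrellaWindow-class] (or numeric per-state bias).
#' @param start starting state index; defaults to the minimum of the biased
#'   energy, so no burn-in is discarded.
#' @return a [SampledHistogram-class].
#' @examples
#' h <- metropolisSample(twoStateLandscape(0), nSteps = 1e4, seed = 1)
#' h@counts
#' @export
metropolisSample <- function(landscape, model = energyModel(), nSteps = 1e6,
                             seed = 1L, bias = NULL, start = NULL) {
    S <- nStates(landscape)
    E <- landscape@dG
    label <- "unbiased"
    if (!is.null(bias)) {
        if (is(bias, "UmbrellaWindow")) {
            if (length(bias@bias) != S)
                stop("bias must have one energy per state")
            E <- E + bias@bias
            label <- bias@label
        } else {
            E <- E + as.numeric(bias)
        }
    }
    if (is.null(start)) start <- which.min(E)
    rt <- .rt(model)
    nSteps <- as.numeric(nSteps)

    ## precomputed acceptance probabilities for +1 / -1 moves
    accUp <- c(pmin(1, exp(-diff(E) / rt)), 0)   # from i to i+1 (0 past end)
    accDown <- c(0, pmin(1, exp(diff(E) / rt)))  # from i to i-1

    set.seed(seed)
    counts <- integer(S)
    tUp <- integer(S - 1L)
    tDown <- integer(S - 1L)
    ## draw in blocks to bound memory at large nSteps
    block <- 1e6L
    cur <- as.integer(start)
    done <- 0
    while (done < nSteps) {
        nb <- as.integer(min(block, nSteps - done))
        up <- stats::runif(nb) < 0.5
        u <- stats::runif(nb)
        for (t in seq_len(nb)) {
            if (up[t]) {
                if (u[t] < accUp[cur]) {
                    tUp[cur] <- tUp[cur] + 1L
                    cur <- cur + 1L
                }
            } else if (cur > 1L && u[t] < accDown[cur]) {
                cur <- cur - 1L
                tDown[cur] <- tDown[cur] + 1L
            }
            counts[cur] <- counts[cur] + 1L
        }
        done <- done + nb
    }
    names(counts) <- landscape@coordinate
    new("SampledHistogram", counts = counts, nSteps = nSteps,
        seed = as.integer(seed), label = label,
        transitionsUp = tUp, transitionsDown = tDown)
}

setMethod("show", "SampledHistogram", function(object) {
    cat(sprintf("SampledHistogram '%s': %g steps, seed %d\n",
        object@label, object@nSteps, object@seed))
    print(object@counts)
    invisible(object)
})

#' Umbrella sampling across a set of windows
#'
#' Runs [metropolisSample()] once per window under its bias; window \eqn{k}
#' uses seed \code{seed + k - 1} so the whole set is reproducible from one
#' seed.
#'
#' @param landscape a [Landscape1D-class].
#' @param model an [EnergyModel-class].
#' @param windows list of [UmbrellaWindow-class] objects (e.g. from
#'   [harmonicWindows()]).
#' @param nStepsPerWindow Monte Carlo steps per window.
#' @param seed base RNG seed.
#' @return list of [SampledHistogram-class], one per window.
#' @export
umbrellaSample <- function(landscape, model = energyModel(), windows,
                           nStepsPerWindow = 1e5, seed = 1L) {
    if (!length(windows))
        stop("need at least one umbrella window")
    lapply(seq_along(windows), function(k)
        metropolisSample(landscape, model, nSteps = nStepsPerWindow,
            seed = as.integer(seed) + k - 1L, bias = windows[[k]]))
}

#' Multi-histogram reweighting (WHAM) of umbrella windows
#'
#' Recovers the unbiased free-energy profile from biased window histograms by
#' iterative multi-histogram reweighting: window free-energy shifts and state
#' probabilities are updated self-consistently until successive shifts change
#' by less than \code{tol}. The profile is anchored to the reference state.
#'
#' @param histograms list of [SampledHistogram-class] from [umbrellaSample()].
#' @param windows the matching list of [UmbrellaWindow-class] objects.
#' @param model an [EnergyModel-class].
#' @param landscape the sampled [Landscape1D-class] (supplies coordinates and
#'   the reference state of the returned profile).
#' @param tol convergence threshold on the window shifts, kcal/mol.
#' @param maxIter iteration cap.
#' @return a [Landscape1D-class] holding the estimated profile.
#' @export
reweight <- function(histograms, windows, model = energyModel(), landscape,
                     tol = 1e-8, maxIter = 10000L) {
    K <- length(histograms)
    if (K != length(windows))
        stop("histograms and windows must match")
    S <- nStates(landscape)
    n <- vapply(histograms, function(h) as.numeric(h@counts), numeric(S))
    n <- matrix(n, nrow = S)              # S x K visit counts
    N <- colSums(n)
    B <- vapply(windows, function(w) w@bias, numeric(S))  # S x K
    rt <- .rt(model)

    visited <- n > 0
    if (any(rowSums(visited) == 0))
        stop(sprintf("state(s) %s never visited in any window; profile undefined",
            paste(landscape@coordinate[rowSums(visited) == 0], collapse = ",")))
    ## overlap check: windows must form one connected component through
    ## shared visited states
    comp <- integer(K); comp[1L] <- 1L
    repeat {
        grew <- FALSE
        for (k in which(comp == 0L)) {
            linked <- any(vapply(which(comp == 1L), function(j)
                any(visited[, k] & visited[, j]), logical(1)))
            if (linked) { comp[k] <- 1L; grew <- TRUE }
        }
        if (!grew) break
    }
    if (any(comp == 0L))
        stop("umbrella windows do not overlap in visited states; cannot reweight")

    eB <- exp(-B / rt)                     # S x K
    f <- numeric(K)                        # window free-energy shifts
    rowN <- rowSums(n)
    for (it in seq_len(maxIter)) {
        denom <- eB %*% (N * exp(f / rt))  # S x 1
        p <- rowN / as.numeric(denom)
        fNew <- -rt * log(as.numeric(crossprod(eB, p)))
        fNew <- fNew - fNew[1L]
        if (max(abs(fNew - f)) < tol) { f <- fNew; break }
        f <- fNew
    }
    dG <- -rt * log(p)
    landscape1D(landscape@coordinate, dG,
        referenceIndex = landscape@referenceIndex,
        coordinateName = paste0(landscape@coordinateName, "_reweighted"),
        stateLabels = landscape@stateLabels)
}

#' Open fraction estimated from a sampled or reweighted profile
#'
#' @param landscape a (reweighted) [Landscape1D-class].
#' @inheritParams toeholdAvailability
#' @return the estimated open fraction.
#' @export
sampledOpenFraction <- function(landscape, model = energyModel(),
                                openMaxIntact = 0L) {
    toeholdAvailability(landscape, model, openMaxIntact)@openFraction
}

#' Total-variation distance between a histogram and exact occupancies
#'
#' @param histogram a [SampledHistogram-class].
#' @param occupancy the matching [OccupancyResult-class] from
#'   [exactOccupancy()].
#' @return total-variation distance in \eqn{[0, 1]}.
#' @export
totalVariation <- function(histogram, occupancy) {
    p <- histogram@counts / histogram@nSteps
    0.5 * sum(abs(p - occupancy@probabilities))
}
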