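## catalytic_kinetics: the cleave -> open -> bind -> displace -> cleave-target
## cycle as a stochastic mass-action network with a mean-field counterpart.

#' Rate parameters for the catalytic cycle
#'
#' All values are configuration-exposed placeholders: the underlying
#' experiments report no enzyme concentration, kcat or binding rates, so
#' these defaults are chosen for plausibility (RNase H turnover of order
#' 1/min, oligonucleotide association of order 1e6 per molar-second, a
#' nanomolar-range target) rather than fitted.
#'
#' @param kCleave pseudo-first-order RNase H cleavage rate on heteroduplex
#'   species, 1/s (applies to both the TDN heteroduplex and the re-formed
#'   target duplex).
#' @param kClose closing rate of the frayed toehold, 1/s. Only the
#'   open/close ratio is thermodynamically constrained
#'   (\eqn{k_{open}/k_{close} = e^{-\Delta G_{open}/RT}}); the absolute scale
#'   sets how often the toehold flaps and is kept at 1/s so exact stochastic
#'   trajectories stay at a desk-scale event count.
#' @param kBind bimolecular target association rate, 1/(M s).
#' @param kUnbind dissociation of a toehold-only bound target, 1/s.
#' @param dispPrefactor attempt frequency for the committed displacement
#'   step, 1/s; the rate is \code{dispPrefactor * exp(-barrier/RT)}.
#' @param targetConc effective target concentration, mol/L; fixes the
#'   reaction volume together with \code{nMiR}.
#' @param nTDN,nMiR initial TDN-site and target molecule counts (default
#'   1:10 TDN:target).
#' @return named list of parameters.
#' @export
cycleRates <- function(kCleave = 1e-3, kClose = 1, kBind = 1e6,
                       kUnbind = 0.1, dispPrefactor = 1e6,
                       targetConc = 2e-8, nTDN = 100L, nMiR = 1000L) {
    list(kCleave = kCleave, kClose = kClose, kBind = kBind,
         kUnbind = kUnbind, dispPrefactor = dispPrefactor,
         targetConc = targetConc, nTDN = as.integer(nTDN),
         nMiR = as.integer(nMiR))
}

#' Build the catalytic-cycle reaction network
#'
#' Species: \code{TDN_intact} (heteroduplex edge uncut),
#' \code{TDN_cleaved_closed} (cut, toehold re-closed / incumbent held),
#' \code{TDN_toehold_open}, \code{TDN_target_bound} (target on the toehold),
#' \code{TDN_target_duplex} (target fully exchanged onto the gapmer),
#' \code{miR_free}, \code{miR_cleaved}, \code{fragment13_free} (displacement
#' events; the incumbent fragment once released).
#'
#' Opening and closing are thermodynamically consistent with the landscape:
#' \eqn{k_{open} = k_{close} e^{-\Delta G_{open}/RT}}. The committed
#' displacement rate derives from the branch-migration barrier of the
#' displacement landscape. RNase H is implicit: cleavage is pseudo-first-order
#' on heteroduplex species. After target cleavage both fragments dissociate
#' instantly and the site regenerates to \code{TDN_toehold_open}.
#'
#' @param occupancy [OccupancyResult-class] of the fraying landscape (its
#'   \code{deltaGOpen} sets the open/close ratio).
#' @param displacement displacement [Landscape1D-class]; with
#'   \code{toeholdLen} it sets the displacement barrier. May be \code{NULL}
#'   only if \code{barrier} is given.
#' @param rates parameter list from [cycleRates()].
#' @param model [EnergyModel-class] (temperature).
#' @param toeholdLen toehold length used for the barrier lookup.
#' @param barrier optional explicit displacement barrier, kcal/mol
#'   (overrides \code{displacement}).
#' @return a [ReactionNetwork-class].
#' @export
buildCycleNetwork <- function(occupancy, displacement = NULL,
                              rates = cycleRates(), model = energyModel(),
                              toeholdLen = 7L, barrier = NULL) {
    if (is.null(barrier)) {
        if (is.null(displacement))
            stop("need a displacement landscape (or an explicit barrier)")
        barrier <- displacementBarrier(displacement, toeholdLen)
    }
    if (is.null(occupancy))
        stop("need the fraying-landscape occupancy (deltaGOpen)")
    rt <- .rt(model)
    kOpen <- rates$kClose * exp(-occupancy@deltaGOpen / rt)
    kDisp <- rates$dispPrefactor * exp(-barrier / rt)
    ## per-molecule-pair bimolecular constant: k / (NA * V), with the volume
    ## fixed by the effective target concentration
    NA_ <- 6.02214076e23
    volume <- rates$nMiR / (NA_ * rates$targetConc)
    cBind <- rates$kBind / (NA_ * volume)

    species <- c(TDN_intact = rates$nTDN, TDN_cleaved_closed = 0,
                 TDN_toehold_open = 0, TDN_target_bound = 0,
                 TDN_target_duplex = 0, miR_free = rates$nMiR,
                 miR_cleaved = 0, fragment13_free = 0)
    rxn <- function(name, reactants, products, rate)
        list(name = name, reactants = reactants, products = products, rate = rate)
    reactions <- list(
        rxn("cleave_tdn", c(TDN_intact = 1L), c(TDN_cleaved_closed = 1L),
            rates$kCleave),
        rxn("toehold_open", c(TDN_cleaved_closed = 1L), c(TDN_toehold_open = 1L),
            kOpen),
        rxn("toehold_close", c(TDN_toehold_open = 1L), c(TDN_cleaved_closed = 1L),
            rates$kClose),
        rxn("target_bind", c(TDN_toehold_open = 1L, miR_free = 1L),
            c(TDN_target_bound = 1L), cBind),
        rxn("target_unbind", c(TDN_target_bound = 1L),
            c(TDN_toehold_open = 1L, miR_free = 1L), rates$kUnbind),
        rxn("displace", c(TDN_target_bound = 1L),
            c(TDN_target_duplex = 1L, fragment13_free = 1L), kDisp),
        rxn("cleave_target", c(TDN_target_duplex = 1L),
            c(TDN_toehold_open = 1L, miR_cleaved = 1L), rates$kCleave))
    new("ReactionNetwork", species = species, reactions = reactions,
        conservations = list(
            tdn_sites = c("TDN_intact", "TDN_cleaved_closed",
                          "TDN_toehold_open", "TDN_target_bound",
                          "TDN_target_duplex"),
            targets = c("miR_free", "TDN_target_bound", "TDN_target_duplex",
                        "miR_cleaved")),
        params = c(rates, list(kOpen = kOpen, kDisp = kDisp,
                               barrier = barrier,
                               deltaGOpen = occupancy@deltaGOpen,
                               volume = volume, cBind = cBind)))
}

setMethod("show", "ReactionNetwork", function(object) {
    cat(sprintf("ReactionNetwork: %d species, %d reactions\n",
        length(object@species), length(object@reactions)))
    for (r in object@reactions)
        cat(sprintf("  %-14s %s -> %s  (rate %.4g)\n", r$name,
            paste(names(r$reactants), collapse = " + "),
            paste(names(r$products), collapse = " + "), r$rate))
    invisible(object)
})

## compile the network into index/stoichiometry form shared by SSA and ODE
.compileNetwork <- function(network) {
    sp <- names(network@species)
    nS <- length(sp); nR <- length(network@reactions)
    stoich <- matrix(0, nrow = nS, ncol = nR, dimnames = list(sp, NULL))
    i1 <- integer(nR); i2 <- integer(nR)  # i2 = nS + 1 means "none"
    k <- numeric(nR)
    for (j in seq_len(nR)) {
        r <- network@reactions[[j]]
        re <- r$reactants
        if (sum(re) > 2L || any(re > 2L))
            stop("at most bimolecular reactions are supported")
        ridx <- rep(match(names(re), sp), re)
        i1[j] <- ridx[1L]
        i2[j] <- if (length(ridx) > 1L) ridx[2L] else nS + 1L
        for (nm in names(re)) stoich[nm, j] <- stoich[nm, j] - re[[nm]]
        for (nm in names(r$products))
            stoich[nm, j] <- stoich[nm, j] + r$products[[nm]]
        k[j] <- r$rate
    }
    list(species = sp, stoich = stoich, i1 = i1, i2 = i2, k = k,
         names = vapply(network@reactions, `[[`, character(1), "name"))
}

#' Exact stochastic simulation of the cycle (Gillespie direct method)
#'
#' Statistically exact trajectory of the jump process defined by the
#' network's mass-action propensities, recorded on a uniform time grid.
#' Reproducible for a fixed seed.
#'
#' @param network a [ReactionNetwork-class].
#' @param tEnd simulated horizon, seconds.
#' @param seed RNG seed.
#' @param nRecord number of grid points recorded (including t = 0 and
#'   \code{tEnd}).
#' @return a [CycleTrajectory-class] (integer counts; per-reaction event
#'   totals in \code{eventCounts}).
#' @export
gillespieSimulate <- function(network, tEnd, seed = 1L, nRecord = 201L) {
    cn <- .compileNetwork(network)
    x <- c(as.numeric(network@species), 1)  # sentinel 1 for unimolecular
    nS <- length(cn$species)
    grid <- seq(0, tEnd, length.out = nRecord)
    out <- matrix(NA_real_, nrow = nRecord, ncol = nS,
                  dimnames = list(NULL, cn$species))
    events <- numeric(length(cn$k))
    set.seed(seed)
    t <- 0
    gi <- 1L
    out[1L, ] <- x[seq_len(nS)]
    gi <- 2L
    i1 <- cn$i1; i2 <- cn$i2; k <- cn$k; St <- cn$stoich
    repeat {
        a <- k * x[i1] * x[i2]
        a0 <- sum(a)
        if (a0 <= 0) break
        dt <- stats::rexp(1L, a0)
        tNew <- t + dt
        while (gi <= nRecord && grid[gi] <= tNew) {
            out[gi, ] <- x[seq_len(nS)]
            gi <- gi + 1L
        }
        if (tNew > tEnd) break
        t <- tNew
        j <- findInterval(stats::runif(1L) * a0, cumsum(a)) + 1L
        x[seq_len(nS)] <- x[seq_len(nS)] + St[, j]
        events[j] <- events[j] + 1
    }
    while (gi <= nRecord) { out[gi, ] <- x[seq_len(nS)]; gi <- gi + 1L }
    names(events) <- cn$names
    new("CycleTrajectory", times = grid, counts = out,
        seed = as.integer(seed), eventCounts = events)
}

#' Mean-field (ODE) trajectory of the cycle
#'
#' Deterministic mass-action integration of the same network with
#' \code{deSolve::lsoda}, on the same recording grid as the stochastic
#' simulator. Integrator failures are surfaced with the solver diagnostic.
#'
#' @inheritParams gillespieSimulate
#' @param atol,rtol integrator tolerances.
#' @return a [CycleTrajectory-class] (real-valued counts, seed \code{NA}).
#' @export
odeSimulate <- function(network, tEnd, nRecord = 201L,
                        atol = 1e-10, rtol = 1e-10) {
    cn <- .compileNetwork(network)
    nS <- length(cn$species)
    deriv <- function(t, y, parms) {
        xx <- c(y, 1)
        a <- cn$k * xx[cn$i1] * xx[cn$i2]
        list(as.numeric(cn$stoich %*% a))
    }
    times <- seq(0, tEnd, length.out = nRecord)
    sol <- deSolve::lsoda(y = as.numeric(network@species), times = times,
                          func = deriv, parms = NULL, atol = atol, rtol = rtol)
    diagn <- attr(sol, "istate")
    if (!is.null(diagn) && diagn[1L] < 0)
        stop(sprintf("ODE integration failed (lsoda istate %d)", diagn[1L]))
    counts <- unname(sol[, -1L, drop = FALSE])
    counts[counts < 0 & counts > -1e-9] <- 0  # clip integrator noise
    dimnames(counts) <- list(NULL, cn$species)
    new("CycleTrajectory", times = as.numeric(sol[, 1L]), counts = counts,
        seed = NA_integer_, eventCounts = numeric())
}

setMethod("show", "CycleTrajectory", function(object) {
    cat(sprintf("CycleTrajectory: %d time points, t = %g .. %g s%s\n",
        length(object@times), min(object@times), max(object@times),
        if (is.na(object@seed)) " (mean-field)" else sprintf(", seed %d", object@seed)))
    print(utils::tail(object@counts, 1L))
    invisible(object)
})

#' Conservation-law totals along a trajectory
#'
#' @param trajectory a [CycleTrajectory-class].
#' @param network the [ReactionNetwork-class] it was simulated from.
#' @return matrix of conserved totals (rows = recorded times).
#' @export
conservationTotals <- function(trajectory, network) {
    vapply(network@conservations, function(group)
        rowSums(trajectory@counts[, group, drop = FALSE]),
        numeric(length(trajectory@times)))
}

#' Flux analysis and rate-limiting step
#'
#' Tabulates per-reaction realized fluxes and flags the productive step where
#' the cycle stalls: for each forward step the time-averaged count of its
#' gating (source) species is divided by the cycle throughput (rate of
#' product formation), giving the waiting time per product attributable to
#' that step; the step with the largest waiting time is the limitation. With
#' the default parameters this is the toehold-opening step -- sites wait in
#' the closed state because the single-stranded toehold is rarely available.
#'
#' @param network a [ReactionNetwork-class].
#' @param trajectory a [CycleTrajectory-class] from [gillespieSimulate()]
#'   (event counts present) or [odeSimulate()].
#' @param product species whose production defines cycle throughput.
#' @param reverse names of non-productive (reverse) reactions excluded from
#'   the limitation flag.
#' @return data.frame with per-reaction \code{events}, \code{flux} (1/s),
#'   \code{source}, \code{meanSource}, \code{waitPerProduct} (s) and a
#'   logical \code{limiting} column flagging the rate-limiting step.
#' @export
rateLimitingReport <- function(network, trajectory, product = "miR_cleaved",
                               reverse = c("toehold_close", "target_unbind")) {
    cn <- .compileNetwork(network)
    tt <- trajectory@times
    totalT <- max(tt) - min(tt)
    ## time-averaged species counts (trapezoid)
    w <- diff(tt)
    avg <- vapply(seq_along(cn$species), function(i) {
        y <- trajectory@counts[, i]
        sum(0.5 * (y[-1L] + y[-length(y)]) * w) / totalT
    }, numeric(1))
    names(avg) <- cn$species

    if (length(trajectory@eventCounts)) {
        events <- trajectory@eventCounts
    } else {
        ## mean-field: integrate propensities over the grid
        events <- vapply(seq_along(cn$k), function(j) {
            a <- cn$k[j] * trajectory@counts[, cn$i1[j]] *
                (if (cn$i2[j] <= length(cn$species))
                     trajectory@counts[, cn$i2[j]] else 1)
            sum(0.5 * (a[-1L] + a[-length(a)]) * w)
        }, numeric(1))
        names(events) <- cn$names
    }
    flux <- events / totalT

    if (product %in% cn$species) {
        made <- trajectory@counts[nrow(trajectory@counts), product] -
                trajectory@counts[1L, product]
        throughput <- made / totalT
    } else throughput <- NA_real_

    src <- vapply(network@reactions, function(r) names(r$reactants)[1L],
                  character(1))
    wait <- avg[src] / throughput
    candidate <- !(cn$names %in% reverse) & flux > 0
    limiting <- rep(FALSE, length(cn$names))
    if (any(candidate) && is.finite(throughput) && throughput > 0) {
        limiting[which(candidate)[which.max(wait[candidate])]] <- TRUE
    } else if (length(cn$names) == 1L) {
        limiting[1L] <- TRUE
    }
    data.frame(reaction = cn$names, events = unname(events),
               flux = unname(flux), source = unname(src),
               meanSource = unname(avg[src]),
               waitPerProduct = unname(wait),
               limiting = limiting,
               stringsAsFactors = FALSE)
}
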