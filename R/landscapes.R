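## landscapes: discrete free-energy landscapes for toehold fraying and
## toehold-mediated strand displacement, with exact Boltzmann occupancies.

#' Construct a Landscape1D
#'
#' @param coordinate strictly increasing integer coordinate values.
#' @param dG free energies (kcal/mol); shifted so the reference state is 0.
#' @param referenceIndex which state defines the zero of free energy.
#' @param coordinateName description of the coordinate.
#' @param stateLabels optional per-state labels.
#' @return a [Landscape1D-class].
#' @export
landscape1D <- function(coordinate, dG, referenceIndex = length(dG),
                        coordinateName = "coordinate",
                        stateLabels = character()) {
    dG <- dG - dG[referenceIndex]
    new("Landscape1D", coordinateName = coordinateName,
        coordinate = as.integer(coordinate), dG = as.numeric(dG),
        referenceIndex = as.integer(referenceIndex),
        stateLabels = as.character(stateLabels))
}

#' @rdname Landscape1D-accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' Accessors for Landscape1D
#'
#' @param x a [Landscape1D-class].
#' @name Landscape1D-accessors
NULL

#' @rdname Landscape1D-accessors
#' @export
setMethod("nStates", "Landscape1D", function(x) length(x@coordinate))

#' @rdname Landscape1D-accessors
#' @export
stateCoordinates <- function(x) x@coordinate

#' @rdname Landscape1D-accessors
#' @export
stateEnergies <- function(x) x@dG

setMethod("show", "Landscape1D", function(object) {
    cat(sprintf("Landscape1D '%s': %d states, coordinate %d..%d\n",
        object@coordinateName, nStates(object),
        min(object@coordinate), max(object@coordinate)))
    cat(sprintf("  dG range: %.3f .. %.3f kcal/mol (reference state %d)\n",
        min(object@dG), max(object@dG), object@referenceIndex))
    invisible(object)
})

#' Two-state bound/open landscape
#'
#' The minimal landscape used for availability arithmetic: coordinate 0 is
#' the fully open toehold, coordinate 1 the bound state (reference, dG = 0).
#'
#' @param deltaGOpen free-energy difference of the open state relative to the
#'   bound state, kcal/mol.
#' @return a [Landscape1D-class].
#' @examples
#' toeholdAvailability(twoStateLandscape(3))
#' @export
twoStateLandscape <- function(deltaGOpen) {
    landscape1D(c(0L, 1L), c(deltaGOpen, 0), referenceIndex = 2L,
        coordinateName = "toehold_bound")
}

## ---------------------------------------------------------------------------
## Fraying (toehold exposure)
## ---------------------------------------------------------------------------

#' Fraying landscape of the retained duplex segment
#'
#' Zipper model of the segment left hybridized after the main RNase H cut:
#' state \eqn{s = 0..L} counts intact base pairs from the anchored end (the
#' end covalently continuous with the framework), so fraying proceeds from
#' the free 5' end created by the cut. \eqn{dG(s)} accumulates the
#' nearest-neighbor stack terms of the intact pairs; every bound state
#' (\eqn{s \ge 1}) additionally carries the tether initiation penalty, so the
#' fully open state \eqn{s = 0} pays none and the \eqn{0 \to 1} closing step
#' pays it all -- the entropic barrier to rebinding of the tethered segment.
#' The fully bound state \eqn{s = L} is the reference (dG = 0).
#'
#' @param design a [TDNDesign-class].
#' @param model an [EnergyModel-class].
#' @param cleavage optional precomputed [CleavageResult-class]; defaults to
#'   [predictMainCut()] on the design.
#' @return a [Landscape1D-class] with \eqn{L + 1} states (coordinate =
#'   intact base pairs).
#' @export
frayingLandscape <- function(design, model = energyModel(), cleavage = NULL) {
    if (is.null(cleavage))
        cleavage <- predictMainCut(design)
    edge <- gapmerEdge(design)
    cleaved <- design@strands[[cleavage@strandName]]
    partnerName <- if (edge@strandA == cleavage@strandName) edge@strandB else edge@strandA
    partner <- design@strands[[partnerName]]

    ## retained pairs: cleaved-strand positions 3' of the cut, still paired
    keep <- pairedPositions(edge, cleavage@strandName) > cleavage@mainCut
    sub <- new("DuplexMap", strandA = cleavage@strandName, strandB = partnerName,
        posA = pairedPositions(edge, cleavage@strandName)[keep],
        posB = pairedPositions(edge, partnerName)[keep])
    .frayingFromSegment(sub, cleaved, partner, model)
}

## anchored end = highest cleaved-strand position (3' side, covalently
## continuous with the framework); fraying removes pairs from the low end.
.frayingFromSegment <- function(duplex, cleaved, partner, model) {
    L <- nPairs(duplex)
    if (L < 2L)
        stop("retained segment too short: need at least 2 base pairs")
    st <- .segmentStacks(duplex, cleaved, partner, model)  # length L - 1
    ## E(s): tether penalty once bound, plus stacks among the s anchored pairs
    ## (the s highest positions; their stacks are the last s - 1 entries)
    E <- numeric(L + 1L)
    for (s in seq_len(L)) {
        E[s + 1L] <- model@tetherInitDG +
            if (s >= 2L) sum(st[seq.int(L - s + 1L, L - 1L)]) else 0
    }
    landscape1D(0:L, E, referenceIndex = L + 1L,
        coordinateName = "intact_bp")
}

## ---------------------------------------------------------------------------
## Occupancy
## ---------------------------------------------------------------------------

#' Equilibrium toehold availability from a landscape
#'
#' Boltzmann occupancies \eqn{p(s) \propto \exp(-dG(s)/RT)} over all landscape
#' states, the probability mass of the open state(s), and the free-energy
#' difference between the fully open and fully bound endpoints.
#'
#' By default only the completely open state (coordinate 0) counts as open;
#' \code{openMaxIntact} relaxes this to "at most k intact base pairs".
#'
#' @param landscape a [Landscape1D-class].
#' @param model an [EnergyModel-class] (supplies the temperature).
#' @param openMaxIntact count states with coordinate \code{<= openMaxIntact}
#'   as open (default 0).
#' @return an [OccupancyResult-class].
#' @examples
#' occ <- toeholdAvailability(twoStateLandscape(3))
#' occ@openFraction  # < 0.01 at 310.15 K
#' @export
toeholdAvailability <- function(landscape, model = energyModel(),
                                openMaxIntact = 0L) {
    rt <- .rt(model)
    dG <- landscape@dG
    w <- exp(-(dG - min(dG)) / rt)
    p <- w / sum(w)
    open <- which(landscape@coordinate <= openMaxIntact)
    names(p) <- landscape@coordinate
    new("OccupancyResult",
        probabilities = p,
        openFraction = sum(p[open]),
        deltaGOpen = dG[1L] - dG[length(dG)],
        openStates = as.integer(open))
}

#' Exact Boltzmann occupancy (enumeration oracle)
#'
#' Identical contract to [toeholdAvailability()]: the exact Boltzmann sum
#' over all states of a finite landscape. Shared implementation; kept as a
#' named entry point because it serves as the oracle against which the Monte
#' Carlo samplers are verified.
#'
#' @inheritParams toeholdAvailability
#' @return an [OccupancyResult-class].
#' @export
exactOccupancy <- function(landscape, model = energyModel(), openMaxIntact = 0L)
    toeholdAvailability(landscape, model, openMaxIntact)

setMethod("show", "OccupancyResult", function(object) {
    cat(sprintf("OccupancyResult: %d states, open fraction %.4g (%.3g%%)\n",
        length(object@probabilities), object@openFraction,
        100 * object@openFraction))
    cat(sprintf("  deltaG(open - bound) = %.3f kcal/mol\n", object@deltaGOpen))
    invisible(object)
})

## ---------------------------------------------------------------------------
## Calibration
## ---------------------------------------------------------------------------

#' Calibrate modification increments to a target opening free energy
#'
#' Rescales the sugar/backbone modification increments by a single factor so
#' that the fraying landscape's bound-to-open free-energy difference matches
#' a supplied value (for instance a landscape difference obtained from
#' coarse-grained simulation). The opening free energy is affine in the
#' scaling factor, so the solution is exact. Calibration is always explicit:
#' the returned model carries the factor as attribute
#' \code{"calibrationFactor"}.
#'
#' @param design a [TDNDesign-class].
#' @param model the starting [EnergyModel-class].
#' @param targetDeltaGOpen desired opening free energy, kcal/mol.
#' @return the calibrated [EnergyModel-class].
#' @export
calibrateToeholdModel <- function(design, model = energyModel(),
                                  targetDeltaGOpen) {
    dOpen <- function(f) {
        m <- model
        m@modIncrements <- model@modIncrements * f
        toeholdAvailability(frayingLandscape(design, m), m)@deltaGOpen
    }
    d0 <- dOpen(0); d1 <- dOpen(1)
    if (abs(d1 - d0) < 1e-9)
        stop("retained segment carries no modified nucleotides; cannot calibrate")
    f <- (targetDeltaGOpen - d0) / (d1 - d0)
    out <- model
    out@modIncrements <- model@modIncrements * f
    attr(out, "calibrationFactor") <- f
    out
}

## ---------------------------------------------------------------------------
## Displacement
## ---------------------------------------------------------------------------

#' Toehold-mediated strand displacement landscape (from stack energies)
#'
#' Progress coordinate: invader base pairs formed, \eqn{m = 0} (toehold fully
#' open, incumbent fully bound) to \eqn{m = T + I} (incumbent fully
#' displaced). Toehold zippering (\eqn{m \le T}) gains invader stack terms;
#' each branch-migration step (\eqn{m > T}) exchanges one incumbent pair for
#' one invader pair and passes over an intermediate plateau state of height
#' \code{bmPlateauDG} above the preceding state. The incumbent keeps its
#' duplex initiation penalty while at least one of its pairs remains; losing
#' the last pair credits its dissociation entropy once.
#'
#' States are laid out on a doubled coordinate so the plateau intermediates
#' are genuine landscape states: coordinate \eqn{2m} for pair states
#' (label \code{"bp"}), \eqn{2m + 1} for the plateau between \eqn{m} and
#' \eqn{m + 1} (label \code{"plateau"}).
#'
#' @param invaderStacks stack energies of successive invader steps
#'   (length \eqn{T + I - 1}).
#' @param incumbentStacks stack energies within the incumbent duplex, ordered
#'   from the toehold-proximal end (length \eqn{I - 1}).
#' @param toeholdLen toehold length \eqn{T} (bp).
#' @param model an [EnergyModel-class].
#' @param invaderInitDG,incumbentInitDG initiation penalties; default the
#'   model's \code{initDG}.
#' @return a [Landscape1D-class]; reference state is \eqn{m = 0}.
#' @seealso [displacementLandscape()] for the design-level wrapper.
#' @export
displacementLandscapeFromStacks <- function(invaderStacks, incumbentStacks,
        toeholdLen, model = energyModel(),
        invaderInitDG = model@initDG, incumbentInitDG = model@initDG) {
    TT <- as.integer(toeholdLen)
    II <- length(incumbentStacks) + 1L
    if (TT < 1L || II < 1L)
        stop("toehold and incumbent must each be at least 1 nt")
    M <- TT + II
    if (length(invaderStacks) != M - 1L)
        stop("invaderStacks must have length toeholdLen + incumbentLen - 1")

    Einv <- c(0, invaderInitDG + cumsum(c(0, invaderStacks)))  # E_inv(m), m=0..M
    ## incumbent energy with r pairs remaining (the r distal ones)
    Einc <- numeric(II + 1L)  # index r+1 -> r pairs
    for (r in seq_len(II))
        Einc[r + 1L] <- incumbentInitDG +
            if (r >= 2L) sum(incumbentStacks[seq.int(II - r + 1L, II - 1L)]) else 0
    dG <- vapply(0:M, function(m) {
        r <- II - max(0L, m - TT)
        Einv[m + 1L] + (Einc[r + 1L] - Einc[II + 1L])
    }, numeric(1))

    coord <- 2L * (0:M)
    labels <- rep("bp", M + 1L)
    ## plateau intermediates in the branch-migration region
    pm <- seq.int(TT, M - 1L)
    coordP <- 2L * pm + 1L
    dGP <- dG[pm + 1L] + model@bmPlateauDG
    o <- order(c(coord, coordP))
    landscape1D(c(coord, coordP)[o], c(dG, dGP)[o],
        referenceIndex = 1L,
        coordinateName = "invader_halfsteps",
        stateLabels = c(labels, rep("plateau", length(pm)))[o])
}

#' Displacement landscape for a design and its target
#'
#' Builds the strand-displacement landscape of the catalytic step: the 22-nt
#' RNA target (invader) binds the toehold exposed by fraying of the retained
#' segment and displaces the incumbent cleavage fragment from the gapmer.
#' Stack energies on both sides are computed from the actual chemistries
#' (hybrid steps, LNA/2'-O-Me increments, PS linkages).
#'
#' @param design a [TDNDesign-class].
#' @param target the invading strand from [generateTarget()].
#' @param model an [EnergyModel-class].
#' @param cleavage optional precomputed [CleavageResult-class].
#' @return a [Landscape1D-class].
#' @export
displacementLandscape <- function(design, target, model = energyModel(),
                                  cleavage = NULL) {
    if (is.null(cleavage))
        cleavage <- predictMainCut(design)
    gap <- extractGapmer(design)
    G <- strandLength(gap)
    toeholdLen <- cleavage@retainedSegment
    incLen <- cleavage@fivePrimeFragment

    ## invader duplex: target paired over the full gapmer, declared register
    tdup <- pairTargetToGapmer(target, gap)
    ## order stacks by invader pairing progress = ascending gapmer position
    invDup <- new("DuplexMap", strandA = gap@name, strandB = strandName(target),
        posA = tdup@posB, posB = tdup@posA)
    invaderStacks <- .segmentStacks(invDup, gap, target, model)

    ## incumbent duplex: the 5' cleavage fragment on the distal gapmer part
    rna <- design@strands[[cleavage@strandName]]
    frag <- modifiedStrand(paste0(cleavage@strandName, "_frag"),
        bases(rna)[seq_len(incLen)], sugars(rna)[seq_len(incLen)],
        linkages(rna)[seq_len(incLen - 1L)])
    incDup <- new("DuplexMap", strandA = gap@name, strandB = frag@name,
        posA = seq.int(toeholdLen + 1L, G),
        posB = seq.int(incLen, 1L))
    incumbentStacks <- .segmentStacks(incDup, gap, frag, model)

    displacementLandscapeFromStacks(invaderStacks, incumbentStacks,
        toeholdLen, model)
}

#' Committed-step barrier of a displacement landscape
#'
#' Maximum free energy along the branch-migration region relative to the
#' toehold-bound state, used to derive the displacement rate constant.
#'
#' @param landscape a displacement [Landscape1D-class].
#' @param toeholdLen toehold length (bp).
#' @return kcal/mol (non-negative).
#' @export
displacementBarrier <- function(landscape, toeholdLen) {
    co <- landscape@coordinate
    atToehold <- landscape@dG[match(2L * as.integer(toeholdLen), co)]
    if (is.na(atToehold))
        stop("landscape has no state at the toehold-bound coordinate")
    max(0, max(landscape@dG[co >= 2L * toeholdLen]) - atToehold)
}

## ---------------------------------------------------------------------------
## Report
## ---------------------------------------------------------------------------

#' Tabulate a landscape as coordinate / dG
#'
#' @param landscape a [Landscape1D-class].
#' @param file optional path; when given, written as TSV (byte-stable for
#'   fixed input).
#' @return data.frame with columns \code{coordinate}, \code{dG} (and
#'   \code{label} when the landscape carries state labels).
#' @export
deltaGProfileReport <- function(landscape, file = NULL) {
    out <- data.frame(coordinate = landscape@coordinate,
                      dG = landscape@dG)
    if (length(landscape@stateLabels))
        out$label <- landscape@stateLabels
    if (!is.null(file)) {
        fmt <- out
        fmt$dG <- sprintf("%.6f", fmt$dG)
        utils::write.table(fmt, file = file, sep = "\t", quote = FALSE,
            row.names = FALSE)
    }
    out
}
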