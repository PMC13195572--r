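#' @import methods
NULL

## ---------------------------------------------------------------------------
## ModifiedStrand
## ---------------------------------------------------------------------------

#' Chemically annotated oligonucleotide strand
#'
#' An ordered run of nucleotides (index 1 is the 5' end), each carrying a
#' base (A, C, G, T, U), a sugar chemistry (\code{DNA}, \code{RNA},
#' \code{LNA} for locked nucleic acid, \code{OME} for 2'-O-methyl) and the
#' backbone linkage on its 3' side (\code{PO} phosphodiester or \code{PS}
#' phosphorothioate; absent for the 3'-terminal nucleotide). Named loci mark
#' functional regions such as the gapmer or the RNA block.
#'
#' @slot name strand identifier.
#' @slot base character vector of single-letter bases, 5' to 3'.
#' @slot sugar character vector of sugar chemistries, same length.
#' @slot linkage character vector of 3'-side linkages, length \code{n - 1}.
#' @slot loci named list of closed 1-based integer ranges \code{c(start, end)};
#'   ranges must be disjoint and within the strand.
#'
#' @seealso [modifiedStrand()], [buildGapmerPattern()]
#' @export
setClass("ModifiedStrand",
    representation(
        name = "character",
        base = "character",
        sugar = "character",
        linkage = "character",
        loci = "list"
    ))

setValidity("ModifiedStrand", function(object) {
    n <- length(object@base)
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (n < 1L)
        msg <- c(msg, "strand must contain at least one nucleotide")
    if (!all(object@base %in% .BASES))
        msg <- c(msg, sprintf("invalid base(s): %s",
                 paste(setdiff(unique(object@base), .BASES), collapse = ", ")))
    if (length(object@sugar) != n)
        msg <- c(msg, "'sugar' must have one entry per nucleotide")
    if (!all(object@sugar %in% .SUGARS))
        msg <- c(msg, sprintf("invalid sugar(s): %s",
                 paste(setdiff(unique(object@sugar), .SUGARS), collapse = ", ")))
    if (any(object@base == "U" & object@sugar %in% c("DNA", "LNA")))
        msg <- c(msg, "U is not allowed on DNA or LNA sugars")
    if (length(object@linkage) != max(n - 1L, 0L))
        msg <- c(msg, "'linkage' must have length one less than the strand")
    if (!all(object@linkage %in% .LINKS))
        msg <- c(msg, "linkages must be 'PO' or 'PS'")
    if (length(object@loci)) {
        if (is.null(names(object@loci)) || any(!nzchar(names(object@loci))))
            msg <- c(msg, "all loci must be named")
        covered <- integer()
        for (nm in names(object@loci)) {
            rg <- object@loci[[nm]]
            if (length(rg) != 2L || rg[1L] > rg[2L] || rg[1L] < 1L || rg[2L] > n)
                msg <- c(msg, sprintf("locus '%s' is not a valid range within the strand", nm))
            else {
                idx <- seq.int(rg[1L], rg[2L])
                if (any(idx %in% covered))
                    msg <- c(msg, sprintf("locus '%s' overlaps another locus", nm))
                covered <- c(covered, idx)
            }
        }
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DuplexMap
## ---------------------------------------------------------------------------

#' Base-pair map between two strands
#'
#' Records Watson-Crick base pairs between two strands as parallel position
#' vectors. Within a contiguous segment the pairing is antiparallel: positions
#' on strand A increase while the paired positions on strand B decrease.
#' Complementarity is enforced at construction time by [pairStrands()].
#'
#' @slot strandA,strandB identifiers of the two strands.
#' @slot posA,posB 1-based paired positions (equal length, aligned).
#'
#' @seealso [pairStrands()], [duplexSegments()]
#' @export
setClass("DuplexMap",
    representation(
        strandA = "character",
        strandB = "character",
        posA = "integer",
        posB = "integer"
    ))

setValidity("DuplexMap", function(object) {
    msg <- character()
    if (length(object@posA) != length(object@posB))
        msg <- c(msg, "posA and posB must be aligned")
    if (anyDuplicated(object@posA) || anyDuplicated(object@posB))
        msg <- c(msg, "each position may appear in at most one pair")
    if (length(object@posA) && (any(object@posA < 1L) || any(object@posB < 1L)))
        msg <- c(msg, "positions are 1-based and must be positive")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## TDNDesign
## ---------------------------------------------------------------------------

#' Tetrahedral DNA nanostructure design
#'
#' The in-silico nanostructure: four strands, six duplex edges (one per pair
#' of strands, each strand traversing three edges), unpaired hinge nucleotides
#' at the vertices, and the location of the anti-miRNA gapmer. One edge is the
#' heteroduplex edge: the gapmer locus on one strand pairs the RNA block (and
#' its DNA flank) on the partner strand.
#'
#' @slot strands named list of four [ModifiedStrand-class] objects.
#' @slot edges named list of six [DuplexMap-class] segments.
#' @slot hinges named list (per strand) of unpaired vertex positions.
#' @slot gapmerEdge name of the edge carrying the gapmer.
#' @slot gapmerStrand,rnaStrand names of the gapmer-bearing and RNA-containing
#'   strands.
#'
#' @seealso [generateDesign()], [validateDesign()]
#' @export
setClass("TDNDesign",
    representation(
        strands = "list",
        edges = "list",
        hinges = "list",
        gapmerEdge = "character",
        gapmerStrand = "character",
        rnaStrand = "character"
    ))

setValidity("TDNDesign", function(object) {
    msg <- character()
    if (length(object@strands) != 4L)
        msg <- c(msg, "a tetrahedron design needs exactly 4 strands")
    if (length(object@edges) != 6L)
        msg <- c(msg, "a tetrahedron design needs exactly 6 edges")
    if (!all(vapply(object@strands, is, logical(1), "ModifiedStrand")))
        msg <- c(msg, "all strands must be ModifiedStrand objects")
    if (!all(vapply(object@edges, is, logical(1), "DuplexMap")))
        msg <- c(msg, "all edges must be DuplexMap objects")
    if (!(object@gapmerEdge %in% names(object@edges)))
        msg <- c(msg, "gapmerEdge must name one of the edges")
    if (!(object@gapmerStrand %in% names(object@strands)) ||
        !(object@rnaStrand %in% names(object@strands)))
        msg <- c(msg, "gapmerStrand and rnaStrand must name design strands")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GapmerScheme
## ---------------------------------------------------------------------------

#' Gapmer chemistry scheme
#'
#' Describes a gapmer modification pattern: a wing of modified sugars applied
#' symmetrically from each end (e.g. four LNA then two 2'-O-Me), an unmodified
#' central DNA block, and phosphorothioate linkages at the ends. A wing
#' covering the whole strand (uniform chemistry) expresses steric-blocker
#' controls such as a fully 2'-O-methylated oligonucleotide.
#'
#' @slot totalLength strand length in nt.
#' @slot wing sugar pattern applied 5' to 3' from each end (mirrored at the
#'   3' end); may be empty for an all-DNA strand.
#' @slot psPerEnd number of PS linkages at each end.
#' @slot fullyPS if \code{TRUE}, every linkage is PS.
#'
#' @seealso [gapmerScheme()], [buildGapmerPattern()]
#' @export
setClass("GapmerScheme",
    representation(
        totalLength = "integer",
        wing = "character",
        psPerEnd = "integer",
        fullyPS = "logical"
    ))

setValidity("GapmerScheme", function(object) {
    msg <- character()
    n <- object@totalLength
    w <- length(object@wing)
    if (length(n) != 1L || is.na(n) || n < 1L)
        msg <- c(msg, "totalLength must be a positive integer")
    if (w && !all(object@wing %in% .SUGARS))
        msg <- c(msg, "wing sugars must be DNA, RNA, LNA or OME")
    if (w > n)
        msg <- c(msg, "wing cannot be longer than the strand")
    if (2L * w > n && !(w == n && all(object@wing == rev(object@wing)))) {
        ## a full-length mirror-symmetric wing (uniform chemistry, e.g. the
        ## all-2'-OMe steric-blocker control) is the only overlap allowed
        msg <- c(msg, "invalid scheme: wing longer than half the strand")
    }
    if (object@psPerEnd < 0L || object@psPerEnd > max(n - 1L, 0L))
        msg <- c(msg, "psPerEnd out of range")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CleavageResult
## ---------------------------------------------------------------------------

#' Outcome of RNase H cleavage-site prediction
#'
#' Cut sites are reported as linkage indices on the cleaved strand: linkage
#' \code{i} sits between nucleotides \code{i} and \code{i + 1}, and a cut at
#' linkage \code{i} releases an \code{i}-nt 5' fragment.
#'
#' @slot strandName cleaved strand identifier.
#' @slot strandLength full length of the cleaved strand (nt).
#' @slot competentLinkages linkage indices satisfying the competence rule.
#' @slot mainCut the designated main cut (3'-most competent linkage).
#' @slot fivePrimeFragment length of the released 5' fragment (nt).
#' @slot fivePrimeChemistry sugar composition summary of the 5' fragment.
#' @slot retainedSegment length (nt) of the region 3' of the cut that is still
#'   hybridized and covalently continuous with the framework.
#' @slot postCleavageLength length (nt) of the covalent remainder.
#' @slot pairedRegion range \code{c(start, end)} of the duplexed region on the
#'   cleaved strand.
#'
#' @seealso [predictMainCut()], [enumerateCompetentLinkages()]
#' @export
setClass("CleavageResult",
    representation(
        strandName = "character",
        strandLength = "integer",
        competentLinkages = "integer",
        mainCut = "integer",
        fivePrimeFragment = "integer",
        fivePrimeChemistry = "character",
        retainedSegment = "integer",
        postCleavageLength = "integer",
        pairedRegion = "integer"
    ))

setValidity("CleavageResult", function(object) {
    msg <- character()
    if (!(object@mainCut %in% object@competentLinkages))
        msg <- c(msg, "mainCut must be one of the competent linkages")
    if (object@fivePrimeFragment + object@postCleavageLength != object@strandLength)
        msg <- c(msg, "5' fragment and remainder must sum to the strand length")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Landscape1D / OccupancyResult
## ---------------------------------------------------------------------------

#' Discrete one-dimensional free-energy landscape
#'
#' Ordered states along an integer reaction coordinate with free energies in
#' kcal/mol relative to a designated reference state (whose dG is exactly 0).
#'
#' @slot coordinateName what the coordinate counts (e.g. intact base pairs).
#' @slot coordinate strictly increasing integer coordinate values.
#' @slot dG free energies, kcal/mol, relative to the reference state.
#' @slot referenceIndex index (into the state vectors) of the reference state.
#' @slot stateLabels optional per-state labels (e.g. \code{"bp"} vs
#'   \code{"plateau"} for displacement landscapes); empty or one per state.
#'
#' @seealso [frayingLandscape()], [displacementLandscape()], [twoStateLandscape()]
#' @export
setClass("Landscape1D",
    representation(
        coordinateName = "character",
        coordinate = "integer",
        dG = "numeric",
        referenceIndex = "integer",
        stateLabels = "character"
    ))

setValidity("Landscape1D", function(object) {
    msg <- character()
    n <- length(object@coordinate)
    if (length(object@dG) != n)
        msg <- c(msg, "dG must have one value per state")
    if (any(!is.finite(object@dG)))
        msg <- c(msg, "all free energies must be finite")
    if (n > 1L && any(diff(object@coordinate) <= 0L))
        msg <- c(msg, "coordinate values must be strictly increasing")
    if (object@referenceIndex < 1L || object@referenceIndex > n)
        msg <- c(msg, "referenceIndex out of range")
    else if (abs(object@dG[object@referenceIndex]) > .Machine$double.eps * 4)
        msg <- c(msg, "the reference state must have dG exactly 0")
    if (length(object@stateLabels) && length(object@stateLabels) != n)
        msg <- c(msg, "stateLabels must be empty or one per state")
    if (length(msg)) msg else TRUE
})

#' Equilibrium occupancy of a discrete landscape
#'
#' @slot probabilities Boltzmann probability of each state (sums to 1).
#' @slot openFraction probability mass of the designated open state(s).
#' @slot deltaGOpen free-energy difference (kcal/mol) between the fully open
#'   and fully bound landscape endpoints.
#' @slot openStates indices of the states counted as open.
#'
#' @seealso [toeholdAvailability()], [exactOccupancy()]
#' @export
setClass("OccupancyResult",
    representation(
        probabilities = "numeric",
        openFraction = "numeric",
        deltaGOpen = "numeric",
        openStates = "integer"
    ))

setValidity("OccupancyResult", function(object) {
    msg <- character()
    if (any(object@probabilities < 0))
        msg <- c(msg, "probabilities must be non-negative")
    if (abs(sum(object@probabilities) - 1) > 1e-12)
        msg <- c(msg, "probabilities must sum to 1 within 1e-12")
    if (object@openFraction < 0 || object@openFraction > 1)
        msg <- c(msg, "openFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## EnergyModel
## ---------------------------------------------------------------------------

#' Nearest-neighbor energy model with modification increments
#'
#' Holds the thermodynamic parameter set: nearest-neighbor stack tables
#' (enthalpy kcal/mol, entropy cal/(mol K)) for DNA:DNA and RNA:DNA hybrid
#' steps, per-base-pair free-energy increments for sugar modifications and PS
#' linkages, duplex initiation penalties, the entropic cost of closing the
#' first base pair of a tethered segment, the branch-migration plateau height,
#' temperature and monovalent salt.
#'
#' @slot nnDNAdH,nnDNAdS named 16-entry DNA:DNA stack tables (key: top-strand
#'   dinucleotide 5' to 3').
#' @slot nnHybDH,nnHybDS named 16-entry RNA:DNA hybrid stack tables (key: the
#'   RNA-strand dinucleotide 5' to 3', U alphabet).
#' @slot modIncrements named ddG values, kcal/mol: \code{LNA} and \code{OME}
#'   per modified-nucleotide-containing pair, \code{PS} per linkage.
#' @slot initDG duplex initiation penalty, kcal/mol.
#' @slot tetherInitDG entropic penalty for closing the first base pair of a
#'   tethered (covalently held) segment, kcal/mol.
#' @slot bmPlateauDG branch-migration intermediate plateau height, kcal/mol.
#' @slot temperature kelvin.
#' @slot saltMM monovalent-equivalent salt, mM (tables are referenced to 1 M).
#'
#' @seealso [energyModel()], [stackDG()], [duplexDG()]
#' @export
setClass("EnergyModel",
    representation(
        nnDNAdH = "numeric",
        nnDNAdS = "numeric",
        nnHybDH = "numeric",
        nnHybDS = "numeric",
        modIncrements = "numeric",
        initDG = "numeric",
        tetherInitDG = "numeric",
        bmPlateauDG = "numeric",
        temperature = "numeric",
        saltMM = "numeric"
    ))

setValidity("EnergyModel", function(object) {
    msg <- character()
    if (object@temperature <= 0)
        msg <- c(msg, "temperature must be positive (kelvin)")
    if (object@saltMM <= 0)
        msg <- c(msg, "saltMM must be positive")
    keysDNA <- outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)
    keysHyb <- outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0)
    if (!all(keysDNA %in% names(object@nnDNAdH)) ||
        !all(keysDNA %in% names(object@nnDNAdS)))
        msg <- c(msg, "DNA:DNA table must cover all 16 dinucleotides")
    if (!all(keysHyb %in% names(object@nnHybDH)) ||
        !all(keysHyb %in% names(object@nnHybDS)))
        msg <- c(msg, "hybrid table must cover all 16 dinucleotides")
    if (!all(c("LNA", "OME", "PS") %in% names(object@modIncrements)))
        msg <- c(msg, "modIncrements must name LNA, OME and PS")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Sampling classes
## ---------------------------------------------------------------------------

#' Umbrella-sampling window
#'
#' Per-state bias energies (kcal/mol) added to the landscape during biased
#' sampling, plus a label used in reports.
#'
#' @slot bias numeric bias energy per landscape state.
#' @slot label window label.
#' @seealso [harmonicWindows()], [umbrellaSample()]
#' @export
setClass("UmbrellaWindow",
    representation(bias = "numeric", label = "character"))

setValidity("UmbrellaWindow", function(object) {
    if (any(!is.finite(object@bias))) "bias energies must be finite" else TRUE
})

#' Histogram from a Metropolis Monte Carlo run
#'
#' @slot counts visits per state (named by coordinate value); sums to
#'   \code{nSteps}.
#' @slot nSteps number of recorded Monte Carlo steps.
#' @slot seed RNG seed used.
#' @slot label window label ("unbiased" for plain sampling).
#' @slot transitionsUp,transitionsDown accepted transition counts between
#'   adjacent states (length: number of states minus one).
#' @seealso [metropolisSample()], [reweight()]
#' @export
setClass("SampledHistogram",
    representation(
        counts = "integer",
        nSteps = "numeric",
        seed = "integer",
        label = "character",
        transitionsUp = "integer",
        transitionsDown = "integer"
    ))

setValidity("SampledHistogram", function(object) {
    msg <- character()
    if (any(object@counts < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (sum(as.numeric(object@counts)) != object@nSteps)
        msg <- c(msg, "counts must sum to nSteps")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Kinetics classes
## ---------------------------------------------------------------------------

#' Stochastic reaction network for the catalytic cycle
#'
#' Species are molecule counts; reactions carry per-molecule (propensity)
#' rate constants, bimolecular rates having been converted with the effective
#' reaction volume. Conservation laws are stored as species groups whose
#' summed counts are invariant.
#'
#' @slot species named initial molecule counts.
#' @slot reactions list; each element has \code{name}, \code{reactants} and
#'   \code{products} (named stoichiometry), and \code{rate} (per-molecule,
#'   1/s, or per molecule pair and second for bimolecular steps).
#' @slot conservations named list of species groups with invariant totals.
#' @slot params list of the physical parameters the network was built from.
#' @seealso [buildCycleNetwork()], [gillespieSimulate()], [odeSimulate()]
#' @export
setClass("ReactionNetwork",
    representation(
        species = "numeric",
        reactions = "list",
        conservations = "list",
        params = "list"
    ))

setValidity("ReactionNetwork", function(object) {
    msg <- character()
    if (is.null(names(object@species)) || any(!nzchar(names(object@species))))
        msg <- c(msg, "species must be named")
    if (any(object@species < 0))
        msg <- c(msg, "species counts must be non-negative")
    for (r in object@reactions) {
        if (!all(c("name", "reactants", "products", "rate") %in% names(r))) {
            msg <- c(msg, "each reaction needs name, reactants, products, rate")
            break
        }
        if (!all(names(r$reactants) %in% names(object@species)) ||
            !all(names(r$products) %in% names(object@species))) {
            msg <- c(msg, sprintf("reaction '%s' references unknown species", r$name))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Simulated trajectory of the catalytic cycle
#'
#' Time series of species counts from the stochastic simulator (integer
#' counts) or the mean-field ODE integrator (real-valued), recorded on a
#' fixed time grid.
#'
#' @slot times seconds.
#' @slot counts matrix, one row per recorded time, one column per species.
#' @slot seed RNG seed (NA for deterministic ODE trajectories).
#' @slot eventCounts realized number of firings per reaction (stochastic runs).
#' @seealso [gillespieSimulate()], [odeSimulate()], [rateLimitingReport()]
#' @export
setClass("CycleTrajectory",
    representation(
        times = "numeric",
        counts = "matrix",
        seed = "integer",
        eventCounts = "numeric"
    ))

setValidity("CycleTrajectory", function(object) {
    msg <- character()
    if (nrow(object@counts) != length(object@times))
        msg <- c(msg, "counts must have one row per recorded time")
    if (any(object@counts < 0))
        msg <- c(msg, "species counts must be non-negative")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SizeDistribution
## ---------------------------------------------------------------------------

#' Particle size distribution (DLS)
#'
#' @slot diameter bin diameters, nm.
#' @slot weight bin weights (non-negative, sum to 1).
#' @slot weighting either \code{"intensity"} or \code{"number"}.
#' @seealso [intensityToNumber()]
#' @export
setClass("SizeDistribution",
    representation(
        diameter = "numeric",
        weight = "numeric",
        weighting = "character"
    ))

setValidity("SizeDistribution", function(object) {
    msg <- character()
    if (length(object@diameter) != length(object@weight))
        msg <- c(msg, "diameter and weight must be aligned")
    if (any(object@diameter <= 0))
        msg <- c(msg, "diameters must be positive")
    if (any(object@weight < 0))
        msg <- c(msg, "weights must be non-negative")
    if (abs(sum(object@weight) - 1) > 1e-9)
        msg <- c(msg, "weights must sum to 1 within 1e-9")
    if (!object@weighting %in% c("intensity", "number"))
        msg <- c(msg, "weighting must be 'intensity' or 'number'")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GeneratorSpec
## ---------------------------------------------------------------------------

#' Specification for the synthetic design generator
#'
#' Defines the layout emulated by [generateDesign()]: base pairs per edge,
#' unpaired hinge nucleotides per vertex passage, the gapmer chemistry scheme,
#' the RNA block placed on the partner strand, the unmodified DNA flank 3' of
#' the RNA block, per-strand GC bounds and the maximum tolerated unintended
#' complementary run.
#'
#' @slot edgeBP base pairs per edge.
#' @slot hingeNT unpaired nucleotides per internal vertex passage.
#' @slot scheme a [GapmerScheme-class].
#' @slot rnaStart,rnaLength RNA block placement on the RNA-containing strand.
#' @slot flankDNA unmodified DNA nucleotides 3' of the RNA block.
#' @slot gcBounds allowed per-strand GC fraction range.
#' @slot crosstalkK maximum allowed unintended complementary run (exclusive;
#'   runs of this length or longer force a retry).
#' @slot maxTries bounded number of generation attempts.
#' @seealso [generatorSpec()], [generateDesign()]
#' @export
setClass("GeneratorSpec",
    representation(
        edgeBP = "integer",
        hingeNT = "integer",
        scheme = "GapmerScheme",
        rnaStart = "integer",
        rnaLength = "integer",
        flankDNA = "integer",
        gcBounds = "numeric",
        crosstalkK = "integer",
        maxTries = "integer"
    ))

setValidity("GeneratorSpec", function(object) {
    msg <- character()
    if (object@edgeBP < 4L)
        msg <- c(msg, "edgeBP must be at least 4")
    if (object@hingeNT < 0L)
        msg <- c(msg, "hingeNT must be non-negative")
    if (object@rnaStart < 1L || object@rnaLength < 1L)
        msg <- c(msg, "RNA block placement must be positive")
    if (object@rnaStart + object@rnaLength - 1L > object@edgeBP)
        msg <- c(msg, "RNA block must lie inside the gapmer-paired region")
    if (length(object@gcBounds) != 2L || object@gcBounds[1L] > object@gcBounds[2L])
        msg <- c(msg, "gcBounds must be an increasing range")
    if (object@crosstalkK < 4L)
        msg <- c(msg, "crosstalkK must be at least 4")
    if (length(msg)) msg else TRUE
})
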