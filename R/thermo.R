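## nn_thermo: hybridization free energies of chemically annotated duplexes.

#' Construct a nearest-neighbor energy model
#'
#' Bundles the stack tables with the tunable knobs of the package: the
#' per-pair free-energy increments of the sugar modifications, the duplex
#' initiation penalty, the entropic penalty for closing the first base pair
#' of a tethered segment, the branch-migration plateau height, temperature
#' and salt. Stack free energies are computed as
#' \eqn{\Delta G(T) = \Delta H - T \Delta S / 1000} plus a uniform per-stack
#' entropic salt term \eqn{-0.368 T \ln([\mathrm{Na}^+]) / 1000} kcal/mol
#' (zero at the 1 M table reference).
#'
#' Defaults: LNA \eqn{-1.0} kcal/mol per LNA-containing pair, 2'-O-Me
#' \eqn{-0.2}, PS \eqn{+0.1} per linkage, matching the affinity ranking
#' LNA > 2'-O-Me > unmodified; 310.15 K; 1 M salt. These are order-of-magnitude
#' defaults meant to be calibrated when a measured or simulated landscape
#' difference is available (see [calibrateToeholdModel()]).
#'
#' @param modIncrements named numeric: \code{LNA}, \code{OME} (per pair
#'   containing the modified nucleotide, split half-half over its two
#'   adjacent stacks) and \code{PS} (per linkage, at the stack spanning it).
#' @param initDG duplex initiation penalty, kcal/mol.
#' @param tetherInitDG entropic cost of the first base pair of a tethered
#'   segment, kcal/mol.
#' @param bmPlateauDG branch-migration plateau height, kcal/mol.
#' @param temperature kelvin.
#' @param saltMM monovalent salt, mM.
#' @return an [EnergyModel-class].
#' @examples
#' m <- energyModel()
#' stackDGValue("AC", "DNA", m)
#' @export
energyModel <- function(modIncrements = c(LNA = -1.0, OME = -0.2, PS = 0.1),
                        initDG = 1.96, tetherInitDG = 2.0, bmPlateauDG = 2.0,
                        temperature = 310.15, saltMM = 1000) {
    new("EnergyModel",
        nnDNAdH = .NN_DNA_DH, nnDNAdS = .NN_DNA_DS,
        nnHybDH = .NN_HYB_DH, nnHybDS = .NN_HYB_DS,
        modIncrements = modIncrements, initDG = initDG,
        tetherInitDG = tetherInitDG, bmPlateauDG = bmPlateauDG,
        temperature = temperature, saltMM = saltMM)
}

setMethod("show", "EnergyModel", function(object) {
    cat(sprintf("EnergyModel: T = %.2f K, salt = %g mM\n",
        object@temperature, object@saltMM))
    cat(sprintf("  increments (kcal/mol): LNA %+.2f, OME %+.2f, PS %+.2f\n",
        object@modIncrements["LNA"], object@modIncrements["OME"],
        object@modIncrements["PS"]))
    cat(sprintf("  initDG %+.2f, tetherInitDG %+.2f, bmPlateauDG %+.2f\n",
        object@initDG, object@tetherInitDG, object@bmPlateauDG))
    invisible(object)
})

## temperature- and salt-adjusted free energy of a raw table entry
.tableDG <- function(dH, dS, model) {
    saltDS <- 0.368 * log(model@saltMM / 1000)
    dH - model@temperature * (dS + saltDS) / 1000
}

#' Look up a single stack free energy by dinucleotide
#'
#' Convenience lookup of the temperature- and salt-adjusted table value,
#' without modification increments.
#'
#' @param dinuc two-letter dinucleotide, 5' to 3'. For the hybrid table this
#'   is the RNA-strand dinucleotide (U alphabet; T is mapped to U).
#' @param class \code{"DNA"} for DNA:DNA or \code{"hybrid"} for RNA:DNA.
#' @param model an [EnergyModel-class].
#' @return kcal/mol.
#' @export
stackDGValue <- function(dinuc, class = c("DNA", "hybrid"), model = energyModel()) {
    class <- match.arg(class)
    if (class == "DNA") {
        key <- chartr("U", "T", dinuc)
        dH <- model@nnDNAdH[key]; dS <- model@nnDNAdS[key]
    } else {
        key <- chartr("T", "U", dinuc)
        dH <- model@nnHybDH[key]; dS <- model@nnHybDS[key]
    }
    if (any(is.na(dH)))
        stop(sprintf("unknown dinucleotide '%s'", dinuc))
    unname(.tableDG(dH, dS, model))
}

## Core stack energy for one step of a duplex.
## bA: top-strand bases (5'->3') at the two adjacent pairs; sA their sugars;
## bB/sB the aligned partner nucleotides (bB[1] pairs bA[1]); psA/psB whether
## the linkage spanned by this step on each strand is phosphorothioate.
.stackDG <- function(bA, sA, bB, sB, psA = FALSE, psB = FALSE, model) {
    hybrid <- any(c(sA, sB) %in% c("RNA", "OME"))
    if (!hybrid) {
        dG <- .tableDG(model@nnDNAdH[paste0(bA[1L], bA[2L])],
                       model@nnDNAdS[paste0(bA[1L], bA[2L])], model)
    } else {
        ## key on the RNA-containing side, read 5'->3'
        if (any(sA %in% c("RNA", "OME"))) {
            key <- chartr("T", "U", paste0(bA[1L], bA[2L]))
        } else {
            key <- chartr("T", "U", paste0(bB[2L], bB[1L]))
        }
        dG <- .tableDG(model@nnHybDH[key], model@nnHybDS[key], model)
    }
    if (is.na(dG))
        stop("unknown dinucleotide in stack lookup")
    inc <- model@modIncrements
    mods <- c(sA, sB)
    dG <- dG + 0.5 * inc[["LNA"]] * sum(mods == "LNA") +
               0.5 * inc[["OME"]] * sum(mods == "OME")
    if (psA) dG <- dG + inc[["PS"]]
    if (psB) dG <- dG + inc[["PS"]]
    unname(dG)
}

## Per-step stack energies along one contiguous duplex segment.
## Returns a numeric vector of length nPairs - 1, ordered by ascending
## position on strand A.
.segmentStacks <- function(duplex, strandA, strandB, model) {
    o <- order(duplex@posA)
    pa <- duplex@posA[o]; pb <- duplex@posB[o]
    if (length(pa) > 1L && (any(diff(pa) != 1L) || any(diff(pb) != -1L)))
        stop("duplex is not a single contiguous antiparallel segment")
    n <- length(pa)
    if (n < 2L) return(numeric())
    bA <- bases(strandA); sA <- sugars(strandA); lA <- linkages(strandA)
    bB <- bases(strandB); sB <- sugars(strandB); lB <- linkages(strandB)
    vapply(seq_len(n - 1L), function(i) {
        .stackDG(
            bA = bA[c(pa[i], pa[i + 1L])], sA = sA[c(pa[i], pa[i + 1L])],
            bB = bB[c(pb[i], pb[i + 1L])], sB = sB[c(pb[i], pb[i + 1L])],
            psA = lA[pa[i]] == "PS",
            psB = lB[pb[i + 1L]] == "PS",
            model = model)
    }, numeric(1))
}

#' Stack free energy of one duplex step
#'
#' The nearest-neighbor free energy of the step between adjacent base pairs
#' \code{index} and \code{index + 1} of a contiguous duplex segment: the
#' table value for the step's chemistry class (DNA:DNA, or RNA:DNA hybrid if
#' any of the four nucleotides carries a ribose-type sugar) plus half the
#' modification increment of each modified nucleotide in the two pairs, plus
#' the PS increment for each phosphorothioate linkage spanned.
#'
#' @param duplex a single-segment [DuplexMap-class].
#' @param index step index (1-based, along ascending strand-A positions).
#' @param strandA,strandB the two [ModifiedStrand-class] objects.
#' @param model an [EnergyModel-class].
#' @return kcal/mol.
#' @export
stackDG <- function(duplex, index, strandA, strandB, model = energyModel()) {
    st <- .segmentStacks(duplex, strandA, strandB, model)
    if (index < 1L || index > length(st))
        stop("step index out of range")
    st[index]
}

#' Hybridization free energy of a duplex segment
#'
#' Initiation penalty plus the sum of all nearest-neighbor stack terms. More
#' negative means more stable.
#'
#' @inheritParams stackDG
#' @return kcal/mol.
#' @examples
#' a <- modifiedStrand("a", "ACGTT")
#' b <- modifiedStrand("b", "AACGT")
#' duplexDG(pairStrands(a, c(1, 5), b, c(1, 5)), a, b)
#' @export
duplexDG <- function(duplex, strandA, strandB, model = energyModel()) {
    if (nPairs(duplex) < 2L)
        stop("duplex segment too short: need at least 2 base pairs")
    model@initDG + sum(.segmentStacks(duplex, strandA, strandB, model))
}

#' Per-stack decomposition of a duplex free energy
#'
#' @inheritParams stackDG
#' @param file optional path; when given the table is written as TSV
#'   (byte-stable for fixed input).
#' @return a data.frame with columns \code{step}, \code{dinucleotide},
#'   \code{dG}; the initiation term is reported as step 0.
#' @export
stackTable <- function(duplex, strandA, strandB, model = energyModel(),
                       file = NULL) {
    st <- .segmentStacks(duplex, strandA, strandB, model)
    o <- order(duplex@posA)
    pa <- duplex@posA[o]
    din <- vapply(seq_along(st), function(i)
        paste0(bases(strandA)[pa[i]], bases(strandA)[pa[i + 1L]]), character(1))
    out <- data.frame(
        step = c(0L, seq_along(st)),
        dinucleotide = c("init", din),
        dG = c(model@initDG, st),
        stringsAsFactors = FALSE)
    if (!is.null(file))
        utils::write.table(format(out, digits = 10), file = file, sep = "\t",
            quote = FALSE, row.names = FALSE)
    out
}
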