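## strand_model: chemically annotated strands, duplex pairing, design checks.

#' Construct a chemically annotated strand
#'
#' @param name strand identifier.
#' @param bases character vector of bases (or a single string) 5' to 3'.
#' @param sugars sugar chemistry per nucleotide (\code{"DNA"}, \code{"RNA"},
#'   \code{"LNA"}, \code{"OME"}); a scalar is recycled.
#' @param linkages 3'-side backbone linkages (\code{"PO"}/\code{"PS"}),
#'   length one less than the strand; a scalar is recycled.
#' @param loci named list of closed integer ranges \code{c(start, end)}.
#' @return a [ModifiedStrand-class] object.
#' @examples
#' s <- modifiedStrand("toy", "ACGU", sugars = "RNA")
#' strandLength(s)
#' @export
modifiedStrand <- function(name, bases, sugars = "DNA", linkages = "PO",
                           loci = list()) {
    if (length(bases) == 1L && nchar(bases) > 1L)
        bases <- strsplit(bases, "")[[1L]]
    n <- length(bases)
    sugars <- rep_len(sugars, n)
    linkages <- if (n > 1L) rep_len(linkages, n - 1L) else character()
    loci <- lapply(loci, function(rg) as.integer(rg))
    new("ModifiedStrand", name = name, base = as.character(bases),
        sugar = sugars, linkage = linkages, loci = loci)
}

#' @rdname ModifiedStrand-accessors
#' @export
setGeneric("strandLength", function(x) standardGeneric("strandLength"))

#' @rdname ModifiedStrand-accessors
#' @export
setGeneric("bases", function(x) standardGeneric("bases"))

#' @rdname ModifiedStrand-accessors
#' @export
setGeneric("sugars", function(x) standardGeneric("sugars"))

#' @rdname ModifiedStrand-accessors
#' @export
setGeneric("linkages", function(x) standardGeneric("linkages"))

#' @rdname ModifiedStrand-accessors
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname ModifiedStrand-accessors
#' @export
setGeneric("strandName", function(x) standardGeneric("strandName"))

#' Accessors for ModifiedStrand
#'
#' \code{strandLength} is the number of nucleotides, \code{bases},
#' \code{sugars} and \code{linkages} return the per-position annotations,
#' \code{loci} the named ranges, \code{locusRange} one named range as a
#' position vector.
#'
#' @param x a [ModifiedStrand-class].
#' @name ModifiedStrand-accessors
NULL

#' @rdname ModifiedStrand-accessors
#' @export
setMethod("strandLength", "ModifiedStrand", function(x) length(x@base))

#' @rdname ModifiedStrand-accessors
#' @export
setMethod("bases", "ModifiedStrand", function(x) x@base)

#' @rdname ModifiedStrand-accessors
#' @export
setMethod("sugars", "ModifiedStrand", function(x) x@sugar)

#' @rdname ModifiedStrand-accessors
#' @export
setMethod("linkages", "ModifiedStrand", function(x) x@linkage)

#' @rdname ModifiedStrand-accessors
#' @export
setMethod("loci", "ModifiedStrand", function(x) x@loci)

#' @rdname ModifiedStrand-accessors
#' @export
setMethod("strandName", "ModifiedStrand", function(x) x@name)

#' @rdname ModifiedStrand-accessors
#' @param locus locus name.
#' @export
locusRange <- function(x, locus) {
    rg <- x@loci[[locus]]
    if (is.null(rg))
        stop(sprintf("strand '%s' has no locus '%s'", x@name, locus))
    seq.int(rg[1L], rg[2L])
}

setMethod("show", "ModifiedStrand", function(object) {
    n <- strandLength(object)
    cat(sprintf("ModifiedStrand '%s': %d nt\n", object@name, n))
    cat("  5'-", paste(object@base, collapse = ""), "-3'\n", sep = "")
    cat("     ", paste(.SUGAR_CODE[object@sugar], collapse = ""), "\n", sep = "")
    if (any(object@linkage == "PS"))
        cat(sprintf("  PS linkages: %s\n",
            paste(which(object@linkage == "PS"), collapse = ",")))
    for (nm in names(object@loci))
        cat(sprintf("  locus %s: %d-%d\n", nm,
            object@loci[[nm]][1L], object@loci[[nm]][2L]))
    invisible(object)
})

## ---------------------------------------------------------------------------
## Gapmer scheme and pattern builder
## ---------------------------------------------------------------------------

#' Construct a gapmer chemistry scheme
#'
#' @param totalLength strand length (nt).
#' @param wing sugar pattern applied from each end, 5' to 3' (mirrored at the
#'   3' end), e.g. \code{c(rep("LNA", 4), rep("OME", 2))}; empty for all-DNA.
#' @param psPerEnd PS linkages at each end.
#' @param fullyPS make every linkage PS.
#' @return a [GapmerScheme-class].
#' @examples
#' gapmerScheme(20L, c(rep("LNA", 4), rep("OME", 2)), psPerEnd = 3L)
#' @export
gapmerScheme <- function(totalLength, wing = character(), psPerEnd = 0L,
                         fullyPS = FALSE) {
    new("GapmerScheme", totalLength = as.integer(totalLength),
        wing = as.character(wing), psPerEnd = as.integer(psPerEnd),
        fullyPS = fullyPS)
}

#' Scheme of the 20-nt gapmer with 4xLNA + 2x2'-O-Me wings
#'
#' The design whose wings are four consecutive LNA nucleotides followed by
#' two 2'-O-methyl nucleotides at each end, leaving a central unmodified-DNA
#' block of 8 nucleotides, with three PS linkages at each end.
#'
#' @param totalLength gapmer length (default 20 nt).
#' @return a [GapmerScheme-class].
#' @export
defaultGapmerScheme <- function(totalLength = 20L) {
    gapmerScheme(totalLength, c(rep("LNA", 4L), rep("OME", 2L)), psPerEnd = 3L)
}

#' Build the chemistry pattern of a gapmer
#'
#' Applies the wing sugars from the 5' end, mirrors them from the 3' end, and
#' leaves the central remainder unmodified DNA. PS linkages are applied to the
#' first and last \code{psPerEnd} linkages (or all linkages if the scheme is
#' fully PS). When no seed sequence is supplied the bases are \code{N}-free
#' placeholders (all \code{A}/\code{U} per sugar) meant to be overwritten by
#' the design generator.
#'
#' @param scheme a [GapmerScheme-class].
#' @param seedSequence optional base string of length \code{totalLength}.
#' @param name strand name.
#' @return a [ModifiedStrand-class] with a \code{central_block} locus when a
#'   central DNA block exists.
#' @examples
#' g <- buildGapmerPattern(defaultGapmerScheme())
#' rle(sugars(g))
#' @export
buildGapmerPattern <- function(scheme, seedSequence = NULL, name = "gapmer") {
    validObject(scheme)
    n <- scheme@totalLength
    w <- length(scheme@wing)
    sug <- rep("DNA", n)
    if (w) {
        sug[seq_len(w)] <- scheme@wing
        sug[seq.int(n, n - w + 1L)] <- scheme@wing
    }
    if (is.null(seedSequence)) {
        b <- ifelse(sug %in% c("RNA", "OME"), "U", "T")
    } else {
        b <- if (length(seedSequence) == 1L) strsplit(seedSequence, "")[[1L]]
             else as.character(seedSequence)
        if (length(b) != n)
            stop("seedSequence length must equal the scheme totalLength")
        ## uracil cannot sit on DNA/LNA sugars and thymine not on RNA/OME
        b[b == "T" & sug %in% c("RNA", "OME")] <- "U"
        b[b == "U" & sug %in% c("DNA", "LNA")] <- "T"
    }
    lnk <- rep("PO", max(n - 1L, 0L))
    if (scheme@fullyPS) {
        lnk[] <- "PS"
    } else if (scheme@psPerEnd > 0L && n > 1L) {
        k <- min(scheme@psPerEnd, n - 1L)
        lnk[seq_len(k)] <- "PS"
        lnk[seq.int(n - k, n - 1L)] <- "PS"
    }
    loci <- list()
    if (n - 2L * w >= 1L)
        loci$central_block <- c(w + 1L, n - w)
    modifiedStrand(name, b, sug, lnk, loci = loci)
}

## ---------------------------------------------------------------------------
## Pairing
## ---------------------------------------------------------------------------

#' Pair two strand ranges into an antiparallel duplex
#'
#' Position \code{i} of \code{rangeA} is paired with position
#' \code{endB - (i - startA)} of \code{rangeB}, and every pair is checked for
#' Watson-Crick complementarity (A-T, A-U, G-C; wobble pairs are rejected).
#'
#' @param strandA,strandB [ModifiedStrand-class] objects.
#' @param rangeA,rangeB closed position ranges \code{c(start, end)} (or full
#'   position vectors) of equal length.
#' @return a [DuplexMap-class].
#' @examples
#' a <- modifiedStrand("r", "ACGU", sugars = "RNA")
#' b <- modifiedStrand("d", "ACGT")
#' pairStrands(a, c(1, 4), b, c(1, 4))
#' @export
pairStrands <- function(strandA, rangeA, strandB, rangeB) {
    pa <- if (length(rangeA) == 2L) seq.int(rangeA[1L], rangeA[2L]) else as.integer(rangeA)
    pb <- if (length(rangeB) == 2L) seq.int(rangeB[1L], rangeB[2L]) else as.integer(rangeB)
    if (length(pa) != length(pb))
        stop("ranges must have equal length")
    if (max(pa) > strandLength(strandA) || max(pb) > strandLength(strandB))
        stop("range exceeds strand length")
    posB <- rev(pb)  # antiparallel register
    ok <- .isWatsonCrick(bases(strandA)[pa], bases(strandB)[posB])
    if (!all(ok)) {
        bad <- which(!ok)
        stop(sprintf(
            "non-complementary pair(s) %s",
            paste(sprintf("%s:%d/%s:%d (%s-%s)",
                strandName(strandA), pa[bad], strandName(strandB), posB[bad],
                bases(strandA)[pa[bad]], bases(strandB)[posB[bad]]),
                collapse = ", ")))
    }
    new("DuplexMap", strandA = strandName(strandA), strandB = strandName(strandB),
        posA = pa, posB = posB)
}

#' @rdname DuplexMap-accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' Accessors for DuplexMap
#'
#' \code{nPairs} counts base pairs; \code{duplexSegments} splits the map into
#' maximal contiguous antiparallel runs and returns a list of index vectors
#' into the pair list; \code{pairedPositions} returns the paired positions of
#' one of the two strands.
#'
#' @param x a [DuplexMap-class].
#' @name DuplexMap-accessors
NULL

#' @rdname DuplexMap-accessors
#' @export
setMethod("nPairs", "DuplexMap", function(x) length(x@posA))

#' @rdname DuplexMap-accessors
#' @export
duplexSegments <- function(x) {
    n <- nPairs(x)
    if (n == 0L) return(list())
    o <- order(x@posA)
    brk <- which(diff(x@posA[o]) != 1L | diff(x@posB[o]) != -1L)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, n)
    mapply(function(s, e) o[s:e], starts, ends, SIMPLIFY = FALSE)
}

#' @rdname DuplexMap-accessors
#' @param strand strand identifier (must match \code{strandA} or
#'   \code{strandB} of the map).
#' @export
pairedPositions <- function(x, strand) {
    if (strand == x@strandA) x@posA
    else if (strand == x@strandB) x@posB
    else stop(sprintf("strand '%s' is not part of this duplex", strand))
}

#' @rdname DuplexMap-accessors
#' @param pos positions on the strand named by \code{strand}.
#' @export
partnerPositions <- function(x, strand, pos) {
    if (strand == x@strandA) x@posB[match(pos, x@posA)]
    else if (strand == x@strandB) x@posA[match(pos, x@posB)]
    else stop(sprintf("strand '%s' is not part of this duplex", strand))
}

setMethod("show", "DuplexMap", function(object) {
    segs <- duplexSegments(object)
    cat(sprintf("DuplexMap %s:%s, %d bp in %d segment(s)\n",
        object@strandA, object@strandB, nPairs(object), length(segs)))
    for (ix in segs)
        cat(sprintf("  %s %d-%d : %s %d-%d\n",
            object@strandA, min(object@posA[ix]), max(object@posA[ix]),
            object@strandB, min(object@posB[ix]), max(object@posB[ix])))
    invisible(object)
})

## ---------------------------------------------------------------------------
## Design accessors and validation
## ---------------------------------------------------------------------------

#' Accessors for TDNDesign
#'
#' @param x a [TDNDesign-class].
#' @name TDNDesign-accessors
NULL

#' @rdname TDNDesign-accessors
#' @export
designStrands <- function(x) x@strands

#' @rdname TDNDesign-accessors
#' @export
designEdges <- function(x) x@edges

#' @rdname TDNDesign-accessors
#' @param name strand name.
#' @export
designStrand <- function(x, name) {
    s <- x@strands[[name]]
    if (is.null(s)) stop(sprintf("no strand '%s' in design", name))
    s
}

#' @rdname TDNDesign-accessors
#' @export
gapmerEdge <- function(x) x@edges[[x@gapmerEdge]]

#' @rdname TDNDesign-accessors
#' @export
rnaStrand <- function(x) x@strands[[x@rnaStrand]]

#' Extract the gapmer as a standalone strand
#'
#' Cuts the gapmer locus out of its host strand, keeping bases, sugars and
#' linkages, so it can be paired against a free target.
#'
#' @param design a [TDNDesign-class].
#' @return a 20-nt (by default) [ModifiedStrand-class] named
#'   \code{"<host>_gapmer"}.
#' @export
extractGapmer <- function(design) {
    host <- design@strands[[design@gapmerStrand]]
    idx <- locusRange(host, "gapmer")
    modifiedStrand(paste0(strandName(host), "_gapmer"),
        bases(host)[idx], sugars(host)[idx],
        linkages(host)[idx[-length(idx)]],
        loci = list(gapmer = c(1L, length(idx))))
}

setMethod("show", "TDNDesign", function(object) {
    cat(sprintf("TDNDesign: 4 strands (%s), 6 edges\n",
        paste(names(object@strands), collapse = ", ")))
    lens <- vapply(object@strands, strandLength, integer(1))
    cat("  strand lengths:",
        paste(sprintf("%s=%d", names(lens), lens), collapse = ", "), "\n")
    cat(sprintf("  gapmer on %s (edge %s), RNA block on %s\n",
        object@gapmerStrand, object@gapmerEdge, object@rnaStrand))
    invisible(object)
})

#' Validate a tetrahedron design
#'
#' Runs the structural checks and returns a report rather than erroring:
#' per-edge Watson-Crick complementarity, gapmer integrity (contiguous locus
#' on a single edge segment), heteroduplex annotation (RNA block fully paired
#' to the gapmer locus), and strand lengths.
#'
#' @param design a [TDNDesign-class].
#' @return a list with elements \code{pass} (logical), \code{edges}
#'   (per-edge logical with failure details as names), \code{gapmerIntegrity},
#'   \code{heteroduplex}, \code{strandLengths} and \code{failures}
#'   (character vector of failure messages, empty when all checks pass).
#' @export
validateDesign <- function(design) {
    failures <- character()
    strands <- design@strands

    edgeOK <- vapply(names(design@edges), function(en) {
        e <- design@edges[[en]]
        sa <- strands[[e@strandA]]; sb <- strands[[e@strandB]]
        if (is.null(sa) || is.null(sb)) return(FALSE)
        if (max(e@posA) > strandLength(sa) || max(e@posB) > strandLength(sb))
            return(FALSE)
        all(.isWatsonCrick(bases(sa)[e@posA], bases(sb)[e@posB]))
    }, logical(1))
    for (en in names(edgeOK)[!edgeOK])
        failures <- c(failures, sprintf("edge %s fails complementarity", en))

    ## gapmer integrity: contiguous locus, fully inside one edge segment
    gapmerOK <- TRUE
    host <- strands[[design@gapmerStrand]]
    gIdx <- tryCatch(locusRange(host, "gapmer"), error = function(e) NULL)
    if (is.null(gIdx)) {
        gapmerOK <- FALSE
        failures <- c(failures, "gapmer locus missing on host strand")
    } else {
        ge <- design@edges[[design@gapmerEdge]]
        onEdge <- pairedPositions(ge, design@gapmerStrand)
        segs <- duplexSegments(ge)
        inOneSegment <- any(vapply(segs, function(ix) {
            segPos <- pairedPositions(ge, design@gapmerStrand)[ix]
            all(gIdx %in% segPos)
        }, logical(1)))
        if (!inOneSegment) {
            gapmerOK <- FALSE
            failures <- c(failures,
                "gapmer locus is not contained in a single edge segment")
        }
    }

    ## heteroduplex: RNA block fully paired to gapmer locus positions
    hetOK <- TRUE
    rs <- strands[[design@rnaStrand]]
    rIdx <- tryCatch(locusRange(rs, "rna_block"), error = function(e) NULL)
    if (is.null(rIdx)) {
        hetOK <- FALSE
        failures <- c(failures, "rna_block locus missing on RNA strand")
    } else if (!is.null(gIdx)) {
        ge <- design@edges[[design@gapmerEdge]]
        partners <- partnerPositions(ge, design@rnaStrand, rIdx)
        hostIdxOfGapmer <- gIdx
        if (any(is.na(partners)) || !all(partners %in% hostIdxOfGapmer)) {
            hetOK <- FALSE
            failures <- c(failures,
                "rna_block is not fully paired to the gapmer locus")
        }
        if (!all(sugars(rs)[rIdx] == "RNA")) {
            hetOK <- FALSE
            failures <- c(failures, "rna_block locus contains non-RNA sugars")
        }
    }

    list(pass = length(failures) == 0L,
         edges = edgeOK,
         gapmerIntegrity = gapmerOK,
         heteroduplex = hetOK,
         strandLengths = vapply(strands, strandLength, integer(1)),
         failures = failures)
}
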