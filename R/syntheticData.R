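## synthetic_data: constraint-satisfying tetrahedron designs and targets.
## The generator defines the study conditions every other module is tested
## under: a 4-strand, 6-edge tetrahedron (each strand traversing three
## 20-bp edges with 2-nt vertex hinges, hence 64-nt strands), the 20-nt
## gapmer encoded in one strand, and the partner strand carrying a 10-nt RNA
## block starting at nucleotide 7 followed by a 6-nt unmodified DNA flank.

#' Construct a generator specification
#'
#' Defaults emulate the reference layout: 20 bp per edge, 2 unpaired
#' nucleotides per internal vertex passage (so every strand is
#' 3 x 20 + 2 x 2 = 64 nt), the 20-nt gapmer with 4xLNA + 2x2'-O-Me wings
#' and 3 PS linkages per end, the RNA block at positions 7-16 of the
#' RNA-containing strand with a 6-nt unmodified DNA flank 3' of it,
#' per-strand GC fraction in [0.4, 0.6], and no unintended complementary
#' run of 9 nt or longer.
#'
#' @param edgeBP base pairs per edge.
#' @param hingeNT unpaired nucleotides per internal vertex passage.
#' @param scheme gapmer [GapmerScheme-class].
#' @param rnaStart,rnaLength RNA block placement on the RNA strand.
#' @param flankDNA unmodified DNA nucleotides 3' of the RNA block.
#' @param gcBounds per-strand GC fraction range.
#' @param crosstalkK shortest forbidden unintended complementary run.
#' @param maxTries generation attempts before giving up.
#' @return a [GeneratorSpec-class].
#' @export
generatorSpec <- function(edgeBP = 20L, hingeNT = 2L,
                          scheme = defaultGapmerScheme(),
                          rnaStart = 7L, rnaLength = 10L, flankDNA = 6L,
                          gcBounds = c(0.4, 0.6), crosstalkK = 9L,
                          maxTries = 100L) {
    new("GeneratorSpec", edgeBP = as.integer(edgeBP),
        hingeNT = as.integer(hingeNT), scheme = scheme,
        rnaStart = as.integer(rnaStart), rnaLength = as.integer(rnaLength),
        flankDNA = as.integer(flankDNA), gcBounds = as.numeric(gcBounds),
        crosstalkK = as.integer(crosstalkK), maxTries = as.integer(maxTries))
}

.randBases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.gcFraction <- function(b) mean(b %in% c("G", "C"))

## segment layout of one strand: three edge segments separated by hinges
.segmentIndex <- function(edgeBP, hingeNT, which) {
    start <- (which - 1L) * (edgeBP + hingeNT) + 1L
    seq.int(start, start + edgeBP - 1L)
}

#' Generate a constraint-satisfying tetrahedron design
#'
#' Draws random edge sequences (each edge duplex is one strand segment and
#' the reverse complement of its partner segment), assembles the four
#' strands, applies the gapmer chemistry on the host strand and the RNA
#' block + DNA flank on the partner strand, and accepts the design only if
#' per-strand GC fractions fall inside the bounds and the crosstalk screen
#' finds no unintended complementary run of \code{crosstalkK} or longer.
#' Generation is bounded: after \code{maxTries} failed draws the violated
#' constraint is reported as an error.
#'
#' Strand S1 hosts the gapmer (its third edge segment); strand S4 is the
#' RNA-containing strand, whose first edge segment (positions 1 to
#' \code{edgeBP}) is the heteroduplex paired to the gapmer with gapmer
#' position 1 opposite S4 position \code{edgeBP}.
#'
#' @param spec a [GeneratorSpec-class].
#' @param seed RNG seed; the same spec and seed give a byte-identical design.
#' @return a [TDNDesign-class] that passes [validateDesign()].
#' @examples
#' d <- generateDesign(generatorSpec(), seed = 1)
#' strandLength(rnaStrand(d))  # 64
#' @export
generateDesign <- function(spec = generatorSpec(), seed = 1L) {
    validObject(spec)
    set.seed(as.integer(seed))
    eb <- spec@edgeBP; h <- spec@hingeNT
    L <- 3L * eb + 2L * h
    if (spec@rnaStart + spec@rnaLength - 1L + spec@flankDNA > L)
        stop("RNA block and flank do not fit on the strand")
    seg <- lapply(1:3, function(w) .segmentIndex(eb, h, w))
    hingeIdx <- setdiff(seq_len(L), unlist(seg))

    lastViolation <- "no attempt made"
    for (try in seq_len(spec@maxTries)) {
        s1 <- .randBases(L)
        s2 <- s3 <- s4 <- character(L)
        s2[seg[[1L]]] <- .revcompBases(s1[seg[[1L]]])
        s3[seg[[1L]]] <- .revcompBases(s1[seg[[2L]]])
        s4[seg[[1L]]] <- .revcompBases(s1[seg[[3L]]])
        s2[seg[[2L]]] <- .randBases(eb)
        s3[seg[[2L]]] <- .revcompBases(s2[seg[[2L]]])
        s2[seg[[3L]]] <- .randBases(eb)
        s4[seg[[2L]]] <- .revcompBases(s2[seg[[3L]]])
        s3[seg[[3L]]] <- .randBases(eb)
        s4[seg[[3L]]] <- .revcompBases(s3[seg[[3L]]])
        s2[hingeIdx] <- .randBases(length(hingeIdx))
        s3[hingeIdx] <- .randBases(length(hingeIdx))
        s4[hingeIdx] <- .randBases(length(hingeIdx))

        gc <- vapply(list(s1, s2, s3, s4), .gcFraction, numeric(1))
        if (any(gc < spec@gcBounds[1L] | gc > spec@gcBounds[2L])) {
            lastViolation <- sprintf(
                "GC fraction outside [%.2f, %.2f] (observed %s)",
                spec@gcBounds[1L], spec@gcBounds[2L],
                paste(sprintf("%.2f", gc), collapse = ", "))
            next
        }

        design <- .assembleDesign(spec, s1, s2, s3, s4, seg)
        xt <- crosstalkScreen(designStrands(design), spec@crosstalkK,
                              design = design)
        if (nrow(xt)) {
            lastViolation <- sprintf(
                "unintended complementary run of %d nt (%s:%d / %s:%d)",
                xt$length[1L], xt$strandA[1L], xt$startA[1L],
                xt$strandB[1L], xt$startB[1L])
            next
        }
        return(design)
    }
    stop(sprintf(
        "design generation failed after %d attempts; last violated constraint: %s",
        spec@maxTries, lastViolation))
}

## build strands with chemistry annotations and the six edge maps
.assembleDesign <- function(spec, s1, s2, s3, s4, seg) {
    eb <- spec@edgeBP
    L <- length(s1)
    gapIdx <- seg[[3L]]                     # gapmer locus on S1
    rnaIdx <- seq.int(spec@rnaStart, spec@rnaStart + spec@rnaLength - 1L)

    ## S1: gapmer chemistry stamped on its third segment
    gp <- buildGapmerPattern(spec@scheme,
        seedSequence = s1[gapIdx], name = "gapmer_tmp")
    sug1 <- rep("DNA", L); lnk1 <- rep("PO", L - 1L)
    sug1[gapIdx] <- sugars(gp)
    b1 <- s1; b1[gapIdx] <- bases(gp)
    lnk1[gapIdx[-length(gapIdx)]] <- linkages(gp)
    S1 <- modifiedStrand("S1", b1, sug1, lnk1,
        loci = list(gapmer = range(gapIdx)))

    ## S4: RNA block (U alphabet) + unmodified flank
    sug4 <- rep("DNA", L)
    sug4[rnaIdx] <- "RNA"
    b4 <- s4
    b4[rnaIdx] <- chartr("T", "U", b4[rnaIdx])
    flankIdx <- seq.int(max(rnaIdx) + 1L, max(rnaIdx) + spec@flankDNA)
    S4 <- modifiedStrand("S4", b4, sug4, "PO",
        loci = list(rna_block = range(rnaIdx),
                    flank_dna = range(flankIdx)))

    S2 <- modifiedStrand("S2", s2, "DNA", "PO")
    S3 <- modifiedStrand("S3", s3, "DNA", "PO")
    strands <- list(S1 = S1, S2 = S2, S3 = S3, S4 = S4)

    edges <- list(
        E12 = pairStrands(S1, range(seg[[1L]]), S2, range(seg[[1L]])),
        E13 = pairStrands(S1, range(seg[[2L]]), S3, range(seg[[1L]])),
        E14 = pairStrands(S1, range(seg[[3L]]), S4, range(seg[[1L]])),
        E23 = pairStrands(S2, range(seg[[2L]]), S3, range(seg[[2L]])),
        E24 = pairStrands(S2, range(seg[[3L]]), S4, range(seg[[2L]])),
        E34 = pairStrands(S3, range(seg[[3L]]), S4, range(seg[[3L]])))

    hingeIdx <- setdiff(seq_len(L), unlist(seg))
    hinges <- lapply(strands, function(s) hingeIdx)

    new("TDNDesign", strands = strands, edges = edges, hinges = hinges,
        gapmerEdge = "E14", gapmerStrand = "S1", rnaStrand = "S4")
}

#' Generate the complementary RNA target
#'
#' A 22-nt all-RNA strand fully complementary to the 20-nt gapmer, with a
#' 2-nt overhang at the target's 5' end (the declared register): target
#' positions 3..22 pair gapmer positions 20..1.
#'
#' @param design a [TDNDesign-class].
#' @param seed RNG seed for the overhang bases.
#' @param overhang overhang length (nt).
#' @return a [ModifiedStrand-class] named \code{"target"}.
#' @export
generateTarget <- function(design, seed = 1L, overhang = 2L) {
    set.seed(as.integer(seed))
    gap <- extractGapmer(design)
    core <- .revcompBases(bases(gap), partnerSugar = "RNA")
    oh <- chartr("T", "U", .randBases(overhang))
    modifiedStrand("target", c(oh, core), "RNA", "PO",
        loci = list(gapmer_complement =
            c(overhang + 1L, overhang + strandLength(gap))))
}

#' Pair a target to the gapmer under the declared register
#'
#' @param target a target strand from [generateTarget()].
#' @param gapmer the gapmer strand (see [extractGapmer()]).
#' @return a [DuplexMap-class] with one pair per gapmer position; errors on
#'   any non-complementary pair (e.g. a scrambled target).
#' @export
pairTargetToGapmer <- function(target, gapmer) {
    rg <- target@loci[["gapmer_complement"]]
    if (is.null(rg))
        rg <- c(strandLength(target) - strandLength(gapmer) + 1L,
                strandLength(target))
    pairStrands(target, rg, gapmer, c(1L, strandLength(gapmer)))
}

#' Screen strand sets for unintended complementary runs
#'
#' Scans every ordered strand pair (including each strand against itself)
#' for antiparallel Watson-Crick complementary runs of length at least
#' \code{k}, excluding the intended base pairs of the design's edges. The
#' generator retries until this report is empty at the spec's
#' \code{crosstalkK}.
#'
#' @param strands named list of [ModifiedStrand-class] objects.
#' @param k minimum reported run length (at least 4).
#' @param design optional [TDNDesign-class] whose edge pairs are masked as
#'   intended.
#' @return data.frame with columns \code{strandA}, \code{strandB},
#'   \code{startA}, \code{startB} (5' positions of the run on each strand)
#'   and \code{length}; zero rows when the set is clean.
#' @export
crosstalkScreen <- function(strands, k, design = NULL) {
    if (k < 4L) stop("k must be at least 4")
    nms <- names(strands)
    if (is.null(nms)) {
        nms <- vapply(strands, strandName, character(1))
        names(strands) <- nms
    }
    intended <- list()
    if (!is.null(design)) {
        for (e in design@edges) {
            key <- paste(e@strandA, e@strandB, sep = "|")
            intended[[key]] <- rbind(intended[[key]], cbind(e@posA, e@posB))
            key2 <- paste(e@strandB, e@strandA, sep = "|")
            intended[[key2]] <- rbind(intended[[key2]], cbind(e@posB, e@posA))
        }
    }
    out <- list()
    for (ia in seq_along(strands)) for (ib in ia:length(strands)) {
        a <- bases(strands[[ia]]); b <- bases(strands[[ib]])
        na <- length(a); nb <- length(b)
        M <- outer(seq_len(na), seq_len(nb),
                   function(i, j) .isWatsonCrick(a[i], b[j]))
        mask <- intended[[paste(nms[ia], nms[ib], sep = "|")]]
        if (!is.null(mask)) M[mask] <- FALSE
        if (ia == ib) diag(M) <- FALSE
        ## antiparallel runs live on anti-diagonals (constant i + j)
        for (s in 2:(na + nb)) {
            i <- seq.int(max(1L, s - nb), min(na, s - 1L))
            if (length(i) < k) next
            v <- M[cbind(i, s - i)]
            r <- rle(v)
            ends <- cumsum(r$lengths)
            for (q in which(r$values & r$lengths >= k)) {
                i0 <- i[ends[q] - r$lengths[q] + 1L]
                len <- r$lengths[q]
                j0 <- s - i0          # partner of the run's first position
                if (ia == ib && i0 > j0) next   # mirrored duplicate
                out[[length(out) + 1L]] <- data.frame(
                    strandA = nms[ia], strandB = nms[ib],
                    startA = i0, startB = j0 - len + 1L, length = len,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(data.frame(strandA = character(), strandB = character(),
                          startA = integer(), startB = integer(),
                          length = integer(), stringsAsFactors = FALSE))
    do.call(rbind, out)
}
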