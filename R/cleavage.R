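## rnaseh_cleavage: rule-based prediction of RNase H-competent linkages on
## the RNA strand of a DNA:RNA heteroduplex, main-cut designation and
## fragment accounting.
##
## Competence rule: linkage i (between nucleotides i and i+1 of the cleaved
## strand) is competent iff nucleotide i carries an RNA sugar AND the base
## pairs at positions i and i+1 both exist and involve no sugar-modified
## nucleotide (no LNA, no 2'-O-Me) on either strand. PS linkages do not
## block cleavage. The main cut is the 3'-most competent linkage -- the cut
## toward the RNA 3' end, immediately before the first modified base pair.

## resolve (cleaved strand, partner strand, duplex) from a design or an
## explicit duplex + strand pair
.cleavageContext <- function(x, strandA = NULL, strandB = NULL,
                             cleavedStrand = NULL) {
    if (is(x, "TDNDesign")) {
        edge <- gapmerEdge(x)
        cleaved <- rnaStrand(x)
        partnerName <- if (edge@strandA == strandName(cleaved)) edge@strandB
                       else edge@strandA
        list(duplex = edge, cleaved = cleaved,
             partner = designStrand(x, partnerName))
    } else if (is(x, "DuplexMap")) {
        if (is.null(strandA) || is.null(strandB))
            stop("a DuplexMap needs its two strands")
        if (is.null(cleavedStrand)) {
            ## default: the strand containing RNA sugars in the duplex
            rnaA <- any(sugars(strandA)[pairedPositions(x, strandName(strandA))] == "RNA")
            cleavedStrand <- if (rnaA) strandName(strandA) else strandName(strandB)
        }
        if (cleavedStrand == strandName(strandA))
            list(duplex = x, cleaved = strandA, partner = strandB)
        else
            list(duplex = x, cleaved = strandB, partner = strandA)
    } else stop("expected a TDNDesign or a DuplexMap")
}

#' Enumerate RNase H-competent cleavage linkages
#'
#' Applies the chemistry rule to the cleaved strand of a heteroduplex:
#' linkage \code{i} is competent iff nucleotide \code{i} is RNA and the base
#' pairs at \code{i} and \code{i + 1} both exist with no LNA or 2'-O-Me
#' nucleotide on either side. A duplex without RNA yields an empty set (not
#' an error).
#'
#' @param x a [TDNDesign-class] (the gapmer heteroduplex edge is used) or a
#'   [DuplexMap-class].
#' @param strandA,strandB the strands of the duplex when \code{x} is a
#'   [DuplexMap-class].
#' @param cleavedStrand optional name of the strand to cleave; defaults to
#'   the RNA-containing strand.
#' @return integer vector of linkage indices on the cleaved strand (linkage
#'   \code{i} sits between nucleotides \code{i} and \code{i + 1}).
#' @examples
#' d <- generateDesign(generatorSpec(), seed = 1)
#' enumerateCompetentLinkages(d)  # 7:13 under the default layout
#' @export
enumerateCompetentLinkages <- function(x, strandA = NULL, strandB = NULL,
                                       cleavedStrand = NULL) {
    ctx <- .cleavageContext(x, strandA, strandB, cleavedStrand)
    dup <- ctx$duplex; cleaved <- ctx$cleaved; partner <- ctx$partner
    cname <- strandName(cleaved)
    pos <- pairedPositions(dup, cname)
    if (!length(pos)) return(integer())
    partnerPos <- partnerPositions(dup, cname, pos)
    unmod <- sugars(cleaved)[pos] %in% c("DNA", "RNA") &
             sugars(partner)[partnerPos] %in% c("DNA", "RNA")
    okPair <- logical(strandLength(cleaved))
    okPair[pos[unmod]] <- TRUE
    isRNA <- sugars(cleaved) == "RNA"
    n <- strandLength(cleaved)
    i <- seq_len(n - 1L)
    which(isRNA[i] & okPair[i] & okPair[i + 1L])
}

#' Predict the main RNase H cut and account for the fragments
#'
#' The main cut is the 3'-most competent linkage (immediately before the
#' first modified base pair toward the RNA 3' end). A cut at linkage
#' \code{i} releases an \code{i}-nt 5' fragment; the remainder of the
#' paired region stays hybridized and covalently continuous with the
#' framework.
#'
#' @inheritParams enumerateCompetentLinkages
#' @return a [CleavageResult-class].
#' @examples
#' d <- generateDesign(generatorSpec(), seed = 1)
#' predictMainCut(d)  # 13-nt 5' fragment, 7-nt retained segment
#' @export
predictMainCut <- function(x, strandA = NULL, strandB = NULL,
                           cleavedStrand = NULL) {
    ctx <- .cleavageContext(x, strandA, strandB, cleavedStrand)
    comp <- enumerateCompetentLinkages(x, strandA, strandB, cleavedStrand)
    if (!length(comp))
        stop("no RNase H-competent linkage in this duplex (no cut)")
    cleaved <- ctx$cleaved
    cname <- strandName(cleaved)
    pos <- sort(pairedPositions(ctx$duplex, cname))
    mainCut <- max(comp)
    frag <- mainCut
    n <- strandLength(cleaved)
    sug <- sugars(cleaved)[seq_len(frag)]
    chem <- paste(sprintf("%s:%d", names(table(sug)), as.integer(table(sug))),
                  collapse = " ")
    new("CleavageResult",
        strandName = cname,
        strandLength = n,
        competentLinkages = comp,
        mainCut = mainCut,
        fivePrimeFragment = frag,
        fivePrimeChemistry = chem,
        retainedSegment = sum(pos > mainCut),
        postCleavageLength = n - frag,
        pairedRegion = c(min(pos), max(pos)))
}

setMethod("show", "CleavageResult", function(object) {
    cat(sprintf("CleavageResult on '%s' (%d nt)\n",
        object@strandName, object@strandLength))
    cat(sprintf("  competent linkages: %s\n",
        paste(object@competentLinkages, collapse = ",")))
    cat(sprintf("  main cut at %d|%d: 5' fragment %d nt (%s)\n",
        object@mainCut, object@mainCut + 1L, object@fivePrimeFragment,
        object@fivePrimeChemistry))
    cat(sprintf("  retained segment %d nt, covalent remainder %d nt\n",
        object@retainedSegment, object@postCleavageLength))
    invisible(object)
})

#' Length range of the covalent remainder over all competent cuts
#'
#' The shortest remainder comes from the 3'-most competent cut (largest 5'
#' fragment), the longest from the 5'-most cut.
#'
#' @inheritParams enumerateCompetentLinkages
#' @return integer \code{c(min, max)} remainder lengths (nt).
#' @examples
#' d <- generateDesign(generatorSpec(), seed = 1)
#' postCleavageLengthRange(d)  # c(51, 57) for the 64-nt strand
#' @export
postCleavageLengthRange <- function(x, strandA = NULL, strandB = NULL,
                                    cleavedStrand = NULL) {
    ctx <- .cleavageContext(x, strandA, strandB, cleavedStrand)
    comp <- enumerateCompetentLinkages(x, strandA, strandB, cleavedStrand)
    if (!length(comp))
        stop("no RNase H-competent linkage in this duplex (no cut)")
    n <- strandLength(ctx$cleaved)
    c(n - max(comp), n - min(comp))
}

#' Cleave a target strand hybridized to the gapmer
#'
#' The catalytic-cycle step: the same competence rule applied with the
#' all-RNA target as the cleaved strand of the target:gapmer duplex. An
#' all-modified complement (steric blocker) gives a no-cut error.
#'
#' @param duplex target:gapmer [DuplexMap-class] (see
#'   [pairTargetToGapmer()]).
#' @param target the all-RNA target strand.
#' @param gapmer the gapmer strand.
#' @return a [CleavageResult-class] for the target.
#' @export
cleaveTargetDuplex <- function(duplex, target, gapmer) {
    if (!all(sugars(target) == "RNA"))
        stop("target strand must be all-RNA")
    predictMainCut(duplex, strandA = target, strandB = gapmer,
                   cleavedStrand = strandName(target))
}
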