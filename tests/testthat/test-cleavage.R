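test_that("competent linkages follow the chemistry rule on toy hybrids", {
    ## 3-bp rArArA / dTdTdT: both internal linkages competent
    r3 <- modifiedStrand("r3", "AAA", sugars = "RNA")
    d3 <- modifiedStrand("d3", "TTT")
    dup <- pairStrands(r3, c(1, 3), d3, c(1, 3))
    expect_identical(enumerateCompetentLinkages(dup, r3, d3), c(1L, 2L))

    ## all-2'-OMe complement: no unmodified pair anywhere -> empty set
    m3 <- modifiedStrand("m3", "UUU", sugars = "OME")
    dupM <- pairStrands(r3, c(1, 3), m3, c(1, 3))
    expect_identical(enumerateCompetentLinkages(dupM, r3, m3), integer())

    ## duplex without RNA: empty, not an error
    a <- modifiedStrand("a", "ACGT"); b <- modifiedStrand("b", "ACGT")
    expect_identical(
        enumerateCompetentLinkages(pairStrands(a, c(1, 4), b, c(1, 4)), a, b),
        integer())

    ## 8-bp pure RNA:DNA: every internal linkage with both flanking pairs
    ## present is competent (hand enumeration: 1..7)
    r8 <- modifiedStrand("r8", "ACGUACGU", sugars = "RNA")
    d8 <- modifiedStrand("d8", "ACGTACGT")
    dup8 <- pairStrands(r8, c(1, 8), d8, c(1, 8))
    expect_identical(enumerateCompetentLinkages(dup8, r8, d8), 1:7)
})

test_that("the default layout reproduces the printed cut arithmetic", {
    d <- defaultDesign()
    expect_identical(enumerateCompetentLinkages(d), 7:13)

    cr <- predictMainCut(d)
    expect_identical(cr@mainCut, 13L)
    expect_identical(cr@fivePrimeFragment, 13L)
    expect_identical(cr@retainedSegment, 7L)
    expect_identical(cr@postCleavageLength, 51L)
    expect_identical(postCleavageLengthRange(d), c(51L, 57L))

    ## fragment sizes span 7..13 nt, so the remainder is 51..57 nt
    expect_identical(range(enumerateCompetentLinkages(d)), c(7L, 13L))
})

test_that("singleton and empty competent sets behave per contract", {
    ## single competent linkage: main cut equals it
    r <- modifiedStrand("r", c("A", "A", "A"), sugars = c("DNA", "RNA", "DNA"))
    dd <- modifiedStrand("dd", "TTT")
    dup <- pairStrands(r, c(1, 3), dd, c(1, 3))
    cr <- predictMainCut(dup, r, dd, cleavedStrand = "r")
    expect_identical(cr@mainCut, 2L)
    expect_identical(cr@fivePrimeFragment + cr@postCleavageLength,
                     strandLength(r))

    ## no competent linkage: no-cut error for cut and range alike
    m <- modifiedStrand("m", "UUU", sugars = "OME")
    r3 <- modifiedStrand("r3", "AAA", sugars = "RNA")
    dupM <- pairStrands(r3, c(1, 3), m, c(1, 3))
    expect_error(predictMainCut(dupM, r3, m), "no RNase H-competent")
    expect_error(postCleavageLengthRange(dupM, r3, m), "no RNase H-competent")
})

test_that("fragment conservation and modification monotonicity hold", {
    d <- defaultDesign()
    s4 <- rnaStrand(d); s1 <- designStrand(d, "S1")
    edge <- gapmerEdge(d)
    base <- length(enumerateCompetentLinkages(d))
    n4 <- strandLength(s4)

    ## every competent cut conserves total length
    for (cut in enumerateCompetentLinkages(d))
        expect_identical(cut + (n4 - cut), n4)

    ## adding one modification at any paired S4 position never increases
    ## the competent count
    set.seed(19)
    for (pos in sample(1:20, 8)) {
        mod <- d
        s <- mod@strands$S4
        s@sugar[pos] <- if (s@base[pos] == "U") "OME" else "LNA"
        mod@strands$S4 <- s
        expect_lte(length(enumerateCompetentLinkages(mod)), base)
    }
})

test_that("the main cut ignores strand sequence outside the duplex", {
    ## same duplex region, different 3' tails: identical cut
    mk <- function(tail) {
        r <- modifiedStrand("r", paste0("ACGUA", tail),
            sugars = c(rep("RNA", 5), rep("DNA", nchar(tail))))
        dd <- modifiedStrand("dd", "TACGT")
        list(r = r, dup = pairStrands(r, c(1, 5), dd, c(1, 5)), dd = dd)
    }
    x1 <- mk("GG"); x2 <- mk("GGTTAC")
    c1 <- predictMainCut(x1$dup, x1$r, x1$dd)
    c2 <- predictMainCut(x2$dup, x2$r, x2$dd)
    expect_identical(c1@mainCut, c2@mainCut)
    expect_identical(c1@fivePrimeFragment, c2@fivePrimeFragment)
})

test_that("target cleavage applies the same rule under the declared register", {
    d <- defaultDesign()
    gap <- extractGapmer(d)
    tg <- generateTarget(d, seed = 4)
    dup <- pairTargetToGapmer(tg, gap)
    expect_identical(nPairs(dup), 20L)

    cr <- cleaveTargetDuplex(dup, tg, gap)
    ## competent target linkages are those across the gapmer's DNA block
    expect_identical(cr@competentLinkages, 9:15)
    expect_identical(cr@mainCut, max(cr@competentLinkages))

    ## a steric blocker (all-2'-OMe in place of the gapmer) cannot recruit
    ## RNase H: no-cut error
    blocker <- modifiedStrand("blocker", bases(gap), sugars = "OME",
        linkages = linkages(gap))
    blocker@base <- chartr("T", "U", blocker@base)
    dupB <- pairStrands(tg, c(3, 22), blocker, c(1, 20))
    expect_error(cleaveTargetDuplex(dupB, tg, blocker), "no RNase H-competent")

    ## only an all-RNA strand is a legal target
    expect_error(cleaveTargetDuplex(dup, gap, tg), "all-RNA")
})
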