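test_that("gapmer patterns reproduce wing / central-block layouts", {
    ## 20-nt, 4xLNA + 2xOME wings, 3 PS per end
    g <- buildGapmerPattern(defaultGapmerScheme())
    expect_identical(sugars(g),
        c(rep("LNA", 4), rep("OME", 2), rep("DNA", 8), rep("OME", 2), rep("LNA", 4)))
    r <- rle(sugars(g))
    expect_identical(max(r$lengths[r$values == "DNA"]), 8L)
    expect_identical(which(linkages(g) == "PS"), c(1:3, 17:19))
    expect_identical(locusRange(g, "central_block"), 7:14)

    ## empty wing: all-DNA, no PS
    g0 <- buildGapmerPattern(gapmerScheme(20L))
    expect_true(all(sugars(g0) == "DNA"))
    expect_false(any(linkages(g0) == "PS"))

    ## 14-nt design with 2xLNA + 1xOME wings also leaves an 8-nt DNA core
    g14 <- buildGapmerPattern(gapmerScheme(14L, c("LNA", "LNA", "OME")))
    r14 <- rle(sugars(g14))
    expect_identical(r14$lengths[r14$values == "DNA"], 8L)

    ## full-length uniform wing expresses the 2'-OMe steric-blocker control
    ctrl <- buildGapmerPattern(gapmerScheme(20L, rep("OME", 20L), psPerEnd = 3L))
    expect_true(all(sugars(ctrl) == "OME"))
    expect_identical(which(linkages(ctrl) == "PS"), c(1:3, 17:19))

    ## an overlapping non-uniform wing is an invalid scheme
    expect_error(gapmerScheme(10L, c(rep("LNA", 5), "OME")),
                 "wing longer than half")
})

test_that("gapmer construction conserves length and mirror symmetry", {
    set.seed(42)
    for (i in 1:25) {
        n <- sample(10:30, 1)
        w <- sample(0:(n %/% 2), 1)
        wing <- if (w) sample(c("LNA", "OME"), w, replace = TRUE) else character()
        g <- buildGapmerPattern(gapmerScheme(n, wing))
        expect_identical(strandLength(g), n)
        ## wing + central + wing accounts for every position
        expect_identical(sum(sugars(g) == "DNA") + 2L * w, n)
        ## the symmetric scheme reads the same 5'->3' and 3'->5'
        expect_identical(sugars(g), rev(sugars(g)))
    }
})

test_that("strand validity enforces the chemistry alphabet", {
    expect_error(modifiedStrand("x", "ACGU", sugars = "DNA"),
                 "U is not allowed")
    expect_error(modifiedStrand("x", "ACGU", sugars = c("DNA", "DNA", "DNA", "LNA")),
                 "U is not allowed")
    expect_silent(modifiedStrand("x", "ACGU", sugars = "OME"))
    expect_error(modifiedStrand("x", "ACGX"), "invalid base")
    expect_error(modifiedStrand("x", "ACG", loci = list(bad = c(1L, 9L))),
                 "not a valid range")
    expect_error(
        modifiedStrand("x", "ACGTA",
            loci = list(a = c(1L, 3L), b = c(3L, 5L))),
        "overlaps")
})

test_that("pairStrands builds antiparallel Watson-Crick maps and flags mismatches", {
    a <- modifiedStrand("r", "ACGU", sugars = "RNA")
    b <- modifiedStrand("d", "ACGT")
    dup <- pairStrands(a, c(1, 4), b, c(1, 4))
    expect_identical(nPairs(dup), 4L)
    expect_identical(dup@posB, 4:1)

    bad <- modifiedStrand("d2", "ACGA")
    expect_error(pairStrands(a, c(1, 4), bad, c(1, 4)), "r:1/d2:4")

    ## unequal ranges are rejected up front
    expect_error(pairStrands(a, c(1, 3), b, c(1, 4)), "equal length")
})

test_that("pairing is involutive in strand roles", {
    d <- defaultDesign()
    s1 <- designStrand(d, "S1"); s4 <- designStrand(d, "S4")
    fwd <- pairStrands(s4, c(1, 20), s1, c(45, 64))
    rev_ <- pairStrands(s1, c(45, 64), s4, c(1, 20))
    expect_setequal(paste(fwd@posA, fwd@posB), paste(rev_@posB, rev_@posA))
})

test_that("the gapmer pairs the generated strand in the standard register", {
    d <- defaultDesign()
    gap <- extractGapmer(d)
    s4 <- rnaStrand(d)
    dup <- gapmerEdge(d)
    expect_identical(nPairs(dup), 20L)
    ## brute-force check of every pair: antiparallel and complementary
    s1 <- designStrand(d, "S1")
    for (i in seq_len(20)) {
        pa <- dup@posA[i]; pb <- dup@posB[i]
        ba <- bases(s1)[pa]; bb <- bases(s4)[pb]
        comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")[ba]
        expect_true(bb == comp || (comp == "T" && bb == "U"))
    }
    ## gapmer position 1 sits opposite strand position 20
    g1 <- locusRange(s1, "gapmer")[1L]
    expect_identical(partnerPositions(dup, "S1", g1), 20L)
})

test_that("validateDesign reports forced defects", {
    d <- defaultDesign()
    expect_true(validateDesign(d)$pass)

    ## one substituted base breaks one edge
    broken <- d
    s2 <- broken@strands$S2
    s2@base[5L] <- setdiff(c("A", "C", "G", "T"), s2@base[5L])[1L]
    broken@strands$S2 <- s2
    v <- validateDesign(broken)
    expect_false(v$pass)
    expect_false(all(v$edges))

    ## a gapmer locus spanning a hinge fails integrity
    hinged <- d
    s1 <- hinged@strands$S1
    s1@loci$gapmer <- c(40L, 59L)  # crosses the unpaired 43-44 hinge
    hinged@strands$S1 <- s1
    v2 <- validateDesign(hinged)
    expect_false(v2$pass)
    expect_false(v2$gapmerIntegrity)
})
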