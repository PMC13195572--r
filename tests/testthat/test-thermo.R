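test_that("stack lookups match hand-computed table arithmetic", {
    m <- energyModel()
    ## unmodified DNA/DNA GT stack (key AC on the complementary strand):
    ## dH = -8.4, dS = -22.4 at 310.15 K, 1 M salt
    expect_equal(stackDGValue("AC", "DNA", m), handDG(-8.4, -22.4),
                 tolerance = 1e-12)
    ## rA.dT / rA.dT hybrid stack: dH = -7.8, dS = -21.9
    expect_equal(stackDGValue("AA", "hybrid", m), handDG(-7.8, -21.9),
                 tolerance = 1e-12)
    ## complementary DNA keys carry the same value (strand relabelling)
    expect_identical(stackDGValue("CA", "DNA", m), stackDGValue("TG", "DNA", m))
    expect_error(stackDGValue("AX", "DNA", m), "unknown dinucleotide")
})

test_that("modification increments are additive on top of table values", {
    m <- energyModel()
    a <- modifiedStrand("a", "ACG")
    b <- modifiedStrand("b", "CGT")
    dup <- pairStrands(a, c(1, 3), b, c(1, 3))
    plain <- stackDG(dup, 1, a, b, m)
    expect_equal(plain, stackDGValue("AC", "DNA", m), tolerance = 1e-12)

    ## one LNA partner: table entry + half the LNA increment
    aL <- modifiedStrand("aL", "ACG", sugars = c("LNA", "DNA", "DNA"))
    dupL <- pairStrands(aL, c(1, 3), b, c(1, 3))
    expect_equal(stackDG(dupL, 1, aL, b, m),
                 plain + 0.5 * m@modIncrements[["LNA"]], tolerance = 1e-12)

    ## PS linkage on one strand adds the PS increment at its stack
    aP <- modifiedStrand("aP", "ACG", linkages = c("PS", "PO"))
    dupP <- pairStrands(aP, c(1, 3), b, c(1, 3))
    expect_equal(stackDG(dupP, 1, aP, b, m),
                 plain + m@modIncrements[["PS"]], tolerance = 1e-12)
    expect_equal(stackDG(dupP, 2, aP, b, m),
                 stackDG(dup, 2, a, b, m), tolerance = 1e-12)
})

test_that("duplex free energy equals the hand-summed stack decomposition", {
    m <- energyModel()
    a <- modifiedStrand("a", "ACGTT")
    b <- modifiedStrand("b", "AACGT")
    dup <- pairStrands(a, c(1, 5), b, c(1, 5))
    ## independent hand sum over the four steps AC, CG, GT, TT
    hand <- m@initDG +
        handDG(-8.4, -22.4) +  # AC
        handDG(-10.6, -27.2) + # CG
        handDG(-8.4, -22.4) +  # GT
        handDG(-7.9, -22.2)    # TT
    expect_equal(duplexDG(dup, a, b, m), hand, tolerance = 1e-12)

    expect_error(duplexDG(pairStrands(a, c(1, 1), b, c(5, 5)), a, b, m),
                 "too short")
    tab <- stackTable(dup, a, b, m)
    expect_identical(nrow(tab), 5L)
    expect_equal(sum(tab$dG), duplexDG(dup, a, b, m), tolerance = 1e-12)
})

test_that("relabelling strands never changes the duplex energy", {
    m <- energyModel()
    set.seed(7)
    for (i in 1:20) {
        n <- sample(3:10, 1)
        sq <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
        a <- modifiedStrand("a", sq,
            sugars = sample(c("DNA", "LNA"), n, replace = TRUE))
        b <- modifiedStrand("b", rev(chartr("ACGT", "TGCA", sq)))
        dup <- pairStrands(a, c(1, n), b, c(1, n))
        swapped <- new("DuplexMap", strandA = "b", strandB = "a",
                       posA = dup@posB, posB = dup@posA)
        expect_equal(duplexDG(dup, a, b, m), duplexDG(swapped, b, a, m),
                     tolerance = 1e-12)
    }
})

test_that("zeroed increments recover unmodified energies exactly", {
    m0 <- energyModel(modIncrements = c(LNA = 0, OME = 0, PS = 0))
    n <- 6L
    set.seed(11)
    sq <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    comp <- rev(chartr("ACGT", "TGCA", sq))

    ## LNA-modified vs plain DNA (same chemistry class)
    aL <- modifiedStrand("aL", sq, sugars = c("LNA", "LNA", rep("DNA", 4)),
                         linkages = "PS")
    a <- modifiedStrand("a", sq)
    b <- modifiedStrand("b", comp)
    dupL <- pairStrands(aL, c(1, n), b, c(1, n))
    dup <- pairStrands(a, c(1, n), b, c(1, n))
    expect_equal(duplexDG(dupL, aL, b, m0), duplexDG(dup, a, b, m0),
                 tolerance = 1e-12)

    ## 2'-OMe-modified vs plain RNA (both hybrid class)
    sqU <- chartr("T", "U", sq)
    aM <- modifiedStrand("aM", sqU, sugars = c("OME", "OME", rep("RNA", 4)))
    aR <- modifiedStrand("aR", sqU, sugars = "RNA")
    dupM <- pairStrands(aM, c(1, n), b, c(1, n))
    dupR <- pairStrands(aR, c(1, n), b, c(1, n))
    expect_equal(duplexDG(dupM, aM, b, m0), duplexDG(dupR, aR, b, m0),
                 tolerance = 1e-12)
})

test_that("segment energies are additive and extension stabilizes", {
    m <- energyModel()
    set.seed(23)
    for (i in 1:10) {
        n <- sample(6:12, 1)
        sq <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
        a <- modifiedStrand("a", sq)
        b <- modifiedStrand("b", rev(chartr("ACGT", "TGCA", sq)))
        dup <- pairStrands(a, c(1, n), b, c(1, n))

        ## split at an interior pair shared by both halves
        k <- sample(2:(n - 1), 1)
        left <- pairStrands(a, c(1, k), b, c(n - k + 1, n))
        right <- pairStrands(a, c(k, n), b, c(1, n - k + 1))
        expect_equal(duplexDG(left, a, b, m) + duplexDG(right, a, b, m) - m@initDG,
                     duplexDG(dup, a, b, m), tolerance = 1e-9)

        ## dropping the terminal pair always destabilizes at 310 K
        shorter <- pairStrands(a, c(1, n - 1), b, c(2, n))
        expect_lt(duplexDG(dup, a, b, m), duplexDG(shorter, a, b, m))
    }
})
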