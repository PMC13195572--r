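## Shared fixtures, built in code. The default design is cached per seed
## because several files exercise the same layout.

.designCache <- new.env(parent = emptyenv())

defaultDesign <- function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(.designCache[[key]]))
        .designCache[[key]] <- generateDesign(generatorSpec(), seed = seed)
    .designCache[[key]]
}

## energy model with every energetic term zeroed (flat-landscape oracle)
zeroEnergyModel <- function() {
    m <- energyModel(modIncrements = c(LNA = 0, OME = 0, PS = 0),
                     initDG = 0, tetherInitDG = 0, bmPlateauDG = 0)
    m@nnDNAdH[] <- 0; m@nnDNAdS[] <- 0
    m@nnHybDH[] <- 0; m@nnHybDS[] <- 0
    m
}

## independent dG-from-table arithmetic used as the hand-sum oracle
handDG <- function(dH, dS, tempK = 310.15) dH - tempK * dS / 1000

RT310 <- 1.98720425e-3 * 310.15

## tiny single-reaction network (A -> B) for kinetics oracles
abNetwork <- function(k = 0.5, nA = 1000L) {
    new("ReactionNetwork",
        species = c(A = nA, B = 0),
        reactions = list(list(name = "decay", reactants = c(A = 1L),
                              products = c(B = 1L), rate = k)),
        conservations = list(total = c("A", "B")),
        params = list())
}
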