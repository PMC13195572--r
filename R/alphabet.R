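## Internal alphabet and complement rules shared across the package.
## Pairing is strictly Watson-Crick: A-T, A-U, G-C (no G-U wobble).

.BASES  <- c("A", "C", "G", "T", "U")
.SUGARS <- c("DNA", "RNA", "LNA", "OME")
.LINKS  <- c("PO", "PS")

## sugars treated as chemically modified for the RNase H competence rule
.MOD_SUGARS <- c("LNA", "OME")

## one-letter sidecar codes for sugars and linkages
.SUGAR_CODE <- c(DNA = "D", RNA = "R", LNA = "L", OME = "M")
.LINK_CODE  <- c(PO = "o", PS = "s")

## gas constant, kcal/(mol K)
.RGAS <- 1.98720425e-3

.isWatsonCrick <- function(b1, b2) {
    (b1 == "A" & (b2 == "T" | b2 == "U")) |
    ((b1 == "T" | b1 == "U") & b2 == "A") |
    (b1 == "G" & b2 == "C") |
    (b1 == "C" & b2 == "G")
}

## complement of a base written in the alphabet of the partner sugar
.complementBase <- function(base, partnerSugar = "DNA") {
    ut <- ifelse(partnerSugar %in% c("RNA", "OME"), "U", "T")
    out <- character(length(base))
    out[base == "A"] <- ut[base == "A"]
    out[base == "T" | base == "U"] <- "A"
    out[base == "G"] <- "C"
    out[base == "C"] <- "G"
    out
}

.revcompBases <- function(bases, partnerSugar = "DNA") {
    rev(.complementBase(bases, rep_len(partnerSugar, length(bases))))
}

.rt <- function(model) .RGAS * model@temperature
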