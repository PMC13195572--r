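## Nearest-neighbor parameter sets shipped as package defaults.
## Units: dH kcal/mol, dS cal/(mol K). Tables are referenced to 1 M NaCl.

## Unified DNA:DNA set. Keyed by the top-strand dinucleotide read 5'->3';
## complementary keys carry the same value, so swapping which strand is
## labelled "top" never changes a lookup.
.NN_DNA_DH <- c(
    AA = -7.9,  TT = -7.9,
    AT = -7.2,
    TA = -7.2,
    CA = -8.5,  TG = -8.5,
    GT = -8.4,  AC = -8.4,
    CT = -7.8,  AG = -7.8,
    GA = -8.2,  TC = -8.2,
    CG = -10.6,
    GC = -9.8,
    GG = -8.0,  CC = -8.0)

.NN_DNA_DS <- c(
    AA = -22.2, TT = -22.2,
    AT = -20.4,
    TA = -21.3,
    CA = -22.7, TG = -22.7,
    GT = -22.4, AC = -22.4,
    CT = -21.0, AG = -21.0,
    GA = -22.2, TC = -22.2,
    CG = -27.2,
    GC = -24.4,
    GG = -19.9, CC = -19.9)

## RNA:DNA hybrid set (rNN/dNN). Keyed by the RNA-strand dinucleotide read
## 5'->3' in the U alphabet; the DNA partner is its complement.
.NN_HYB_DH <- c(
    AA = -7.8,  AC = -5.9,  AG = -9.1,  AU = -8.3,
    CA = -9.0,  CC = -9.3,  CG = -16.3, CU = -7.0,
    GA = -5.5,  GC = -8.0,  GG = -12.8, GU = -7.8,
    UA = -7.8,  UC = -8.6,  UG = -10.4, UU = -11.5)

.NN_HYB_DS <- c(
    AA = -21.9, AC = -12.3, AG = -23.5, AU = -23.9,
    CA = -26.1, CC = -23.2, CG = -47.1, CU = -19.7,
    GA = -13.5, GC = -17.1, GG = -31.9, GU = -21.6,
    UA = -23.2, UC = -22.9, UG = -28.4, UU = -36.4)
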