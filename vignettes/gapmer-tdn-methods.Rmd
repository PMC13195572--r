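---
title: "Modelling the catalytic cycle of a gapmer-bearing DNA tetrahedron"
author: "gapmerTDN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the catalytic cycle of a gapmer-bearing DNA tetrahedron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapmerTDN)
```

# The system

A tetrahedral DNA nanostructure (TDN) self-assembles from four
oligonucleotide strands; each of the six edges is a duplex and each vertex
leaves a few unpaired hinge nucleotides. In the design modelled here, one
strand encodes a 20-nt antisense *gapmer* — a central block of 8 unmodified
DNA nucleotides flanked on each side by wings of four locked-nucleic-acid
(LNA) and two 2′-O-methyl (2′-O-Me) nucleotides, with three
phosphorothioate (PS) linkages at each end. The partner strand on that edge
carries a 10-nt RNA block starting at its seventh nucleotide, hybridised
onward by 6 nt of unmodified DNA, forming a DNA:RNA heteroduplex inside the
framework. RNase H cleaves the RNA strand of such a heteroduplex; the
resulting single-stranded toehold lets a complementary target RNA (a
miRNA mimic) invade, be cleaved in turn, and regenerate the site — a
catalytic cycle.

The package models this mechanism at base-pair resolution: cleavage-site
chemistry rules, nearest-neighbor hybridisation thermodynamics, discrete
free-energy landscapes for toehold exposure and strand displacement
(sampled exactly and by Monte Carlo), and a stochastic reaction network for
the cycle. Everything runs on synthetic designs from `generateDesign()`
because the physical strand sequences are not distributed with the package.

# The synthetic design generator

`generatorSpec()` fixes the study conditions:

* `edgeBP = 20`, `hingeNT = 2`: each strand traverses three 20-bp edges
  with 2 unpaired nt per internal vertex passage, so every strand is
  3 × 20 + 2 × 2 = 64 nt. This pins the RNA-containing strand to 64 nt,
  the length required for the 51–57-nt post-cleavage arithmetic
  (64 − 13 = 51).
* the gapmer occupies the third edge segment of strand S1 (positions
  45–64) and pairs positions 1–20 of the RNA-containing strand S4 in the
  standard antiparallel register (gapmer position 1 ↔ S4 position 20).
* S4 carries RNA sugars at positions 7–16 and unmodified DNA at 17–22
  (the flank), so the gapmer's central DNA block (gapmer positions 7–14)
  faces S4 positions 7–14.
* sequences are uniform random draws subject to per-strand GC fraction in
  [0.4, 0.6] and a cross-talk screen: no unintended antiparallel
  complementary run of ≥ 9 nt anywhere in the strand set (intended edge
  pairs are masked). Nine is chosen as the tightest bound random 64-nt
  sequences satisfy with acceptably few retries; it stands in for an
  ensemble-level sequence-design procedure, which is out of scope.

What the generator does **not** emulate: the actual published strand
sequences, the exact hinge layout and nick placement, G-quadruplex or other
secondary-structure pathologies, and any thermodynamic-ensemble
orthogonality beyond the k-mer screen. Tests passing on these designs
therefore validate the *rules and algorithms*, not sequence-specific
behaviour of any particular synthesis.

The cleavage arithmetic below depends only on this layout, never on the
drawn sequence — the test suite checks it across 100 seeds.

# RNase H cleavage rule

Linkage *i* of the cleaved strand (between nucleotides *i* and *i* + 1) is
competent iff

1. nucleotide *i* carries an RNA sugar, and
2. the base pairs at positions *i* and *i* + 1 both exist and involve no
   sugar-modified nucleotide (LNA or 2′-O-Me) on either strand.

PS linkages do not block cleavage. The *main cut* is the 3′-most competent
linkage — the cut toward the RNA 3′ end, immediately before the first
modified base pair. On the default layout this yields competent linkages
7|8 … 13|14, a 13-nt 5′ fragment, a 7-nt retained segment still hybridised
and covalently continuous with the framework, and a 51–57-nt range for the
covalent remainder:

```{r cleavage}
design <- generateDesign(generatorSpec(), seed = 1)
predictMainCut(design)
postCleavageLengthRange(design)
```

This two-flanking-pairs rule is the minimal one that simultaneously
reproduces all three observables; single-pair variants overshoot the cut
window. Only the main cut is propagated downstream; minor-site frequencies
are not modelled.

# Nearest-neighbor thermodynamics

`energyModel()` combines the unified DNA:DNA nearest-neighbor ΔH/ΔS set
with a published RNA:DNA hybrid set (keyed by the RNA-strand dinucleotide).
A step is scored from the hybrid table when any of its four nucleotides
carries a ribose-type sugar (RNA or 2′-O-Me). Chemistry increments are
additive free energies: −1.0 kcal/mol per LNA-containing pair and
−0.2 per 2′-O-Me pair (split half/half over the two adjacent stacks),
+0.1 kcal/mol per PS linkage at the stack spanning it. These defaults
respect the affinity ranking LNA > 2′-O-Me > unmodified but are
order-of-magnitude placeholders — no thermodynamic parameters are published
for this construct — and every knob is a constructor argument.

Temperature enters as ΔG(T) = ΔH − TΔS/1000 (default 310.15 K); salt as a
uniform per-stack entropic term −0.368·T·ln[Na⁺]/1000, zero at the 1 M
table reference. Dangling ends and coaxial stacking at nicks are ignored;
the tetrahedral context enters only through the tether initiation term
below.

# Landscapes

**Toehold fraying.** The 7-bp retained segment opens as a single-coordinate
zipper from the cut-created free end; state *s* counts intact base pairs
from the anchored (framework-continuous) end. Interior bubbles are
excluded: a 1-D zipper keeps the state space exactly enumerable, which is
what makes the samplers verifiable. Every bound state pays the tether
initiation penalty `tetherInitDG` (default 2 kcal/mol); the fully open
state pays none, so re-closing the first pair carries an entropic barrier,
as expected for a tethered segment whose partner cannot diffuse away.

`toeholdAvailability()` reports exact Boltzmann occupancies. "Open" means
all retained pairs open (*s* = 0) by default; `openMaxIntact` exposes the
partial-availability alternative. `deltaGOpen` compares the two landscape
endpoints (fully bound vs fully open).

With the default nearest-neighbor tables the 7-bp segment opens at
≈ 10 kcal/mol — the stock parameters overestimate the stability of this
short modified hybrid relative to coarse-grained simulation estimates of
about 3 kcal/mol for the same construct. `calibrateToeholdModel()` therefore
rescales the modification increments by a single factor so that
`deltaGOpen` matches a supplied value; the calibration is explicit (the
factor is attached to the returned model) and never silent. The headline
availability number uses the printed 3 kcal/mol directly on a two-state
landscape: at 310.15 K the open fraction is
`exp(-3/RT)/(1+exp(-3/RT))` ≈ 0.76 %, i.e. below 1 %.

**Strand displacement.** Progress is the number of invader (target) base
pairs formed, from 0 to toehold + incumbent (7 + 13 = 20). Toehold
zippering accrues invader stacks; each branch-migration step exchanges one
incumbent pair for one invader pair and passes an intermediate plateau of
height `bmPlateauDG` (default 2 kcal/mol, the order of measured
branch-migration step barriers). Plateau intermediates are genuine states
on a doubled coordinate (2*m* for pair states, 2*m* + 1 for plateaus), so
barriers can be read directly off the landscape. The incumbent keeps its
initiation penalty while bound and is credited its dissociation entropy
once, at full displacement; the invader, arriving from solution, pays the
standard initiation on its first pair. With the 22-nt target against the
13-nt incumbent the final state is the global minimum — displacement is
thermodynamically driven by the toehold:

```{r displacement}
target <- generateTarget(design, seed = 1)
disp <- displacementLandscape(design, target)
range(stateEnergies(disp))
stateCoordinates(disp)[which.min(stateEnergies(disp))] / 2  # invader bp
```

The target register (2-nt overhang at the target 5′ end) is a declared
assumption; it shifts which target linkage is cut but none of the
landscape dimensions.

# Monte Carlo and umbrella sampling

`metropolisSample()` runs single-state-increment Metropolis moves
(±1 with equal proposal probability, reflecting ends via rejection), which
satisfy detailed balance on the discrete landscape. Cluster or virtual
moves are unnecessary in one dimension. The point of the sampler is
methodological verification: `exactOccupancy()` enumerates the same
landscape exactly, so sampling error is measurable rather than assumed.
Umbrella windows (`harmonicWindows()`, default stiffness 1 kcal/mol per
state² with one window per state) capture rare open states;
`reweight()` recombines the biased histograms by iterative multi-histogram
reweighting, converged when successive window shifts change by less than
10⁻⁸ kcal/mol, anchored to the reference state. Windows that share no
visited state raise an error rather than extrapolating.

Budgets used throughout: 10⁶ unbiased steps and 10⁵ steps per window.
At these budgets the round trip landscape → sample → reweight recovers
every state of the default 8-state fraying landscape to better than
0.1 kcal/mol, and the unbiased histogram sits within total-variation 0.02
of the exact occupancies. Seeds are recorded in every histogram; one seed
reproduces an entire window set.

# The catalytic cycle

`buildCycleNetwork()` assembles eight species and seven mass-action
reactions: cleave (TDN heteroduplex) → open ⇌ close → bind target ⇌
unbind → displace incumbent → cleave target → regenerate.

Thermodynamic consistency is imposed, not fitted:
k_open/k_close = exp(−ΔG_open/RT), with ΔG_open taken from the landscape
stage (the printed 3 kcal/mol in the headline runs). The displacement rate
is `dispPrefactor · exp(−barrier/RT)` with the barrier read off the
displacement landscape. RNase H is implicit — pseudo-first-order cleavage
at 10⁻³ s⁻¹ on heteroduplex species — because no enzyme concentration or
turnover number is available; all rate parameters are labelled
placeholders and are constructor arguments.

Two deliberate simplifications:

* `kClose` defaults to 1 s⁻¹. Only the open/close *ratio* is physically
  constrained; the absolute scale merely sets how often the toehold flaps.
  A diffusion-limited closing rate (10³ s⁻¹ or more) would multiply the
  event count of an exact stochastic trajectory a thousand-fold without
  changing any occupancy or flux ratio, so the package keeps the
  slow-flapping equivalent as its default and exposes the knob.
* After target cleavage both product fragments dissociate instantly and
  the site regenerates to the open state; the re-closed state is shared
  with the incumbent-held closed state, so `fragment13_free` counts
  displacement *events* (an upper bound on distinct fragments after the
  first turnover round). The stated conservation laws — total TDN sites
  and total targets — hold exactly at every recorded time.

`gillespieSimulate()` is an exact direct-method simulator;
`odeSimulate()` integrates the same propensities as mean-field ODEs
(deSolve/lsoda, tolerances 10⁻¹⁰). Default initial condition is 100 TDN
sites and 1000 targets (1:10) at an effective 20 nM target concentration;
a 10⁵-s horizon yields several cleaved targets per site — catalytic
turnover:

```{r cycle, eval = FALSE}
occ <- toeholdAvailability(twoStateLandscape(3))
net <- buildCycleNetwork(occ, disp, cycleRates())
traj <- gillespieSimulate(net, tEnd = 1e5, seed = 1)
tail(traj@counts, 1)
rateLimitingReport(net, traj)
```

`rateLimitingReport()` attributes waiting time per product to each
productive step (time-averaged source-species occupancy divided by cycle
throughput) and flags the largest. Under defaults sites overwhelmingly wait
in the closed state, so toehold opening is flagged — availability of the
single-stranded toehold limits target binding. Accelerating opening
100-fold moves the flag to the implicit RNase H step on the re-formed
duplex, confirming the metric responds to the intended perturbation.

# Numerical choices and degenerate inputs

* Positions are 1-based, ranges closed, throughout. U never sits on DNA or
  LNA sugars; LNA carries T.
* G–U wobble is rejected everywhere: designs are strictly Watson–Crick.
* Landscape reference states carry dG = 0 exactly; Boltzmann weights are
  computed after subtracting the state minimum, so large landscapes cannot
  overflow.
* Duplex energies require ≥ 2 bp; fraying requires a ≥ 2-bp retained
  segment; empty competent-cut sets are an error for `predictMainCut()`
  but an empty *enumeration* (no RNA in the duplex) is a legal result.
* The generator retries a bounded number of times and reports the violated
  constraint; GC bounds of (0, 0) fail fast and informatively.
* Ties in `which.max`/`which.min` (flat landscapes, equal waiting times)
  resolve to the first index — stable and documented rather than random.

# Problem sizes

The shipped tests and the acceptance script use the sizes the methods were
designed around: 64-nt strands, 8-state fraying landscapes, 34-state
displacement landscapes, 10⁶-step unbiased chains, 8 × 10⁵ umbrella steps,
single 10⁵-s stochastic trajectories (~1.5 × 10⁵ events) and a 100-seed
ensemble at 200 sites / 2000 targets for the mean-field comparison. These
are desk-scale by intent: each quantity the package claims is recomputed
from scratch in seconds on one core.

# Known limitations

* The nearest-neighbor defaults are literature tables plus uncalibrated
  increments; absolute free energies of short modified hybrids should be
  treated as provisional until calibrated against a measured or simulated
  ΔG (the calibration hook exists and is exact).
* The zipper and sawtooth landscapes exclude bubbles, misaligned
  registers, and coaxial stacking at the cut nick.
* The kinetic rates are placeholders; the simulator demonstrates the
  cycle's logic (conservation, thermodynamic consistency, turnover > 1,
  the availability bottleneck), not quantitative time courses.
* Tetrahedron height ignores the helix diameter; it is the edge-skeleton
  height of a regular tetrahedron.
* DLS conversion assumes spherical scatterers in the Rayleigh d⁶ regime.
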