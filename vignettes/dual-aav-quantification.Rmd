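---
title: "Quantifying dual-AAV transgene reconstitution by droplet digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dual-AAV transgene reconstitution by droplet digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualAAVquant)
```

## The problem

A transgene too large for one adeno-associated virus (AAV) can be split
across two vectors that share a homologous overlap. After co-transduction,
homologous recombination (HR) of the overlap reconstitutes the full coding
sequence at the DNA level. Two competing fates threaten this design: the
inverted terminal repeats (ITRs) at the ends of every vector genome can
join genomes into concatemers in three orientations (head-to-tail,
head-to-head, tail-to-tail), and the single vectors might express truncated
products on their own. Dosing and safety both hinge on knowing how often
each fate occurs, which is what this package quantifies.

The concrete system modeled here is a split "quasidystrophin" cassette: a
5' vector carrying a muscle-specific promoter (sp512), chimeric intron,
Kozak sequence and the amino-terminal half of the coding sequence, and a
promoterless 3' vector carrying the carboxy-terminal half and the SV40
polyA. The two halves share an 800 bp homologous region; each construct
stays within the ~4.7 kb ITR-to-ITR packaging capacity of AAV.

## Assay design

All quantification runs on droplet digital PCR (ddPCR). A reaction is
partitioned into ~20,000 droplets; a template molecule ends up in a given
droplet following Poisson statistics, so the fraction of positive droplets
$\hat p = k/N$ yields the absolute concentration through
$\hat\lambda = -\ln(1-\hat p)$ copies per droplet.

The panel built by `default_assay_panel()`:

* **FIVE**, **THREE** — primer pairs entirely inside the unique region of
  each vector; count all delivered 5' and 3' genome units.
* **REC** — forward primer in the 5'-unique region just upstream of the
  overlap, reverse primer in the 3'-unique region just downstream. Only a
  molecule that carries the reconstituted overlap in one piece amplifies;
  the intact amplicon is 900 bp.
* **TTN** — a diploid host reference locus (Titin, two copies per genome)
  used to normalize copy numbers.
* **jxAB, jxCD, jxAD, jxCB** — the ITR-junction panel (below).
* **FIVE_RT, THREE_RT, REC_RT** — transcript assays.

Two restriction digests make the concentrations interpretable:

* **SmaI** cuts once inside every ITR. A head-to-tail concatemer of a 5'
  and a 3' genome presents the same primer-facing geometry as a true HR
  product, but it retains the two ITRs at its junction; SmaI pre-digestion
  therefore separates the REC primer sites of concatemers while leaving HR
  molecules (whose internal ITRs were resolved by elimination during
  recombination) intact. It also cuts every unit of a chain apart, so
  FIVE/THREE count units rather than molecules.
* **AleI** cuts exactly once per vector unit, outside ITRs and outside the
  overlap. After AleI, a concatemer of any length falls into fragments
  carrying at most one ITR junction each, short enough for PCR.

### The junction panel

Four primers sit just inside the four vector ends: A near the 5' vector's
overlap-proximal (right) ITR, B near the 3' vector's overlap-proximal
(left) ITR, and C and D at the opposite ends. A and B bind inside the
shared overlap, with A placed *after* B in overlap coordinates and both
pointing outward: on any single intact molecule — in particular a pure HR
product — A and B face away from each other and nothing amplifies. Across
an ITR junction, the outward primers of the two joined ends converge and
do amplify; at a palindromic junction (e.g. tail-to-tail of two 5'
genomes) one primer serves as both forward and reverse.

Each junction is therefore labeled by the unordered pair of outward
primers that flank it. The four two-primer reactions partition the
junction classes they are designed for:

| reaction | junction classes counted |
|----------|--------------------------|
| jxAB     | A–B (5'→3' head-to-tail), A–A, B–B (palindromic flips at the overlap-proximal ends) |
| jxCD     | C–D (3'→5' head-to-tail), C–C, D–D |
| jxAD     | A–D (5'/3' tail-to-tail) |
| jxCB     | C–B (5'/3' head-to-head) |

Two design consequences are worth stating plainly. First, same-identity
tandem junctions (5'→5' or 3'→3' head-to-tail, classes A–C and B–D) are
invisible to all four reactions: no reaction contains both required
primers. The ground-truth census kept by the simulator accordingly counts
*assay-detectable* junctions, so estimator recovery remains well-posed;
the blind spot is a property of the four-primer design itself, not of the
simulation. Second, the multiplexed reaction (all four primers in one
tube) is modeled as the union of the four pair reactions evaluated on the
same droplets, with each palindromic product attributed to the one
reaction designed for it; cross-reaction products that only the full
mixture could form are not modeled. Under this convention the multiplexed
count equals the sum of the four single reactions exactly, which mirrors
the empirical observation that motivates running the mixture in one tube.

## Estimators

With per-assay concentrations $c$ (copies/µL) from the appropriate digest:

* **Vector copy number** (vg per diploid genome):
  $\mathrm{VCN}_x = 2 \, c_x / c_{TTN}$, the ratio to the Titin
  amplification; the factor is the reference ploidy and is configurable.
* **HR efficiency**: $100 \cdot c_{REC} / \min(c_{FIVE}, c_{THREE})$ from
  the SmaI run. The limiting (less abundant) vector sets the ceiling on
  possible recombination events, hence the denominator.
* **Concatemer fraction**:
  $100 \cdot \sum_j c_{jx_j} / (c_{FIVE} + c_{THREE})$ from the AleI run.
  The default uses Poisson-corrected copies; a raw positive-droplet
  variant is available (`poisson_correct = FALSE`).
* **Fold ratio**: HR efficiency over concatemer fraction.
* **Expression specificity**: class-specific RT assays; the verdict is
  "specific" when the 3' signal is below 1% and the 5' leak below 10% of
  the recombined message (both thresholds configurable), with a minus-RT
  control guarding against genomic contamination.

Confidence intervals use the delta method on the Poisson scale,
$\mathrm{se}(\hat\lambda) = \sqrt{\hat p / (N(1-\hat p))}$, propagated to
ratios by first-order error analysis; an exact binomial option exists.
This is standard digital-PCR practice; the acceptance suite verifies 93–97%
empirical coverage at $N = 20{,}000$ droplets over $\lambda$ from 0.01 to 2.

```{r example}
cs <- build_default_constructs()
panel <- default_assay_panel(cs$five_prime, cs$three_prime)
p <- sim_params(u5 = 8, u3 = 12, hr_fraction = 0.5,
                concat_fraction = phi_for_concat_target(0.04,
                  sim_params(hr_fraction = 0.5)),
                host_genomes = 10000, seed = 7)
out <- simulate_and_quantify(p, n_droplets = 20000)
out$report
```

## The synthetic-data generator

`simulate_sample()` draws the molecule population the assays see:

* Delivered units $T_5 \sim \mathrm{Pois}(u_5 G)$,
  $T_3 \sim \mathrm{Pois}(u_3 G)$ for $G$ diploid genomes. Defaults
  $u_5 = 8$, $u_3 = 12$ mirror the observed asymmetry of a higher copy
  number for the 3' vector without asserting its mechanism (differential
  uptake vs genome stability).
* $R = \mathrm{round}(\theta \min(T_5, T_3))$ HR molecules, each one 5'
  unit joined to one 3' unit with the overlap merged once and internal
  ITRs removed. Ground-truth HR is defined exactly as the estimator's
  estimand, $R/\min(T_5,T_3)$, because the assay defines the quantity;
  there is no separate mechanistic "true efficiency".
* Of the remaining units, a fraction $\varphi$ enters linear concatemer
  chains with length $1 + \mathrm{Geometric}(p)$ (mean $1/p$, default
  $p = 0.5$), identities drawn without replacement from the remaining
  pools, and junction types drawn from `orientation_weights`. Junction
  type availability is constrained by the free end of the growing chain (a
  tail end can only form head-to-tail or tail-to-tail), so the weights act
  conditionally on the end state; the unconditional junction-type marginal
  is consequently *not* proportional to the weights — an inherent feature
  of sequential chain growth, and the property the tests check is the
  conditional one. Chain length and orientation distributions are not
  observable in the source system; both are configurable.
* The remainder stays monomeric. Host genomes contribute two intact Titin
  targets each. Every stage keeps exact unit bookkeeping, audited by
  `ground_truth_metrics()`.

`phi_for_concat_target()` inverts the expected assay-detectable junction
fraction analytically, so a scenario can be parameterized directly by the
junction load the assays would report (the bundled reference scenarios
use 4%, the middle of the observed 3–5% range).

Transcripts are simulated per class: full message proportional to $R$
(rate $r$, default 2 per template), premature 5' leak proportional to the
free 5' units (rate $\varepsilon$, default 0.02), and zero aberrant 3'
message for the promoterless 3' construct. The RT assays are modeled as
class-specific: the junction-spanning assay reports only recombined
message, and the single-vector RT assays report only the leak/aberrant
classes. This is an idealization — a region-based model would make the
full-length message positive for all three assays — chosen so that the
specificity verdict measures exactly what the wet protocol's primer
design aims at.

## Droplet simulation and gating

Fragment classes load droplets independently,
$\mathrm{occupancy}_i \sim \mathrm{Pois}(c_i v_d)$ with droplet volume
$v_d = 0.85$ nL and $N = 20{,}000$ droplets by default (standard QX
geometry; class concentrations above $\lambda = 10$ abort as a saturated
run). Calls mode records exact per-assay booleans. Amplitude mode builds
the two-channel cloud grid of probe-concentration multiplexing: channel
amplitude = baseline + amplitude unit × the sum of levels of positive
assays + Gaussian noise. The default level assignment is FIVE = FAM×1,
THREE = FAM×2, REC = VIC×1, TTN = VIC×2 (the dye-to-assay mapping is not
observable and is configurable). Levels 1 and 2 make the four clouds per
channel binary-decodable, so noiseless amplitude gating reproduces calls
mode exactly — a property the tests assert on every panel and seed. Cloud
deconvolution for overlapping clouds, intermediate-amplitude "rain" and
PCR competition are out of scope.

## Numerical and design choices

* Coordinates are 0-based half-open; the plus strand is each construct's
  coding strand. Element lengths are stand-ins that honor the printed
  anchors (800 bp overlap, 900 bp REC amplicon, ≤4700 bp capacity); the
  true sequence is proprietary, so `realize_sequence()` emits seeded
  pseudo-random sequences whose only guaranteed motifs are the declared
  SmaI/AleI sites (spurious motifs are masked outside the shared overlap).
* Digestion is complete (no partials) and operates on structural
  coordinates, not sequences — exact and fast; sequences exist for
  FASTA/BED export only.
* Maximum genomic amplicon is 2500 bp, which deliberately lets an
  *undigested* head-to-tail dimer amplify with the REC primers — the bias
  that motivates SmaI pre-digestion, demonstrated by running the protocol
  without it (`vcn_digestion = "none"`), which strictly inflates the
  apparent HR efficiency.
* Concatemers are linear by default; circular species are supported
  structurally (an uncut circle retains all sites and junctions) but
  amplicons spanning the origin of an uncut circle are not evaluated.
* One global scenario seed fans out into fixed substreams (simulation,
  each reaction's partitioning, transcripts), making full runs
  byte-identical and letting stages re-run independently.

## Study sizes and what the tests do (and do not) show

The acceptance suite runs the estimators at the sizes the method is meant
for: 20,000-droplet reactions on samples of 10,000 diploid genomes (about
2×10^5 vector genomes), 100 seeded replicates for recovery and coverage
studies, 50 for the digestion-bias direction, and 10^4 small populations
for exact conservation checks. Passing them shows the estimators are
consistent and calibrated *under the generative model*: Poisson loading,
complete digestion, perfect specificity, class-clean RT signals. Real
tissue data add partial digestion, rain, inhibitors, pipetting and
dilution error, and an unknown concatemer length/orientation law; none of
these are emulated, so recovered in-silico accuracy bounds real-world
accuracy from below only in the counting-statistics sense.

## Limitations

Same-identity tandem junctions are invisible to the four-primer panel (a
design property, quantified above); absolute in vivo copies/µL are not
reconstructable without the unreported DNA input and dilution factors;
the package models neither AAV production/titration, nor image-based
histology, nor inter-group hypothesis testing — phenotype inputs arrive
as tabulated per-fiber and per-session records.
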