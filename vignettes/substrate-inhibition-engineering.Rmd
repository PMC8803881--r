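---
title: "Designing around substrate inhibition: variant libraries, Haldane kinetics and the flow-restrictor model"
author: "SubInhib maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing around substrate inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SubInhib)
```

## The problem

Lycopene cyclase, the terminal enzyme of the fungal beta-carotene pathway,
is inhibited by its own substrate: its activity curve rises with lycopene
concentration, peaks, and then declines. In a producing strain this turns
the enzyme into a trap — once lycopene accumulates past the peak, the
conversion rate falls, lycopene accumulates further, and the product
spectrum collapses toward the intermediate. SubInhib implements the two
computational strategies used to engineer around this failure mode, plus
the arithmetic used to evaluate fermentations:

1. a conservation-guided **variant design pipeline** that proposes a
   50-member substitution library from a position-specific scoring matrix
   (PSSM);
2. a **kinetic analysis** toolkit that fits and discriminates
   substrate-inhibition (Haldane) versus plain saturation
   (Michaelis–Menten) rate laws;
3. a **flow-restrictor model** of the GGPP → lycopene → beta-carotene
   segment showing how tuning the upstream supply rate avoids (or
   deliberately triggers) runaway intermediate accumulation;
4. **fermentation metrics**: molar media C/N ratio, OD600→DCW conversion,
   carotenoid selectivity, volumetric productivity and fold improvement.

Because the enzyme's homolog set and raw assay tables are not bundled
with the package, a seeded synthetic-data module generates every input
the pipeline needs; all statistical claims in the test suite are claims
about those synthetic conditions.

## Variant design

### Scoring

Given an L×20 PSSM anchored to a wild-type sequence (built from an
alignment with `buildPSSM()`, or read from a psiblast ASCII file with
`readPSSM()`), every substitution at every position is scored by the delta

$$\Delta_{i,a} = s(i, a) - s(i, a_{wt,i}),$$

so positive deltas mark replacements by residues more conserved in the
protein family than the wild-type residue. `buildPSSM()` uses the
half-bit rounded-integer convention of the psiblast dialect,

$$s(i,a) = \mathrm{round}\left(2\log_2
  \frac{c(i,a) + \beta q_a}{(n_i + \beta)q_a}\right),$$

with gaps excluded from the column counts, a single pseudocount
$\beta = 1$ by default, and a uniform background $q_a = 1/20$. Ties in
the delta ranking are broken by position and then residue alphabet order
so the ranking is a total, reproducible order.

Substitutions **introducing glycine are removed** before ranking
(flag-controlled). Losing a side chain to glycine adds backbone
flexibility that commonly disrupts secondary structure, which is the
usual reason such screens exclude it; removal of substitutions *to* G,
rather than at glycine positions, is the interpretation adopted here.

### Library composition

The defaults of `designParams()` encode the screening scheme:

| parameter | default | meaning |
|---|---|---|
| `n_top` | 25 | top-ranked substitutions paired into doubles |
| `n_clusters` | 25 | clusters over the double pool; one draw each |
| `n_single_lo..hi` | 26..50 | rank window taken verbatim as singles |
| `linkage` | average | agglomerative linkage criterion |
| `pool` | exhaustive | pairing strategy for the top candidates |
| `seed` | — | drives every random choice; recorded in outputs |

The top 25 substitutions are combined into **all** position-disjoint
pairs (C(25,2) = 300 when the positions are distinct): exhaustive
enumeration is used because the subsequent clustering step, whose whole
point is to cut the pool down to a testable number, is only meaningful
when it down-selects from a complete pool — and it reproduces the
25 + 25 = 50 library size. A `pool = "random"` mode subsamples the pool
first for users who prefer a sparser random pairing.

Each double is a full mutated sequence; the distance between two
variants is derived from PAM30 similarities by the self-similarity
centring

$$d(x, y) = \sum_{k:\,x_k \ne y_k}
  \frac{m(x_k,x_k) + m(y_k,y_k)}{2} - m(x_k,y_k),$$

which is zero for identical sequences, symmetric, and local (shared
substitutions contribute nothing). PAM30 — a matrix for closely related
sequences — is the right scale here because variants differ from the
wild type at one or two sites only. Average linkage is the default for
the agglomerative step (the linkage criterion is not dictated by the
procedure being reproduced; complete and single linkage are exposed as
options), and one member per cluster is drawn with the seeded RNG,
spreading the tested doubles across sequence space. Ranks 26–50 enter
the library unchanged as singles. Anything that would silently shrink
the library — too few surviving candidates, a pool smaller than the
cluster count — is a hard error instead.

```{r design}
demo <- system.file("extdata", "synthetic_demo.pssm", package = "SubInhib")
lib <- designLibrary(readPSSM(demo), designParams(seed = 7))
lib
head(designs(lib), 3)
```

## Kinetics

The canonical single-substrate inhibition law (Haldane) is used for the
biphasic curve:

$$v(S) = \frac{V_{max} S}{K_m + S + S^2/K_i},$$

which peaks at $S^* = \sqrt{K_m K_i}$ with
$v(S^*) = V_{max}/(1 + 2\sqrt{K_m/K_i})$ and reduces to
Michaelis–Menten as $K_i \to \infty$. The observed phenomenon being
modelled — a rise-then-fall of relative cyclase activity over a
50–350 µmol/L substrate series — fixes the qualitative shape but not the
functional form, so the classical Haldane law was chosen as the simplest
member of the family; a generalised exponent on the inhibition term is
available in `haldaneRate()`. Absence of inhibition is an explicit state
(`Ki = NA`), never a large sentinel value, to keep the two regimes
unambiguous in code and output.

`fitKinetics()` fits both laws by multi-start Levenberg–Marquardt least
squares (starts: $K_m$ at the median concentration, $K_i$ at the maximum
concentration and 10× it, $V_{max}$ scaled from the maximum observed
activity) and classifies the enzyme by the smaller small-sample
corrected information criterion (AICc, counting the error variance as a
parameter). AICc is preferred over an F-test so both models are treated
symmetrically and the criterion stays honest at the small n typical of
enzyme assays. A fitted $K_i$ exceeding $10^6 K_m$ — the regime where
the two laws are numerically indistinguishable over any realistic
concentration window — is reported as "unbounded" and the returned
Haldane parameters carry `Ki = NA`.

`compareEnzymes()` encodes the engineering goal as a decision rule: the
variant counts as a full rescue when it classifies as Michaelis–Menten
*and* keeps at least 90% of the wild-type $V_{max}$ (tolerance
configurable).

A caveat established by this package's own simulation suite: with
additive noise at 5% of $V_{max}$ on an 8-concentration, 3-replicate
design, roughly one in ten to twenty simulated datasets has its global
least-squares optimum on a compensated parameter ridge (inflated
$V_{max}$ and $K_m$, small $K_i$). Median parameter errors stay within a
few percent, but tail fits make the *mean* estimator error large, and
about 5% of inhibited datasets are classified as saturating. This is a
property of unconstrained least squares on this model at this noise
level, not of the optimizer — the acceptance suite documents it rather
than hiding it, and users fitting real single-assay data should treat
point estimates of $K_i$ with corresponding caution.

## The flow-restrictor model

The pathway segment is reduced to three pools — G (GGPP), L (lycopene),
B (beta-carotene):

$$\frac{dG}{dt} = v_{in} - r_{carB}(G),\qquad
  \frac{dL}{dt} = r_{carB}(G) - r_{cyc}(L),\qquad
  \frac{dB}{dt} = r_{cyc}(L),$$

with $r_{carB}$ a saturation law lumping the phytoene
synthase/dehydrogenase steps (lycopene is the only intermediate that
accumulates, so finer resolution adds state without insight) and
$r_{cyc}$ the Haldane law. The supply $v_{in}$ is zero order: it stands
for the in vivo GGPP synthesis rate of whichever GGPPS ortholog the
strain expresses, the single dial the flow-restrictor strategy turns.
There is no growth or dilution term by default (the model is cumulative
per culture volume, matching end-point titer logic); a first-order
dilution flag exists for exploration.

The model's central quantity is analytic: the cyclase's maximal
steady-state throughput

$$v_{crit} = \max_S r_{cyc}(S) = \frac{V_{max}}{1 + 2\sqrt{K_m/K_i}}.$$

For $v_{in} \le v_{crit}$ the lycopene pool settles on the rising branch
of the curve and essentially all carbon ends in beta-carotene; for
$v_{in} > v_{crit}$ no finite lycopene steady state exists, the pool
runs away, and lycopene becomes the majority product — which is exactly
the lever used deliberately when lycopene itself is the target. An
inhibition-free cyclase with the same $V_{max}$ and $K_m$ has no such
threshold below $V_{max}$, reproducing the variant-rescue contrast.

```{r flux}
cyc <- kineticParams(Vmax = 10, Km = 100, Ki = 400)
criticalSupply(cyc)
base <- pathwayParams(v_in = 1, carB = kineticParams(50, 10),
                      cyclase = cyc, t_end = 600, dt = 1)
productProfileSweep(base, c(2, 4, 6, 8))
```

Numerical choices: `lsoda` with rtol 1e-9/atol 1e-10; mass balance
$G + L + B = v_{in}t$ is asserted to relative 1e-6 at every output time
and violations are errors, as are negative pools beyond tolerance —
trajectories are never silently clipped. Runaway is detected from the
trailing 10% of a trajectory: if the mean $dL/dt$ there still exceeds 5%
of $v_{in}$, the pool has not settled; below the threshold this slope
decays to zero, above it it tends to $v_{in} - v_{crit}$, so the
detector separates the regimes cleanly one grid step away from the
threshold.

## Fermentation metrics

`cnRatio()` implements the media formula literally: moles of
carbon from glucose (180.156 g/mol, 6 C) over moles of nitrogen from the
complex sources (10.9% N in yeast extract, 15.4% in peptone, N at
14 g/mol), with carbon in the complex sources ignored by default because
it is negligible next to 50 g/L glucose (mass-fraction arguments add it
back for sensitivity analyses). The 50/10/10 g/L optimum medium gives
8.86, formatted "9:1". `foldChange()` defaults to floor rounding — an
improvement is only counted once fully attained, and 39 500/27.4 = 1441.6
then yields the canonical 1441-fold figure; plain rounding is exposed
as an option.

## Synthetic data: what it does and does not emulate

`generateMsa()` samples alignment columns independently: the wild-type
residue with probability `conservation[i]`, the rest spread over a
background (uniform by default). This produces PSSMs with a controlled
conservation signal — which is all the design pipeline consumes — but
has no phylogenetic correlation between sequences or positions, no
indels, and no composition bias. Passing tests therefore demonstrate the
pipeline's arithmetic and determinism, not performance on real homolog
sets; real psiblast PSSMs can be supplied directly via `readPSSM()`.

`generateAssay()` adds Gaussian noise truncated at zero (relative
activities cannot be negative) to a chosen rate law over the
50–350 µmol/L series. The truncation matters only near zero activity;
over the ranges used in the tests the averaged curves recover the
noise-free law within sampling error.

Every generator is a pure function of its arguments and a seed, and the
package restores the caller's RNG state, so results are byte-reproducible
without side effects.

## Problem sizes used in the checks

The shipped test suite and acceptance script use: alignments of 500
sequences over a 239-residue wild type for the full pipeline (the scale
of the enzyme's catalytic domain), 2 000 sequences for the
column-frequency convergence check, 100 random ≤12-point matrices for
the clustering cross-check, 500 seeded simulations for the kinetic
recovery study, and 500–1 000 h horizons for the pathway sweeps. These
sizes were chosen so each claim is tested at a scale where its
statistical bound is meaningful.

## Known limitations

- The PSSM builder implements a single-pseudocount profile without
  sequence weighting or iterative refinement; it is a stand-in for
  psiblast, not a reimplementation of it.
- The glycine rule, the exhaustive-versus-random double pool and the
  linkage criterion are interpretations of a tersely described
  procedure; all three are flag-controlled.
- The pathway model is deliberately qualitative: supply rates are only
  known relatively, so it predicts regimes and selectivities, not
  titers.
- Kinetic point estimates from single noisy assays are heavy-tailed (see
  the kinetics caveat above); replicate and, where possible, widen the
  concentration range beyond the peak.
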