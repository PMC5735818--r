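---
title: "Kinetic models of TEK-driven follicle signalling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models of TEK-driven follicle signalling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follisim)
```

## The biological question

During each ovarian cycle a cohort of follicles starts growing, but only a
dominant follicle (DF, > 10 mm) matures to ovulation while its subordinate
siblings (SF, < 5 mm) regress. Transcriptome comparisons of granulosa cells
from the two classes point at the angiopoietin receptor TEK (Tie2) and its
two downstream cascades — Ras/ERK/MYC (growth and proliferation) and
PI3K/AKT/mTORC1 (survival and translation control) — as the axis that
separates them: dominant follicles over-express ANGPT1 and TEK and
down-regulate the antagonist ligand ANGPT2, together with a set of miRNAs
that repress MYC translation (hsa-miR-30d-3p, hsa-miR-451a) or target the
receptor itself (hsa-miR-548v, bta-miR-22-3p).

`follisim` turns this picture into three executable kinetic models —
SF, DF, and DF plus the four miRNAs — and computes the comparison
statistics that distinguish them: peak times, peak amplitudes,
time-to-half-maximum, and a suite of cross-scenario ordering checks.

## Model formalism

Every model is a mass-action reaction network. A reversible elementary step
such as ligand–receptor binding,

$$\mathrm{ANGPT1} + \mathrm{TEK} \underset{k_r}{\overset{k_f}{\rightleftharpoons}} \mathrm{ANGPT1{-}TEK},$$

contributes the net rate $v = k_f[\mathrm{ANGPT1}][\mathrm{TEK}] -
k_r[\mathrm{ANGPT1{-}TEK}]$, and the full system is
$\dot{x} = N\,v(x)$ with $N$ the species-by-reactions stoichiometric
matrix. Reversible reactions are stored as single entities with a
forward/reverse constant pair rather than split in two, so reaction counts
stay comparable across representations. Elementary steps are capped at
order two per side. A saturable Michaelis–Menten rate form exists for
completeness but the default builder uses pure mass action throughout.

**Units.** Concentrations are dimensionless "concentration units" and time
is in seconds; first-order constants are s⁻¹ and second-order constants
(concentration·s)⁻¹. No absolute concentration scale is implied and none is
needed for the ordering statistics the package computes.

**Constant species.** miRNAs are modelled as buffered pools (`constant =
TRUE`): their net rate is forced to zero. This represents sustained
expression without committing to turnover kinetics that are not known.

**Rules.** Each assembled model carries one assignment rule defining the
observable `ERK_active_total` (currently equal to ppERK). The mechanism is
generic — any algebraic expression over species — and this rule is the
designated substitution point for model variants that need a different
derived observable.

## The three scenarios

The builder assembles four modules — receptor, adaptor/Ras, MAPK/MYC, and
PI3K/Akt/mTORC1 — into one network of 51 species and 50 reactions, then
derives the scenarios:

* **SF** is the baseline: every expression multiplier 1, no miRNAs.
* **DF** shares the identical reaction list and rate constants; only
  initial amounts change, through fold-change multipliers on five axes:
  ANGPT1 ×2, TEK ×2, ANGPT2 ×0.5, Ras ×2, PIK3R1 ×2. The magnitudes are
  free configuration choices; the directions follow the reported
  up/down-regulation pattern.
* **DF+miRNA** is DF plus four constant miRNA species and their actions:
  the two MYC-directed miRNAs divide the MYC synthesis flux by
  $(1 + s\,[\mathrm{miR}])$ each (competitive translational repression;
  repeated blocks multiply), and the two receptor-directed miRNAs add a
  removal reaction first order in TEK. This adds 4 species and 2 reactions,
  making DF+miRNA a strict structural superset of DF.

The reference comparison places the TEK trajectory of the DF+miRNA model
*above* DF, although the same miRNAs are described as TEK suppressors. The
intended sign of that interaction is ambiguous, so the builder exposes both
directions through the `mode`/`strength` arguments of
`add_mirna_repression()`, ships a deliberately weak default suppression
(`k_mir_tek = 1e-5`), and no check asserts the TEK ordering.

## What shapes the kinetics

Three structural choices drive the qualitative behaviour:

1. **Transient input.** The phosphorylated receptor dimer is internalized
   (`k_internal = 0.08 s⁻¹` on the free form; adaptor-bound receptor is
   shielded until it dissociates). Every downstream readout therefore rises
   and falls, and peak times become meaningful statistics.
2. **Substrate-depletion nonlinearity.** Each cascade tier has a finite
   substrate pool (total MEK, total ERK, ... are conserved moieties).
   The strong DF input partially saturates the tiers, so DF peaks both
   *higher and earlier*, while the weak SF input integrates slowly and
   peaks later — the characteristic lag of the subordinate follicle.
3. **Signal-coupled MYC turnover.** MYC is the one pool with explicit
   synthesis and decay, plus a Ras-GTP-dependent destabilization reaction
   (`MYC + RasGTP → RasGTP`). This is the package's own design choice and
   deserves its own paragraph.

**Why Ras-coupled MYC destabilization?** The data to reproduce are: total
MYC highest in SF, lower in DF, lowest under miRNA repression; and
phospho-MYC *higher* in SF than DF even though DF has several-fold more
active ERK. With shared parameters, any destabilizing signal that lives on
the same cascade tier as the phosphorylating signal cancels out of the
comparison: the DF trajectory traverses every SF operating point with at
least as full a MYC pool, so its phospho-MYC peak can never drop below
SF's. Coupling destabilization to Ras-GTP breaks this: Ras activation
completes roughly 400 s before ppERK rises in both scenarios, so the DF
pool is already run down when DF's large ERK signal arrives, while the SF
pool — facing a 3–4× weaker Ras signal — is still largely intact at SF's
later ERK peak. Slow basal MYC turnover (`k_mycsyn = 0.001`,
`k_mycdeg = 1e-4`, rest state 10) keeps the pool from re-equilibrating
within the simulation window. Biologically this stands in for the
phosphorylation-triggered MYC degradation arm; the source network gives no
MYC turnover kinetics, so the mechanism and its constants are this
package's modelling decision.

## Parameters

All rate constants and initial amounts live in one ledger
(`default_ledger()`), each entry tagged with its provenance. The defaults
are literature-style magnitudes for RTK/MAPK/PI3K cascade models,
calibrated once so that the expected cross-scenario pattern emerges, and
then frozen. The most consequential groups:

| group | constants | role |
|---|---|---|
| receptor residence | `k_internal`, `kr_grb_rt`, `kr_p85` | duration of the input transient; sets the overall timescale |
| tier relaxation | `k_gap`, `k_rafdeact`, `k_mekdp`, `k_erkdp` | per-tier lag; the cumulative lags place ppMEK near 270–350 s and ppERK near 680–930 s |
| tier gain | `k_mekp`, `k_erkp` | degree of saturation, hence the DF-earlier/higher pattern |
| MYC arm | `k_myc_destab`, `k_mycp`, `k_pmycdeg` | the SF/DF MYC and phospho-MYC orderings |
| miRNA action | `s_mir_myc`, `k_mir_tek` | depth of translational repression; TEK suppression strength |

`sample_parameters()` applies independent mean-one log-normal factors to
every rate constant (deterministic per seed) for robustness exploration of
the ordering checks.

## Numerical choices

* **Integrator.** `deSolve::ode` with `lsoda` (stiff-capable) at
  `rel_tol = 1e-8`, `abs_tol = 1e-10`; `vode` is used as an independent
  cross-check and agrees to better than 1e-4 relative on the SF model.
* **Output grid.** 1500 evenly spaced points over [0, 1500] s, resolving
  peak times to about one second; receptor readouts are typically re-run
  on [0, 70] s. The window end is a package choice: the comparison
  statistics stabilise well before 1500 s.
* **Peak detection.** The discrete maximum is refined by the vertex of the
  parabola through the three surrounding points, decoupling peak times from
  the grid; ties break to the earliest time; boundary maxima are flagged
  `non_interior` and all-zero series `zero_amplitude` rather than guessed.
* **Negativity.** Concentrations are clamped at zero only in readout
  evaluation, never inside the integrator, preserving its error control.
* **Conservation.** Conserved moieties are computed by exact integer
  elimination (`conserved_moieties()`), and simulations are required to
  hold every conserved total to within `100 × rel_tol` relative drift.
* **"Overlap".** The near-coincidence of the DF and DF+miRNA curves for
  ppMEK/ppERK is quantified as a maximum absolute gap ≤ 5% of the DF peak
  amplitude — a configurable threshold standing in for a qualitative
  statement.
* **Tolerance refinement.** `refine_until_converged()` halves tolerances
  until successive peak-time estimates move by less than one grid step
  (at most five refinements), guarding peak statistics against solver
  artefacts.

## SBML exchange

Models round-trip through SBML Level 3 Version 1 via `write_sbml()` /
`read_sbml()` (Level 2 core documents also parse). Kinetic laws are emitted
as explicit MathML with reaction-local parameters named `kf`, `kr`,
`km`/`vmax` and `inh_*`; the reader reconstructs rates from those local
parameters and raises an explicit unsupported-feature error naming any
reaction whose kinetic law it cannot interpret. The parameter count
convention — global parameters plus reaction-local constants — is applied
identically by `model_summary()` and the SBML writer, so summaries are
invariant under a round-trip. Annotation subtrees (e.g. CellDesigner
extensions) are carried as opaque blobs. Externally curated models can
be dropped into `inst/extdata/sbml/` and flow through the same simulation
and analysis path as built models (`run_config(sbml_paths = ...)`).

## What the generator does and does not emulate

The builder is a synthetic stand-in for a hand-curated model: it reproduces
the described topology and the qualitative comparison surface, not the
original's exact species inventory (51 species here versus roughly twice
that in the curated version, which tracks many more intermediate
complexes), nor its fitted rate constants, nor real granulosa-cell
variability: the models are deterministic, spatially homogeneous, and
single-compartment, with no transcriptional feedback, no receptor
recycling, and no steroidogenesis arm. Passing checks therefore demonstrate
that the implemented mechanisms are *sufficient* to generate the reported
ordering pattern — not that the constants are biologically measured, and
not that real follicles obey them. Peak times for ppMEK and ppERK land
within the reference "about" bands under the default ledger; the phospho-MYC
peak *ordering* (SF later and higher than DF) is reproduced, but its
absolute peak times are earlier than the reference kinetics, a known
limitation of the compact MYC arm.

## Test problem sizes

The test suite and acceptance checks run entirely on generated inputs: toy
networks with closed-form solutions (first-order decay, reversible
binding, two-step chains), randomized mass-action networks of up to 10
species for property tests, and the three 51-species scenario models over
[0, 1500] s with a fixed-step RK4 reference on a 100 s window. These sizes
keep the full suite to a couple of minutes on one core while exercising
every code path the larger curated models would use.
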