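---
title: "Inferring carbon sources from expression-constrained flux models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring carbon sources from expression-constrained flux models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxprior)
```

## The inference problem

A microorganism adapts to its nutrient environment largely by adjusting
gene expression: transporters and catabolic enzymes for the carbon source
in use are induced, alternatives are repressed (in enteric bacteria,
often by catabolite repression). `fluxprior` inverts this logic: given a
gene-expression profile measured under an *unknown* carbon source, it asks
which of a panel of candidate nutrients is most compatible with that
profile, using a constraint-based (FBA) model of metabolism as the prior
biological knowledge. No genes are hand-picked; every gene in the model
contributes through its gene–protein–reaction (GPR) association.

## The model and procedure

Growth is modeled by flux balance analysis: fluxes $v$ satisfy
steady-state mass balance $S v = 0$ and bounds $a \le v \le b$, and the
predicted growth rate is $F(a, b) = \max f^\top v$ with $f$ selecting the
biomass reaction. The pipeline has three stages.

**1. Baseline flux limits** (`compute_baseline`). For each candidate
nutrient $k$, uptake through its exchange reaction $j_k$ is calibrated by
bisection so the optimum matches the measured growth rate, or a nominal
0.5 h⁻¹ when none is supplied (all other candidate uptakes closed; the
mineral medium stays open at model defaults). With the calibrated bound in
place and the optimum $F_k$ recorded, flux variability analysis maximizes
and minimizes every reaction subject to biomass $\ge 0.9\,F_k$. The
baseline limits are the elementwise envelope over candidates,
$b^{base}_j = \max_k v^{max}_{j,k}$ and
$a^{base}_j = \min_k v^{min}_{j,k}$ — a proxy for the maximal enzyme
capacity each reaction ever needs across the panel. Because capacities
cap flux but cannot force it, lower limits are clamped at zero from above
(a reaction that never ran backward has no reverse capacity, and a
uniformly positive $v^{min}$ — e.g. the biomass reaction itself, pinned at
$0.9 F_k$ in every variability run — is not a minimum requirement);
hard model lower bounds such as ATP maintenance are preserved. Without
this clamp, down-scaled problems for non-matching candidates are almost
always infeasible and the score degenerates to all-or-nothing.

**2. Expression-derived limits** (`condition_means`, `reaction_ratios`,
`scale_limits`). Replicate samples are averaged on the log2 scale and
exponentiated (a geometric mean). GPR trees convert gene values to
reaction values: isozymes (`or`) add, complex subunits (`and`) take the
minimum, applied recursively for nested rules. The scaling ratio of
reaction $j$ under challenge condition $l$ is its reaction value in $l$
divided by its maximum over all supplied conditions, so the ratio is 1 in
the condition where the reaction is maximally expressed. Positive upper
limits shrink to $r\,b^{base}$; negative lower limits shrink
symmetrically (one enzyme pool limits both directions of a reversible
reaction). Exchanges, the ATP-maintenance reaction, and reactions without
GPRs are never scaled, and missing genes are dropped from their GPR so an
unmeasured probe cannot fabricate a bottleneck.

**3. Ranking** (`prioritize`). Relative biomass production for challenge
$l$ and candidate $k$ is
$\mathrm{RBP}(l,k) = 100 \cdot F(\text{scaled limits for } k) / F_k$.
Since scaled limits are a subset of baseline limits, RBP $\le 100$;
an infeasible scaled problem scores 0 rather than erroring. Candidates are
ordered by decreasing RBP with tie-averaged ranks.

Two robustness analyses repeat the whole ranking: `stochastic_analysis`
adds Gaussian noise to log2 condition means with gene-wise sd
$s/\sqrt{n}$ estimated from the $n$ replicates (the division emulates
re-averaging $n$ noisy replicates), and `permutation_analysis` permutes
gene labels consistently across conditions — the null in which the
matching candidate's expected rank is $(n_{cand}+1)/2$.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `fraction` | 0.9 | – | near-optimality level of the variability envelope |
| `nominal_growth` | 0.5 | h⁻¹ | calibration target without a measured rate |
| `cap` | 1000 | mmol·gDW⁻¹·h⁻¹ | finite stand-in for unbounded model limits |
| `floor_epsilon` | off / 0.03 | mmol·gDW⁻¹·h⁻¹ | minimum upper limit after scaling |
| `filter_alpha` | off / 0.05 | – | Welch-test cut-off for the significance filter |
| `iterations` | 1000 | – | robustness iterations |
| `tie_tol` | 1e-4 | percent RBP | tie band for rank averaging |

Two deliberate alternatives exist for the cofactor problem: reactions
synthesizing cofactors carry tiny biomass coefficients, hence tiny
baseline limits that choke growth once scaled. Either remove the cofactor
constituents from the biomass reaction
(`remove_biomass_constituents`; the conventional 15-metabolite list for
iAF1260 ships with `iaf1260_biomass_cofactors()`), or raise every small
positive upper limit to `floor_epsilon = 0.03` after scaling
(`apply_floor`). Both are off by default and give essentially identical
rankings on the cofactor-bearing toy variant.

The significance filter (restricting scaling to reactions with a
Welch-test p below `filter_alpha` between challenge replicates and the
replicates of the max-achieving condition, gene-level, log2 scale) is
likewise off by default: filtering discards the collective effect of many
small, coordinated changes and demonstrably blunts discrimination.

## Numerical choices

The LP core is a bounded-variable two-phase revised simplex
(`src/simplex.cpp`), with Dantzig pricing, a Bland fallback after
degenerate streaks, feasibility tolerance 1e-9, and refactorization at
every iteration — appropriate for the dense, small-to-medium problems
here. Unbounded model limits resolve to ±1000 before solving. Uptake
calibration bisects on the uptake bound (growth is continuous and
nondecreasing in it) to a relative growth tolerance of 1e-6. Flux
variability is used for the baseline precisely so results cannot depend on
which optimal vertex a single FBA solve returns. RBP values within
`tie_tol = 1e-4` percent are tied before ranking: measured solver
round-off produces spurious RBP differences up to ~1e-5 percent between
exactly-equivalent candidates, and ordering within such clusters would
otherwise correlate with irrelevant problem scaling; genuine RBP
differences in practice are orders of magnitude above the band.
Degenerate inputs are handled explicitly: inverted bounds report an
infeasible solution rather than erroring, all-zero expression profiles
and GPRs with no measured gene leave a reaction unconstrained, and a
single-replicate condition falls back to the median of computable noise
sds.

## What the synthetic fixture emulates

`make_toy_model` builds a fixed core network — glucose and acetate
transport, lumped glycolysis, a pyruvate-dehydrogenase step (isozyme
pair), lumped TCA/energy production (complex-or-isozyme nested GPR), a
glyoxylate-shunt analogue lumped with anaplerosis (acetyl units to
biomass precursor), an anabolic precursor step, and a biomass reaction —
plus seeded decoy candidates that enter central metabolism through one
single-gene transport/degradation step each, alternating between
sugar-like (hexose node) and acid-like (pyruvate node) entry points with
randomized carbon yields. Core stoichiometry is fixed in code so closed
forms hold (biomass yield 8/9 per glucose uptake, 1/4 per acetate
uptake); build-time checks verify that both real carbons grow, that
optimal glucose growth leaves the shunt silent, and that acetate growth
is impossible without it. Entry chains are deliberately one reaction long
for every candidate: equal chain length keeps candidates exchangeable
under gene-label permutation, so the permutation null concentrates at its
symmetry expectation instead of reflecting chain-length artifacts.

`simulate_expression` emulates a multi-condition chip study: one
condition per real carbon (five replicates for the glucose analogue, two
elsewhere), log-normal replicate noise, adaptive induction (`fold`, default
8) of genes whose reactions carry optimal flux for the condition's carbon,
catabolite repression (`1/fold`) of unused enzyme genes on the preferred
sugar only, and a background of `n_background = 200` genes outside every
GPR whose condition means wobble sub-significantly
(`bg_sigma_log2 = 0.3`, i.e. within about two-fold). The background
matters: in the real data the vast majority of genes do not respond to
the carbon source, and a label permutation over a realistic gene pool
hands mostly uninformative profiles to enzyme genes — that, not the
permutation per se, is what destroys the ranking signal. Levels are on an
arbitrary linear scale (baseline 100) because only ratios enter the
method.

What passing tests on this fixture do **not** show: performance on
genome-scale reconstructions (thousands of reactions, alternate pathways,
realistic media), probe-level microarray artifacts, post-transcriptional
regulation (the method assumes activity tracks mRNA, which the source
system satisfies only approximately), or carbon-source mixtures. The
fixture is a controlled testbed for the algorithmic claims, not a model
of E. coli.

## Problem sizes used in the shipped analyses

The test suite and the acceptance script run the full pipeline on the
18-candidate toy panel (58 reactions): baseline construction solves about
3×10³ LPs, the permutation analysis 1000 iterations × 2 challenge
conditions × 18 candidates = 3.6×10⁴ LPs, and the seeded-recovery check
20 seeds × 2 challenges. These sizes give Monte-Carlo error well below
the 0.3-rank band used for the permutation null while keeping a complete
run in a few minutes on one core.

## Known limitations

* The envelope underestimates capacities of reactions that are
  substrate-limited under every panel nutrient; this is harmless only
  when their expression is roughly condition-independent.
* With two measured conditions the per-gene expression maximum is a crude
  range estimate; an external max profile can be injected via
  `expression_set(means, max_profile = ...)`.
* The `or`-sum / `and`-min GPR convention is one defensible reading of
  isozyme and complex kinetics; alternatives (max for `or`) would change
  ratios for isozyme-rich reactions.
* Whether secretion of non-challenge candidate carbons should stay open
  during ranking is configurable in principle; the default keeps
  secretion open and uptake closed, mirroring single-carbon-source
  experiments with overflow metabolism.
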