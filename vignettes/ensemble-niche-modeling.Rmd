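---
title: "Ensemble niche modeling with rangecast: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble niche modeling with rangecast: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(rangecast)
library(dplyr)
```

# The problem

Species distribution models (SDMs, also called ecological niche models)
estimate how environmentally suitable each location on a map is for a
species, from two inputs: georeferenced occurrence records (typically
herbarium or museum specimens) and gridded environmental layers (climate,
elevation, soil). Projecting the fitted niche onto past or future climate
layers turns the model into a forecast of range shifts, and — for timber
species — of the economic value tied to the shifting range.

rangecast implements this workflow as a single reproducible pipeline:

1. clean and deduplicate occurrence records, and collapse them to
   *presence cells* on the working grid;
2. prune collinear predictors by Spearman rank correlation;
3. fit five algorithms over many replicated splits with pseudoabsence
   sampling;
4. score every replicate by AUC and the true skill statistic (TSS),
   keep only strong replicates, and blend them into a weighted consensus
   map;
5. binarize the consensus at the lowest presence threshold (LPT), compare
   periods into stable/lost/gained areas with curvature-corrected cell
   areas, and map uncertainty;
6. convert lost and gained areas into timber value.

Because real climate/soil layers are large external downloads, the package
ships a virtual-species simulator: synthetic environments with known
properties and species with *known* niches, so every stage can be validated
against ground truth.

# The modeling protocol

## Presence cells, pseudoabsences and splits

The modeling unit is the grid cell: all records inside one cell count as a
single presence. Absence data do not exist for herbarium records, so
pseudoabsence cells are drawn uniformly, without replacement, from cells
with data but no record of the species, in a 1:1 ratio with the presences
of each partition — a balanced design that suits SVM and random forests and
is harmless for GLM. Each repetition splits the presence cells 70/30
(calibration/test, `round(0.7 n)` half-up), redraws its pseudoabsences, and
shares this partition across all five algorithms; with the default 100
repetitions this yields 500 candidate replicates per species and period.
Pseudoabsences are redrawn independently at every repetition so the ensemble
averages over background-sampling noise, and background sampling excludes
*all* presence cells of the species (train and test).

No species-specific accessible-area mask and no spatial thinning are
applied; models are deliberately comparable across species and periods.

## The five algorithms

* **BIOCLIM** (presence-only envelope). For a query value with mid-rank
  percentile $p_v$ among the calibration values of variable $v$, the
  per-variable score is $2\min(p_v, 1-p_v)$ and the cell score is the
  minimum over variables. The exact median scores 1; anything outside the
  calibration range scores 0. The score is purely rank-based, hence
  invariant to monotone transforms of any variable.
* **Domain** (presence-only similarity). Gower distance to the nearest
  calibration point, $d = \frac1V \sum_v |q_v - b_v| / r_v$ with $r_v$ the
  calibration range (a zero-range variable contributes 0 when equal, else
  1), mapped to suitability $\max(0, 1 - \min_B d)$.
* **GLM**: binomial logistic regression with linear terms, via `stats::glm`.
  Non-convergent or separated fits are flagged and excluded.
* **SVM**: radial-kernel support vector machine via `kernlab::ksvm`; raw
  decision values are mapped to $[0,1]$ by range normalization over the
  prediction raster.
* **Random forest**: 500 trees via `randomForest`; the score is the
  fraction of trees voting presence.

All five share one contract: a deterministic (seeded) continuous score in
$[0,1]$ over the raster.

## Evaluation, filtering, consensus

Each replicate is evaluated on its held-out 30% only. AUC is the rank-based
(Mann–Whitney) probability that a presence outscores a background cell,
ties counting one half. TSS $=$ sensitivity $+$ specificity $- 1$ is
evaluated at the sensitivity–specificity threshold: every observed score is
scanned and the threshold maximizing sensitivity $+$ specificity is chosen
(prediction positive iff score $\ge$ threshold; ties go to the smallest
threshold, which favours sensitivity). The alternative reading — the
threshold where sensitivity and specificity cross — is available via
`method = "equal"`; maximization is the default because it is the standard
interpretation and coincides with maximizing TSS itself.

Replicates pass the filter iff AUC $\ge 0.75$ **and** TSS $\ge 0.7$, both
inclusive. Retained replicates are each range-normalized to span $[0,1]$
over their own raster (normalizing per replicate, not over the pooled set,
is what makes differently-scaled algorithms commensurable), then combined
per cell by a weighted mean with weights $\mathrm{TSS}_i^2$ — squaring
emphasizes the best models. The same machinery, applied within each GCM's
projected members, yields per-GCM consensus maps.

A cell that is nodata in any member is nodata in the consensus (mask
intersection). The alternative — per-cell renormalization over members with
data — is exposed as a flag, but is not the default because it silently
changes the effective weights where members are missing.

## Binarization, change and area accounting

The consensus is binarized at the **lowest presence threshold**: the
minimum consensus value over the species' occurrence cells. Binarization is
inclusive ($\ge$ LPT), which guarantees by construction that every known
occurrence falls inside the predicted range. Scenario consensus maps are
binarized at the same LPT.

Change maps cross-classify the present and scenario binary rasters into
stable/lost/gained/absent. Areas are summed per category using the
spherical cell area on WGS 84,
$$A = R^2\,\Delta\lambda\,(\sin\phi_N - \sin\phi_S),$$
with $R = 6371.0072$ km, the authalic radius (the sphere radius with the
Earth's true surface area). This closed form is exact on the sphere and
within about 0.3% of ellipsoidal areas — adequate next to the modeling
uncertainty, and testable to machine precision (a global grid sums to
$4\pi R^2$). Percent change is
$(\text{scenario} - \text{present})/\text{present} \times 100$ (positive =
expansion) and percent maintained is the stable share of the present area;
`stable + lost = present` and `stable + gained = scenario` hold exactly
because they are sums over the same cells.

## Uncertainty maps

Two families of per-cell standard-deviation maps (sample SD, divisor
$n-1$; the divisor is configurable): **across GCMs**, over the per-GCM
consensus maps of a period, and **across algorithms**, over per-algorithm
sub-ensembles of the retained replicates. Per-algorithm ensembles (rather
than raw replicates) are the default members of the second family so the
map isolates between-algorithm disagreement from within-algorithm
replicate noise.

## Timber valuation

Lost and gained areas are converted to value as
$\text{USD} = \text{km}^2 \times 100\,\text{ha/km}^2 \times 1.74\,
\text{m}^3\text{ha}^{-1} \times 1000\,\text{USD/m}^3$, i.e. 174,000 USD
per km². The defaults are an inventory-based volume for large Amazonian
*Dipteryx odorata* and an approximate cumaru export price; both are static
by assumption, so results are illustrative scale estimates, not forecasts.
Per species, the net value at stake is `value(lost) − value(gained)`
(gains enter negatively); gross loss ignoring gains is reported alongside,
since either convention may be wanted when totalling across species.

# The virtual-species simulator

`simulate_environment()` builds each variable as a random linear
latitude/longitude gradient plus spatially smoothed Gaussian noise (coarse
white noise, bilinearly upsampled; the `smoothness` parameter is the
correlation length in cells), rescaled to a variable-specific unit range.
Pairs listed in `correlated_pairs` are rebuilt by Gaussian-copula mixing of
normal scores using $\rho_P = 2\sin(\pi\rho_S/6)$, which hits a target
Spearman correlation to within about $\pm 0.1$ on a finite grid — exact
rank correlation on a grid is not controllable, so the tolerance is part of
the contract.

The truth model is a product of independent Gaussian responses,
$S = \prod_v \exp\{-(e_v-\mu_v)^2 / 2\sigma_v^2\}$: the simplest smooth
unimodal niche. Occurrences are sampled either with probability
proportional to $S$ (realistic, noisy) or as the top-$S$ cells (sharply
separable, for algorithm stress tests); coordinates are cell centers, since
the pipeline operates on presence cells and sub-cell jitter would add
nothing. Scenario stacks are emulated by `perturb_stack()`: a constant
per-variable shift (in SDs) plus smooth noise, one stack per emulated GCM.

What the simulator does *not* emulate: real spatial sampling bias,
taxonomic error, dispersal limits, non-Gaussian or interacting niche
responses, and the actual physics of LGM/SSP climate fields. Passing tests
therefore demonstrate that the pipeline recovers a knowable niche under
clean conditions — not that any particular real-world projection is
correct.

## Study conditions used in the validation runs

The niche-recovery checks use conditions chosen once as a realistic
"well-sampled species" and not revisited: a 60×60-cell environment with
two informative variables (optimum about 1 SD off-center, breadth about
0.5 SD of the variable) plus one correlated nuisance variable (target
Spearman 0.9, which the pruning step removes), 120 presences sampled
probabilistically, 5 algorithms × 8 repetitions, three independent seeds.
The structural-fidelity run uses a 50×50 grid with the full 5 × 100
replicate protocol. These sizes keep a complete run in the order of
seconds to a couple of minutes while leaving every statistical property
intact; the full-scale protocol is identical but for `n_reps` and grid
size.

# Numerical and degenerate-input choices

* Grids are equal-angle WGS 84, row-major, 0-based cell ids, row 0 at the
  north edge; cell membership uses half-open intervals
  $[\text{west},\text{east}) \times [\text{south},\text{north})$, so a
  record on a shared boundary belongs to exactly one cell. These
  conventions are fixed so tests can assert exact cell arithmetic.
* Duplicate occurrence keys are exact (species, longitude, latitude); the
  first record of a duplicate group is kept. Coordinates (0, 0) are
  treated as missing, a standard herbarium-data red flag.
* The Spearman threshold comparison is inclusive (keep when
  $|\rho| \le 0.6$), and which member of a correlated cluster survives is
  decided greedily by an explicit priority order (default: input order) —
  the retention rule must be deterministic and auditable. Constant
  variables have undefined rank correlation and are excluded with a
  warning. Whether $\rho$ should be computed over the full extent or only
  occurrence cells is a genuinely open choice; full extent is implemented.
* Threshold ties in TSS selection go to the smallest threshold, with a
  $10^{-12}$ guard so floating-point noise in the sensitivity/specificity
  sums cannot decide a tie.
* A constant prediction raster cannot be range-normalized; since a
  constant model cannot pass TSS $\ge 0.7$, this raises an error rather
  than being silently tolerated.
* Presence cells that fall on nodata are dropped with a warning before
  fitting; the LPT, by contrast, errors on nodata presence cells, because
  at that stage they indicate an upstream inconsistency.
* Seeds: every stochastic step derives a child seed from the master seed
  and stage labels via a polynomial string hash modulo $2^{31}-1$
  (`derive_seed()`), so adding a species or stage never perturbs another's
  draws, and all results are bit-reproducible given (config, seed).

# Worked example

```{r example}
stack <- simulate_environment(40, 40, n_vars = 3, seed = 3,
                              correlated_pairs = list(list("var1", "var3", 0.9)))
suit <- true_suitability(stack, optima = c(var1 = 27, var2 = 32),
                         breadths = c(var1 = 1.5, var2 = 2.0))
occ <- sample_occurrences(suit, 100, seed = 5, species = "virtual_sp")
future <- lapply(c("GCM-A", "GCM-B"), function(g)
  perturb_stack(stack, shift_sd = 0.8, seed = 9, period_label = "2031-2040",
                gcm_label = g))

run <- run_enm_pipeline(occ, stack, future, n_reps = 8, seed = 42)
glance(run)
tidy(run)
run$economics$totals
```

```{r plots, fig.height = 4}
autoplot(run$species$virtual_sp$consensus_present)
autoplot(run$species$virtual_sp$scenarios$`2031-2040`$change)
```

# Known limitations

* The scenario emulator shifts and jitters the present-day fields; it does
  not reproduce the spatial patterns of real paleoclimate or CMIP6
  projections, so conclusions about any *specific* real scenario require
  real layers (read in via `read_stack_dir()` after external conversion to
  ASCII grids).
* Only linear GLM terms are fit; a strongly interior niche optimum is
  better captured by the envelope, similarity and machine-learning
  members, which is one of the reasons ensembles are used at all.
* SVM and random-forest hyperparameters are pinned defaults, not tuned.
* The spherical area model ignores the WGS 84 ellipsoid's ~0.3% area
  distortion.
* Valuation assumes static prices and a fixed per-hectare volume; it
  ignores forest structure, growth and market dynamics by design.
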