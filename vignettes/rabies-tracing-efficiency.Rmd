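---
title: "Modeling the efficiency of monosynaptic rabies tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the efficiency of monosynaptic rabies tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvtrace)
```

## The problem

Glycoprotein-deleted rabies virus (RVdG), trans-complemented with optimized
glycoprotein (oG) in a defined population of starter cells, jumps exactly one
synapse retrogradely and labels first-order input neurons. Dual-labeled rabies
constructs that tag excitatory postsynaptic densities (PSD-95) and presynaptic
terminals (synaptophysin) make the efficiency of that jump measurable at the
level of individual synaptic contacts: the **synaptic fraction (SF)** is the
proportion of a starter cell's excitatory postsynaptic specializations whose
presynaptic terminal is rabies-labeled.

What most experimenters actually care about is the **input fraction (IF)** —
the proportion of presynaptic input *neurons* that are labeled — and the
**unitary synaptic efficiency (U)** — the probability that rabies crosses one
individual synaptic contact. `rvtrace` implements the closed-form model
connecting the three, the corrections required to go from a measured SF to IF
and U, a Monte Carlo simulator that brute-forces the same quantities on
explicit circuits, and a synthetic measurement pipeline so every stage is
testable without any imaging or connectomic data.

## The model

Assume rabies crosses each synaptic contact independently with probability
$U$, and that a labeled input neuron marks *all* of its terminals. An input
neuron making $M$ contacts onto the starter is labeled with probability

$$p = 1 - (1 - U)^M.$$

With two input populations $a$ and $b$ in count ratio $R = N_a/N_b$ and
multiplicities $M_a$, $M_b$:

$$\mathrm{IF} = \frac{R\,p_a + p_b}{R + 1}, \qquad
  \mathrm{SF} = \frac{R\,p_a M_a + p_b M_b}{M_a R + M_b}.$$

SF weights each input neuron by its number of contacts, so SF $\ge$ IF always,
with equality when $M_a = M_b$ or $U \in \{0, 1\}$. A multi-contact input is
both more likely to be labeled and contributes more labeled contacts once it
is.

```{r model}
evaluate_model(R = 2, Ma = 1, Mb = 2, U = 0.28)
solve_unitary_efficiency(0.4, R = 10, Ma = 1, Mb = 2)
minimize_if_sf_over_R(U = 0.22, Ma = 1, Mb = 3, R_min = 0.01, R_max = 100)
```

`evaluate_mixture()` generalizes the two-population form to an arbitrary
discrete multiplicity distribution; the two-population form remains canonical
for all headline-number reproduction, and the mixture reduces to it exactly
for two entries. The default mixture (92% single-contact, 6.7% double, 1.3%
triple; mean 1.093) is calibrated to adult mouse V1 EM reconstructions in
which ~92% of excitatory-to-excitatory connections involve a single contact
and the mean is 1.0965.

### Numerical choices

* `solve_unitary_efficiency()` uses bisection on $[0,1]$ (SF is strictly
  increasing in U) to an absolute tolerance of 1e-9 — robustness over speed.
* `minimize_if_sf_over_R()` scans a log-spaced grid (≥200 points) before
  golden-section refinement, because the IF/SF minimum over $R$ is a shallow
  interior dip that a naive local optimizer can step over.
* $R$ is treated as a positive real, not an integer ratio.
* IF/SF is defined as 1 at $U = 0$ (where SF $=$ IF $= 0$) so sweep tables
  stay NaN-free. That convention equals the true $U \to 0$ limit only when
  $M_a = M_b$; the exact limit for $M_a \ne M_b$ is the ratio of the analytic
  derivatives $(R M_a + M_b)/(R+1)$ over $(R M_a^2 + M_b^2)/(M_a R + M_b)$,
  which the test suite checks directly rather than via the convention.

### A note on two figure-derived values

The inversion of SF $= 0.4$ at $R = 10$, $M_a = 1$, $M_b = 2$ has the exact
quadratic root $U = 0.3615$, and IF/SF at $U = 0.35$, $R = 10$ is exactly
0.9556. The published readings of ~0.35 and ~0.95 for these scenarios come
from plotted curves, not algebra. `rvtrace` always reports the computed
values; the reproduction report (`reproduce` subcommand) compares such rows at
figure-reading precision (±0.02) and everything else at printed precision.

## Shared-input correction

An input neuron that synapses onto two starter cells can have its terminal on
starter A labeled because rabies spread from starter B — labeling without
spread at the observed contact, inflating SF above IF. The correction sums,
over distance bins, `n_neighbors × starter_fraction × shared_fraction × IF ×
(1 − IF)`: a fraction IF of each neighbor's shared inputs are labeled, and
only the $(1-\mathrm{IF})$ not already labeled directly are new additions.

```{r shared}
correct_common_input(default_sharing_profile(), IF = 0.3, starter_fraction = 1)
```

Design notes:

* The per-neighbor increments are computed exactly in floating point and
  rounded only at reporting (exact per-bin values 7.35%, 9.009%, 5.88% print
  as 7%, 9%, 6%).
* Sharing beyond 200 µm (~0.1%) is excluded from the default profile as
  negligible; `read_sharing_profile()` accepts extra bins.
* The calculation assumes a fixed IF = 0.3 inside a formula that itself
  determines IF. The default replicates that one-pass convention;
  `iterate_common_input()` is a clearly flagged fixed-point extension
  (iterate until |ΔIF| < 1e-6), which lands within ~0.02 of the one-pass
  value for these parameters.
* The multiplicity inflation factor relating IF to U defaults to 1.08 ("IF
  about 8% larger than U"); its provenance is not derivable from the printed
  scenarios, so it is an explicit parameter, never hard-coded logic.
  `estimate_if_and_u(round_intermediate = TRUE)` reproduces the printed
  arithmetic chain (0.4 × 0.74 → 0.30 → /1.08 → 0.28), which rounds IF
  before the division.

## Monte Carlo simulator as oracle

`simulate_spread()` realizes the model's assumptions literally on an explicit
starter/input contact graph: one uniform draw per individual contact, an
input labeled iff any of its contacts onto any starter is crossed, and every
contact of a labeled input counted as labeled. Because draws are compared to
U, a common seed yields a monotone coupling: raising U can only add labeled
inputs. Replicates in `estimate_metrics()` use child seeds derived from one
root seed, so a single integer reproduces an entire experiment.

The simulator deliberately contains no shared logic with the closed-form
model, so the two validate each other; the test suite additionally checks
both against exhaustive enumeration of all $2^C$ crossing patterns on
circuits with $C \le 12$ contacts. There is no spatial decay of U with
dendritic distance — matching the empirical finding of no proximal/distal
difference — but a per-connection efficiency map (`u_map`) is accepted as a
hook.

## Synthetic data: what it does and does not emulate

`generate_circuit()` realizes spatially embedded starters with
distance-dependent pairwise sharing (rewiring a fraction $s(d)$ of a
starter's inputs to also contact each neighbor; higher-order overlap arises
only by chance under independence, since only pairwise rates are known) and
multiplicities drawn from the mixture. `generate_puncta_table()` emulates the
counting procedure: per-segment PSD counts are Poisson (the simplest count
model consistent with abundant synapses and no printed dispersion), apposed
counts are binomial given a per-neuron true fraction drawn from a Beta
distribution. The Beta concentrations in `default_puncta_spec()` (17 for the
oG group, 49 for the no-oG group) are calibrated so the between-neuron SEMs
match the printed 3.92% and 1.79%, not just the means (50.61%, 8.86%) —
per-neuron raw values are not published, so matching the first two moments is
the strongest available calibration. Segment geometry for
`generate_puncta_points()` is a straight dendrite; geometry is irrelevant to
the detector contract.

None of this emulates pixel data, point-spread functions, nuclear aggregate
artifacts, or manual counting bias. A green pipeline test therefore
establishes that the *statistics* downstream of puncta counting behave as
specified on data with the assumed structure — not that the imaging and
counting themselves are unbiased.

## Quantification

`detect_appositions()` matches presynaptic to postsynaptic puncta within an
anisotropic ellipsoid (defaults 0.12 µm lateral, 0.35 µm axial, the Airyscan
resolution limits; the manual criterion of "partial overlap" has no numeric
threshold, so the tolerances are explicit parameters). Matching is greedy
nearest-first and one-to-one with deterministic tie-breaking — reproducibility
over optimal bipartite matching, which is overkill at these densities.

`colocalization_summary()` treats the neuron as the statistical unit (pooling
its segments), matching the published n; SEM uses sample SD (n−1) over
√n. Animal identity is carried and reported but not modeled, mirroring the
observation that values did not vary significantly across animals.
`background_corrected_sf()` subtracts the no-oG background mean (50.61% −
8.86% → SF = 0.42). `rank_sum_test()` is exact by complete enumeration
(shift-algorithm) for ≤20 pooled observations without ties, otherwise a
normal approximation with tie and continuity corrections; two-sided p-values,
no multiple-testing correction (single pairwise comparisons). The published
p = 0.001 for the oG comparison is not reproducible because per-neuron raw
values are unprinted; it is excluded from acceptance checks.

## Command line

```
rvtrace model eval --r 2 --ma 1 --mb 2 --u 0.28
rvtrace model solve-u --sf 0.4 --r 10 --ma 1 --mb 2
rvtrace correct --starter-fraction 0.5
rvtrace generate circuit --n-starters 2 --inputs-per-starter 5000 --share --seed 7
rvtrace simulate --circuit circuit.tsv --starters starters.csv --u 0.28 --seed 1
rvtrace generate puncta --seed 5 && rvtrace quantify --table puncta.csv --compare oG,no_oG
rvtrace reproduce
```

Every run writes a `manifest.json` (command, config, seed, package version)
sufficient to re-run bit-identically; stochastic commands require `--seed`.
Config files are JSON (`--config cfg.json`), with explicit flags taking
precedence. Logs go to stderr; results only to files.

## Known limitations

* The first-order shared-input formula ignores saturation across neighbors;
  the compounding variant (`compound = TRUE`) bounds the effect and the
  simulator quantifies it exactly.
* U = 0.22 enters only as a given worst-case scenario parameter; the package
  does not attempt to derive it.
* Independence of spread across contacts of the same connection is the
  model's assumption, implemented as stated; biology may differ.
* No viral kinetics, titer effects, or time courses; no estimation of the
  sharing profile from histology or EM — profile values are fixture
  parameters.
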