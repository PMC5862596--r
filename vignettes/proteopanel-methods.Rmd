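---
title: "Methods: consensus iTRAQ analysis, network propagation and MRM validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus iTRAQ analysis, network propagation and MRM validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopanel)
```

# The study design this package models

`proteopanel` implements a tumor/matched-control tissue-proteomics workflow
built around a pooled-reference iTRAQ 4-plex design. Eleven tumor lysates and
their matched controls are distributed over four 4-plex labelling sets. In
every set, channel 114 carries a pool of all eleven control lysates; channels
115--117 carry individual tumor lysates, except in the last set where channel
117 carries a pool of all tumor lysates (a QC sample that never enters
patient-level statistics). Because the identical control pool sits in every
set, the ratio of a tumor channel to channel 114 is comparable across sets,
and each patient contributes exactly one fold change from exactly one
set/channel.

Two database search engines process the same spectra independently. They
overlap only partially in which proteins they identify and quantify, so the
analysis runs the full filter chain per engine and only then combines the
engine-level lists.

# Quantitation model

For each peptide-spectrum match (PSM), reporter ratios are
$r_c = I_c / I_{114}$ for $c \in \{115, 116, 117\}$; rows with
$I_{114} \le 0$ cannot be ratioed and are excluded (and counted). A protein's
per-channel fold change in a set is the **median** of its PSM ratios. The
median was chosen over the mean for robustness to the heavy right tail of
reporter-intensity noise; the mean is available via
`aggregate_protein_ratios(aggregate = "mean")`. A protein is retained in a
set only if supported by at least two distinct protein-unique peptide
sequences (modified forms of one sequence count once).

Two deliberate simplifications: no isotope-impurity correction is applied to
the reporter channels, and no global channel normalization is applied by
default (`median_center = FALSE`); both are upstream instrument/loading
corrections that the synthetic data does not need and real data may already
carry.

# The consensus filter chain

Per engine, proteins pass four stages, all boundaries inclusive:

1. **Identification**: $\ge 2$ unique peptides (above).
2. **Multi-set detection**: quantified in $\ge 3$ of the 4 sets.
3. **Average fold change**: the geometric mean of per-patient fold changes is
   $\ge 1.5$ (up) or $\le 1/1.5 \approx 0.667$ (down). The geometric mean is
   the natural average of multiplicative ratios and makes a doubled and a
   halved patient cancel exactly; the down threshold is the reciprocal of the
   up threshold, not a fixed $0.5$ — published panels include proteins at
   0.6-fold, which a $\le 0.5$ rule would wrongly discard.
4. **Trend agreement**: at least 7 of the 11 patients (64% of the
   population) lie on the called side of 1; a fold change of exactly 1, or a
   missing patient, counts as disagreement. Agreement is judged against the
   pooled-control ratio being above/below 1, not against the engine-average
   direction.

The two engine lists are then **intersected** (kept only when both engines
call the same direction) and **combined** into a union list; proteins the
engines call in opposite directions are excluded from both and logged. The
cardinality identity
$|union| = |L_1| + |L_2| - |intersection| - 2 \cdot conflicts$
is asserted in the test suite on every run.

External concordance uses two reference styles: a fold-change reference
(concordant when the reference ratio falls on the same side of 1 as the
call) and a categorical immunohistochemistry reference (the reference calls
"up" when the high + medium population fraction is $\ge 0.5$, inclusive).

# Network propagation

Candidate disease-associated interactors are prioritized by diffusing the
consensus list over a confidence-weighted, undirected PPI network. With $W$
the weighted adjacency matrix, $D$ the diagonal weighted-degree matrix and
$W' = D^{-1/2} W D^{-1/2}$, the iteration

$$F_t = \alpha\, W' F_{t-1} + (1 - \alpha)\, Y, \qquad F_0 = Y$$

is run until the L1 change between iterates falls below `tol`. $Y$ is the
0/1 indicator of the prior (consensus) proteins, and
$\alpha \in (0, 1)$ weighs network smoothing against the prior. Under the
symmetric normalization the spectral radius of $W'$ is at most 1, so for
$\alpha < 1$ the iteration converges to
$(1-\alpha)(I - \alpha W')^{-1} Y$; the test suite checks the iterative
solution against that dense linear solve to $10^{-8}$ on random graphs.
Only the largest connected component is propagated; nodes outside it are
dropped with a warning.

Tunable parameters, with defaults and rationale:

* `alpha = 0.8`: the original propagation literature reports robustness over
  a broad range; 0.8 favors network structure while keeping the prior
  visible. The source study does not state its value, so it is exposed as a
  parameter.
* `tol = 1e-6` (L1), `max_iter = 1000`: with `alpha = 0.8` the error
  contracts by a factor $\approx \alpha$ per step, so ~60--70 iterations
  suffice; `max_iter` is a safety cap and non-convergence is flagged, never
  silently accepted.
* `k = 50`, `final_k = 20`: the pooled prior list and every single-protein
  prior are each propagated, the 50 strongest non-prior proteins are taken
  from each ranking, and the final report is the pooled top-50 intersected
  with the union of the per-protein top-50s, cut to the 20 strongest by
  pooled score. "Strongest interactions" is read as *nodes* ranked by
  diffusion score, not edges, matching the first-degree-neighbor framing of
  the procedure; a strict first-degree filter (candidates must touch at
  least one prior) is on by default. The intersection uses the union of
  per-protein lists because a strict per-protein intersection across dozens
  of priors is empty in practice.
* Tie-breaking is deterministic — score, then number of adjacent priors,
  then identifier — so reports are bit-reproducible.
* No score cut-off is applied by default: selection is purely rank-based,
  since no usable threshold value is published.

Each neighbor is reported with its pooled rank, the number of priors whose
individual top lists contain it, and the number of priors it touches
directly (`common_prior_count`).

# MRM panel validation

A panel method requires at least 3 peptides per protein and 3 transitions
per peptide, unique transition ids, scheduled retention-time windows of
$\pm 1$ minute, and stores dwell (0.005 s) and pause (0.003 s) times as
metadata. Quantitation rolls up as: replicate injections (3 per sample) are
**averaged** per transition; a peptide's abundance is the **sum** of its
detected transition areas; a protein's abundance in a sample is the
**median** over detected peptides of log2 peptide abundance. Zero or missing
areas mean *not detected* and are excluded — never imputed as zero, which
would fabricate infinite fold changes.

Differential testing pairs tumor and control by patient: the protein's log2
fold change is the mean paired difference and the p-value comes from a
two-sided paired t-test (patients are matched pairs, so a paired design is
assumed). A protein is significant when fold change $\ge 1.5$ in either
direction and $p \le 0.05$; no multiple-testing correction is applied, and
proteins with fewer than 3 complete pairs are reported untested. The
original study delegated this step to a mixed-model package; this package
deliberately defines the simpler explicit estimator above so the computation
is self-contained and directly testable. Only relative quantification is
performed (no synthetic reference peptides).

# What the synthetic-data generator emulates

`sim_config()` fixes the study conditions; `simulate_truth()`,
`simulate_psm_tables()`, `simulate_network()`, `simulate_external_refs()`
and `simulate_mrm()` generate every pipeline input with the statistical
structure the analysis assumes:

* **Effects.** `round(frac_up * n)` up and `round(frac_down * n)` down
  proteins; each patient of a planted protein draws an effect magnitude
  $|N(\mu, \sigma)|$ in log2 units (`effect_log2fc_mean = 1`,
  `effect_log2fc_sd = 0.2`) and agrees with the planted direction with
  probability `trend_consistency = 0.9`. Discordant patients show a *weak*
  opposite change — their magnitude is attenuated by a $U(0,1)$ factor —
  because in real cohorts a patient that bucks the trend sits near the
  null, not at a full-strength inversion. Null proteins are exactly null.
* **Reporter noise.** Multiplicative log-normal noise with coefficient of
  variation `noise_cv = 0.2` on every reporter intensity (and MRM peak
  area), the standard noise model for reporter-ion data; the mean of the
  noise factor is 1 so ratios are unbiased. No published per-patient
  variance exists for this design, so `noise_cv` is a free parameter, not a
  fitted one.
* **Depth and detection.** Proteins average 5 peptides (at least 1) with 3
  PSMs per peptide per set; 95% of peptides are protein-unique. Engine
  detection uses one latent Gaussian per protein thresholded per engine
  (`engine_detect_prob = 0.995`, latent correlation
  `engine_overlap_corr = 0.5`), and a detected protein appears in any given
  set with probability `set_detect_prob = 0.99`. These defaults describe
  *confidently present* proteins — deep, nearly complete detection — which
  is the regime in which the filter chain's recovery behavior is
  well-defined; they were fixed once by a power analysis of the filter
  chain, not fitted to data.
* **Network.** A preferential-attachment backbone
  (`network_edges_per_node = 2`) with uniform $(0.5, 1]$ edge confidences;
  truth proteins are mapped onto random nodes. Hub planting is explicit
  configuration (`n_hubs`, `hub_prior_fraction`), wiring each hub to a
  fixed fraction of the differential proteins with high-confidence edges —
  emulating highly connected transcription-factor-like neighbors.
* **MRM.** Triplicate injections for 10 tumor/control pairs; a transition's
  area is protein abundance × peptide response × transition share ×
  log-normal noise.

Identical configurations (including the seed) give bit-identical outputs;
each simulator stage draws from its own seed offset so stages can be rerun
independently.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: spectrum-level artifacts (isotope impurity,
ratio compression from co-isolation), decoy/FDR behavior, shared-peptide
protein inference, batch and loading effects, and realistic engine
disagreement. In the published study the two engines overlapped far less
(94 common proteins out of lists of 147 and 232) than the simulated engines
do; the simulator models engines as concordant observers of the same truth,
which is the regime the recovery guarantees address. Recovering planted
effects here validates the *filter logic and its calibration*, not search
engines or instruments.

# Numerical and degenerate-input choices

* Fold changes stay on ratio scale in all tables; logs are taken only
  inside statistics. Boundary cases are inclusive throughout
  ($\ge 1.5$, $\ge 3$ sets, $\ge 7$ patients, $\ge 50\%$, $p \le 0.05$).
* A zero pooled-control intensity excludes the PSM (counted), never yields
  an infinite ratio.
* A paired test with zero-variance differences is degenerate; it returns
  $p = 1$ when the mean difference is 0 and $p = 0$ otherwise, rather than
  erroring.
* Isolated network nodes and small components are dropped before
  normalization (logged); a prior set that does not map to the network at
  all is an error, a partially mapping one a warning.
* All list selections (top-k, reports) use total, deterministic orderings.

# Problem sizes used by the shipped checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make every stochastic check sharp but quick: 200-protein studies
(10 seeds) for consensus recovery, 600 null proteins across 3 runs for
false-positive calibration, 500 null proteins for the paired-test type-I
error, 20 random graphs up to 200 nodes for the propagation oracle, 10
seeded networks with 5 planted hubs each for hub recovery, and a
9-protein + 20-null panel for MRM recovery. These sizes are the package's
own choices for a crisp, reproducible characterization of the method.

# Known limitations

* Protein identifiers are taken as given; no protein grouping or identifier
  harmonization between quantitation tables and the network is performed.
* The consensus stage computes no p-values and applies no multiple-testing
  correction — it is a fold-change/consistency screen by design, with the
  statistical test deferred to the targeted MRM stage.
* The MRM estimator is simpler than a full mixed model over peptides and
  transitions; with three peptides per protein and triplicate injections
  its paired t-test is slightly anti-conservative (empirical type-I error
  around 5--7%).
* The propagation stage ranks; it does not assign significance to
  neighbors.
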