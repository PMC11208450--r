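---
title: "Calling gene fusions from nCounter hybridization counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling gene fusions from nCounter hybridization counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusioncall)
```

## The problem

Most pediatric leukemias carry a diagnostic, prognostic or therapeutically
actionable gene fusion (*BCR::ABL1*, *PML::RARA*, *ETV6::RUNX1*, Ph-like
kinase fusions, ...). The NanoString nCounter platform detects these with
breakpoint-spanning hybridization probe pairs: molecules are counted
directly, without amplification, library preparation or a bioinformatics
pipeline, which makes the assay practical in laboratories without sequencing
infrastructure. The output of a run is a lane of raw counts per probe set —
internal assay controls (POS_A–F, a descending spike-in titration ladder, and
NEG_A–F, absent targets), five housekeeping genes (B2M, EEF2, GUSB, PGK1,
TBP) gauging RNA adequacy, and one probe set per fusion breakpoint.

`fusioncall` turns those counts into a reviewed clinical-style
interpretation: per-probe calls against background-calibrated cutoffs,
lane-level QC gates, a sample verdict with repeat/reflex recommendations,
concordance against the flow-cytometry immunophenotype, and a color-coded
run report. A seeded simulator generates whole runs with ground truth, so
every stage is testable offline.

## The calling model

Fusion probes report low, noisy background counts in fusion-negative
samples. For probe $p$, background is summarized by the mean $\mu_p$ and
sample standard deviation $s_p$ (denominator $n-1$) of counts over samples
negative for that fusion. Two cutoffs follow:

$$\mathrm{cut3}_p = \mu_p + 3 s_p, \qquad \mathrm{cut5}_p = \mu_p + 5 s_p.$$

A count strictly above $\mathrm{cut5}_p$ is **POSITIVE** (a strong indicator
of the fusion transcript); strictly above $\mathrm{cut3}_p$ but not above
$\mathrm{cut5}_p$ is **REVIEW** (flagged for repeat testing); otherwise
**NEGATIVE**. Both inequalities are strict: a count exactly equal to a
cutoff takes the lower status. We read "above the cutoff" literally and test
the boundary explicitly; with integer counts and fractional cutoffs the
distinction rarely matters in practice, but it must be deterministic.

The $n-1$ denominator is a deliberate choice: calibration cohorts are small
(tens of samples), and the wider cutoffs it yields are the conservative
direction for a positivity threshold. Cutoffs are kept at full precision
internally and rounded only for display.

A probe with fewer than two usable background values is flagged
`UNCALIBRATED` and never given a fabricated cutoff; a missing count (an
unparseable template cell such as a literal `F`) is `MISSING` and is never
coerced to zero anywhere in the pipeline.

### Per-instrument recalibration

Background levels differ between instruments, so cutoffs calibrated on one
instrument do not transfer. `recalibrate()` recomputes both cutoffs in full
from locally run fusion-negative samples (rather than rescaling the
originals — recomputation needs no extra assumptions and uses the same
estimator as the original calibration); probes that cannot be calibrated
locally inherit the base cutoffs and are flagged `inherited`.

## QC gates

**Assay controls.** The POS ladder must behave like a titration series: the
top control at or above `pos_floor` (default 1000 counts) and counts not
rising down the ladder beyond a tolerance factor (default 1.5× per step,
admitting counting noise at the dim end). The mean NEG count must stay at or
below `neg_ceiling` (default 50 counts). These three numbers are invented
defaults — no published rule exists, only the exemplar of a collapsed lane
whose top control read 35 against passing lanes reading 17,000–37,000 — so
all are configuration-exposed (`call_config()`), and the NEG check can be
disabled entirely.

**RNA quality.** A housekeeping probe passes when its count is strictly
above its threshold; a lane's RNA is adequate when at least 3 of 5 pass. A
missing housekeeping count is evaluable-and-failed (conservative). RNA
adequacy is a precondition for calling a lane *negative*, not positive: a
strong fusion signal in degraded RNA is still a finding, and is reported
with a note. The bundled worked example ships the template's fixed
thresholds; when a site needs to derive its own,
`derive_housekeeping_thresholds()` takes an externally judged RNA-adequate
cohort and sets each threshold at a lower quantile (default 0.05) of the
observed counts — the method is ours, since no derivation rule is published.

## The decision procedure

`interpret_sample()` applies gates in strict precedence:

1. **FAILED_ASSAY** — collapsed assay controls void the lane. No fusion
   calls are emitted even for counts above cutoff: without working
   chemistry a high count is uninterpretable. (The worked example's lane
   24C shows exactly this: an above-cutoff *PML::RARA* count voided by a
   collapsed ladder.)
2. **NOT_INTERPRETABLE** — half or more of the lane's fusion probes
   missing. The trigger is our own (the category exists in field practice
   but is undefined); 50% is configurable.
3. **HIGH_BACKGROUND** — more than `high_background_k` (default 5) distinct
   fusions at REVIEW or above. Genuine multi-fusion positives at diagnosis
   are rare, so diffuse elevation means too much input RNA; recommend
   repeating with less. The threshold of 5 is an invented default
   ("numerous probe sets" is not quantified) and configurable.
4. **POSITIVE** — any probe above its positivity cutoff; all positive
   fusions are reported (no ranking; display orders by count/cutoff ratio).
5. **REVIEW** — any probe in the review zone; repeat with more RNA, naming
   the flagged fusion(s).
6. **NEGATIVE** if RNA is adequate, else **FAILED_RNA** (repeat with more
   RNA).

Under reflex testing the second panel tube is run only when the first is
negative (`reflex_decision()`); a REVIEW or failed lane is repeated, not
reflexed — reflexing an unresolved lane would waste the reagent the reflex
strategy exists to save. A patient-level verdict across tubes is positive if
either tube is positive and negative only if all run tubes are negative.

## Concordance with flow cytometry

Each panel fusion maps to the leukemia lineages it is associated with
(e.g. *BCR::ABL1* → {B-ALL, CML}; *PML::RARA* → {AML}). A positive lane is
`CONCORDANT` when every called fusion's lineage set contains the flow
immunophenotype and `DISCORDANT` when some non-empty set excludes it; a
negative lane is `CONCORDANT` with flow showing no leukemia. Two edge cases
the mapping does not decide are resolved as follows: a *negative* lane in a
flow-confirmed leukemia is `NOT_ASSESSABLE` (roughly half of pediatric
leukemias carry no panel fusion, so negativity contradicts nothing), and a
*positive* lane with no leukemia by flow is `DISCORDANT`. Failed, review
and uninterpretable lanes, and fusions with no lineage annotation, are
`NOT_ASSESSABLE`.

## The synthetic generator

`synthetic_spec()` / `simulate_run()` emulate the count regimes a reviewer
sees in real runs:

- **Background** fusion counts are negative binomial with mean 8 and size
  10 (variance $\mu + \mu^2/\mathrm{size}$) by default — real hybridization
  background is overdispersed relative to Poisson, and Poisson is
  recoverable as the large-size limit. At these defaults the probability
  mass beyond $\mu + 5\sigma$ is about $2\times10^{-4}$ per probe
  (computed numerically from the NB tail), i.e. ≈ 99.7% of pure-background
  13-probe lanes call negative.
- **Spikes** plant a fusion at `fold_over_cut5` times the true positivity
  cutoff, drawn with size 500 (fusion signal is a high-count, tight
  measurement); a fold-2 spike is then missed with probability ~$10^{-5}$.
- **Degraded lanes** multiply housekeeping and fusion-signal means by a
  quality factor $q$ (default 0.1) — mimicking what partial RNA degradation
  does to hybridization yield.
- **Collapsed-assay lanes** draw the whole POS ladder at NEG level.
- **High-background lanes** multiply the fusion background mean by 8.
- Housekeeping means (30,000 / 10,000 / 800 / 3,000 / 200) and the POS
  ladder (top 30,000, decay 0.3 per step) mirror the magnitudes of a
  typical passing run.

Counts are integer draws with floor zero, and every run is reproducible
from its seed (the simulator restores the caller's RNG state). What the
generator does **not** emulate: probe cross-hybridization structure,
lane-position effects, binding-density saturation, or the correlated
degradation profile of real archival RNA. Passing synthetic tests therefore
demonstrates the correctness of the decision logic and estimators under the
stated noise model, not clinical performance on real samples — the bundled
worked-example run is the anchor to real data.

## Problem sizes and test design

The suite exercises: background-mean recovery on cohorts of 48 simulated
negatives across 20 seeds (estimates within 3 standard errors of truth for
≥ 95% of probes); calling sensitivity at fold-2 spikes and specificity on
pure background over 500 simulated lanes at the generator's calibrated
cutoffs (a REVIEW lane counts as a repeat request, not a positive call, so
specificity is assessed on the POSITIVE verdict); probe-status equivalence
against an independent brute-force re-scan on 1,000 random lanes; and the
boundary, precedence, reflex and round-trip properties individually. These
sizes keep the full suite under a minute while leaving the Monte-Carlo
margins comfortable.

## Known limitations

- Raw counts are compared to cutoffs directly; no lane normalization is
  applied. This matches the deployed workflow, but cutoffs are therefore
  instrument-specific by construction — recalibrate per instrument.
- The assay is diagnostic only: without amplification its sensitivity is
  far below what minimal-residual-disease monitoring requires.
- Housekeeping thresholds derived by the quantile helper depend on an
  externally supplied notion of "adequate RNA"; the helper makes no attempt
  to discover it.
- The bundled panel fixture covers the 13 fusion probes of the worked
  example, not a full production panel; manifests for larger panels load
  through the same format.
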