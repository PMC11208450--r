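# fusioncall

Interpretation pipeline for gene-fusion panels run on the NanoString
nCounter platform, as used for rapid pediatric leukemia diagnosis in
laboratories without sequencing infrastructure. The assay counts
hybridization events on breakpoint-spanning probe pairs; `fusioncall`
turns a run's raw lane counts into reviewed fusion calls: per-probe
positivity against background-calibrated cutoffs, assay-control and
RNA-quality gating, repeat-testing and reflex recommendations,
flow-cytometry concordance, color-coded run reports, and a seeded
simulator so the whole pipeline is testable offline.

## The statistic at the core

For each fusion probe set $p$, background counts over fusion-negative
samples give a mean $\mu_p$ and sample standard deviation $s_p$ (n−1
denominator). A lane's count $c_p$ is classified

- **POSITIVE** if $c_p > \mu_p + 5 s_p$ (a strong indicator of the fusion),
- **REVIEW** if $\mu_p + 3 s_p < c_p \le \mu_p + 5 s_p$ (flag for repeat),
- **NEGATIVE** otherwise —

with lane-level gates taking precedence: collapsed POS_A–F assay controls
void all calls (`FAILED_ASSAY`); diffuse elevation across many fusions
means too much input RNA (`HIGH_BACKGROUND`, repeat with less); and a lane
may be called fusion-negative only when at least 3 of 5 housekeeping genes
(B2M, EEF2, GUSB, PGK1, TBP) clear their thresholds (`FAILED_RNA`
otherwise, repeat with more). Cutoffs are recalibrated per instrument,
since background levels differ between machines. See the vignette
(`vignettes/fusion-calling.Rmd`) for the full model and the design
decisions behind it.

## Worked example

The package bundles a complete worked-example Heme 1 run — nine lanes,
thirteen fusion probe sets with their printed cutoffs, housekeeping
thresholds and assay controls — exhibiting every interpretation outcome:

```r
library(fusioncall)

fx <- table2_fixture()
interps <- interpret_run(fx$samples, fx$calibration, fx$manifest)
for (x in interps) print(x)
#> <interpretation '5'> POSITIVE: RUNX1::RUNX1T1
#> <interpretation '6'> REVIEW [review: CBFB::MYH11] -> REPEAT_MORE_RNA
#>   note: repeat with more RNA to check CBFB::MYH11
#> <interpretation '8'> NEGATIVE
#> <interpretation '15'> POSITIVE: RBM15::MKL1
#> <interpretation '16'> FAILED_RNA -> REPEAT_MORE_RNA
#>   note: RNA quality failed (0/5 housekeeping pass)
#> <interpretation '22'> POSITIVE: EBF1::PDGFRB
#> <interpretation '24'> POSITIVE: TCF3::PBX1
#> <interpretation '24C'> FAILED_ASSAY -> REPEAT_MORE_RNA
#>   note: assay controls failed; fusion counts not interpreted
#>   note: positive control ladder collapsed: top control POS_A = 35 below floor 1000
#>   note: positive control ladder collapsed: count rises at POS_B, POS_E
#> <interpretation 'IVS-020'> POSITIVE: PML::RARA
```

Lane 5 carries *RUNX1::RUNX1T1* (count 373 against a positivity cutoff of
142); lane 6 has one probe in the review zone (23 vs cutoffs 21/28), so it
is repeated rather than called; lane 16's housekeeping counts all fail, so
its negativity cannot be established; lane 24C's collapsed control ladder
voids an otherwise above-cutoff *PML::RARA* count; and IVS-020 is the run's
positive-control RNA, correctly positive for *PML::RARA*. Cohort tallies
exclude flagged control lanes:

```r
summ <- summarize_cohort(interps, is_control = names(interps) == "IVS-020")
summ$status_counts
#>          POSITIVE          NEGATIVE            REVIEW        FAILED_RNA
#>                 4                 1                 1                 1
#>      FAILED_ASSAY   HIGH_BACKGROUND NOT_INTERPRETABLE
#>                 1                 0                 0
```

A shell entry point wires the same pipeline
(`inst/scripts/fusioncall`): `calibrate`, `call`, `report`, `simulate` and
`concordance` subcommands; QC failures are results, not process errors, so
only usage problems exit nonzero.

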