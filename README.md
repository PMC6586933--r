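# caTrace

Calcium-imaging trace analysis for perfused tissue slices.

Confocal Ca²⁺-indicator recordings of acute slices — tracheal epithelium
probed with bitter tastants and artificial sweeteners, or any preparation
stimulated through a valve-switched perfusion system — produce one raw
fluorescence trace per cell (ROI) plus a stimulus schedule. Turning those
traces into "which cells responded to what, how strongly, and how fast"
involves a chain of small, error-prone conventions: baseline definition,
photobleaching correction, a thresholded responsiveness rule, artifact
exclusions, viability conditioning and small-sample statistics. caTrace
implements that chain as a tested, reproducible pipeline for experimenters
analysing such recordings, together with a ground-truth-labelled synthetic
generator so every stage can be validated without experimental data.

## The analysis in brief

* **Normalization**: $\Delta F/F_0 = (F(t) - F_0)/F_0$, with $F_0$ the mean
  fluorescence before the first stimulus application.
* **Bleaching**: the exponential decay observed in non-responding cells,
  $\bar F(t) = C + B e^{-t/\tau_b}$, is fitted by least squares and divided
  out (two-pass: responses are first called without correction to find the
  non-responders).
* **Responsiveness**: a cell responds to an epoch iff $\Delta F/F_0$ stays
  strictly above the prestimulus mean + 3 SD (15 s window) for at least
  5 s, starting within the search window after valve opening — and the cell
  shows neither a response to the Ringer (vehicle) application nor
  spontaneous activity.
* **Onset delay**: valve opening to the interpolated threshold crossing of
  the qualifying run.
* **Population summaries**: responder frequencies conditioned on the ATP
  viability control, per-cell response profiles and pairwise overlap
  (Venn) counts, before/after-treatment retention fractions, within-cell
  dose-response and repeated-stimulation normalization.
* **Statistics**: Pearson χ² on 2×2 responder tables (no continuity
  correction), exact/approximate Wilcoxon–Mann–Whitney U, exact one-sample
  sign test, and a Shapiro–Wilk / Jarque–Bera normality gate that routes
  comparisons to the nonparametric tests.

See `vignettes/calcium-trace-analysis.Rmd` for the full model, parameter
meanings and design rationale.

## Worked example

```r
library(caTrace)

cfg  <- synth_config(n_cells = 100, seed = 7)   # synthetic slice recording
gen  <- generate_recording(cfg)
norm <- normalize_recording(gen$recording)       # dF/F0 + auto bleach fit
calls <- call_recording(norm)                    # three-criterion calls
profiles <- build_profiles(calls)                # conditioned on ATP viability

frequency_table(profiles, c("denatonium", "saccharin"))
#>                  label      kind count denominator  percent percent_display
#> 1                  ATP viability    64          93 68.81720              69
#> 2           denatonium  compound    24          64 37.50000              38
#> 3            saccharin  compound    20          64 31.25000              31
#> 4           denatonium   profile    17          37 45.94595              46
#> 5 denatonium+saccharin   profile     7          37 18.91892              19
#> 6            saccharin   profile    13          37 35.13514              35

onset_delay_summary(calls, "denatonium")
#> $mean 12.0   $sem 0.335   $n 24

chisq_2x2(44, 5, 40, 7)
#> Pearson chi-squared (no continuity correction): statistic = 0.4824, p = 0.4874 (n = 96)
```

Reading the table: of 93 analysable cells (7 of 100 were excluded as
vehicle-responsive or spontaneously active), 64 (69 %) responded to the ATP
viability control; among those, 38 % responded to denatonium and 31 % to
saccharin; of the 37 cells responding to at least one tastant, 19 %
responded to both — close to the generator's configured responder
structure. The recovered denatonium onset delay (12.0 ± 0.3 s, n = 24)
matches the configured 12.1 s mean. The χ² line is the retention
comparison for a gap-junction-blocker experiment computed from its
published 2×2 counts.

A file-oriented front end mirrors the same steps
(`run_simulate`, `run_extract`, `run_call`, `run_analyze`), and
`inst/cli/catrace.R` exposes them as `simulate` / `extract` / `call` /
`analyze` subcommands:

```sh
Rscript inst/cli/catrace.R simulate --seed 1 --out-dir out/
Rscript inst/cli/catrace.R call     --traces out/traces.csv --out-dir out/
Rscript inst/cli/catrace.R analyze  --calls out/calls.csv \
        --schedule out/traces_schedule.csv --out-dir out/
```

All file formats are plain text (CSV traces/schedules/calls, YAML/JSON
configs) except image stacks (multi-page TIFF) and ROI label masks
(single-page 16-bit TIFF).

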