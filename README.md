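# mtordyn

Single-cell analysis of mTORC1 reporter dynamics: from fluorescence
trajectories and multiplexed immunofluorescence tables to per-cell
response metrics, volatility and reporter-coupling statistics,
analog/digital dose–response classification, and PLSR variance
decomposition of protein-synthesis labeling.

## The problem

mTORC1 integrates amino-acid, glucose, energy and growth-factor inputs
into one kinase activity controlling anabolic metabolism.  In live
cells it is read out by translocation reporters: mTORC1 phosphorylation
retains a truncated TFEB reporter in the cytosol, so the **C/N ratio**
(mean cytosolic ÷ mean nuclear fluorescence) rises with mTORC1
activity.  Companion reporters cover AKT (FOXO translocation), AMPK
(AMPKAR2 FRET) and protein synthesis (a stabilization reporter).  In
fixed cells, cyclic immunofluorescence yields per-cell intensities of
phosphorylated mTORC1 substrates plus an OPP protein-synthesis label.

`mtordyn` provides the quantitative layer for both data types, plus
seeded synthetic-data generators with known ground truth so every
statistic can be validated against a planted answer.  The package is
aimed at quantitative cell biologists analyzing kinase translocation
reporter or multiplexed immunofluorescence experiments.

## Core statistics

With a per-cell trace *x(t)* (C/N ratio or FRET ratio, sampled every
6–7 min) and a treatment at *t₀*:

* **Δi** = extremum of the 3-point-smoothed trace in *[t₀+30, t₀+60]*
  min minus the mean over *[t₀−30, t₀)* — the signed initial response.
* **Δss** = mean over *[t₀+180, t₀+240]* minus the same baseline — the
  steady-state response.
* **AMPKAR2 phosphorylation** = `2.74 · FRETratio − 0.59` (printed
  affine linearization).
* **RTA** = slope(post-stimulus) ÷ slope(pre-stimulus) of the
  translation reporter, Theil–Sen fitted.
* **CV** = sd/mean over a 2–6 h post-perturbation window, every other
  point (stride 2) to suppress imaging noise.
* **Coupling** = per-cell lagged cross-correlation of two reporters;
  median optimal lag; per-cell correlations at the median lag vs a
  *scrambled null* (randomly paired distinct cells).
* **Modality** = bimodal iff dip-test p < 0.05 **and** 2-vs-1 Gaussian
  mixture BIC margin > 10; a dose series is *analog* when all doses are
  unimodal with a monotone mean trend.
* **PLSR** = percent variance in (log) OPP explained by stain subsets,
  cross-validated, with the component count (dF) chosen by a one-SE
  rule; population-average models collapse to the 16 condition means
  with leave-one-condition-out.

Trace QC follows the published selection rules: mean intensity > 2×
background, span ≥ 8 h, no more than 3 contiguous missing points;
interior gaps are linearly interpolated.  Imaging follows the stated
mask geometry: nuclei eroded 2 px, cytoplasmic ring within 5 px
(Euclidean) of the nuclear border.

## Worked example

```r
library(mtordyn)

cfg <- sim_config(n_cells = 200, duration = 600,
                  treatment_schedule = treatment_schedule(120, "aa", 0.5),
                  latent_params = list(baseline_gf = 1),
                  reporter_params = list(
                    TFEB_TR = reporter_spec(ec50 = 0.4, hill_exp = 1.2)),
                  missing_rate = 0.03, seed = 42)
sim <- simulate_trajectories(cfg)

qc <- filter_traces(sim$traces, background = 100)
print(qc$report)
#> Trace QC report: 200 passed, 0 failed
#>   failures by reason: intensity = 0 , length = 0 , gap = 0

clean <- interpolate_set(qc$set)
m <- response_metrics(clean, t_treat = 120, treatment = "amino acids 0.5x")
mean(m$delta_i); mean(m$delta_ss)
#> [1] 0.5181531
#> [1] 0.4996008

cohort_cv(clean, t_perturb = 120, group_col = "dose")$summary
#>   group   n  median_cv     iqr_lo     iqr_hi
#> 1   0.5 200 0.04828278 0.04141956 0.05494998

cm <- classify_modality(m$delta_i, seed = 1)
sprintf("%s (dip p = %.2f, BIC margin = %.1f)", cm$call, cm$dip_p, cm$bic_margin)
#> [1] "unimodal (dip p = 0.37, BIC margin = -1.2)"

ampkar_phos(c(0, 0.5, 1))
#> [1] -0.59  0.78  2.15
```

Reading the numbers: a half-saturating amino-acid dose on an insulin
background moves the mean C/N by ≈ 0.52 within the first hour and the
response is sustained (Δss ≈ 0.50); per-cell volatility after the
stimulus is low (median CV ≈ 0.05); the per-cell Δi distribution is
unimodal — a graded, analog response, not a switch.  The AMPKAR2 map
reproduces its defining values (−0.59 at ratio 0).

A command-line front end covering simulation, QC, metrics, dynamics,
modality, PLSR and segmentation is installed at
`<library>/mtordyn/cli/mtordyn-cli.R` (run it with `Rscript` and no
arguments to see usage).

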