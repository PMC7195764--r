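# ascoh

Coherence analysis of beat-by-beat arterial-stiffness (AS) time series
for predicting post-spinal hypotension.

## The problem

Hypotension after spinal anesthesia for cesarean section is common and
clinically consequential; it is treated reactively with phenylephrine
boluses (100 mcg each) once systolic pressure drops below 90 mmHg.
Patients who will later need large cumulative vasopressor doses tend to
show slow, coherent modulations — time scales on the order of 3 minutes —
in their pre-induction arterial-stiffness signal, while patients with
mild courses show low-coherence noise.  `ascoh` implements the full
analysis that turns this observation into a prediction pipeline, for
anesthesiology and biosignal researchers who want to reproduce, stress
or extend it.

## The method

For each patient, a non-uniform beat-by-beat AS series is spline-resampled
to a uniform 10 Hz grid (5x oversampling of the 1–2 Hz beat band at heart
rates of 70–103 bpm) over a 2000 s analysis window (20,000 samples).
The biased, mean-subtracted autocorrelation spectrum

    r(k) = c(k) / c(0),    c(k) = (1/N) Σᵢ (xᵢ − x̄)(xᵢ₊ₖ − x̄)

is computed for lags 0 … 2000 s, and coherence is summarized by the
absolute-area statistic

    M = Σ_{100 s ≤ lag < 2000 s} |r(lag)| · Δlag ,   Δlag = 0.1 s,

which isolates long-range coherent structure from short-range
correlation.  `M` is assessed as a classifier of severe hypotension
(cumulative phenylephrine dose > threshold) by ROC/AUC analysis with the
Youden index `J = sensitivity + specificity − 1` selecting the operating
point, swept across dose thresholds.  The same classification task is
given to a from-scratch single-hidden-layer feed-forward network
(12 log-sigmoid nodes, full-batch gradient descent on MSE, learning rate
0.01, random 0.7/0.15/0.15 train/validation/test splits, early stopping
after 6 stalled epochs), evaluated over multi-run ensembles with
node-count and layer-depth sweeps.  Because the original patient
recordings are not public, a synthetic-cohort generator reproduces the
statistical skeleton of the data (heart-rate bounds, 3-minute severe-class
modulations, dose distribution near mean 462 / SD 299 mcg) so every stage
can be validated against known ground truth.

## Worked example

```r
library(ascoh)

coh <- generate_cohort(cohort_config(seed = 2026))
coh
#> <cohort> 45 patients (23 severe / 22 mild), dose mean 458 mcg, SD 315 mcg

metrics <- cohort_metrics(coh, keep_spectra = TRUE)
truth <- as.integer(metrics$latent_class == "severe")
roc_curve(metrics$metric, truth)
#> <roc_result> AUC = 1.000 (n+ = 23, n- = 22); Youden J = 1.000 at cutoff 525.2 (sens 1.00, spec 1.00)

dose_threshold_sweep(metrics, seq(300, 600, by = 100))$table
#>   threshold_mcg       auc  youden_j sensitivity specificity n_pos n_neg
#> 1           300 0.9226190 0.7797619   0.8750000   0.9047619    24    21
#> 2           400 0.9347826 0.8221344   0.9130435   0.9090909    23    22
#> 3           500 0.9271255 0.8461538   1.0000000   0.8461538    19    26
#> 4           600 0.9073276 0.7650862   0.9375000   0.8275862    16    29

feats <- prepare_inputs(attr(metrics, "spectra"), 400)
run_ensemble(feats, truth, mlp_config(hidden_layers = 12, n_runs = 20, seed = 7))
#> <run_ensemble> 20 runs (12 network): mean error 0.116 (SD 0.008, range 0.031), mean AUC 1.000, 1 degenerate run(s)
```

Reading the output: the coherence metric separates the latent severity
classes perfectly on this synthetic cohort (AUC 1.0 against ground
truth), while labelling by noisy dose thresholds — the only label
available in practice — peaks at the 400 mcg threshold (AUC 0.93).  The
network ensemble reaches mean test AUC 1.0; its mean absolute error of
0.12 reflects continuous sigmoid outputs that classify correctly without
saturating at 0/1.  One of the 20 random test splits contained a single
class and is flagged degenerate rather than scored.

`run_pipeline(pipeline_config(), "out/")` runs all of the above end to
end and writes per-patient metrics, sweep tables, ensemble results and a
JSON summary, each artifact stamped with the config hash and seed.

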