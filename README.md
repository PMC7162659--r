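# gbodykit

Quantitative analyses of RNA-nucleated glycolytic (G) bodies — the
membraneless granules into which yeast glycolysis enzymes condense under
hypoxia — packaged as tested, reusable R functions with synthetic-data
generators for every input.

G-body biology poses six recurring quantitative problems, and this package
implements each as a small, composable module:

1. **PAR-CLIP binding-site calling.** Aligned reads carrying 0–2 T-to-C
   conversions (the 4-thiouridine crosslink signature) are aggregated into
   sites; site coverage is scored in reads per million mapped (RPM), and a
   data-driven RPM threshold is selected where the mean two-sample
   Kolmogorov–Smirnov statistic between repeated 20% subsamples of the
   thresholded sites stabilizes (10,000 subsample pairs per threshold on a
   36-point grid over 0–25 RPM). Sites are then classified across datasets
   (identical / overlapping / unique), annotated to genic regions, and
   compared with expression via log10(site RPM / gene RPKM).
2. **RIP-seq / qPCR enrichment.** Per-gene fold change of IP over
   flow-through and over total RNA on RPM with a 0.5 pseudocount, unpaired
   Student t-tests across replicates, and a high-confidence set passing
   fold > 2, p < 0.05 against both references; chi-square overlap tests
   against independent gene sets; qPCR percent of input with the
   log2(1/fraction) cycle correction (2 cycles for a 25% flow-through).
3. **Puncta quantification.** Each fluorescent focus in a 4.9 µm patch is
   fitted by nonlinear least squares to a rotated 2D Gaussian
   `b + A·exp(−(aΔx² + 2cΔxΔy + dΔy²))` with σx, σy in px and µm;
   cells are classified none/single/multiple and condition fractions
   compared with Bonferroni-corrected t-tests.
4. **smFISH colocalization.** Otsu segmentation of the G body, spots in
   the focal plane ± 1 slice, Euclidean distance profiles (percent within
   one 0.13 µm pixel, boundary inclusive), and cumulative-distribution
   fold change against a control mRNA with a bootstrap null band.
5. **FRAP kinetics.** Background and acquisition-photobleach correction
   against ≥ 3 unbleached control cells, a strict <40%-remaining bleach
   filter, and least-squares fits of `I(t) = A(1 − e^(−τt))` with
   half-time ln(2)/τ (40-min window; 25 min for plasmid constructs).
6. **Competition fitness.** The mixed-culture composition
   `f_GB+ = (%mix − %GB−)/(%GB+ − %GB−)` with a binomial bootstrap, and
   generations from optical density, log2(OD_end/OD_start).

A `synthetic_data` layer generates every input with known ground truth —
planted binding sites with conversion-bearing reads, negative-binomial
RIP-seq counts with exact planted fold, Gaussian puncta and mRNA spots
under Poisson noise, exponential FRAP traces with acquisition bleaching,
and binomial competition counts — so the whole pipeline is testable
offline. See `vignettes/gbody-quantification.Rmd` for models, parameter
defaults, and design decisions.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running
it end to end regenerates all synthetic inputs and the derived tables
under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

Script 04, for instance, quantifies G-body size in an untreated condition
versus an aliphatic-alcohol condition with planted shrinkage, and prints:

```
untreated: 9 maxima detected (9 planted)
  mean sigma_x 1.12 um, sigma_y 1.07 um, amplitude 18521 (planted 1.10 um / 18521)
hexanediol: 9 maxima detected (9 planted)
  mean sigma_x 0.74 um, sigma_y 0.71 um, amplitude 12180 (planted 0.72 um / 12171)
sigma shrinks under the hexanediol-like condition:
     axis condition_a condition_b    t        p    p_adj
1 sigma_x   untreated  hexanediol 16.4 1.94e-11 3.89e-11
2 sigma_y   untreated  hexanediol 17.7 6.35e-12 1.27e-11
```

i.e. every planted focus is detected, the fitted Gaussian widths and
amplitudes recover the planted values to a few percent, and the
size reduction is detected at Bonferroni-adjusted p ≈ 4×10⁻¹¹. Script 03
reports a RIP-seq screen with sensitivity 0.95 and FDR 0.00 against the
planted 4-fold enriched genes plus qPCR percent-of-input values between
1.5% and 6.3%; script 07 estimates the mixed-culture GB+ fraction at
0.65 (planted 0.65) with bootstrap intervals of ±0.013.

A one-call version of the whole workflow is `run_demo(default_config(1))`,
which returns the same stage summaries as a deterministic report.

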