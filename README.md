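# spotdecon

Deconvolution, single-cell decomposition and spatial imputation for
spot-based spatial transcriptomics (ST), in R.

Sequencing-based ST platforms (Visium and kin) return whole-transcriptome
counts at ~55 µm spots, each covering several cells of mixed type, with
roughly half of the section falling between spots. Given an annotated
scRNA-seq reference, `spotdecon`:

1. **selects marker genes** per cell type (fold-change quantile
   `f_gt(v) > l_fold`, one-sided Welch z-tests `max λ < l_λ`, coverage
   `w > l_cover`) and builds the signature matrix
   `φ̂_tg = Σ_{τ(c)=t} y_cg / Σ_{τ(c)=t} Σ_g' y_cg'` (rows sum to 1);
2. **deconvolves** spot counts under a multinomial generative model
   `x_s ~ Multinomial(m'_s, ρ̃_s)` with gene mixture `ρ = QΦ` and
   per-gene log2 batch effects `ρ̃_sg ∝ ρ_sg·2^{r_g}`, fitted by MAP
   (Dirichlet(1) prior on contribution scores Q, Normal(0,1) on r, Adam
   on analytic gradients, deterministic given the seed);
3. **decomposes** every spot's counts into per-cell expression (iscRNA):
   integer cell counts by L1-optimal largest-remainder apportionment of
   the nucleus count `N_s`, gene-wise splits
   `û_stg = x_sg · p̃_st φ_tg / Σ_t' p̃_st' φ_t'g` that conserve the input
   matrix bit-exactly;
4. **imputes** proportions for nuclei outside capture areas with per-type
   Gaussian-process regression (squared-exponential kernel) and their
   expression with kernel smoothing of per-cell profiles, yielding a
   typed whole-slide pseudo-single-cell table.

A simulator with known ground truth (hex grid, scRNA cell sampling,
batch/dropout/noise corruption at three severities) and the six standard
per-spot metrics (absolute error, square error, JSD, Pearson, cosine,
fraction correctly mapped) make the whole pipeline testable offline.

## Worked example

Simulate a slide from a small synthetic reference, run the full pipeline,
and score the recovered proportions against the generator's truth:

```r
library(spotdecon)

set.seed(7)
types <- c("astro", "neuron", "oligo")
base <- matrix(rgamma(3 * 200, 2, 2), 3, 200)
for (t in 1:3)                       # plant 20 strong markers per type
  base[t, ((t - 1) * 20 + 1):(t * 20)] <- base[t, ((t - 1) * 20 + 1):(t * 20)] * 8
labels <- rep(types, each = 25)
counts <- t(sapply(seq_along(labels), function(i)
  rpois(200, base[match(labels[i], types), ] * 5)))
rownames(counts) <- sprintf("cell%03d", seq_along(labels))
colnames(counts) <- sprintf("gene%03d", 1:200)
scrna <- annotated_counts(counts, labels = labels)

truth <- generate_truth_pattern(S = 60, T_types = 3,
                                pattern = "gaussian-bumps", seed = 7,
                                type_ids = types)
sim <- simulate_spots(scrna, truth, noise_level = "medium", seed = 7)

res <- run_pipeline(sim$X_sim, scrna, truth$geometry,
                    nuclei = truth$nuclei,
                    config = pipeline_config(n_iterations = 2000,
                                             learning_rate = 0.03,
                                             seed = 7))
res
#> pipeline_result: 60 spots x 3 types, 146 marker genes, 394 cells

benchmark_report(res$P, truth$P_true)
#> metric_report over 60 spots (overall Pearson 0.9917)
#>            metric        mean      median
#>    absolute_error 0.070519925 0.063565095
#>      square_error 0.003313628 0.001588488
#>               jsd 0.049550590 0.044324466
#>           pearson 0.989177745 0.997066982
#>            cosine 0.996943513 0.998667304
#>  fraction_correct 0.964740038 0.968217452

head(res$cells$meta, 3)
#>   nucleus_id    spot   type        x         y provenance
#> 1   nuc00001 spot001  astro 131.1054  98.87748 decomposed
#> 2   nuc00005 spot001  astro 131.5318 158.98572 decomposed
#> 3   nuc00002 spot001 neuron 118.0537 123.16730 decomposed
```

Even at the medium corruption level the per-spot compositions track the
truth closely (mean JSD ≈ 0.05 on a 0–1 scale; overall Pearson 0.99
across the flattened spot × type matrix), and every nucleus on the slide
— inside or outside a spot — carries a type and an expression profile.
`merge_iscrna_to_pseudo_spots(res$cells)` reproduces the input count
matrix, a conservation property the test suite checks bit-exactly at the
spot × gene level.

## Command line

A thin dispatcher wraps the exported functions:

```sh
Rscript inst/cli/spotdecon.R simulate   --scrna sc.mtx --labels sc_labels.csv \
                                        --pattern blocks --spots 100 --noise medium --out simdir
Rscript inst/cli/spotdecon.R reference  --scrna sc.mtx --labels sc_labels.csv --out signature.csv
Rscript inst/cli/spotdecon.R deconvolve --st simdir/st.mtx --signature signature.csv --out props.csv
Rscript inst/cli/spotdecon.R evaluate   --est props.csv --truth simdir/truth_n_st.csv --out report.csv
Rscript inst/cli/spotdecon.R pipeline   --config run.json
```

## Vignette

`vignettes/spotdecon-methods.Rmd` documents the generative model and its
assumptions, every tunable parameter with units and defaults, what the
simulator does and does not emulate, numerical conventions, and known
limitations.
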