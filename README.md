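# dragoncolour

Genetic and environmental partitioning of continuous dorsal colouration in
lizards, from standardised photographs to heritability estimates.

Captive jacky dragons (*Amphibolurus muricatus*) show continuous variation
in three aspects of dorsal colouration: overall **brightness**, the
**elongation** of the pattern (separate blotches versus fused longitudinal
stripes) and the **contrast** between its lightest and darkest elements.
This package is for quantitative geneticists and colour-pattern researchers
who want to (i) measure those three responses from rectangular dorsal
"swatch" images and (ii) estimate their narrow-sense heritability with a
Bayesian animal model over a breeding-design pedigree, while controlling
for sex, age, sampling year and experimental thermal treatments of both
parents and offspring.

## The model

Per-pixel brightness is $(R/255 + G/255 + B/255)/3$. Pixels are assigned to
$k$ colour classes by k-means; adjacent sampled pixel pairs are tallied by
direction, and elongation is the smoothed transition-density ratio
$E = \frac{(T_{LR}+1)/(N_{LR}+2)}{(T_{UD}+1)/(N_{UD}+2)}$ (higher when
along-body transitions are rarer than across-body ones). Contrast is the
brightness difference between the brightest and darkest class centroids.

Each metric $y$ is then modelled with the animal model

$$y = X\beta + Z_a a + Z_d d + Z_p p + Z_o o + e, \qquad
a \sim N(0, A\sigma^2_A),$$

where $A$ is the pedigree-derived additive relationship matrix and $d, p,
o$ are maternal-identity, parental-cage and offspring-cage effects. A Gibbs
sampler (RcppArmadillo; joint location updates via the mixed-model
equations, scaled-inverse-chi-square variance updates with prior $V = 1$,
$\nu = 0.002$) yields posterior draws, and heritability is computed per
draw as

$$h^2 = \sigma^2_A / (\sigma^2_A + \sigma^2_{dam} + \sigma^2_{pcage} +
\sigma^2_{ocage} + \sigma^2_R).$$

A direct REML implementation (`reml_oracle()`) provides an independent
cross-check of the sampler, and a synthetic-data module simulates the whole
study — pedigree, covariates, latent traits and rendered swatch images with
known ground truth — so every stage is testable offline.

## Worked example

```r
library(dragoncolour)

# a synthetic study: ~195 offspring from 39 dams over two seasons
sim <- simulate_pedigree(breeding_config(seed = 42))
records <- simulate_records(sim$pedigree, sim$covariates,
                            default_truth(), seed = 7)

# render a swatch per individual and measure it
images  <- render_study_swatches(records, seed = 8)
metrics <- run_metrics(images, k = 3, seed = 9)$metrics

# fit the three animal models (desk-scale chain)
res <- run_models(metrics, sim$covariates, sim$pedigree,
                  n_iter = 50000, burnin = 5000, thin = 50, seed = 10)
res$fits$brightness$h2
```

```
run_metrics: 196 image(s) kept, 0 discarded
h2 posterior mode 0.1284 (95% HPD 0.0468, 0.3913; 900 draws)
```

The generating truth for brightness had $h^2 = 0.16$: the posterior mode
sits nearby and the 95% highest-posterior-density interval comfortably
covers it — intervals this wide are exactly what a ~180-animal design
supports. (Metrics measured from rendered images carry measurement error,
so their heritabilities are attenuated relative to the latent truth; the
effect is strongest for elongation, whose latent-to-image mapping is the
most nonlinear.) `res$fits$<trait>$coefficients` holds the 10-row fixed-effect
table (posterior mode, 95% HPD, pMCMC per term) and
`res$fits$<trait>$variance_summary` the five variance components.

The numbered drivers under `analysis/` run the same workflow as a
narrative: `01_simulate.R` (synthetic study + swatch PNGs),
`02_metrics.R` (measurement + fixed-k concordance check), `03_fit.R`
(three model fits, JSON/CSV reports), `04_recovery.R` (parameter-recovery
benchmark across true $h^2 \in \{0, 0.2, 0.5\}$), writing everything under
`results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main analysis from scratch at the given seed —
simulating the breeding design, rendering and measuring all swatches, and
fitting the three animal models — printing the per-trait heritability
summaries it obtains and writing the result JSON to `--out`.

See `vignettes/methods.Rmd` for the full account of the model, the
synthetic world's assumptions, numerical conventions and known limitations.
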