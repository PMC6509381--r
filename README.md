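# coastniche

Presence-only niche modelling for coastal species under climate change and
sea-level rise, with variance-based global sensitivity analysis and a
four-set attribution of habitat change.

Coastal species — salt-marsh plants in particular — respond jointly to
climate and to sea level: warming shifts the climatic envelope while a rising
sea inundates the lowest elevations and pushes the habitable band landward.
Assessments that vary one driver at a time miss the interaction between the
two. `coastniche` implements a complete workflow for separating them:

1. **Maximum-entropy niche model.** Habitat suitability is modelled from
   presence records and background cells as a Gibbs distribution over the
   landscape, `P(x) = exp(λ·f(x)) / Z`, with linear, quadratic and hinge
   features on continuous predictors and level indicators on categorical
   ones, fitted by minimizing the L1-penalized log loss
   `-(1/n) Σᵢ λ·f(xᵢ) + log Z + Σⱼ βⱼ|λⱼ|` (a convex problem, solved by
   accelerated proximal gradient). Suitability is reported on the cloglog
   scale `1 − exp(−e^H · raw)`, with `H` the entropy of the fitted raw
   distribution.
2. **Model tuning and evaluation.** The regularization multiplier (RM) and
   feature-class combination (FC ∈ {L, LQ, LQH}) are tuned by AICc
   (`2k − 2lnL + 2k(k+1)/(n−k−1)`, `k` = nonzero coefficients); performance
   is measured by rank AUC and the true skill statistic
   `TSS = sensitivity + specificity − 1` under 10-fold cross-validation.
   Binarization uses three standard cloglog threshold rules (maximum
   sens+spec; 10% training presence; equal sensitivity/specificity) combined
   into a TSS-weighted average threshold.
3. **Extended-FAST global sensitivity analysis.** Each predictor is driven
   along a sinusoidal search curve (`Ns = 2·M·ω_max + 1` model runs per
   factor, one block per factor) through the inverse CDF of its fitted
   marginal distribution; first-order (`S_F`) and total (`S_T`) sensitivity
   indices are read off the Fourier spectrum of the predicted suitability.
   `S_T − S_F` measures how much a variable acts through interactions.
4. **Scenario projection and Venn attribution.** Habitat maps are binarized
   under current conditions (CUR) and three futures — climate change only
   (CLC), sea-level rise only (SLR), both (CCS). The change between CUR and
   CCS is decomposed cell by cell into *pure climate*, *pure sea-level-rise*,
   *shared* and *coupling* effects via four-set algebra, and reported as an
   area table (km² and percentages) plus a coded change map.
5. **Synthetic coastal landscape.** A generator builds 15 co-registered,
   spatially autocorrelated raster layers (7 bioclimatic, 6 soil of which 2
   categorical, elevation with a coastal ramp), a known "true" suitability
   surface, presence samples from it, and the future scenarios — so the whole
   pipeline runs and is testable with no external GIS data.

## Worked example

```r
library(coastniche)

stack <- synth_landscape(grid_spec(60, 120, 1), seed = 42)
truth <- true_model(stack)                      # known generating model
occ   <- sample_occurrences(stack, true_suitability(truth, stack),
                            n = 200, seed = 1)
occ   <- thin_occurrences(occ, cell_size = 1)   # one record per cell
pres  <- extract_predictors(occ, stack)
bg    <- sample_background(stack, 4000, seed = 2)

keep  <- c("Bio02", "Bio08", "Toc", "Elevation")
tuned <- tune_maxent(pres[keep], bg[keep], rm_list = 1:2,
                     fc_list = c("L", "LQ"),
                     config = maxent_config(n_hinge_knots = 10))
tuned
#>  rm fc k       lnL    aicc
#>   1  L 4 -1239.253 2486.74
#>   1 LQ 4 -1233.462 2475.15
#>   2  L 2 -1246.250 2496.57
#>   2 LQ 4 -1239.787 2487.80
#> best: rm = 1, fc = LQ (AICc 2475.15)
```

The AICc-selected model separates presences from background well
(training AUC 0.919), and the three threshold rules agree closely:

```r
model <- tuned$best_model
sp <- predict(model, pres[keep]); sb <- predict(model, bg[keep])
thr <- habitat_thresholds(sp, sb)
thr
#> thresholds: MTSS 0.4036 (TSS 0.763), PTSS 0.4312 (TSS 0.739), ETSS 0.4555 (TSS 0.702)
#>   weighted average threshold: 0.4294
```

The sensitivity analysis recovers the generating structure — Elevation and
Bio02 carry nearly all the variance, and their totals exceed their main
effects, i.e. they act partly through interactions:

```r
stack_k <- stack
stack_k$layers <- stack$layers[keep]; stack_k$kinds <- stack$kinds[keep]
sens <- efast_gsa(model, stack_k, M = 4, omega_max = 64, seed = 3,
                  n_repeats = 3)
sens
#> eFAST sensitivity (M = 4, omega_max = 64, Ns = 513, 3 repeats)
#>   variable             S_F rank             S_T rank   diff rank
#>      Bio02 0.1020 (0.0022)    2 0.2744 (0.0008)    2 0.1724    2
#>      Bio08 0.0009 (0.0005)    3 0.0086 (0.0003)    3 0.0077    4
#>        Toc 0.0001 (0.0000)    4 0.0085 (0.0002)    4 0.0083    3
#>  Elevation 0.7199 (0.0072)    1 0.8932 (0.0028)    1 0.1733    1
#> Sum: S_F 0.8229, S_T 1.1847, diff 0.3617
```

Projecting to the three futures and decomposing the change attributes each
gained or lost square kilometre to one driver, both, or their coupling:

```r
scen <- make_scenarios(stack, deltas = list(Bio02 = 1.0, Bio08 = 1.5),
                       rise = 1)
sh     <- scenario_habitats(model, scen, thr$weighted)
decomp <- decompose_change(sh)          # convention = "as_printed"
area_table(decomp)
#>   direction H_p_clc pct_p_clc H_p_slr pct_p_slr H_s_ics pct_s_ics H_c_ics pct_c_ics H_changed pct_changed
#> 1 increased       0      0.00      14    100.00       0         0       0      0.00        14         100
#> 2 decreased     233     56.83      90     21.95       0         0      87     21.22       410         100
```

Here warming (a +1 °C shift of the diurnal-range layer against a negative
response) mostly removes habitat (233 km², 56.8% of the loss), a 1-m rise
inundates another 90 km², 87 km² disappear only when the two act together
(coupling), while the small gain is a band uncovered by the landward shift
of the suitable elevation zone.

The whole workflow — screening, tuning, cross-validation, GSA, projection,
decomposition, reports — also runs as one call:

```r
run <- run_pipeline(default_config(seed = 7))
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model, the
sensitivity estimator, the attribution algebra, the synthetic-landscape
design and the package's numerical choices in detail.
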