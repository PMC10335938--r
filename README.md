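# hoxtimer

A stochastic loop-extrusion model of the **Hox timer**: the sequential,
3'-to-5' temporal activation of the mouse HoxD genes during axial
elongation in gastruloids. The package is for computational biologists who
want to simulate, perturb and quantify the mechanism by which oriented
CTCF-binding sites (CBSs) pace colinear gene activation.

## The model

The HoxD locus is represented as a 1D lattice (chr2:73,900,037–75,621,560
at 2-kb bins). Three coupled stochastic layers reproduce the
condensation → translocation → progression sequence:

* **Extrusion engine.** Cohesin loads at rate proportional to a
  transcription-coupled profile (the NIPBL proxy), extrudes bidirectionally
  at `v·bin_size/dt` bp/h, stalls at occupied CBSs whose orientation
  opposes its travel (probability `p_stall`), bypasses a stall with
  probability `p_bypass` per step, and unloads — more slowly while
  anchored at a CBS (`stall_unload_factor`), which lets loops migrate down
  the convergent CBS series.
* **Activation layer.** After the Wnt pulse (72 h) the CTCF-free anterior
  genes fire at rate `anterior_activation_rate`. Once the sub-TAD1
  enhancers are active (96 h), a silent gene fires with hazard
  `k_act · C_gE · att`, where `C_gE` counts extruded loops spanning both
  the gene and the enhancer region (the gene has "fallen into the positive
  domain") and `att` is a polycomb attenuation lifted by a repressive-mark
  retraction front that follows transcription at `erasure_velocity` bp/h.
  Every activated gene becomes a loading site: a self-propagating relay.
* **Observables.** Anchor-occupancy tracks (RAD21 proxy) and their
  per-CBS share shifts, bridging contact maps with virtual 4C,
  mean-contact curves and centroid migration against CS38-40, micro-TAD
  split scores, cumulative and hour-interpolated signal timecourses,
  FPKM-like expression proxies with posterior dilution, cross-cluster
  normalization, Welch genotype comparisons, and a Spearman colinearity
  score.

A genotype-editing engine reproduces the CBS perturbation experiments
(Del(CBS1), Del(CBS2), Del(CBS4), Del(CBS1-2), Del(CBS1-5),
Ins(2xCBS-d4d8)), and a synthetic-data module generates waves, structured
contact matrices, expression tables and valid-pair lists with known ground
truth for every analysis operation.

## Worked example

```r
library(hoxtimer)

locus <- hoxd_locus()
locus
#> <hox_locus> chr2:73900037-75621560 [WT]
#>   10 genes, 14 CTCF sites (9 in-cluster), 9 regions

res <- run_timer(locus, seed = 1)
res
#> <timer_result> genotype WT, seed 1
#>   onsets (h): Hoxd1=90.4, Hoxd3=77.2, Hoxd4=72.8, Hoxd8=97.0, Hoxd9=107.0,
#>   Hoxd10=119.8, Hoxd11=130.1, Hoxd12=143.7, Hoxd13=146.9, Evx2=149.3

runs <- run_replicates(locus, 1:10, keep_trajectory = FALSE)
onsets <- onset_table(runs)
round(apply(onsets, 2, median), 1)
#>  Hoxd1  Hoxd3  Hoxd4  Hoxd8  Hoxd9 Hoxd10 Hoxd11 Hoxd12 Hoxd13   Evx2
#>   79.5   77.5   78.5   96.7  107.7  119.7  130.7  145.8  149.3  152.3

median(apply(onsets, 1, colinearity_score, locus = locus))
#> [1] 0.988

mut <- apply_genotype(locus, hoxd_mutants()[["Del(CBS1)"]], label = "Del(CBS1)")
mruns <- run_replicates(mut, 1:10, keep_trajectory = FALSE)
wilcox.test(onset_table(mruns)$Hoxd8, onsets$Hoxd8, alternative = "less")$p.value
#> [1] 0.000641
```

The onset medians read directly in model-hours on the gastruloid protocol
clock: the anterior CTCF-free genes complete shortly after the Wnt pulse,
the central genes follow stepwise as extrusion bypasses CBS1 and CBS2, and
the posterior genes close the series — a colinearity score near 1.
Deleting CBS1 significantly advances Hoxd8, the gene immediately 5' of the
deleted site.

`vignettes/hox-timer-model.Rmd` documents the model, its parameters and
the design decisions; `scripts/calibrate.R` is the grid search that
produced the shipped default configuration.

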