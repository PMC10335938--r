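---
title: "A loop-extrusion model of the HoxD activation timer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A loop-extrusion model of the HoxD activation timer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

During axial elongation, the genes of a Hox cluster switch on one after the
other in the order they sit on the chromosome, 3' genes first and 5' genes
last — the *Hox timer*. In mouse gastruloids ("stembryos"), the HoxD cluster
runs through this program between roughly 72 and 144 hours after cell
aggregation: the anterior, CTCF-free part of the cluster (Hoxd1–Hoxd4) fires
quasi-simultaneously after the Wnt-agonist pulse, Hoxd8/Hoxd9 follow around
108 h, Hoxd10/Hoxd11 around 132 h, and Hoxd13 around 144 h. The pace of this
progression depends on a series of oriented CTCF-binding sites (CBSs) inside
the cluster: deleting the first site advances the next genes, adding extra
sites delays them, and removing the whole anterior series (CBS1–CBS5)
largely collapses the schedule while leaving a weak colinear remnant.

`hoxtimer` implements this mechanism as a stochastic one-dimensional model
with three coupled layers:

1. **Condensation.** The cluster starts as a silent, polycomb-covered
   (H3K27me3) domain. A ~20-kb element containing CBS1 is annotated as
   pre-looped (depleted of the repressive mark before activation).
2. **Translocation.** After the Wnt pulse (`t_wnt`, 72 h), the CTCF-free
   anterior genes fire independently at a fixed rate. Transcribed gene
   bodies become cohesin-loading sites (the NIPBL proxy), so loop extrusion
   starts from the active segment and the cluster splits into an active
   anterior and an inert posterior micro-TAD.
3. **Progression.** Extruding cohesin stalls at occupied CBSs whose
   orientation opposes its travel, bypasses them stochastically, and loops
   the growing active domain onto the sub-TAD1 enhancers in T-DOM. A silent
   gene activates when it falls into this positive loop domain; every newly
   activated gene becomes a loading site in turn, feeding a self-propagating
   relay down the cluster.

## The lattice and the wild-type fixture

The modeled axis spans chr2:73,900,037–75,621,560 (1.72 Mb), discretized
into 2-kb bins (861 bins), the finest resolution of the contact maps the
model is compared against. `hoxd_locus()` builds the wild-type annotation:
ten genes in canonical 3'→5' order, nine occupied in-cluster CBSs (CBS1,
CBS2, CBS4, CBS5 oriented toward T-DOM; CBS3 and CBS6–CBS9 toward C-DOM),
five T-DOM CBSs in sub-TAD1 oriented toward the cluster (convergent with the
in-cluster series), the CBS-rich CS38-40 region, and three enhancer elements
in sub-TAD1 that become active at `t_enh = 96` model-hours. Exact CBS
base-pair positions are not published; the fixture interleaves them with the
genes in the order the mutant phenotypes imply (CBS1 between Hoxd4 and
Hoxd8, CBS2 between Hoxd8 and Hoxd9, and so on), placing each gating CBS in
the bin adjacent to the gene it gates. Everything can be overridden from BED
files via `load_annotation()`.

**Orientation convention.** A site oriented TOWARD_TDOM presents its
blocking face to anchors travelling toward C-DOM (decreasing coordinate);
TOWARD_CDOM blocks anchors travelling toward T-DOM. This is the standard
convergent-CTCF rule: it lets CBS1 stall the C-DOM-ward anchors of cohesin
loaded on the anterior genes, and makes the CBS1–CBS5 series convergent with
the T-DOM CBSs so that stable cluster/T-DOM loops can form.

## The extrusion engine

`simulate_step()` applies, per `dt = 0.01` model-hours: Poisson loading with
positions proportional to the loading profile; movement of each non-stalled
anchor by `v = 1` bin outward (200 kb/h); stalling with probability
`p_stall` when a blocking-face CBS lies in the path; bypass of stalled
anchors with probability `p_bypass` per step; and unloading. Two choices
deserve comment:

* `p_stall = 1`: occupied CBSs always engage a correctly oriented anchor;
  passage happens only through the bypass process. This keeps the gating
  semantics clean — the per-site transmission is controlled by one
  parameter rather than two redundant ones.
* `stall_unload_factor = 0.3`: while an anchor is stalled at a CBS the
  extruder's release probability is reduced. CTCF-anchored cohesin is
  stabilized in vivo, and the measured locus shows long-lived CBS/T-DOM
  loops and CBSs acting as anchoring points. Mechanistically this
  stabilization is what lets one loop migrate down the CBS series over
  several stall–bypass cycles; without it, cohesin loaded at newly
  activated central genes dies with its T-DOM-ward anchor still trapped at
  the reverse-oriented CBS3 and the posterior genes never gain enhancer
  contact. Setting the factor to 1 restores memoryless unloading.

Loading is transcription-coupled: `w_active = 50` per active-gene-body bin
against `w_background = 0.1` per other bin of the cluster-plus-T-DOM span,
and `run_timer()` scales the total loading rate with the mass of this
profile (normalized so `load_rate = 20`/h is the post-Wnt total). The
measured RAD21/NIPBL coverage grows strongly as the transcribed domain
expands; with a fixed total rate the activation front would be
progressively starved of relay loading.

## The activation layer

A silent non-anterior gene `g` fires in a window of length `dt` with
probability `1 − exp(−k_act · C_gE · att · dt)` once the enhancers are
active. `C_gE` is the trailing 2-h mean of the gene–enhancer contact: the
number of extruders whose loop spans both the whole gene body and the first
enhancer element — the gene has fallen into the positive loop domain shared
with the enhancers — plus the analytic distance-decay background. This
loop-coverage definition implements the mechanism directly; contact-map
*observables* (`contact_map()`, `virtual_4c()`, `split_score()`, ...) use
anchor-pair bridging as in a Hi-C experiment, and the maintenance contact
used by `expression_proxy()` counts anchors parked in the gene's body plus
one bin on its 5' side, so that cohesin stalled at the gene's 5'-flanking
CBS acts as its anchoring point (this is what makes a CBS deletion lower
the *maintenance* of the gene 3' of it while advancing the gene 5' of it).

`att` is the polycomb attenuation: `polycomb_factor = 0.002` while the gene
still carries the repressive mark. The mark over a silent gene's body is
erased by a retraction front launched when its 3'-side neighbor activates,
travelling the intergenic gap at `erasure_velocity = 300` bp per
model-hour; pre-looped `*_element` regions are excluded from the path
length. The measured retraction (front at CBS1 by ~96 h, erased between
CBS1 and CBS2 by ~120 h over a ~6-kb gap) corresponds to a few hundred bp
per hour, and the front-velocity form reproduces the non-uniform spacing of
the schedule: ~3-kb gaps between the central genes give ~10-h lags, while
the ~0.7-kb gap between Hoxd12 and Hoxd13 lets the last genes follow in
quick succession. The CTCF series still sets the pace — with `p_stall = 0`
the posterior genes activate far earlier and only a weak colinear remnant
survives, mirroring the multiple-deletion genotype.

## Calibration

The shipped defaults are the output of the committed grid search
(`scripts/calibrate.R`): `calibrate_defaults()` minimizes the squared
distance between median simulated onsets (50 replicates here; at least 20
per grid point) and the printed wild-type anchors (anterior by 84 h,
Hoxd8/9 at 108 h, Hoxd10/11 at 132 h, Hoxd13 at 144 h) over `k_act`,
`p_bypass` and, on an outer loop, `erasure_velocity` and `polycomb_factor`.
All targets land within the 12-h experimental sampling interval. Problem
sizes used throughout the package's own validation: 861-bin lattice, 12,000
steps per replicate (48–168 h at dt = 0.01), 50 replicates per condition —
one replicate takes well under a second, a 50-replicate condition about half
a minute.

## Synthetic data and what passing tests show

The generator module produces inputs with known ground truth: sigmoid
activation waves spreading at a set velocity with posterior dilution
(`gen_wave_tracks()`), contact matrices with blocks, a stripe and loops over
a power-law background (`gen_contact_matrix()`), replicate expression tables
with step onsets and rank dilution (`gen_expression_table()`), and
valid-pair lists sampled from any map (`sample_pairs()`). Every generator is
deterministic given its seed, and every structural parameter is recoverable
by the matching analysis operation (front velocity by half-maximum
regression, loop enrichment as a background ratio, onset order by the
colinearity score, pair frequencies by binomial concentration).

These synthetic inputs emulate the *statistical structure* the analyses
assume — not real data. They contain no capture bias, no fragment-level
noise, no replicate batch structure and no cell-population heterogeneity
beyond a scalar dilution factor; passing recovery tests demonstrates that
the analysis operations are correct and well-conditioned, not that they
would be unbiased on experimental libraries.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open; lattice bins are 1-based in R.
  `discretize()` is deterministic and invertible to bin intervals; two CBSs
  in one bin are an error unless merging is enabled.
* The gene-state update interval is 0.1 model-hours (10 engine steps); the
  Wnt window is clipped at `t_wnt`, so the infinite-rate limit fires
  exactly at `t_wnt`.
* `virtual_4c()` masks the viewpoint ± 2 bins by default and errors if the
  profile is empty after masking; all normalized profiles sum to 1 within
  1e-12.
* `split_score()` excludes the diagonal from within-block means and errors
  on degenerate sides or zero cross-contact. When scoring the two
  micro-TADs, the boundary is placed just 5' of CBS1 so the CBS1 bin —
  which loops with T-DOM and accumulates dwelling anchors — belongs to the
  active anterior block.
* `colinearity_score()` gives never-activated genes the maximal rank with
  average tie handling; at least three finite onsets are required.
* `compare_genotypes()` reports p = 1 for identical zero-variance groups
  and p = 0 for distinct ones; the Welch machinery is `stats::t.test`.
* Timecourse interpolation is linear between flanking measured timepoints
  and exact at the measured times.

## Known limitations

The model is a 1D lattice with a phenomenological contact rule: no 3D
polymer physics, no nucleosome-scale detail, no CTCF binding kinetics
(occupancy is static per genotype), no extruder–extruder steric blocking,
and C-DOM is inert. Loop-coverage contact treats a gene inside a spanning
loop as uniformly close to the enhancers regardless of loop size. The
dilution factor is a constant per-rank scalar standing in for the posterior
restriction of expressing cells; it affects measured proxies only, never
the mechanism. Activation is irreversible — maintenance versus initiation
is distinguished only through the contact-scaled expression proxy.
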