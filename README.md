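# aridsuit

Ensemble habitat-suitability modelling and aridity-driven change analysis
for climate-sensitive crops, built around the workflow used to project the
future of olive (*Olea europaea* L.) cultivation: where is the crop
climatically suitable today, where will it be under SSP-style forcing, and
how much of the projected habitat loss is attributable to increasing
aridity?

The package implements the full chain as tested, reusable functions:

1. **Occurrence preparation** — 5-km spatial rarefaction of presence
   records (greedy, seeded), pseudo-absence generation with 100-km spacing
   (one absence per 10,000 km² neighbourhood), covariate extraction.
2. **Variable screening** — iterative VIF pruning at threshold 5
   (`VIF = 1/(1−R²)` by per-variable OLS) plus a confirmatory Pearson
   matrix.
3. **Ensemble SDM** — six algorithms (GLM, random forest, boosted trees,
   SVM, and first-principles Bioclim envelope and Mahalanobis scorers) over
   10 replicates of a stratified 80/20 split; rank (Mann–Whitney) AUC and
   max-TSS evaluation (TSS = sensitivity + specificity − 1, threshold by
   exhaustive scan); algorithm-level gating at AUC ≥ 0.9 and TSS ≥ 0.7;
   unweighted (or TSS-weighted) ensemble probability rasters; permutation
   variable importance.
4. **Classification and change** — equal-interval classes (0.25/0.5/0.75),
   latitude-aware km² area tables, gain/loss/stable change maps between
   reference and future periods.
5. **Aridity** — Thornthwaite PET
   (`PET = 16·AdjF·(10·Td/I)^a`, heat index `I = Σ(Td/5)^1.514`, day-length
   correction `AdjF = (N/12)(d/30)`) and the UNEP Aridity Index
   `AI = P/PET`, classified from hyper-arid (< 0.05) to humid (> 1).
6. **Loss attribution** — area-weighted frequency of suitable habitat
   across aridity classes, and binomial logistic regression of habitat loss
   on standardized AI, reporting β, the odds ratio `exp(−β)` per one-SD
   increase in aridity, Wald p, McFadden pseudo-R² and AUC.

Everything runs on synthetic worlds with a **known ground-truth suitability
surface** (spatially correlated climate fields, lapse-coupled terrain,
presences sampled from a logistic niche), so the pipeline is testable by
parameter recovery. Rasters travel as plain-text ESRI ASCII grids; points
and tables as CSV.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic world (100 × 160 cells of 10 km, two scenarios × two periods):

```sh
Rscript analysis/01_simulate.R 42   # world, terrain, scenario climates
Rscript analysis/02_prepare.R      # presences, absences, covariate table
Rscript analysis/03_screen.R       # VIF pruning
Rscript analysis/04_fit_ensemble.R # fit, evaluate, gate, ensemble rasters
Rscript analysis/05_classify_change.R
Rscript analysis/06_aridity.R
Rscript analysis/07_attribution.R
```

A run at seed 42 prints, in sequence:

```
presences: 256 raw -> 256 after 5-km rarefaction
pseudo-absences: 119 placed at >= 100 km spacing
screened 9 candidate variables at VIF threshold 5
dropped: elevation (VIF 12.2)
retained: slope, aspect, bio3, bio4, bio8, bio9, bio14, bio19
...
change ssp585_2090: stable 3.2%, gain 0.5%, loss 3.9%
ssp585_2090: PET 598-2920 mm, AI 0.17-1.02; sub-humid 25%, dry sub-humid 28%, semi-arid 46%
ssp585_2090: suitable habitat mostly semi_arid (50.3%) then dry_sub_humid (39.4%)
ssp585_2090: beta -1.3177 (p <0.001), OR 3.73 per SD aridity, pseudo-R2 11.7%, AUC 0.785
```

Reading the last lines: under the strongest forcing, 3.9% of the region
loses suitability relative to the reference period; half of what remains
suitable sits in semi-arid climate (versus mostly sub-humid in the
reference period); and a one-standard-deviation increase in aridity
multiplies the odds of habitat loss by ≈ 3.7 (β = −1.32 on standardized AI,
aridity explaining ≈ 12% of the deviance, discrimination AUC 0.79).
Elevation being pruned while its lapse-coupled temperature proxies survive
is expected behaviour of VIF screening on this world.

The same run is available as one call:

```r
library(aridsuit)
report <- run_all(pipeline_config(seed = 42), out_dir = "results/run")
report$gates              # per-algorithm mean AUC / TSS and gate decisions
report$loss_regressions$ssp585_2090
```

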