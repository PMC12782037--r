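# megamorph

Species identity, abundance and per-specimen biomass are the three
quantities a thorough freshwater invertebrate assessment needs, and no
single instrument measures all three. `megamorph` implements a
multimodal pipeline that combines them on the level of the individual
specimen:

* **DNA megabarcoding** — one tagged amplicon per specimen gives a
  per-specimen OTU read table; the dominant OTU, filtered by a
  read-count threshold and consistency with the morphological order,
  yields the species label (and counting specimens yields abundance);
* **semi-automated imaging** — two perpendicular cameras photograph
  each specimen sinking through a cuvette, giving dozens of silhouette
  frames plus per-frame morphometrics: area *A*, maximum Feret
  diameter *MFD* and perimeter *P*;
* **image-based biomass estimation** — convolutional networks trained
  on the DNA-labelled images predict dry mass per frame, benchmarked
  against ordinary least squares allometric baselines of the form
  log-mass ~ log *A* + log *MFD* + log *P*, and optionally warm-started
  from a taxonomic classifier (transfer learning, with frozen or
  unfrozen backbone).

The statistical core is the allometric power law `m = c_s * L^(b_s) *
exp(eps)` relating body length to dry mass, the dominant-OTU assignment
rule with its three failure modes (insufficient reads, order mismatch,
no species-level hit), stratified grouped k-fold evaluation (the
specimen is the group; folds are shared between tasks), and
jackknife-combined per-frame metrics: weighted precision/recall/F1 and
row-normalized confusion matrices for classification; MAE, MdAE, MAPE,
MdAPE and R-squared for biomass.

A first-class synthetic-data module generates the whole study — nested
taxonomy, silhouette frames from two cameras, weighing records with a
detection limit, and OTU tables with injected failure modes — so every
stage is testable on one CPU without downloads.

## Worked example

```r
library(megamorph)

# a small synthetic study: 4 species, 8 specimens each
tax   <- generate_taxonomy(4, 4, 3, 2, seed = 11)
allom <- allometry_params(tax, seed = 11)
spm   <- generate_specimens(tax, 8, allom, seed = 11)
spm$measured_mass_mg <- weigh(spm$true_mass_mg, allom, seed = 11)

otu <- generate_otu_table(spm, seed = 11)
res <- assign_all(otu$records,
                  data.frame(specimen_id = spm$specimen_id,
                             morphological_order = spm$order))
unlist(res$summary[c("n_total", "n_assigned", "recovery_rate")])
#>       n_total    n_assigned recovery_rate
#>      32.00000      29.00000       0.90625
```

29 of 32 specimens get a species-level DNA label; the sequence recovery
rate (specimens yielding any valid sequence) is 90.6%, with the
remainder split across the three injected failure modes exactly as the
truth ledger records.

The full pipeline — rendering frames, extracting morphometrics,
assigning taxa, curating, 5-fold training of the classifier, the
baselines and the biomass networks, and jackknife evaluation — runs
from one config:

```r
config <- default_pipeline_config(output_root = "mm_run", seed = 1)
run_pipeline(config)
metrics <- jsonlite::read_json("mm_run/metrics.json", simplifyVector = TRUE)
metrics$classifier$species$weighted$f1   # per-frame species F1
#> [1] 0.9080472
metrics$cnn_scratch$frame$r2             # biomass CNN R^2 (mg scale)
#> [1] 0.8575776
metrics$`linear(A,MFD,P)`$frame$mdape    # best linear baseline MdAPE
#> [1] 0.380192
```

On the default desk-scale study (8 species, 12 specimens each, 16
frames per specimen, seed 1) the species classifier reaches a combined
weighted F1 of 0.91; the biomass network without pre-training reaches
frame-level R-squared 0.86 with MdAPE 0.27, against MdAPE 0.38 for the
all-predictor linear model, 0.79 for the perimeter-only model, and an
MAE more than three times smaller than the mean predictor's — the same
qualitative ordering seen on real imaging data. A command-line wrapper
lives at `inst/cli/pipeline.R`.

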