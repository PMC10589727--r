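# peakAtlas

Tools for building an atlas of **intergenic RNA polymerase II consensus
regions** from many ChIP-seq peak sets, and for quantifying and mining
transcription at those regions.

Genomes are pervasively transcribed outside genes, but any single RNAPII
ChIP-seq experiment sees this activity noisily and partially. `peakAtlas`
integrates hundreds of peak sets: peaks are filtered to intergenic space
(transcripts ± 1 kb and blacklist excluded, q < 1e-5, datasets with < 100
intergenic peaks dropped), pooled peak summits are turned into a
Gaussian-smoothed per-bp density, and **consensus regions** are the
segments between local minima of that density supported by ≥ 2 distinct
datasets — with boundaries from the farthest member peaks and centroid at
the mean member summit.

Downstream, the package provides:

- the binary **occupancy matrix** M (datasets × consensus), biotype
  contribution scores `n_ij = s_ij / Σ_j' s_ij'` and per-consensus
  Gini-Simpson diversity `λ_j = 1 − Σ_i p_ij²`;
- binomial (coverage-based) and hypergeometric (subset) **overlap
  enrichment**, a category cascade (Promoter-like → LNC-body →
  Enhancer-like → Regulatory-like → Gene-tail → Unannotated),
  epigenome-state proportions with paired tests, and tissue-eQTL
  enrichment;
- a single-cell-style **count transform**: detectability-restricted
  pooling size factors, a per-region regularized negative-binomial model
  `ln μ = β₀ + ln s`, `V(μ) = μ + αμ²` with a 20-bin overdispersion trend,
  and Pearson residuals clipped at `±√(9 + n/4)`;
- χ² **highly-variable-region selection**, Horn's parallel analysis,
  balanced-accuracy cross-validation (kNN / gradient boosted trees),
  SNN-Leiden clustering and a three-step hierarchical ordering;
- per-biotype **marker calling** (expression t-test + fold change +
  detectability; occupancy hypergeometric), tumor/normal differential
  regions, **Yule-distance meta-clustering** across data sources, and a
  resampling-based **pan-cancer marker threshold** at 5% FDR;
- GREAT-style **regulatory domains** with an NB-GLM gene-set test using
  expected hits as an offset (`ln μ = β₀ + β₁G + ln E`), plus redundancy
  reduction of significant terms;
- a per-region **Cox survival screen** on residuals and maximally
  selected log-rank cutpoints with permutation p-values.

A synthetic-data module (`sim_config()`, `simulate_*`) generates peak
sets, annotations, NB count matrices and proportional-hazards survival
tables with known ground truth, so the entire pipeline is testable end to
end without external data.

## Worked example

```r
library(peakAtlas)

cfg  <- sim_config(seed = 7, n_datasets = 20, peaks_per_dataset = 120,
                   n_source_loci = 100, n_samples_per_biotype = 10)
ps   <- simulate_peak_datasets(cfg)
ann  <- simulate_annotation(cfg)
mask <- build_intergenic_mask(ann$transcripts, ann$blacklist)
fl   <- filter_dataset_peaks(ps$peaks, mask, min_peaks = 50)
cons <- segment_consensus(fl$peaks, sigma = "auto")
nrow(cons)
#> [1] 100

M  <- build_occupancy_matrix(cons, ps$datasets)
bs <- biotype_scores(M, ps$datasets)
range(bs$lambda, na.rm = TRUE)
#> [1] 0.0000000 0.8169371

cm     <- simulate_count_matrix(cons, cfg)
counts <- filter_low_counts(cm$counts)
top    <- detectability_rank(counts)$top
s      <- pooling_size_factors(counts[top, ])
model  <- fit_regularized_nb(counts, s, seed = 1)
res    <- pearson_residuals(counts, model)
hv     <- select_hvr(res)
hp     <- horn_pca(t(res[hv$selected, ]), seed = 1)
hp$n_components
#> [1] 5

classify_balanced(hp$scores, cm$sample_meta$biotype, "knn",
                  seed = 1)$balanced_accuracy
#> [1] 0.8333333
```

The 100 simulated source loci are all recovered as consensus regions; a
Gini-Simpson index of 0 marks fully biotype-specific regions and values
near `1 − 1/R` mark shared ones; five principal components survive
parallel analysis and a kNN classifier recovers the sample biotypes with
0.83 balanced accuracy at this small size (it approaches 1 at the default
study scale).

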