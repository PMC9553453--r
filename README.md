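# lrxtalk

Inference of **ligand–receptor crosstalk between tumor cells and
macrophages** from coupled single-cell and bulk transcriptomic cohorts.

Tumor microenvironments are shaped by signaling between malignant cells and
tumor-associated macrophages (TAMs). Where one population expresses a
secreted or surface ligand and the same (autocrine) or another (paracrine)
population expresses its receptor, coordinated expression of the pair is
evidence for an active communication axis. `lrxtalk` implements that
screen as a reusable, fully tested pipeline for anyone with a single-cell
count matrix (10x MTX triplet or dense TSV), a bulk expression cohort and a
directed ligand→receptor catalogue (FANTOM5-style two-column TSV):

* marker-score **cell-type annotation** on a PCA/k-means embedding
  (tumor: *EPCAM, SOX4, MDK*; alveolar epithelium: *SFTPD, AGR3, FOLR1*;
  myeloid split by *CD163/LYZ*, *FCER1A*, *ELANE*);
* **hurdle differential expression** — per gene, a detection G-test plus an
  equal-variance Gaussian likelihood-ratio test on detected cells,
  `stat = G_disc + N·ln(RSS₀/RSS₁)` referred to χ² with additive df, BH
  correction;
* **pair screening**: autocrine pairs concordantly up or down in one
  contrast, paracrine pairs up in sender (ligand) and receiver (receptor);
* **bulk coexpression filtering**: Spearman ρ across the bulk cohort,
  pair retained when ρ > 0.3 (strict, signed; `abs_rho` switch available);
* **networks and hubs**: simple graph over passed pairs, edge weight ρ,
  hubs by degree;
* **signature scoring**: module z-scores for pathway contrasts, M1/M2 and
  pro-/anti-inflammatory polarization of macrophage subtypes, and a
  CellPhoneDB-style permutation-null interaction score
  `mean(ligand | sender) × mean(receptor | receiver)`;
* **survival**: Kaplan–Meier / log-rank, per-gene prognostic screening by
  median split, and a gradient-boosted-tree classifier of stage-derived
  risk labels (high = stage III–IV) with a stratified 2:1 split and
  external validation;
* a **synthetic-data generator** that plants marker programs, concordant DE
  pairs, rank-correlated bulk pairs and survival effects with a ground-truth
  manifest, so every stage is testable by parameter recovery.

## Worked example

Simulate a four-population study (200 cells each; planted fold change 4,
planted bulk Spearman ρ = 0.5 over 500 samples), annotate it from scratch,
and run the autocrine screen:

```r
library(lrxtalk)

cfg <- sim_config(seed = 1)
sc  <- generate_sc_cohort(cfg)
expr <- normalize_log(sc$counts)
emb  <- embed_pca(expr, select_hvg(expr, 1000), n_components = 20)
ann  <- annotate_clusters(expr, cluster_cells(emb, k = 4, seed = 1),
                          markers = sc$truth$marker_genes)
summarize_composition(ann, by = "cell_type")
#>               group count percentage
#> 1        epithelial   200       25.0
#> 2 macrophage_normal   199       24.9
#> 3  macrophage_tumor   201       25.1
#> 4       tumor_cells   200       25.0
```

Three cells land in the wrong cluster (200/199/201/200 vs the planted
200/200/200/200) — annotation recovery here is 99.9%. Differential
expression between the pipeline's own tumor and epithelial labels, then the
concordance + bulk-correlation screen:

```r
de <- de_table(expr, ann$cell[ann$cell_type == "tumor_cells"],
               ann$cell[ann$cell_type == "epithelial"])
table(de$direction)
#> down   ns   up
#>   51 1092   57

pairs <- classify_autocrine_pairs(de, sc$truth$lr_pairs)
bulk  <- generate_bulk_cohort(cfg, sc$truth)
pairs <- filter_pairs_by_bulk(pairs, bulk$bulk, screen_config())
head(pairs[pairs$passed_filter, c("ligand", "receptor", "direction", "rho")], 3)
#>   ligand receptor direction       rho
#> 1 G00023   G01041        up 0.5093847
#> 2 G00637   G00465        up 0.4857234
#> 3 G00409   G01100        up 0.4996122
sum(pairs$passed_filter)
#> [1] 25
```

All 25 planted concordant pairs pass the ρ > 0.3 filter, with sample ρ
scattered around the planted 0.5. The `up`/`down` calls include the planted
50 DE genes plus the tumor marker program; the remainder of the ~1200-gene
panel stays `ns`. Survival screening flags every planted prognostic gene:

```r
prog <- prognostic_screen(bulk$bulk, bulk$survival,
                          sc$truth$prognostic_genes$gene)
sum(prog$prognostic)
#> [1] 20
```

The same stages are scriptable from the shell via `inst/cli/lrxtalk`
(`simulate`, `annotate`, `de`, `screen`, `score`, `survival`, `model`),
each stage reading and writing plain TSV/MTX files.

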