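# hicradial

Statistics for detecting **spatial co-clustering of co-regulated gene
classes** in the 3D genome. Given a gene table (TSS positions, DE flags,
co-regulation class labels from an upstream expression clustering) and a
Hi-C contact map, `hicradial` answers: do genes of the same class sit
closer together — along the chromosome, in 3D space, or both — than all
genes or all DE genes would predict?

## What it computes

* **Spatial distances from Hi-C** — contact frequencies are inverted
  (`d = c^(-1/γ)`, default γ = 1) and completed with exact all-pairs
  shortest paths on the contact graph, in the spirit of shortest-path
  (Shrec3D-style) reconstruction.
* **Linear distribution function** `σ^L_α(i)` — mean density of
  class-α genes in the *i*-th pair of Δl-wide sequence bins flanking a
  tagged class-α TSS, normalized by `N_α − 1`, with all-gene (`σ^LA`)
  and DE-gene (`σ^LD`) controls.
* **Radial distribution function** `σ^R_αβ(i)` — mean number density of
  class-β genes in the *i*-th spherical shell of thickness Δr around
  the bin of a tagged class-α gene,
  `σ^R_αβ(i) = ⟨ n_βi / (N_β V_i / V) ⟩_α` with `V = 1`, plus the same
  two controls and the **first-shell enrichment ratio**
  `σ^R_αα(0)/σ^RA_α(0)` (values > 1 ⇒ intra-class spatial
  co-clustering).
* **Significance** — one-sided permutation test (labels shuffled among
  DE genes, class sizes preserved) with BH adjustment across classes;
  class-merging utilities to study how unresolved class mixtures dilute
  enrichment.
* **Synthetic data** — a seeded generator (genome → polymer random-walk
  structure with class anchors → distance-decay Poisson contacts) that
  plants known linear and/or 3D clustering, so the whole pipeline is
  verifiable end to end.

## Worked example

```r
library(hicradial)

sim <- simulate_dataset("strong", seed = 11)   # planted 3D co-clustering
D   <- distances_from_contacts(sim$contacts, gamma = 1)
dr  <- default_shell_width(D)                  # 5th-percentile shell width
#> shell width delta_r set to 0.0122 (5th percentile of pairwise distances)

round(first_shell_ratios(sim$genes, sim$binning, D, dr)$ratios, 2)
#>      C1   C2   C3   C4
#> C1 2.87 0.39 0.49 0.31
#> C2 0.50 3.15 0.37 1.37
#> C3 0.60 0.36 3.65 0.43
#> C4 0.37 1.29 0.41 3.20

permutation_test_first_shell(sim$genes, sim$binning, D, "C1", dr,
                             B = 999, seed = 5)$p
#> [1] 0.001
```

The diagonal entries near 3 say that around a tagged class gene, genes
of the *same* class are about three times denser in the first spatial
shell than genes in general — the planted co-localization — while
off-diagonal entries stay at or below background (no cross-class
clustering was planted). The permutation p-value of 1/1000 means the
observed enrichment beat all 999 label-shuffled null draws.

Real data enter the same way via `read_gene_table()` (TSV or BED6 plus
a class table) and `read_contact_map()` (COO triplets or dense matrix,
with a bin BED); see the vignette in `vignettes/` for the model, the
conventions, and the generator's design.

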