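# wphom — weighted persistent homology descriptors for molecular aggregation

`wphom` computes topological descriptors of coarse-grained molecular point
configurations in periodic boxes, aimed at questions like: do osmolytes
(TMAO, urea) spread into an even network or concentrate into clusters, and
how is the surrounding water organized? It is written for structural
bioinformaticians and simulators who have (or want to emulate) frames of
labeled points — one point per molecule — inside an orthorhombic box.

Two weighted persistent-homology constructions are provided, with the
standard summaries on top:

* **Localized persistent homology (LPH):** the Vietoris–Rips barcode of
  the molecules inside a sphere of radius `R_c` around each molecule
  (minimum-image distances), ensemble-averaged over molecules and frames.
* **Interactive persistent homology (IPH):** persistence of a
  dissimilarity matrix `M_ij = d_ij` across molecule types and `∞` within
  a type, so only osmolyte–water contacts form connections; the
  dimension-0 barcode carries the solvation structure, and every
  dimension-1 feature provably persists forever.
* **Descriptors:** persistent Betti number curves
  `f(x; L_k) = Σ_j χ_[a_j, b_j](x)`; persistent entropy
  `S_k = Σ −p ln p` with `p_j ∝ (b_j − a_j)`; Boltzmann persistent
  entropy, built from the Betti energy `E_j = α((b_j − a_j)/η)^κ`
  (defaults `α = k_BT`, `η = 1 Å`, `κ = 2`) so that *longer* bars get
  *lower* probability; and the persistent radial distribution function —
  dimension-0 deaths binned and normalized by `4πr²Δr·ρ`, which for the
  global-scale IPH model is the conventional RDF.

Seeded synthetic generators (uniform, hard-core, Thomas-clustered, and
solvated configurations with a first hydration shell near 4 Å) replace MD
trajectories; multi-frame XYZ and GROMACS GRO readers plus coarse-graining
rules (TMAO → N, urea → C, water → OW) handle real data. The Rips engine
is compiled (Rcpp) boundary-matrix reduction over GF(2); dimension-0 takes
a union-find fast path so global-scale IPH works at 3001 × 3001 without
ever building a complex.

## A worked example

Clustered versus evenly spread osmolytes at the same count, separated by
where their loop structures live:

```r
library(wphom)

cl <- gen_clustered(10, 15, sigma = 2, box = 40, seed = 101)   # clusters
hc <- gen_hardcore(nrow(cl), box = 40, min_dist = 6, seed = 101) # network

pb_cl <- lph_average_pbn(mol_trajectory(list(cl)), "OSMOLYTE", r_c = 9, k = 1)
pb_hc <- lph_average_pbn(mol_trajectory(list(hc)), "OSMOLYTE", r_c = 9, k = 1)
pb_cl$x[which.max(pb_cl$value)]   # 2.6  (A): small circles inside clusters
pb_hc$x[which.max(pb_hc$value)]   # 8.3  (A): loops at the network spacing

glance(lph_barcode(cl, center = 1, r_c = 9, species = "OSMOLYTE"))
#>   dimension n_bars n_finite n_infinite max_finite_death    pe   bpe
#> 1         0     19       18          1             4.91 2.80  1.40
#> 2         1      2        2          0             8.03 0.635 0.690
```

The clustered configuration's average dimension-1 PBN peaks at 2.6 Å
(height 0.662) against 8.3 Å (height 0.345) for the hard-core one: local
clustering contributes many small circles, an even network few large ones.

A synthetic hydration shell is recovered by the global-scale PRDF:

```r
osm <- gen_hardcore(20, box = 40, min_dist = 8, seed = 1)
cfg <- gen_solvated(osm, 2000, shell_radius = 4, shell_fraction = 0.5,
                    jitter = 0.3, seed = 2)
prdf <- global_prdf_pipeline(mol_trajectory(list(cfg)), bin_width = 0.2)
prdf$r[which.max(prdf$value)]                         # 4    (A)
max(prdf$value)                                       # 10.8 (peak height)
mean(prdf$value[prdf$r >= 12 & prdf$r <= 20])         # 0.98 (bulk tail ~ 1)
```

`autoplot()` methods draw barcodes and curves; `tidy()`/`glance()` give
broom-style tables. A command line mirrors the pipelines:

```sh
exec/wphom synth --kind solvated --n 4 --min-dist 5 --n-water 25 \
    --box 20 --frames 2 --seed 5 --out data/
exec/wphom lph --input data/config.xyz --species OSMOLYTE --cutoff 6 --out out/
exec/wphom iph-global --input data/config.xyz --bin-width 0.5 --out out/
```

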