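# cycim

Analysis of **cyclic (sequential-round) multiplexed immunofluorescence
imaging** of iPSC-derived neural cultures, for labs that image more protein
markers than four fluorophores allow: antibodies carry short DNA docking
strands, fluorophore-bearing imager strands hybridize and are imaged two
markers per round, then a low-salt wash releases them for the next round.
Persistent nuclear and actin stains imaged every round serve as fiducials.

The package covers the full downstream chain:

1. **Registration** — per-round drift estimated by phase correlation on the
   fiducial channels with subpixel (upsampled-DFT) refinement; one rigid
   translation per round, quality-flagged.
2. **Segmentation & tracking** — Otsu + distance-transform watershed nuclei,
   seeded-watershed cell bodies on actin, greedy deterministic
   nearest-centroid tracking across rounds; only cells present in *every*
   round (and off the field border) are analyzed, with full exclusion
   accounting.
3. **Quantification** — per-cell marker intensities (robust perinuclear-core
   quantile for gating), Laplacian-of-Gaussian puncta counts, Hessian-ridge
   filament scores, plus the QC statistics of the field: n=6/n=6 ROI
   signal-to-noise ratio, pixel-wise Pearson correlation against a
   conventional IF control, and post-wash residual checks.
4. **Gating** — data-driven per-marker positivity thresholds
   (Otsu-anchored two-sided rule with an absent-marker guard; `kmad` and
   `fixed` alternatives), then an all-markers-positive rule tree:

   | class | signature |
   |---|---|
   | ipsc (residual pluripotent) | Oct4A+ |
   | excitatory_neuron | Tuj1+ MAP2+ VGLUT1+ |
   | inhibitory_neuron | Tuj1+ MAP2+ VGAT+ |
   | neuron (subtype unresolved) | Tuj1+ MAP2+ |
   | radial_glia | Pax6+ Vimentin+ Tuj1− |
   | npc | Pax6+ Vimentin− |
   | astrocyte_mature / _immature | CD44+ Vimentin+ Tuj1− Pax6− (GFAP±) |

   Unmatched cells are reported as `unclassified`, never dropped. Rule sets
   are JSON-serializable and fully overridable; a motor-neuron variant
   (Islet1/NF200) ships alongside.
5. **Strand design** — orthogonal DNA docking/imager pairs: 11–12 nt, GC
   0.30–0.40, nearest-neighbor Tm (unified DNA/DNA parameters with
   monovalent-salt correction) inside a documented window, pairwise
   complementary runs ≤ 6 nt; FASTA export.
6. **Synthetic ground truth** — a first-class generator
   (`simulate_culture()`, `render_round_stacks()`) producing multi-round
   16-bit TIFF stacks with known classes, expression, drift and detachment,
   so every stage is testable offline.

## Worked example

```r
library(cycim)

cfg      <- sim_config(n_cells = 300, field_shape = c(400L, 400L), seed = 7)
cells    <- simulate_culture(cfg)           # ground-truth culture
rendered <- render_round_stacks(cells, cfg) # 5 rounds x 4 channels
res      <- analyze_experiment(rendered$stacks)
res$composition
#> <composition_table> 273 analyzed of 300 sampled (27 excluded)
#>               class count   pct
#>                ipsc     0  0.0%
#>   excitatory_neuron   122 44.7%
#>   inhibitory_neuron     0  0.0%
#>              neuron     0  0.0%
#>         radial_glia    48 17.6%
#>                 npc    25  9.2%
#>    astrocyte_mature    72 26.4%
#>  astrocyte_immature     0  0.0%
#>        unclassified     6  2.2%
```

273 of 300 simulated cells survived every round and the border filter; the
27 excluded cells are counted, not hidden. The recovered fractions sit
within ~1 percentage point of the generator truth among surviving cells
(44.7% vs 45.5% excitatory neurons, 26.4% vs 26.4% mature astrocytes,
17.6% vs 19.1% radial glia, 9.2% vs 9.0% NPCs), with 2.2% unclassified.
The registration report recovers the seeded drift to ~0.01 px:

```r
res$registration
#>   round_id d_row d_col quality flagged
#> 1        1  0.00  0.00   1.000   FALSE
#> 2        2  1.05 -1.75   0.976   FALSE    # truth ( 1.04, -1.75)
#> 3        3  0.58  0.60   0.964   FALSE    # truth ( 0.59,  0.59)
#> 4        4  2.58  2.50   0.957   FALSE    # truth ( 2.58,  2.50)
#> 5        5  0.00 -0.10   0.937   FALSE    # truth ( 0.02, -0.11)
```

Strand design:

```r
design_orthogonal_panel(3, seed = 1)[, c("docking", "imager", "gc", "tm")]
#>        docking       imager    gc   tm
#> 1  CGACTACAAAT  ATTTGTAGTCG 0.364 37.2
#> 2  CAATGTATCAC  GTGATACATTG 0.364 34.8
#> 3 ATACTAATCCAC GTGGATTAGTAT 0.333 37.3
```

Gating an external per-cell CSV (no images needed):

```r
run_gating_from_table("percell.csv", cortical_ruleset(),
                      column_map = c(Tuj1 = "TUJ1_mean_intensity"))
```

## Command line

```sh
Rscript inst/scripts/cycim simulate --out fixture/ --seed 3
Rscript inst/scripts/cycim run --fixture fixture/ --out results/ --seed 3
Rscript inst/scripts/cycim gate-table --table percell.csv --out composition.csv
Rscript inst/scripts/cycim design-strands --n 10 --seed 1 --out panel.fasta
```

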