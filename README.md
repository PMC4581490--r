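# ishquant

Quantification and comparative analysis of spatial gene expression from in
situ hybridization (ISH) images of developing embryos, built around the
starlet sea anemone *Nematostella vectensis*.

## The problem

Whole-mount ISH images show *where* a gene is expressed, but comparing
hundreds of staining patterns across genes and developmental stages needs a
common quantitative representation. For genes with cylindrically symmetric
staining, one spatial dimension suffices: intensity as a function of
position along the oral–aboral body axis. `ishquant` provides the full
pipeline from image to comparative statistics:

1. **Profile extraction.** A "digital morphology" — two index-paired
   boundary polylines tracing the inner and outer surface of the cell
   layer — decomposes the layer into quadrilateral segments. Mean pixel
   intensity per segment, plotted against normalized midline arc length,
   gives a raw profile; artifact stretches are replaced by interpolation;
   the result is interpolated at 100 equidistant points on [0, 1] and
   scaled to unit maximum (a *standardized profile*).
2. **Stage-wise clustering.** Profiles from each of seven stages (blastula
   → late planula) are clustered with unweighted average linkage (UPGMA)
   under the Pearson correlation distance *d* = 1 − *r* (range 0–2).
   Dendrograms are cut at stage-specific thresholds
   (0.7, 1.3, 1.1, 0.6, 0.9, 0.9, 0.9), and a structural 2-vs-3 rule
   extracts the main clusters: the root split gives two, or three if the
   second-highest merge subdivides the larger branch.
3. **Transition statistics.** Curated expression-domain descriptions per
   gene and stage are mapped onto three major regions (R1 central
   domain/endoderm, R2 central/external ring + oral ectoderm, R3 vegetal
   hemisphere/aboral ectoderm). Between a gene's consecutive available
   stages the change is classified as *minor* (same region set), *major*
   (shifted across regions), *appeared*, *vanished* or *none*; counts per
   (initial, final) stage pair are aggregated into two-stage periods — a
   pair spanning stages *i*…*f* is credited to every period between them —
   with integer percentages, and a two-tailed Fisher's exact test
   (exhaustive hypergeometric enumeration) compares period compositions.
4. **Synthetic data.** Generators produce embryo-like images with ground
   truth morphology and profile, planted-cluster profile sets, and domain
   tables with a known minor/major/appeared/vanished transition kernel, so
   every stage of the pipeline is testable end to end without any
   external download. Reference transition counts for 73 *N. vectensis*
   genes from the Kahi Kai ISH database ship as a plain-text fixture.

## Worked example

```r
library(ishquant)

# a blastula-like scene: central domain plus an external ring
arch <- archetype_spec("blastula",
  data.frame(name = c("Cd", "Er"), start = c(0, 0.45), end = c(0.3, 0.6),
             amplitude = c(0.8, 0.5)))
scene <- generate_embryo_image(archetype = arch, noise_sd = 0.02, seed = 42)
scene
#> image_scene: 240 x 240 pixels, stage blastula , 0 artifact region(s)

profile <- extract_profile(scene$image, scene$true_morphology,
                           gene = "demo", stage = "blastula",
                           sample_id = "demo_01")
round(profile$values[seq(1, 100, by = 10)], 3)
#>  [1] 0.998 0.996 0.998 0.460 0.109 0.666 0.277 0.109 0.111 0.110
```

The profile is near 1 over the central domain (positions < 0.3), rises
again over the ring (0.45–0.6), and sits at the background level
elsewhere — the standardized shape the clustering consumes.

```r
ps <- generate_profile_set(list(
  archetype_spec("blastula", data.frame(name = "Cd",   start = 0,    end = 0.3)),
  archetype_spec("blastula", data.frame(name = "VeHe", start = 0.65, end = 1))),
  n_per_archetype = 5, noise_sd = 0.05, seed = 1)
cluster_stage_profiles(ps, "blastula")$cut
#> cluster_assignment: 2 cluster(s) at threshold 0.7 ; sizes: 5/5

aggregate_periods(nv_reference_counts()$R1)
#> period_summary (filter R1)
#>                             counts percentages
#> blastula-early gastrula     22:2:1      88:8:4
#> early gastrula-mid gastrula  9:4:0     69:31:0
#> mid gastrula-late gastrula   8:2:0     80:20:0
#> late gastrula-early planula  5:2:0     71:29:0
#> early planula-planula       11:2:0     85:15:0
#> planula-late planula         9:1:0     90:10:0
```

Read: of the 25 genes expressed only in the central domain at the
blastula, 88 % stay within the endoderm lineage at their next available
stage, 8 % shift across major regions and 4 % stop being expressed. The
major-change plus first-appearance rate per period,

```r
period_change_rate(aggregate_periods(nv_reference_counts()$all),
                   c("major", "appeared"))
#> blastula-early gastrula  early gastrula-mid gastrula  mid gastrula-late gastrula
#>                      19                           45                          48
#> late gastrula-early planula  early planula-planula  planula-late planula
#>                          55                     37                    25
```

peaks during gastrulation (45–55 %) and drops in the planula stages
(37 %, 25 %): expression domains are decided while the embryo
gastrulates.

A command-line wrapper (`exec/ishquant`) exposes the same pipeline as
subcommands: `simulate-image`, `simulate-profiles`, `simulate-domains`,
`extract`, `cluster`, `transitions`, `report`.

## See also

The methods vignette (`vignettes/ish-quantification.Rmd`) documents the
model assumptions, parameter choices, numerical decisions and known
limitations in detail.
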