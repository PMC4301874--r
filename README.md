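# fibroquant

Trichrome histomorphometry for skeletal-muscle fibrosis and regeneration.

Muscular dystrophies progressively replace contractile muscle with
extracellular-matrix collagen (fibrosis). In histology this is measured on
Masson's trichrome-stained cross-sections, where muscle cytoplasm stains
red, collagen stains blue and unstained background appears white; disease
models are then compared on the blue area fraction, and muscle regeneration
is scored in parallel as the percentage of myofibers whose nucleus sits
centrally instead of at the periphery (centrally nucleated fibers, CNF).

`fibroquant` implements that workflow end to end for R users:

* **Collagen segmentation** — each micrograph is converted to CIE L\*a\*b\*,
  the (a\*, b\*) chroma of every pixel is partitioned by k-means (k = 2)
  into "red" and "blue" groups, a uniform lightness threshold masks white
  regions (pixel white iff L\* > threshold, default 85), morphological
  closing with a radius-3 disk fills small gaps in the red and blue
  regions, and

  &nbsp;&nbsp;&nbsp;&nbsp;% collagen = 100 · blue_px / (H · W)

* **CNF scoring** — from fiber polygons and nucleus points (GeoJSON/CSV):
  a nucleus is *central* iff its distance to the fiber boundary exceeds
  0.25 · √(area/π); a fiber counts if ≥ 1 of its nuclei is central.
* **Group statistics** — one-way ANOVA followed by Tukey's post-hoc test
  (Tukey–Kramer for unequal n), computable from raw per-animal values *or*
  directly from published summary statistics (n, mean, SD), with
  significance stars (\* p < 0.05, \*\* p < 0.01, \*\*\* p < 0.001).
* **Synthetic histology** — a generator of trichrome-like sections with
  exact ground truth (Voronoi myofiber mosaics, collagen bands solved to a
  target area fraction within ±0.005, controlled central-nucleation rate),
  so every stage is validated against known truth.

## Worked example

Reproduce a published four-group comparison of gastrocnemius collagen
content in dystrophic mouse models directly from the printed
"mean ± SD" table:

```r
library(fibroquant)
gm <- data.frame(label = c("wt", "mdx", "mdx_utrn_het", "dko"),
                 n    = c(3, 5, 5, 3),
                 mean = c(3.40, 3.38, 7.28, 9.49),
                 sd   = c(0.2, 0.9, 2.2, 1.5))
anova_oneway_summary(gm)
#> <anova_result> F(3, 12) = 14.47, p = 0.0002731
tukey_hsd(gm)[, c("group1", "group2", "mean_diff", "p_adj", "stars")]
#>         group1       group2 mean_diff        p_adj stars
#> 1           wt          mdx     -0.02 0.9999977041    ns
#> 2           wt mdx_utrn_het      3.88 0.0187742395     *
#> 3           wt          dko      6.09 0.0016336512    **
#> 4          mdx mdx_utrn_het      3.90 0.0069789992    **
#> 5          mdx          dko      6.11 0.0006190328   ***
#> 6 mdx_utrn_het          dko      2.21 0.2373799763    ns
```

The omnibus p of 2.7e-4 matches the published 0.0003: fibrosis is absent
in wild-type and mdx gastrocnemius but present in the utrophin-haploin-
sufficient and double-knockout models at 8 weeks.

And a fully synthetic round trip with known truth:

```r
sec <- generate_image(synthetic_spec(1024, 1024, n_fibers = 200,
                                     target_collagen_fraction = 0.10,
                                     cnf_rate = 0.4, seed = 7))
sec
#> <synthetic_section 1024 x 1024> collagen 0.1000 (target 0.1000),
#>   200 fibers, 200 nuclei (80 central)
segment_image(sec)
#> <collagen_measurement> 11.12% collagen (blue 116653 / red 830141 /
#>   white 101782 of 1048576 px)
percent_cnf(gt_fibers(sec), sec$gt$nuclei[, c("x", "y")])
#> <cnf_result> 40.00% CNF (80 of 200 fibers; band_frac 0.25)
```

(The ~+1.1 point offset of measured vs true collagen is the dark nuclei,
whose chroma clusters with blue — see the methods vignette.)

## Command line

```sh
Rscript inst/cli/fibroquant.R simulate --groups groups.csv --out cohort/ --seed 1
Rscript inst/cli/fibroquant.R quantify --manifest cohort/manifest.csv --out results/
Rscript inst/cli/fibroquant.R stats    --summaries summaries.csv --out report.json
Rscript inst/cli/fibroquant.R run      --manifest cohort/manifest.csv --out results/
```

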