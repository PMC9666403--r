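# tubvar

Residue-level mapping and enrichment analysis of tubulin missense variants.

Heterozygous missense variants in alpha-tubulin (TUBA1A) cause cortical
malformations — lissencephaly, microlissencephaly, pachygyria,
polymicrogyria. tubvar asks whether variants linked to one malformation
cluster in particular parts of the protein: a secondary-structure class
(helix, sheet, loop) or a functional domain of the microtubule lattice
(longitudinal, lateral, MAP binding, GTP binding, lumen, intradimer,
other). It is aimed at structural bioinformaticians and genetics groups who
want that analysis reproducible, auditable, and testable end to end.

## What it computes

With `R` residues, `R_s` of them in category `s`, and `f_s = R_s / R`, the
composition-proportional null expects `E_s = f_s · N` of `N` variants in
category `s`. tubvar tests:

- globally, the chi-squared goodness of fit
  `X² = Σ_s (O_s − E_s)² / E_s`, df = k − 1, upper-tail p;
- per phenotype `m` and category `s`, a two-sided exact Fisher test
  (point-probability rule) on
  `[[x_ms, n_m − x_ms], [R_s, R − R_s]]`,
  with alternative backgrounds for sensitivity analysis.

Around the statistics sit a residue-level structure model (PDB/mmCIF via
bio3d), a lattice-neighborhood model that partitions every residue into
exactly one of the seven functional domains (heavy-atom contacts at 4.5 Å,
nucleotide pockets at 4.0 Å, neighbor-count burial, radial outer/luminal
orientation, GTP-first precedence), a four-way amino-acid-property
taxonomy of substitutions, and a synthetic toy-lattice generator with
planted ground truth that makes the whole pipeline testable offline. See
`vignettes/tubulin-variant-enrichment.Rmd` for the methods account.

## Worked example

```r
library(tubvar)

toy  <- make_toy_lattice(toy_lattice_params(seed = 1))
part <- assign_domains(toy$model, toy$lattice)
part
#> Functional-domain partition of 180 residues
#> longitudinal      lateral  MAP binding  GTP binding        lumen   intradimer        other
#>           36           48           24            8           24           24           16

comp   <- composition(toy$model, part, chains = "A")
labels <- partition_labels(part, "A")
variants <- load_variant_table(
  system.file("extdata", "synthetic_variants.tsv", package = "tubvar"),
  model = toy$model)
scan <- enrichment_scan(variants, labels, comp)
scan
#> Variant enrichment scan
#>   119 variants (53 clinically labeled, 66 without imaging data)
#>   background: residues; alpha = 0.05; two.sided Fisher
#>   global GOF: X^2 = 5.422, df = 6, p = 0.491
#>   no cell below alpha
summary(scan)
#> p-values (rows: categories; columns: phenotypes)
#>              lissencephaly microlissencephaly pachygyria polymicrogyria
#> longitudinal          0.73               0.45       0.47           1.00
#> lateral               0.51               0.19       0.51           1.00
#> MAP binding           1.00               1.00       0.12           0.36
#> GTP binding           0.50               0.50       1.00           1.00
#> lumen                 0.40               1.00       0.35           0.42
#> intradimer            1.00               0.35       1.00           1.00
#> other                 0.59               0.61       0.61           0.62
```

The packaged variant table is a synthetic null cohort (53 clinically
labeled + 66 unlabeled records drawn uniformly over the toy structure), so
the correct reading is exactly what the scan prints: the global fit is
consistent with the composition-proportional null (p = 0.49) and no
phenotype-by-domain cell reaches alpha = 0.05. Planting an enrichment
changes that:

```r
tbl <- make_variant_table(labels, alpha_sequence(toy$model),
                          target_phenotype = "pachygyria",
                          target_category = "MAP binding",
                          fold = 10, seed = 2)
print(enrichment_scan(tbl, labels, comp))
#>   global GOF: X^2 = 16.854, df = 6, p = 0.00983
#>   cells with p < alpha:
#>     pachygyria / MAP binding: 19 of 30 variants, p = <0.01
```

Substitution utilities work standalone:

```r
parse_substitution("p.Arg402Cys")   # list(wt_aa = "R", position = 402, mut_aa = "C")
classify_substitution("R", "C")     # "charge_loss_or_swap" "hydrophobicity_change"
```

`pipeline_annotate()`, `pipeline_enrich()` and `pipeline_simulate()` wrap
these steps for file-based runs (TSV/JSON outputs with provenance
headers), and `inst/cli/tubvar.R` exposes them as a small command line
with subcommands `annotate`, `enrich`, `simulate`, `fixtures`.

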