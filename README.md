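# edmdpanel

Multistage candidate-gene discovery for genetically heterogeneous
muscular dystrophies, built around Emery-Dreifuss muscular dystrophy
(EDMD).

## The problem

EDMD is a rare neuromuscular disorder (early contractures, progressive
wasting, cardiac conduction defects) in which only about half of
clinically diagnosed patients carry a mutation in one of the six known
disease genes, all of which encode nuclear-envelope proteins.  Families
are small, penetrance is variable and the disease is genetically
heterogeneous, so genome-wide association approaches fail.  The
strategy implemented here attacks the problem in stages:

1. **Family stage.**  Exome variants from a small number of informative
   pedigrees are filtered by (a) phenotype co-segregation under the
   family's declared inheritance mode, (b) a two-stage population
   allele-frequency cascade (MAF < 1%, then < 0.05%, both strict),
   (c) coding-consequence, and (d) tissue expression (muscle expression
   strictly greater than 2-fold the maximum of other tissues).
2. **Panel stage.**  A targeted panel is assembled from four
   categories: (I) the 8 known EDMD genes (whole-gene regions for
   *LMNA* and *EMD*, ORFs otherwise), (II) 25 genes of similar
   muscular dystrophies, (III) the family exome candidates (252), and
   (IV) 16 functional candidates, mostly muscle-specific
   nuclear-envelope transmembrane proteins — 301 genes in total.
3. **Cohort stage.**  Each unrelated patient of a screening cohort is
   filtered on the panel (coding-altering consequence, MAF < 0.05%),
   hits are checked for consistency with each gene's known inheritance
   mode (a single heterozygous hit in a recessive gene does not
   qualify; two variants are accepted phase-unaware), category-III
   genes recurrently hit in ≥ 2 unrelated patients are elevated, and
   every patient receives exactly one status by the precedence
   I > II > III(elevated) > IV.
4. **Candidate statistics.**  The resulting candidate set is tested for
   over-representation of nuclear-envelope localisation against the
   genome background (one-sided exact hypergeometric; the exact
   binomial against the genome-wide NE fraction of 5.9% when only a
   fraction is known), for genes simultaneously annotated with genome
   organisation *and* cytoskeleton GO terms, and for connectivity over
   a high-confidence (score ≥ 0.7) protein-interaction graph, looking
   for a physical chain from the nuclear envelope to the plasma
   membrane — the mechanotransduction hypothesis.

For a focal statistic: with a foreground of *n* candidates of which
*k* carry a flag, and a background of *N* genes with *K* flagged, the
enrichment p-value is the hypergeometric upper tail
P(X ≥ k), X ~ Hypergeom(N, K, n).

Because real patient cohorts of this kind cannot be distributed, the
package ships
a first-class synthetic-cohort generator: Mendelian transmission over
pedigrees under AD/AR/XLR/XLD/de-novo modes, planted causal alleles at
MAF ≈ 0 with a ground-truth ledger, a rare-tailed Beta(0.2, 20)
background frequency spectrum, and all side tables (gnomAD-style
frequencies, per-tissue expression, GO/localisation flags, interaction
edges).

## Worked example

The built-in scenario simulates a 56-patient screening cohort whose
planted hit pattern mirrors a characteristic panel-screen outcome
(three missed *LMNA* alleles; eighteen patients with causative-grade
hits in related-dystrophy genes such as *CAPN3*, *GBE1*, *VCP*,
*TTN*, *DMD*; recurrent exome candidates *ANK2*, *INTS1*, *XIRP1*,
*USP34*; and seventeen functional-candidate hits across sixteen
patients, one patient carrying both *TMEM38A* and *PLPP7*):

```r
library(edmdpanel)

sim   <- simulate_cohort(edmd_screen_scenario(seed = 1))
panel <- edmd_panel()
panel
#> <panel_registry> 301 genes (I: 8, II: 25, III: 252, IV: 16)

hits <- patient_filter(sim$variants, sim$genotypes, panel,
                       patients = sim$patients)
cls  <- classify_patients(hits, sim$patients)
cohort_summary(cls, panel)
#> <cohort_summary> 56 patients; 21 clearly assigned
#> # A tibble: 6 x 2
#>   status                   n
#>   <chr>                <int>
#> 1 solved_known_edmd        3
#> 2 solved_related_md       18
#> 3 candidate_recurrent     17
#> 4 candidate_functional    15
#> 5 ambiguous_multi          1
#> 6 unsolved                 2
#> # A tibble: 4 x 3
#>   category n_genes_hit n_genes_total
#> 1 I                  1             8
#> 2 II                10            25
#> 3 III                4           252
#> 4 IV                 8            16
```

Reading the output: 3 patients are solved through *LMNA* (category I,
tier dark green), 18 through related-dystrophy genes (category II) —
21 clearly assigned in total; 17 patients carry recurrently elevated
exome candidates (purple), 16 distinct patients carry a
functional-candidate hit (yellow; one of them carries two and is
classified `ambiguous_multi`), and 2 remain unsolved.
`render_patient_table(cls)` expands this to one row per patient × gene
hit with protein changes, zygosity, frequency, tier and notes, and
`autoplot(cls)` draws the status distribution.  The one-command
orchestration `run_pipeline(list(seed = 1, out_dir = "out"))` writes
the VCF/TSV/JSON artifacts of every stage plus a Markdown report.

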