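# genrelate

Comparative genomic relatedness and insecticidal-factor screening for fungal
strains, in one self-contained R package.

## The problem

Entomopathogenic fungi (EPF) such as *Beauveria* are used as biological
insecticides. Placing a new isolate at the species level, and asking how much
of its insecticidal gene repertoire — secreted exoenzymes, bacterial-like
toxins, nonribosomal peptide synthetases (NRPS) and polyketide synthases
(PKS) — is shared with related strains, rests on a small set of whole-genome
computations that are usually delegated to web services. `genrelate`
implements them directly, for users who want the computations scriptable,
testable and reproducible:

* **ANIb** — fragment-based average nucleotide identity. The query genome is
  cut into 1020-nt fragments; each fragment's best local alignment against
  the subject must reach ≥ 30% identity over ≥ 70% of the fragment, and ANIb
  is the mean identity of accepted fragments. Conspecific genomes sit at
  ANIb ≈ 95–96%.
* **dDDH** — digital DNA–DNA hybridization. Over the retained set of
  high-scoring segment pairs (HSPs), the genome distance is
  `d = 1 − Σ identities / Σ alignment columns`, mapped to the wet-lab DDH
  scale by a logistic curve with the 70% species boundary calibrated to
  ANIb ≈ 95.5%.
* **BSR** — BLAST score ratio: a gene's best bit score against a target
  genome divided by its self-score, clipped to [0, 1]; `ratio > 0.4` calls a
  homolog, and per-category percent-homologous summaries quantify repertoire
  sharing.
* **Relatedness statistics** — taxonomic-degree coding (1 = same species …
  5 = shared subphylum only), linear regression of ANIb/dDDH on degree with
  confidence and prediction bands, and the Pearson correlation matrix over
  ANIb, dDDH and the four gene-category percentages.
* **Bioassay statistics** — one-way ANOVA on replicate-level mortality
  percentages with protected Fisher's LSD and a compact-letter display.

Alignments run on the package's own k-mer seeded, x-drop extended local
aligner (Rcpp) with Karlin–Altschul bit scores
(`bits = (λ·raw − ln K)/ln 2`), so no BLAST installation or genome download
is required. A synthetic generator produces genomes at controlled divergence,
categorized gene families with known ground truth, and binomial mortality
tables, making the whole pipeline testable offline.

## Worked example

```r
library(genrelate)

# two synthetic genomes at ~3% substitution divergence
ref <- generate_ancestor(50000, 0.517, seed = 1)
qry <- evolve_genome(ref, evolution_params(substitution_rate = 0.03,
                                           indel_rate = 0.2, seed = 2))

anib(c(strainB = qry$sequence), c(strainA = ref),
     query_id = "strainB", subject_id = "strainA")
#> ANIb strainB -> strainA: 96.92% (49/49 fragments accepted)

ddh(c(strainB = qry$sequence), c(strainA = ref),
    a_id = "strainB", b_id = "strainA")
#> dDDH strainB vs strainA: distance 0.0310, dDDH 95.6% (>= 70% species boundary)
```

The ANIb of 96.9% sits just above the 95–96% species boundary and the dDDH
well above 70%, as expected for a pair at 3% divergence: by both criteria
these two genomes would be called conspecific.

The packaged 27-strain EPF comparison table drives the relatedness
statistics:

```r
tab <- load_epf_table()          # 27 strains, taxonomy + ANIb/dDDH/gene %
rep <- relatedness_report(tab)
rep$summary
#>           quantity          r r_2dp
#> 1    r_anib_degree -0.9649972 -0.96
#> 2     r_ddh_degree -0.7517861 -0.75
#> 3 r_anib_exoenzyme  0.9561171  0.96
#> 4      r_anib_nrps  0.9439239  0.94
#> 5       r_anib_pks  0.8005440  0.80
#> 6     r_anib_toxin  0.9370347  0.94

rep$anib_fit
#> y = 101.262 + -7.496 x;  r = -0.965, R-squared = 93.1%, residual SD = 2.026
```

ANIb drops ~7.5 points per degree of taxonomic distance and correlates at
−0.96 with the degree code; the exoenzyme, NRPS and toxin repertoires track
ANIb at 0.94–0.96, i.e. repertoire sharing decays in near lock-step with
genome identity, while PKS content is more broadly conserved (0.80).

A simulated injection bioassay (six doses, 10 larvae × 3 replicates × 4
experiments):

```r
mt <- simulate_mortality(mortality_sim_spec(seed = 11))
bioassay_analysis(mt)$lsd
#> One-way ANOVA: F(5, 66) = 31.638, p = 2.715e-16; MSE = 205.177
#> Fisher LSD (alpha = 0.05, harmonic-n LSD = 11.675):
#>   dose_0     mean    0.00  a
#>   dose_0.7   mean   44.17  bc
#>   dose_1.75  mean   35.83  c
#>   dose_3.5   mean   51.67  bd
#>   dose_5.25  mean   61.67  d
#>   dose_7     mean   62.50  d
```

The control is separated from every treatment (letter `a` alone); doses
sharing a letter do not differ significantly — here the treatments form
overlapping groups with no monotone dose response, only a control-versus-
treatment effect.

A thin command-line front end (`exec/genrelate`) exposes the same stages as
`simulate | anib | ddh | bsr | relate | bioassay | run` subcommands, and
`run_relatedness(pipeline_config(...))` orchestrates the full FASTA-to-report
pipeline (or a stats-only rerun from a precomputed table) with a seed-stable,
byte-identical output contract.

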