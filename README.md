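# ltrkit

Structural annotation, classification and insertion-age dating of intact
LTR retrotransposons (LTR-RTs), as a self-contained R toolkit.

LTR-RTs are the dominant repeat class of most plant genomes. An intact
element is `TSD – LTR – PBS – internal domains – PPT – LTR – TSD`: a
4–6 bp target-site duplication on both flanks, two near-identical long
terminal repeats with `TG…CA` termini, a primer binding site complementary
to a host tRNA tail near the 5′ LTR, the GAG/Pol coding domains, and a
polypurine tract near the 3′ LTR. `ltrkit` finds intact candidates from
sequence alone, annotates PBS/PPT, classifies elements from their domain
arrangement, dates insertions from LTR divergence, relates elements to
genes, builds redundant and non-redundant libraries, and scores
annotations against a reference — with a synthetic-genome simulator
providing exact ground truth for every stage.

The two quantitative cores:

* **Classification** — the domain order distinguishes the superfamilies:
  Gypsy is `GAG–PROT–RT–RH–INT` (integrase last), Copia is
  `GAG–PROT–INT–RT–RH` (integrase before the reverse transcriptase). The
  full template with PBS and PPT is autonomous; structural derivatives are
  called non-autonomous Gypsy/Copia, BARE-2 (no GAG), TR-GAG (GAG only),
  TRIM (miniature non-coding) and LARD (large non-coding).
* **Insertion age** — with transition proportion *P* and transversion
  proportion *Q* between the two LTRs, the Kimura two-parameter distance
  is `K = −½·ln((1−2P−Q)·√(1−2Q))`, and the age is `T = K/(2r)` for a
  neutral substitution rate `r` (per site per year, supplied by the user).

## Worked example

Everything runs off tibbles and pipes. Here a genome with twelve known
implants (5% LTR divergence) is simulated, detected, and annotated; the
external domain-hit table (normally the output of an HMM domain scanner
on the detected elements) is taken from the simulator truth:

```r
library(ltrkit)

sim <- simulate_genome(n_seqs = 1, seq_len = 5e5,
                       implants = default_implants(12, true_K = 0.05),
                       seed = 42)

# detect, then key the external domain-hit table to the detected ids
det  <- detect_elements(sim$genome)
ids  <- map_truth_ids(sim$elements, det)
hits <- sim$domains
hits$element_id <- ids$detected_id[match(hits$element_id, ids$truth_id)]

run <- run_pipeline(sim$genome, "demo_out",
                    genes = sim$genes, trnas = sim$trnas, domains = hits,
                    cfg = ltr_config(R = 1.3e-8))
glance(run)
#> # A tibble: 1 × 7
#>   n_elements n_autonomous n_gypsy n_copia n_clusters mean_age_mya n_chimeric
#>        <int>        <int>   <int>   <int>      <int>        <dbl>      <int>
#> 1         12            4       4       4         12         2.25          3

head(dplyr::select(tidy(run), element_id, start, end, category,
                   superfamily, K, T_mya), 8)
#> # A tibble: 8 × 7
#>   element_id   start    end category       superfamily      K T_mya
#>   <chr>        <int>  <int> <chr>          <chr>        <dbl> <dbl>
#> 1 LTRRT_00001  25584  28184 AUTON_GYPSY    Gypsy       0.0851  3.27
#> 2 LTRRT_00002  67890  69830 AUTON_COPIA    Copia       0.0517  1.99
#> 3 LTRRT_00003 110889 114389 NONAUTON_GYPSY Gypsy       0.0629  2.42
#> 4 LTRRT_00004 145103 146603 NONAUTON_COPIA Copia       0.0670  2.58
#> 5 LTRRT_00005 179232 183432 LARD           unknown     0.0737  2.84
#> 6 LTRRT_00006 210047 211347 TR_GAG         unknown     0.0577  2.22
#> 7 LTRRT_00007 253681 259181 BARE2          unknown     0.0413  1.59
#> 8 LTRRT_00008 295900 298500 AUTON_GYPSY    Gypsy       0.0307  1.18
```

All twelve implants are recovered; four carry the full autonomous
template; simulated divergence of `K* = 0.05` at `r = 1.3e-8` corresponds
to an expected age of ~1.9 Mya, and the per-element estimates scatter
around it (mean 2.25 Mya here — LTRs are a few hundred bp, so single
elements are noisy). Per-base agreement with the truth annotation:

```r
bm <- benchmark_annotation(sim$elements, run$elements,
                           setNames(sim$genome$length, sim$genome$seq_id))
bm
#> <ltr_benchmark>
#>   TP=34280 FP=0 FN=0 TN=465720 bp
#>   sensitivity  1.0000
#>   specificity  1.0000
#>   accuracy     1.0000
#>   precision    1.0000
#>   FDR          0.0000
#>   F1           1.0000
```

`run_pipeline()` writes GFF3 (elements with LTR, TSD, PBS, PPT and domain
child features), classification/age/gene-context TSVs, both libraries in
FASTA, density tracks and a JSON run manifest to the output directory;
`plot_length_distribution()`, `plot_age_distribution()` and
`plot_density_ideogram()` draw the standard summary figures. A thin
command-line front end is installed as `exec/ltrkit`
(`ltrkit run | simulate | bench`).

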