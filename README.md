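# circseam

Quantitative analysis of circular RNA (circRNA) biogenesis from
back-splicing junction (BSJ) read counts.

Circular RNAs arise when a downstream 5' donor splice site is joined to an
upstream 3' acceptor, circularizing the intervening exon(s). The junction
created by this back-splicing reaction is unique to the circular isoform, so
reads spanning it quantify the circRNA independently of its cognate linear
transcript. `circseam` implements the computational workflow used to ask
whether changes in circRNA abundance reflect altered *biogenesis* rather
than transcription of the host locus, and whether an RNA-binding protein
binds preferentially near the back-splicing junctions of the circRNAs it
regulates:

* **Junction quantification.** Per-sample CIRI2-style tables report, for
  each BSJ, the back-splicing reads and the reads mapping linearly over the
  same two splice junctions. `complete_counts()` merges samples over the
  union of BSJs, recovering linear-junction coverage for samples where the
  BSJ itself was not detected, so the count matrix is dense.
* **Differential testing.** After the expression filter (≥ 2 counts in
  ≥ 3 samples) counts are TMM-normalized (`tmm_factors()`) and each
  circular and linear junction feature is tested between two conditions
  with a negative-binomial likelihood-ratio test (`nb_lrt()`): per feature,
  the NB likelihood with fixed dispersion φ is maximized under a common
  mean scale (null) and per-group scales (alternative), and
  2·(ℓ₁ − ℓ₀) is referred to χ²(1). Significance uses the raw p-value at
  α = 0.05; CPM values come from effective library sizes.
* **Concordance classes and CLR.** `classify_pairs()` labels each
  circular/linear pair *Concordant* (both isoforms deregulated in the same
  direction), *Discordant circ* (circular changes, linear unaltered or
  opposite), *Discordant lin*, or *Unaltered*; discordant circRNAs are the
  candidates for biogenesis-level regulation. The circular-to-linear ratio
  CLR = CPM(circ)/CPM(linear) is compared across conditions with the
  two-sided Kolmogorov–Smirnov test (`clr_cdf_compare()`), and up/down
  proportions with the two-tailed Fisher exact test (`proportion_test()`).
* **Meta-BSJ binding enrichment.** For RIP-seq peaks (narrowPeak, one file
  per replicate), 100-nt windows sliding in 10-nt steps over ±1000 nt of
  each BSJ extremity are compared between downregulated circRNAs and
  property-matched control windows drawn from invariant circRNAs at the
  same relative position (matched on exon/UTR/CDS overlap, host biotype and
  exon-number class). Each (extremity, offset) bin is a 2×2 Fisher test
  per replicate (`meta_bsj_enrichment()`). Interactors are circRNAs whose
  span overlaps a peak in ≥ 2 replicates (`interactor_call()`).
* **Summit structure profiles.** `metaprofile()` folds a 151-nt window
  around every position of a 500-nt peak-summit-centered window and
  reports per-offset mean minimum folding free energy (ΔG) and GC content;
  the folding backend is either the bundled nested-structure dynamic
  program or the thermodynamic `RNAfold` engine.
* **Synthetic scenarios with planted truth.** `simulate_scenario()`
  generates a toy genome, multi-exonic annotation, NB junction counts with
  planted concordance categories and fold changes, and peak replicates
  planted near the 5' donor sites of downregulated circRNAs with GC-rich
  summit motifs — so every pipeline stage can be scored without external
  data.

## Worked example

```r
library(circseam)

cfg <- scenario_config(n_circ = 24L)
sim <- simulate_scenario(cfg, seed = 42L)

de <- run_junction_de(sim$records, sim$groups,
                      linear_supplement = sim$linear_supplement,
                      dispersion = cfg$dispersion)
de$matrix
#> CountMatrix: 48 features ( 24 circ ) x 6 samples

table(de$pairs$category)
#>     Concordant DiscordantCirc  DiscordantLin      Unaltered
#>              4              9              4              7

down <- sum(de$circ_de$status == "down"); up <- sum(de$circ_de$status == "up")
pr <- deregulation_proportions(down, up)
sprintf("downregulated: %d (%.0f%%), upregulated: %d (%.0f%%)", down, pr$pct_down, up, pr$pct_up)
#> "downregulated: 10 (77%), upregulated: 3 (23%)"

enr <- meta_bsj_enrichment(de$circ_de, de$matrix$meta, sim$ann, sim$peaks)
sig <- subset(enr$bins, significant & extremity == "five_prime_ss")
head(sig[order(sig$pvalue), ], 3)
#>     replicate offset a b c  d odds_ratio       pvalue
#> 477      rep3    -60 9 1 0 20   259.6667 6.989512e-07
#> 478      rep3    -50 9 1 0 20   259.6667 6.989512e-07
#> 479      rep3    -40 9 1 0 20   259.6667 6.989512e-07
```

The deregulated circRNAs split 10 down / 3 up (the scenario plants a 0.8
down-fraction), the pair classification recovers the planted category mix,
and the enrichment bins with significant odds ratios cluster around the 5'
donor splice site (offsets −210…160 nt here), where the peaks were planted:
9 of 10 downregulated circRNAs carry a replicate-3 peak in those windows
versus 0 of 20 matched control windows.

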