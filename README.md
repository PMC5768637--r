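# phorep

Phosphatase repertoires, cis-regulatory motifs and phosphatogenesis
geochemistry for bacterial genomes.

Many bacteria hydrolyse organic phosphoesters with non-specific
phosphatases (alkaline families PhoA, PhoK, PhoD, PhoX; acid families
AcpA, PhoN, AphA, NSAPc). The released orthophosphate can, in Ca-rich
media, push the solution past saturation with respect to hydroxyapatite
Ca<sub>5</sub>(PO<sub>4</sub>)<sub>3</sub>OH and precipitate
calcium-phosphate minerals — *phosphatogenesis*. `phorep` provides a
tested, reusable pipeline for the in-silico side of that question: which
phosphatase families does a genome encode, how are the genes regulated,
what do the proteins look like, and do measured solution compositions
actually reach supersaturation?

## What it computes

* **Family annotation** — ungapped PSSM scanning (maximal-scoring diagonal
  segments, Karlin–Altschul E-values `E = K·m·n·exp(−λS)` with empirical
  Gumbel calibration), the 70% mutual-coverage redundancy rule for
  building family profile sets, the all-profiles membership rule at
  `E ≤ 1e-10`, and Smith–Waterman validation (BLOSUM62 11/1, `E ≤ 1e-3`).
  Six-frame scanning of intergenic DNA screens for missed genes.
* **Regulatory motifs** — TF-binding-site scanning with *exact* p-values
  under an order-1 Markov background trained on the organism's upstream
  noncoding sequences (`p ≤ 1e-4` ≈ 1 false positive / 10 kb), upstream
  region extraction and a distance/strand transcription-unit heuristic.
* **Protein features** — molecular weight (average masses), theoretical pI
  (Bjellqvist pKa set, bisection on the net-charge function), signal
  cleavage bookkeeping, Tat twin-arginine motif detection.
* **Structures** — active-site detection by ligand/metal contacts (4 Å),
  Shrake–Rupley solvent-accessible surface area, the summed "active-site
  accessibility", homologous-position mapping through alignments, Kabsch
  superposition RMSD.
* **Geochemistry & kinetics** — hydroxyapatite saturation index
  `SI = log10(IAP/Ks)` with `log Ks = −57.74`, Davies activity
  corrections and a documented simplified speciation; Beer–Lambert
  conversion (ε = 18,000 M⁻¹cm⁻¹ at 405 nm) and initial-phase hydrolysis
  rates in pmol/s.
* **Genome survey** — per-family prevalence, gene densities per Mb,
  size–count regression and Kruskal–Wallis statistics over genome
  collections.
* **Synthetic data** — seeded generators for proteomes with implanted
  domains, promoters with implanted motifs, toy structures, kinetics
  series and survey tables, so the full pipeline is testable offline.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
carry broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()`.

## Worked example

```r
library(phorep)

# -- is the assay medium supersaturated w.r.t. hydroxyapatite?
si <- saturation_index_hydroxyapatite(total_ca = 10e-3,  # 10 mM Ca
                                      total_pi = 267e-6, # 267 uM Pi
                                      pH = 7.5)
round(as.numeric(si), 2)
#> [1] 13.36
```

An SI of 13.4 is far above the empirical precipitation threshold of ~10,
so this solution precipitates hydroxyapatite. The ideal-solution value
(`davies = FALSE`) is 15.44 and bounds the corrected value from above.

```r
# -- annotate a (synthetic) proteome into phosphatase families
fams <- gen_reference_families(seed = 1)          # 2 families, calibrated
sim  <- gen_proteome(fams, implants = c(PhoD = 1, PhoX = 4),
                     n_decoys = 200, seed = 1)
annotate_proteome(sim$proteome, fams$family_sets, fams$calibrations)
#> # A tibble: 5 × 4
#>   protein_id family worst_evalue validated
#>   <chr>      <chr>         <dbl> <lgl>
#> 1 prot_0201  PhoD       3.26e-24 TRUE
#> 2 prot_0202  PhoX       3.15e-48 TRUE
#> 3 prot_0203  PhoX       7.61e-41 TRUE
#> 4 prot_0204  PhoX       2.41e-43 TRUE
#> 5 prot_0205  PhoX       3.09e-52 TRUE
```

All five implanted proteins — and none of the 200 decoys — are recovered
with their correct families (`worst_evalue` is the weakest per-PSSM best
hit; all far below the 1e-10 membership threshold).

```r
# -- hydrolysis rate from a noisy absorbance-derived series
k   <- gen_kinetics(rate_pmol_s = 358.6, noise_sd = 0.02, seed = 1)
fit <- hydrolysis_rate(k)
tidy(fit)
#> # A tibble: 1 × 5
#>   rate_pmol_s slope_m_per_s r.squared window_n n_points
#>         <dbl>         <dbl>     <dbl>    <int>    <int>
#> 1        359.   0.000000359     0.998       16       16
autoplot(fit)   # series, fitted line, fitting window
```

The estimator recovers the generating rate (358.6 pmol/s) within 0.1% at
2% noise by fitting only the initial linear phase.

## Documentation

The methods vignette (`vignettes/phosphatase-repertoires.Rmd`) describes
the models, parameter defaults, numerical conventions, what the synthetic
generators do and do not emulate, and known limitations.
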