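---
title: "Methods: phosphatase repertoires, regulatory motifs and phosphatogenesis geochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphatase repertoires, regulatory motifs and phosphatogenesis geochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phorep)
```

# Scope

`phorep` characterises the repertoire of non-specific phosphatases encoded
by a bacterial genome and the geochemical consequences of their activity.
Non-specific phosphatases hydrolyse phosphomono- and diesters, releasing
orthophosphate (Pi); where dissolved calcium is abundant, the local rise in
Pi can drive the solution past saturation with respect to hydroxyapatite
(Ca~5~(PO~4~)~3~OH) and trigger phosphatogenesis — microbially induced
calcium-phosphate precipitation. The package covers eight widely recognised
families: the alkaline phosphatases PhoA, PhoK, PhoD and PhoX and the acid
phosphatases AcpA, PhoN, AphA and NSAPc.

This vignette is the package's methods account: the models, the tunable
parameters and their defaults, the numerical choices, what the synthetic
generators do and do not emulate, and the known limitations.

# Profile-based family annotation

## Model

Each family is described by a reference protein and a set of
position-specific scoring matrices (PSSMs). Scanning is ungapped: for a
PSSM of length $m$ and a query of length $n$, every diagonal offset defines
a vector of per-position log-odds weights (half-bit units), and the
maximal-scoring contiguous segment on each diagonal is found with Kadane's
algorithm. Raw segment scores are converted to E-values with the
Karlin–Altschul form

$$E = K\,m\,n\,e^{-\lambda S},$$

where $(\lambda, K)$ come from an empirical calibration: best-segment
scores on i.i.d. background sequences (Robinson–Robinson amino-acid
frequencies) are fitted to a Gumbel law by maximum likelihood
(`calibrate_pssm()`, deterministic given its seed). The search space is the
per-comparison $m \times n$; no database-size correction is applied, so
E-value thresholds act as per-comparison significance levels.

Two decision rules make up the annotation:

* **Redundancy removal** (`deduplicate_profiles()`): among PSSMs hitting
  the family reference, any pair whose hit intervals overlap with mutual
  coverage above 70% of the longer hit is redundant; the lower-E profile
  wins. Selection is greedy by ascending E-value, ties broken by accession,
  which makes the rule well defined for more than two mutually overlapping
  profiles and idempotent.
* **Membership** (`assign_family()`): a protein joins a family only if
  *every* PSSM of the family set hits it at $E \le 10^{-10}$. A
  low-stringency Smith–Waterman validation against the family reference
  (BLOSUM62, gap open 11 / extend 1, $E \le 10^{-3}$) then removes remote
  superfamily homologs that happen to pass the profile rule.

The same threshold ($10^{-10}$) is used for "significant" hits during
reference-set construction and for membership; nothing in the procedure
requires them to differ.

Internal E-values will not numerically equal those of external profile
search engines (different extension model and statistics); only threshold
*decisions* are expected to transfer. An import adapter
(`read_rpsblast_tabular()`) lets externally computed profile searches feed
the same membership logic when curated domain databases are available.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `e_member` | 1e-10 | per-PSSM membership threshold |
| `e_validate` | 1e-3 | local-alignment validation threshold |
| `max_coverage` | 0.70 | mutual-coverage redundancy cutoff |
| `n_samples`, `sample_length` | 500, 200 | calibration sample size |

Calibration with 500 samples of length 200 takes a couple of seconds per
PSSM and gives tail probabilities accurate to within a factor of two at the
quantiles where decisions are made; scores are lattice-valued, so the
Gumbel law is approached only asymptotically and small systematic
deviations at the distribution's centre are expected and harmless.

## Noncoding search

`scan_noncoding_sixframe()` translates every intergenic span of at least
60 bp in all six frames and scans the translations with the family PSSMs,
reporting the frame and the genomic interval of any hit — a screen for
phosphatase genes or pseudogenes missed by the structural annotation.

# Cis-regulatory motif scanning

## Model

Transcription-factor binding sites are sought in the noncoding region
upstream of a gene (or of the first gene of its transcription unit). The
background is a Markov model of order 1 trained on the organism's own
upstream noncoding sequences (`train_markov()`; counts never cross sequence
boundaries; Laplace pseudocount 1). A motif's window score is the
log-likelihood ratio

$$S = \sum_i \big[\log P_\text{matrix}(w_i \mid i) - \log P_\text{bg}(w_i \mid w_{i-1})\big],$$

with the initial distribution for the first base when no left context
exists. P-values are *exact*: a dynamic program over (position, previous
base, discretised score) yields the full null distribution of $S$ for
windows drawn from the background chain (`exact_pvalue_table()`). Scores
are discretised to 0.01-score bins and p-values reported at the bin lower
edge (conservative). Because each per-position increment is rounded, the
DP's lattice can deviate from a continuous window score by up to $L$ bins
over a length-$L$ motif — on its own lattice the DP is exact, as the test
suite verifies by brute-force enumeration of all $4^L$ windows.

Both strands are scanned by default (a configuration flag restricts to the
forward strand); the reverse strand is handled by scanning the reverse
complement, which makes strand symmetry exact by construction. No
multiple-testing correction is applied: the raw threshold $p \le 10^{-4}$
corresponds to about one false positive per 10 kb scanned, and the test
suite checks that empirical null hit counts fall inside the 99% Poisson
band of that expectation.

Hit coordinates follow the upstream convention: position $-1$ is the base
immediately 5′ of the start codon, so a 16-bp hit ending there is reported
as `[-16, -1]`.

## Upstream regions and transcription units

`extract_upstream()` returns the noncoding span between a gene's 5′ end and
the nearest annotated feature boundary, reverse-complemented for
reverse-strand genes so it always reads toward the start codon; regions at
contig edges are truncated with a warning. Transcription units are
predicted by a deliberately simple heuristic
(`predict_transcription_units()`): consecutive same-strand genes with
intergenic gaps of at most 150 bp (inclusive) are merged. Only the choice
of upstream region depends on the operon call, so a distance/strand rule is
adequate; it is not a reimplementation of database-backed operon
predictors, and the gap parameter is exposed.

# Protein features

Molecular weight is the sum of average (isotope-weighted) residue masses
plus one water — the ProtParam convention, so published values computed
that way are directly comparable. The theoretical pI is the unique root of
the net-charge function (Henderson–Hasselbalch over the termini and the D,
E, C, Y, H, K, R side chains), found by bisection to $10^{-4}$ pH; the
charge function is strictly decreasing in pH, so the root is unique and
bisection cannot fail. Two pKa sets are provided: Bjellqvist (default; the
ProtParam set, with residue-specific N-terminal pKa) and EMBOSS.

Signal peptides are consumed as annotations (their lengths come from
dedicated predictors, which are out of scope); `cleave_signal()` does the
bookkeeping and the mass additivity `MW(mature) + MW(signal) − H2O =
MW(precursor)` holds exactly. Tat export signals — twin-arginine motifs
that route folded proteins across the inner membrane — are detected by a
documented heuristic: the consensus `[ST]-R-R-x-[FGAVML]-[LITMVF]` within
the first 45 residues, with a bare `R-R` pair reported as low-confidence.
This flags candidates; it is not a trained classifier.

# Structural analysis

Active-site residues are defined by noncovalent contact: any residue with a
heavy atom within 4.0 Å of a phosphate-ligand or metal-ion atom
(`detect_active_site()`). The 4.0 Å default is a conventional heavy-atom
contact cutoff; it is exposed because published contact lists depend on the
exact criterion used, and can be tuned so that a reference structure
reproduces its published site size before mapping the site onto homologs.

Solvent-accessible surface area uses the Shrake–Rupley construction:
960 near-uniform test points (golden spiral) on each atom's
probe-expanded sphere (probe 1.4 Å), points buried by any neighbour's
expanded sphere removed, Bondi van der Waals radii, hydrogens ignored. The
test-point sphere is anchored to the molecule's principal axes (axis signs
fixed by the third moment), which makes the computed area exactly invariant
under rigid motion of the structure; a perfectly symmetric coordinate cloud
would make that anchoring ill-defined, which never arises for real
proteins. Different SASA engines differ by several percent in absolute
values (radii sets, point densities, coarse-graining), so cross-engine
comparisons should rely on orderings and ratios rather than absolute areas.

The *active-site accessibility* is the sum of per-residue SASA over the
site residues, computed after stripping the ligand and co-factors
(`strip_hetero()`) so the site's surface is not masked by its own ligand.
Site positions transfer to homologs through a pairwise alignment
(`map_site_to_homolog()`); positions aligned to gaps are reported absent
rather than silently dropped. Rigid superposition uses the Kabsch/SVD
solution with the determinant correction (`kabsch_superpose()`), reporting
C-alpha RMSD. A per-residue formal-charge summary near the site
(`site_charge_summary()`) gives a coarse electrostatic character; it is
explicitly not a Poisson–Boltzmann potential map.

# Geochemistry and kinetics

## Saturation index

The saturation index is $\mathrm{SI} = \log_{10}(\mathrm{IAP}/K_s)$ with
$\mathrm{IAP} = a(\mathrm{Ca}^{2+})^5\,a(\mathrm{PO_4}^{3-})^3\,a(\mathrm{OH}^-)$
and $\log_{10} K_s = -57.74$ for hydroxyapatite. Speciation is a documented
simplified model: orthophosphate protonation with pKa 2.148 / 7.199 / 12.35
(25 °C), water autoionisation, Davies activity coefficients
($\log_{10}\gamma_z = -0.509\,z^2(\sqrt I/(1+\sqrt I) - 0.3 I)$), and ionic
strength solved by fixed-point iteration to $10^{-8}$ M, with charge
balance closed by an inert monovalent counter-ion. Ca-phosphate ion pairs
(CaHPO~4~^0^, CaPO~4~^−^) and carbonate equilibria are neglected; this
biases SI upward by at most about one unit in these media, which does not
affect conclusions phrased against the empirical precipitation threshold
SI ≥ 10. The ideal-solution SI ($\gamma = 1$) is an upper bound on the
Davies-corrected value and serves as a hand-checkable cross-check
(`davies = FALSE`). The SI is reported as undefined when total Ca or total
Pi is zero or below the detection limits (0.85 µM Pi, 50 µM Ca — the
instrumental errors of the standard colorimetric assays).

```{r}
saturation_index_hydroxyapatite(total_ca = 10e-3, total_pi = 267e-6,
                                pH = 7.5)
```

## Hydrolysis kinetics

Absorbance at 405 nm converts to released p-nitrophenol (hence Pi) through
$c = A/(\varepsilon \ell)$ with $\varepsilon = 18{,}000$ M⁻¹cm⁻¹. The rate
is the ordinary least-squares slope over the *initial linear phase*,
selected as the longest prefix of at least 4 points with $R^2 \ge 0.98$;
this confines the fit to the pre-plateau region when the substrate is
depleted, at the cost of a small downward bias if the plateau onset is
gradual. The slope times the reaction volume is reported in pmol/s.

# Genome survey

`build_survey()` tabulates per-genome family counts;
`summarize_survey()` reports, over a collection: the fraction of genomes
with at least $k$ alkaline-phosphatase genes (alkaline = PhoA + PhoK +
PhoD + PhoX), per-family prevalence, per-genome densities in genes/Mb with
the focal genome's percentile and rank, the least-squares regression of
total phosphatase count on genome size with $R^2$, and a Kruskal–Wallis
test of counts across genome-size quantile bins (quintiles by default; the
bin count is a documented convention and configurable). Densities are
normalised per Mb; per-1000-genes would require gene counts that annotation
tables do not always carry.

# Synthetic data

Each generator derives a private substream from the global seed, so adding
or re-running one generator never perturbs another, and outputs are
byte-identical given a seed.

* `gen_reference_families()` / `gen_proteome()`: peaked random count
  matrices (dominant residue 0.85 per column, 60 columns) with their
  consensus as the family reference; decoy proteins i.i.d. from
  Robinson–Robinson frequencies (lengths 200–600 aa); implants sampled from
  the PSSM's per-column emission probabilities and embedded at random
  positions. A `sharpness` exponent interpolates from background sampling
  (0; signal-free negative control) through faithful matrix sampling (1).
  The standard desk-scale benchmark is 200 decoys plus implants shaped as
  the focal repertoire (1 PhoD-like + 4 PhoX-like), on which annotation is
  expected to achieve precision = recall = 1.
* `gen_promoters()`: order-1 background with stationary A+T = 0.70 (the
  AT-richness typical of prokaryotic regulatory regions) and mild
  within-pool persistence; motif instances sampled from the matrix and
  implanted at stated positions/strands relative to the gene start.
* `gen_toy_structure()`: C-alpha pseudo-atoms along a coarse helix, with
  the designated site residues relocated along well-separated directions to
  sit at an exact stated distance from a phosphate ligand (P + 4 O,
  tetrahedral), optional metal ions, clash-checked PDB text output.
* `gen_kinetics()`: linear concentration growth with Gaussian noise
  (default 2% of the final level) and an optional plateau.
* `gen_survey()`: lognormal genome sizes (median 4 Mb, sdlog 0.35);
  per-family counts Poisson with mean proportional to size. The default
  per-Mb rates are chosen so the synthetic collection reproduces published
  marginal prevalences of the families in complete bacterial genomes
  (about 62% of genomes with ≥ 1 alkaline-phosphatase gene; 35%, 22% and
  17% with ≥ 1 PhoA, PhoX and PhoD respectively); phylum labels are
  assigned round-robin.

What the generators do *not* emulate: real domain architectures and
homology gradients (implants are emission samples, not evolved sequences),
phylogenetic correlation among genomes, genuine promoter grammar, protein
packing (toy structures are CA-only), or substrate-dependent kinetics.
Green tests on synthetic data therefore demonstrate that the decision rules
and estimators are implemented correctly under their stated statistical
assumptions — not that the thresholds are optimal for any particular real
dataset.

# Numerical choices and edge cases

* Unknown residues: `X` (protein) and `N` (DNA) are legal everywhere and
  score 0 in all scanners.
* Reverse-strand gene rows may list start > end (coordinates read 5′→3′ on
  the coding strand); both orders are accepted and normalised to
  (left, right, strand). Derived protein length excludes the stop codon:
  span/3 − 1.
* E-value ties in redundancy removal break lexicographically by accession.
* The p-value lookup is conservative (bin lower edge); the DP warns if its
  total mass deviates from 1 by more than 10⁻⁹.
* Gumbel fitting solves the scale equation by Brent's method bracketed
  around the sample standard deviation; degenerate (constant) score
  distributions are an error, not a silent fit.
* The ionic-strength fixed point converges from any reasonable start
  (contraction verified in tests); pH is taken on the activity scale.
* Kabsch superposition refuses fewer than 3 pairs or collinear point sets.

# Problem sizes

The test suite and the acceptance script run entirely at desk scale: the
synthetic repertoire benchmark uses 205 proteins against 3 calibrated
PSSMs (about 15 s), null motif calibration scans 50–100 kb, the survey
benchmark uses 500 genomes, and structural checks use 50–70-atom toys.
These sizes were chosen so the whole pipeline exercises every decision rule
while remaining quick to re-run; all of them scale linearly for users with
larger inputs.

# Known limitations

* E-values from the internal ungapped scanner are not numerically
  comparable with gapped profile-search engines; use the import adapter to
  consume external searches when exact engine parity matters.
* The simplified speciation omits ion pairing; for media far from the
  assay conditions (high ionic strength, carbonate-buffered), use a full
  speciation code and feed the activities directly.
* Tat-motif detection is a pattern heuristic with no discrimination
  against Sec signals.
* Absolute SASA values depend on the engine parameterisation; published
  accessibilities from other tools are reproducible only to within ~10%,
  and comparisons should be made on orderings.
* The operon heuristic has no confidence model; genes in large complex
  operons with long internal gaps will be split.
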