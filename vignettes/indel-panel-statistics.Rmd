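---
title: "Forensic statistics for biallelic InDel panels: models, choices, limits"
author: "indelpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic statistics for biallelic InDel panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelpop)
```

## The setting

Insertion/deletion polymorphisms (InDels, also called DIPs) are biallelic
length variants: each locus has a short (deletion, DIP−) and a long
(insertion, DIP+) allele, typed by ordinary capillary electrophoresis. A
forensic panel — the commercial Investigator DIPplex kit types 30 such loci —
is characterized in a new population by a standard battery of statistics:
allele frequencies, observed and expected heterozygosity, a Hardy–Weinberg
equilibrium test, polymorphic information content, power of exclusion,
discrimination power and typical paternity index per locus, and the
panel-level cumulative power of exclusion and combined discrimination power.
`indelpop` implements that battery end to end, together with the
between-population comparisons that normally accompany such surveys:
pairwise Weir–Cockerham $F_{ST}$ with permutation significance, Nei genetic
distances with UPGMA tree construction, and PCA of population × locus
allele-frequency tables.

The package ships the published summary rows of a 30-locus survey of 223
unrelated Chinese Xibe individuals (`xibe_panel()`), both as a worked
reference surface and as the default frequency profile of the synthetic-data
generator.

## From printed tables to integer counts

Published surveys print, per locus, the deletion-allele frequency $p$, the
observed heterozygosity $H_o$ and the sample size $n$, all at four decimals.
Because the underlying data are integer genotype counts
$(n_{DD}, n_{DI}, n_{II})$, the printed triple can be inverted exactly:
$n_{DI} = \mathrm{round}(H_o n)$ and the deletion-allele count
$a = \mathrm{round}(2np)$, with $n_{DD} = (a - n_{DI})/2$. When rounding
leaves $a - n_{DI}$ odd, `counts_from_summary()` nudges $a$ by one in the
direction that better matches the printed frequency (ties resolved
downward) and flags the adjustment; the result is then verified by
round-trip against the printed values. For the shipped 30-locus table no
parity adjustment is needed, and every derived column is reproduced exactly
at four decimals from the reconstructed counts:

```{r}
summary <- summarize_panel(xibe_panel(), hwe_method = "none")
head(format_panel_report(summary)[, c("locus_id", "ho", "he", "pic", "pe", "dp", "tpi")])
attr(summary, "panel_powers")[c("cpe", "cpd")]
```

One caveat is inherent to the inversion: for $n \ge 5000$ a printed 4-dp
frequency can sit exactly halfway between the two parity-compatible allele
counts, in which case the printed values no longer determine the counts
uniquely and the deterministic tie rule picks one of the two equally good
reconstructions. At forensic-survey sample sizes (a few hundred) the
inversion is unambiguous.

## The per-locus statistics and why these forms

With $p$ the deletion-allele frequency, $q = 1-p$, $h$ the observed
heterozygosity and $H = 1-h$:

* $H_e = 2pq$, **without** the $2n/(2n-1)$ small-sample correction. The
  uncorrected form reproduces the published table cell-for-cell (e.g.
  $2pq = 0.4994$ at HLD92, where the corrected form gives 0.5005); the
  spreadsheet lineage of forensic panel reports uses plain $2pq$.
* $PIC = 1 - (p^2+q^2) - 2p^2q^2$, Botstein's biallelic form.
* $PE = h^2(1 - 2hH^2)$, the exclusion power driven by *observed*
  heterozygosity (Brenner's form). Allele-frequency-driven PE variants
  exist; feeding $H_e$ instead of $H_o$ to `power_of_exclusion()` yields
  the HWE-expectation variant, but the observed-heterozygosity form is the
  default because it is the one the published table uses.
* $DP = 1 - \sum_g \tilde g^2$ over the three **observed** genotype-class
  frequencies, not their HWE expectations — again selected by verification
  against the published table.
* $TPI = 1/(2(1-h))$, undefined at $h = 1$.

Panel-level powers assume independent loci (the 30 DIPplex markers are
unlinked): $CPE = 1 - \prod_i (1 - PE_i)$ and
$CPD = 1 - \prod_i (1 - DP_i)$. The complements are accumulated in log
space; $1 - CPD$ for a 30-locus panel is of order $10^{-11}$, far below
what naive subtraction of rounded per-locus values would resolve, so
`combined_powers()` also returns the complement itself.

## Hardy–Weinberg testing

`hwe_exact()` is the conditional exact test for a biallelic locus: given
the allele counts, every heterozygote count of the right parity is a
possible configuration with a hypergeometric-form probability, and the
p-value sums the probabilities of all configurations no more probable than
the observed one. The plain tail definition is used (no mid-p), the default
convention for biallelic forensic loci. Probabilities are built by the
stable two-step recurrence
$P(h+2)/P(h) = 4\,n_{DD}(h)\,n_{II}(h) / ((h+2)(h+1))$ in log space and
normalized, so sample sizes in the thousands pose no overflow risk; the
test suite checks the implementation against independent log-factorial
enumeration to $10^{-12}$ up to $n = 200$ and its type-I error at
$\alpha = 0.05$ under the survey's own design ($n = 223$, $p = 0.5$,
2,000 replicates).

A chi-square goodness-of-fit test (`hwe_chi2()`, 1 df, no continuity
correction) is provided for comparison. The shipped survey's printed HWE
p-values come from an unpublished spreadsheet whose test is unstated; on
the reconstructed counts at HLD97 (94, 91, 38) the exact test gives
0.0626 and the chi-square test 0.0542, neither equal to the printed
0.0660. The printed p column is therefore displayed by the package's
reports but not treated as a reference surface; both methods are exposed
so users can compare.

## Between-population differentiation

`pairwise_fst()` implements the Weir–Cockerham (1984) moment estimator
$\theta$ for two populations at a biallelic locus, from genotype counts,
with the observed heterozygosities entering the within-individual variance
component. This is a deliberate substitution for the two-population AMOVA
used by survey software such as Arlequin: for diploid biallelic genotype
data with no within-individual haplotype structure the two frameworks
estimate the same quantity up to estimator variant, and Weir–Cockerham is
fully and openly specified. Negative estimates are reported as-is — they
are the expected outcome for undifferentiated pairs — and a locus
monomorphic in the pooled sample raises an error rather than returning a
misleading zero. The multi-locus estimator is the standard ratio of summed
components.

Significance is by permutation of whole individuals (genotypes, not
alleles) between population labels, preserving group sizes, with
$p = (\#\{\theta^* \ge \theta\} + 1)/(B + 1)$. The seed is mandatory, and
the permutation routine snapshots and restores the caller's RNG state, so
embedding tests inside larger seeded simulations cannot silently couple
the two streams. Because $\theta$ is a function of the permuted count
tables, its permutation distribution has atoms; the p-value is therefore
valid but mildly conservative, which the calibration tests account for.
`differentiation_table()` assembles the loci × references grid, accepts
frequency-only references (expanded to HWE-expected counts and flagged
approximate), marks loci absent from a reference as no-result rows, flags
raw $p < \alpha$ by default (matching survey practice), and offers a
Bonferroni option.

## Distances, trees, PCA

`nei_da()` is the Nei–Tajima–Tateno (1983) allele-sharing distance
$D_A = 1 - \tfrac1L \sum_\ell \sum_a \sqrt{x_a y_a}$, the default because
it is the distance DISPAN-style survey pipelines draw trees from and it is
well behaved for small locus counts; `nei_ds()` (Nei standard distance,
with an `Inf` sentinel when cross-population identity vanishes) is the
alternative, since survey reports often do not name their distance.

`upgma()` is authored in-package rather than delegated to
`hclust(method = "average")` for one reason: determinism under ties. The
agglomeration order of tied pairs, and the child order within each merge,
are fixed by the lexicographically smallest leaf label, so the Newick
output (`write_newick()`, serialized via ape) is byte-stable across runs
and platforms. Node heights are half the merge distance, so branch lengths
are in distance units and the tree is ultrametric by construction; on an
ultrametric input matrix the cophenetic distances of the result equal the
input exactly. The test suite cross-checks cophenetic distances against
average-linkage `hclust` on generic matrices.

`pca_from_frequencies()` column-centers the population × locus frequency
matrix and takes the SVD, without unit-variance scaling: frequencies
already share a scale, and scaling would up-weight near-fixed loci. The
preprocessing used by published survey PCAs is generally unstated, so the
simplest convention is taken and documented; explained-variance
percentages depend on this choice. Component signs are fixed by making
each component's largest-magnitude loading positive.

## The synthetic-data generator

`simulate_study()` emulates the statistical structure the analyses assume,
with defaults matching the shipped survey's design: 223 diploid
individuals, the 30 panel loci at their published DIP− frequencies, HWE
within populations. Around that core it provides the two departures the
pipeline needs for calibrated testing: an inbreeding coefficient $f$
(genotype probabilities $p^2 + fpq,\; 2pq(1-f),\; q^2 + fpq$), which gives
the HWE tests a known alternative to detect, and Balding–Nichols
divergence (per-population frequencies drawn from
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, mean $p$, variance $Fp(1-p)$),
optionally hierarchical with two clades (clade ancestors at
`fst_between`, populations within clades at `fst_within`) to mirror the
two-continental-cluster structure typical of such surveys. A single RNG
stream is seeded once per run with a documented draw order, so every run
is bit-reproducible.

What the generator does **not** emulate: linkage disequilibrium between
loci (the combined-power formulas assume independence, and so does the
generator), genotyping error and allelic dropout, missing-data mechanisms
(missingness is supported by the containers but never generated), mutation,
and within-population substructure other than the single inbreeding
coefficient. Tests passing on these simulations therefore validate the
estimators under their own model assumptions; they do not certify
robustness to kit artifacts or cryptic relatedness in real casework data.

## Numerical and design choices, in brief

* Report rendering rounds half away from zero at 4 decimals
  (`format_panel_report()`), the spreadsheet convention of the published
  tables; all internal computation is full precision.
* Combined powers accumulate complements in log space.
* The exact-test tail includes configurations within a $1 + 10^{-12}$
  relative factor of the observed probability, guarding against
  ties lost to floating-point noise.
* UPGMA tie-breaks and child order are lexicographic; Newick output is
  deterministic.
* Missing genotypes are excluded per locus (pairwise deletion), never
  imputed.
* Permutation p-values use the add-one convention and are never zero.
* Degenerate inputs fail loudly (`monomorphic locus`, `no data at locus`,
  `degenerate PCA input`) rather than returning conventional values,
  except where a defined value exists (HWE p = 1 for monomorphic loci,
  flagged).

The statistical guarantees in the test suite run at deliberately chosen
problem sizes: HWE exact-vs-enumeration agreement up to $n = 200$ and
type-I error at 2,000 replicates of the $n = 223$ design; $F_{ST}$
recovery at $F \in \{0.01, 0.05, 0.15\}$ with 30 loci, 200 individuals
per population and 50 replicates; null calibration of the permutation test
over 500 loci; UPGMA exactness over 50 random ultrametric matrices up to
12 taxa; and clade recovery on 50 replicates of an 11-population
two-clade design ($F_{within} = 0.01$, $F_{between} = 0.15$, five
populations in one clade and six in the other, mirroring the
European/Asian split of the reference surveys).

## Known limitations

* The published survey's HWE p column cannot be reproduced exactly
  (unstated test; see above), and its between-population $F_{ST}$ table
  and the PCA/tree figures depend on ten reference populations' genotype
  or frequency data published elsewhere, so they are out of reach of a
  self-contained reproduction. The package reproduces the full
  within-population parameter table and both panel-level powers exactly,
  and provides the same comparative machinery for users who supply
  reference data.
* $F_{ST}$ is the two-population Weir–Cockerham estimator; there is no
  hierarchical (multi-level) AMOVA and no $\Phi$-statistics.
* Loci are strictly biallelic throughout; no multi-allelic HWE
  permutation test, no mixture/likelihood-ratio casework statistics, and
  no $\theta$-corrected match probabilities.
* Trees carry no bootstrap support (the surveys this mirrors report
  none); only UPGMA is offered, not neighbor-joining.
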