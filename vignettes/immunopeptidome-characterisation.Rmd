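---
title: "Comparative characterisation of MHC class-I immunopeptidomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative characterisation of MHC class-I immunopeptidomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscape)
```

## The problem

Mass-spectrometry immunopeptidomics elutes the peptides presented by MHC
class-I molecules at the cell surface and identifies them against a protein
database. Comparing the resulting repertoires across engineered cell lines
— for example a wild-type line against a knockout that induces the
immunoproteasome — asks a recurring set of questions: which peptides are
unique to each condition and which are shared; how strongly the peptides
are predicted to bind MHC-I; whether the repertoires differ in length and
C-terminal chemistry (the two physicochemical axes of class-I binding);
how the abundance of the shared peptides shifts between conditions; and
whether any identified peptide is a neoantigen arising from a somatic
variant. `pepscape` implements that whole characterisation as composable,
tested functions plus one orchestrating pipeline.

The pipeline starts from *validated peptide/PSM tables* — database
searching, FDR control and search-engine merging happen upstream. Where
two search pipelines produce tables for the same sample,
`merge_repertoires()` consolidates them as a union with summed spectral
counts; how a consolidated dataset resolves engine disagreements is not
standardised anywhere, and the documented union is this package's choice.

## Repertoire comparison

A repertoire is the deduplicated set of peptide sequences of one sample,
with per-peptide spectral counts (number of PSM rows unless an explicit
count column is configured) and protein accessions. Peptide identity is
exact uppercase string match; no I/L equivalence collapsing is applied,
the simplest convention consistent with set-count reporting in
ligandomics. Rows containing non-standard residues (B, J, O, U, X, Z) are
rejected and counted rather than imputed, and an ingest run rejecting
more than half of its rows aborts, since that almost always signals a
wrong column mapping.

`partition_repertoires()` computes the unique/shared partition of two
samples by exact set operations, ignoring spectral counts (presence or
absence is the question at this stage), and `multiway_summary()` applies
it to every unordered pair of a sample panel.

## Binder classification and the scaled binding score

Binding predictions are consumed as per-(peptide, allele) percentile
ranks, the output convention of modern pan-allele predictors: a peptide's
rank locates its predicted affinity within a large background set, and
lower is stronger. The conventional cut-offs of 0.5 (strong) and 2 (weak)
are the defaults; both boundaries are inclusive, a choice this package
documents because the convention leaves boundary handling unstated.

A peptide's class is the class of its *minimum* rank across the supplied
alleles — standard practice, since presentation requires only one
binding allele — with ties broken by a fixed allele order (H2-Db, Dd,
Kb, Kd, Kk, Ld, then lexicographic) for determinism. An allele filter
allows single-allele analyses (e.g. H2-Kb only). Peptides missing from
the rank table are counted as non-binders by default and listed
explicitly, so the class tally always sums to the sample total.

Because repertoires differ greatly in depth, raw strong-binder counts are
not comparable across samples. The scaled binding score expresses the
strong-binder count as a percentage of the focal sample's own total
peptide number:

$$\text{scaled binding score} = \frac{n_\text{strong} \times 100}{s}$$

with $s$ the sample's total peptide count. The denominator is the focal
sample's own total — strong binders are normalised to the number of
peptides in that sample — which is the reading consistent with reporting
the score as "percent of all peptides identified" from one sample.

## Physicochemical profiles

Length distributions and C-terminal residue profiles are computed over
*distinct peptides*, unweighted by spectra, matching how repertoire
composition percentages are phrased. C-terminal hydrophobicity uses the
Kyte-Doolittle hydropathy index; a residue is "hydrophobic" when its
score is positive, which selects {A, C, F, I, L, M, V}. Two summary
statistics are reported per sample:

* `hydrophobic_fraction` — the fraction of peptides whose C-terminal
  residue has a positive score;
* `weighted_avg_hydrophobicity` — by default the mean C-terminal score
  over the peptides with a hydrophobic C-terminus. A weighted-average
  hydrophobicity over a repertoire is genuinely under-specified (all
  peptides, or hydrophobic termini only?); the hydrophobic-only mean is
  the default because the profile section concerns the hydrophobic
  C-termini specifically, and the all-peptide mean is available via
  `hydro_mean = "all"`. When no peptide has a hydrophobic C-terminus the
  statistic is undefined and reported as `NA`.

## Significance machinery

Between-sample differences in length and C-terminal hydrophobicity are
assessed with two-sample permutation tests on the per-peptide values.
The test statistic defaults to the difference in means (a median option
exists); tests are two-sided throughout. When all distinct relabelings
fit within the permutation budget the exact permutation p-value is
computed by enumeration (the identity arrangement included, so p is
never 0); otherwise random relabelings are drawn and the add-one
estimator $(1 + \#\{|T^*| \ge |T|\})/(B+1)$ is used, again bounded away
from 0. All pairwise tests across a panel are Bonferroni-adjusted,
$p_\text{adj} = \min(1, p \times n_\text{pairs})$.

The shared-peptide expression comparison reports both a Wilcoxon
rank-sum test and a Welch unequal-variance t-test on the normalised
scores; the two are near-interchangeable here, and both are printed with
the rank-sum result as the headline since it assumes nothing about the
distribution of count-derived scores.

## Normalised Expression Score

Spectral counts (SC: spectra mapping onto a peptide) proxy abundance but
are not comparable across repertoires of different depth. The NES
rescales them by the sample's total peptide number with a fixed factor of
1000 so values read at two decimals:

$$\mathrm{NES}_{cmp} = \frac{SC \times 1000}{n_{peptide}}, \qquad
  \mathrm{NES}_{ref} = \frac{SC \times 1000}{n_{peptide}}
  \times \frac{s_1}{s_2}$$

where $s_1/s_2$ (reference total / comparison total) corrects the
reference sample for overestimation due to its smaller denominator.
Algebraically, with $s_1$ equal to the reference sample's own
$n_{peptide}$, both samples end up sharing the comparison sample's
denominator, so the log2 fold change $\log_2(\mathrm{NES}_{cmp} /
\mathrm{NES}_{ref})$ reduces to $\log_2(SC_{cmp}/SC_{ref})$ — a property
the test suite checks numerically.

Fold-change classes use 1.5-fold up ($\log_2 = 0.58$) and 0.5-fold down
($\log_2 = -1$) cut-offs, both boundaries inclusive (the internal
up-cut-off is the exact $\log_2 1.5 = 0.58496\ldots$; reports print
0.58). Zero-reference fold changes cannot arise for a shared set defined
by presence in both samples, but are defensively classed
`"comparison-only"` and excluded from the three-way tally with a
warning.

Protein-level grouping sums member-peptide spectra per sample as a total
measure of protein expression and re-applies the same NES and cut-offs.
A peptide mapping to several proteins contributes its full counts to
each by default; `multimap = "split"` divides counts evenly instead.

## Neoantigen search

`build_mutated_proteome()` converts a variant file plus gene models (GTF
CDS intervals and CDS sequences in transcript orientation) into mutated
protein sequences: variants are mapped into spliced-CDS coordinates
(minus-strand alleles reverse-complemented), reference-checked against
the CDS, and applied on a single haplotype in 5'→3' transcript order —
an unphased bulk variant file carries no phase, so one haplotype is the
only defensible construction. SNVs substitute; in-frame indels add or
remove codons; frameshifts are translated in the new frame to the first
stop with every downstream residue counted as altered. Start-loss and
pure truncations are flagged rather than emitted as searchable mutants.
Splice-site disruption is out of scope: variants are applied in CDS
space after concatenating CDS intervals.

`append_decoys()` produces the standard reversed-sequence decoy database
(prefix `rev_`) for downstream FDR-controlled searching; a user-supplied
contaminant FASTA can be concatenated to the targets beforehand.

`find_mutant_peptides()` then reports identified peptides occurring
verbatim in a mutated protein at an interval covering at least one
altered residue. Peptides matching only unaltered stretches are not
evidence of a mutation, and peptides that also occur in a reference
translation are excluded by default for the same reason
(`exclude_reference_matches = FALSE` disables this).

## The synthetic-data generator

The generator exists so that every stage runs and is testable without
any external download; its defaults are fixed at the study conditions
the pipeline was built to characterise, not tuned per analysis:
reference and comparison repertoires of 144 and 613 peptides sharing 82;
a comparison sample with 53.5% 8-mers and a 53.3% C-terminal-leucine
frequency against a longer-tailed reference (37.5% 8-mers); a 40%
strong-binder fraction for the comparison sample; and a shared set
carrying 58 planted up- and 6 down-regulated peptides (4-fold, i.e.
|log2| = 2, a representative strong effect chosen once) mapping onto 61
proteins. Spectral counts follow a gamma-Poisson (negative-binomial-like)
law, `1 + Poisson(base)` with a gamma base of mean 20 and shape 10 shared
between the two samples for each shared peptide — the shared base makes
paired counts correlated, as repeated measurements of one peptide are,
and the +1 guarantees every identified peptide at least one spectrum.

Peptide sequences are sampled residue-wise (configurable length,
C-terminal and internal residue laws) with no homology structure; that
is adequate for set arithmetic and statistics but carries no binding
motifs, so passing tests demonstrate correctness of the computations,
not motif-level realism of real eluted ligand data. Rank tables are
drawn directly from the configured binder fractions rather than from a
predictor. The toy genome is 4 transcripts of 30–60 codons (one on the
minus strand, one split across two exons) with non-synonymous SNVs and
an in-frame codon deletion planted at construction-known positions at
least 10 codons apart, so each spiked peptide window is unaffected by
the other variants.

## Numerical choices and problem sizes

Determinism: every generator is a pure function of its configuration and
seed; the permutation test restores the caller's RNG state, so embedding
it in a larger simulation does not perturb the outer stream. Exhaustive
enumeration replaces sampling automatically whenever the number of
distinct relabelings fits the permutation budget. Floating-point
comparison of permutation statistics uses a 1e-12 slack so ties count as
reaching the observed value.

The test suite and the acceptance script run the full synthetic study at
its native size (144/613 peptides, 82 shared) and the statistical
property checks at reduced sizes chosen to estimate each property
stably: 1000 replicate null tests at 200 permutations for the type-I
error of the sampled test, 20 seeds of a 100-shared-peptide pair with 30
planted effects for fold-change recovery, and 10 randomized fixtures for
the set-theoretic and bounds invariants.

## Known limitations

* The table-union consolidation of multi-engine searches is a documented
  simplification; engine-specific output dialects are not parsed.
* Predictor output is consumed, never produced: no neural-network
  affinity model is run, and eluted-ligand vs binding-affinity modes are
  not distinguished.
* Expression analysis is spectral-count based; intensity-based
  quantification and missing-value imputation are out of scope.
* The neoantigen stage ignores phasing, splice-site effects,
  selenocysteine and stop-codon readthrough.
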