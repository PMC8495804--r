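---
title: "Methods: comparative molecular evolution of farmed and wild foxes"
author: "farmfox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative molecular evolution of farmed and wild foxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

farmfox compares the protein-coding repertoires of two farmed fox
species — the blue fox (BF, a farmed form of the arctic fox AF) and
the silver fox (SF, a farmed form of the red fox RF) — with their wild
progenitors, to locate genes whose coding sequences may have responded
to domestication. The package implements the full analysis chain:
CDS recovery and length filtering, single-copy ortholog pairing,
codon-aware alignment, counting-based Ka/Ks estimation with positive
selection calls, a conservation-panel screen for lineage-exclusive
amino-acid substitutions, microsatellite discovery, term enrichment,
and a concatenated-ortholog phylogeny. A synthetic-data module
generates every input under a fixed seed, so the whole chain is
testable end to end without any sequencing data.

This vignette documents the models, the defaults and why they were
chosen, the numerical conventions, and what the synthetic fixtures do
and do not demonstrate.

## CDS recovery

Assembled transcripts ("unigenes") carry untranslated flanks.
`find_longest_orf()` performs a six-frame search for the longest
ATG-initiated open reading frame; the returned CDS excludes the
terminal stop, and an ORF may end at the sequence end without a stop
(transcriptome fragments are routinely truncated), recorded in
`has_stop`. Ties between equally long ORFs resolve deterministically:
plus strand before minus, then leftmost. Codons containing the
ambiguity code N translate to `X` and are excluded from all downstream
counting.

The retention rule is `length >= 300` nt. A strict reading of "longer
than 300" would be 301, but with codon-multiple ORF lengths the two
conventions differ only for a length-300 ORF, and the inclusive
boundary matches the usual practice of quoting a 100-codon minimum.
The boundary is a parameter (`min_len_nt`) for users who want the
strict form. Stop-to-stop ORFs without an ATG are accepted only behind
`allow_no_atg = TRUE` (default off): coding-potential predictors can
recover start-less fragments, but a longest-ORF extractor that
accepted them by default would inflate spurious antisense calls.

## Ortholog pairing

Single-copy orthologs between a wild and a farmed taxon are recovered
by reciprocal best hit (RBH) over global protein alignments
(Needleman–Wunsch, BLOSUM62, affine gaps with opening 10 and
extension 0.5 — conventional protein-scoring defaults). A pair is kept
only when each member is the unique top hit of the other and both
alignment coverages reach `min_coverage` (default 0.5, half of each
protein aligned — permissive enough for fragmentary transcriptome
CDSs, strict enough to reject domain-only matches). An equal-top-score
tie *excludes* the gene rather than picking a winner: a tie is exactly
the signature of a recent duplicate, and the downstream analyses are
only valid for single-copy genes. Four-taxon quartets join an AF–BF
pair and an RF–SF pair through a cross-group RBH between the AF and RF
members, giving the set of genes shared by both comparisons.

RBH replaces all-vs-all clustering (OrthoMCL-style) deliberately:
the single-copy orthologs that the analyses keep are precisely the
pairs RBH recovers, and no external alignment binary is needed.

## Ka/Ks estimation

Selection pressure on each ortholog pair is summarised by
$\omega = K_a/K_s$, the ratio of nonsynonymous substitutions per
nonsynonymous site to synonymous substitutions per synonymous site,
estimated with the Nei–Gojobori (1986) counting method:

* **Sites.** For each codon position, the synonymous fraction is the
  number of synonymous single-nucleotide neighbours divided by the
  number of non-stop neighbours (renormalising over non-stop
  neighbours is the MEGA convention). Each sense codon contributes
  exactly 3 sites; per-gene N and S are averaged over the two
  sequences.
* **Differences.** Codons differing at $d$ positions are scored by
  averaging synonymous/nonsynonymous step counts over all $d!$
  orderings of the changes, excluding any pathway that passes through
  a stop codon. All pathways are weighted equally (classic NG86; no
  transition/transversion weighting).
* **Correction.** $K_a = \mathrm{JC}(N_d/N)$ and
  $K_s = \mathrm{JC}(S_d/S)$ with the Jukes–Cantor map
  $d = -\tfrac34\ln(1-\tfrac43 p)$; $p \ge 0.75$ is reported as
  saturated (`NA`), not an error.

Pairs are aligned codon-aware: the proteins are aligned globally and
the gap pattern is back-translated, so gaps always occupy whole
codons; columns with a gap, an N, or a stop in either row are excluded
pairwise. $\omega > 1$ is flagged `positive`, $\omega < 1$
`purifying`. When $K_s = 0$ the ratio is reported as undefined rather
than infinite — such genes are listed with an explanatory note, since
a ranking by finite $\omega$ values cannot place them.

A counting estimator was chosen over maximum-likelihood codon models:
it is deterministic, dependency-free, exhaustively checkable against
enumeration over the 61 sense codons, and estimates the same $\omega$
statistic. Estimates will differ from codeml-style ML on real data
(no rate-matrix modelling, no ts/tv correction); that divergence is
expected and documented, not a defect.

## Lineage-exclusive substitution screen

The screen asks, per amino-acid column of a multi-mammal panel
alignment: does a focal group carry a residue found in *no* other
taxon, while all remaining taxa are invariant? Three categories are
reported: `shared_farmed` (BF and SF share the derived residue),
`farmed_species_specific` (exactly one farmed taxon), and
`wild_specific` (AF and RF). Both directions are screened because, as
printed, one of the three reference sites is a *wild*-exclusive
residue — a farmed-only screen would miss it.

Strict invariance of all non-focal taxa is the default
(`max_mismatch = 0`); a tolerance of up to *k* deviating panel taxa
can be enabled, but a fox taxon outside the focal set must always
match the background exactly — tolerance exists for distant panel
species, not for the comparison animals themselves. Gapped and
ambiguous columns are skipped rather than counted as differences,
since absence of data is not evidence of substitution. The filter is
monotone: adding panel taxa can only remove flagged sites, never add
them.

Nucleotide positions are reported 1-based relative to the CDS start.
When codon data are available the reported `nt_site` is the single
differing nucleotide within the codon (`3(i-1) + p` for codon `i`,
position `p`); codons differing at several nucleotides report the
first differing position and are flagged `multi_nt`.

The three reference substitutions used throughout the tests are the
worked examples of the study this pipeline emulates: W→R at CDS site
235 (codon 79, TGG→AGG) exclusive to the wild pair, L→Q at site 527
(codon 176, CTA→CAA) and K→N at site 153 (codon 51, AAG→AAC) each
exclusive to the silver fox. The published text gives the L→Q
nucleotide change in the opposite direction (A→T at a second codon
position), which cannot produce L→Q; the package follows the
figure-level description (the silver fox carries Q), and the
inconsistency is simply noted here.

## Microsatellites

`detect_ssrs()` reports every maximal perfect tandem repeat with unit
size 1–6 whose complete-unit copy number reaches its threshold.
Defaults are the MISA defaults — minimum 10 copies (mono), 6 (di), 5
(tri–hexa) — because the emulated workflow names MISA without printing
a parameter set; everything is configurable. Only perfect repeats are
considered. A repeat whose unit is itself periodic (ACAC) is reported
at its smallest period only, and coordinates cover complete units.
Motifs are additionally reported in canonical form (lexicographic
minimum over rotations; joint canonicalisation over both strands is
available behind a flag, default off, so that reported motif classes
match single-strand MISA output). Consecutive loci separated by at
most 100 nt (configurable) share a compound id.

Primer feasibility replaces thermodynamic design with placement
arithmetic: a locus is feasible when 18–22 nt windows exist on both
flanks such that the product (inclusive of primers) spans 100–400 bp;
candidate window pairs are ranked by closeness of their GC content to
50% and up to three are returned. This is a screening stand-in, not a
primer designer; melting temperature, dimers and hairpins are out of
scope.

## Enrichment

Term enrichment uses the upper-tail hypergeometric probability of
observing at least $k$ study genes in a term of size $K$, drawing $n$
genes from a population of $N$. This is the single statistic to which
the usual over-representation tools reduce; their differences on real
data come from databases and background choices, not the test. The
default background is every gene in the supplied annotation,
overridable. Raw p-values are reported (matching how such tables are
usually printed); Benjamini–Hochberg adjustment is available as
`bh_adjust()` and no significance cutoff is imposed.

## Phylogeny

Per-gene quartet alignments are concatenated into a supermatrix with
recorded partitions; pairwise p-distances use pairwise deletion of
gapped/ambiguous columns; the tree is neighbor-joining, which on
additive matrices recovers the generating topology exactly — that
property, over 20 random additive fixtures plus the fox topology with
an outgroup, is the correctness check. Bootstrap support resamples
columns with replacement, rebuilds, and maps bipartition frequencies
as percentages onto the full-data tree; rooting on a designated
outgroup is optional. Distance-NJ was chosen over parsimony or ML
because the emulated study does not pin down its tree criterion, and
NJ is deterministic and oracle-checkable.

## Synthetic data: what it emulates and what it does not

`generate_study()` builds the complete input tree: per-taxon CDS
FASTAs for AF/BF and RF/SF ortholog quartets, 13-taxon conservation
panels (the four foxes plus nine panel mammals), unigenes with planted
SSRs, an annotation map, and TSV truth tables for all of it.

Sequence evolution uses an acceptance–ratio scheme: each event
proposes a uniform single-nucleotide change at a uniform site
(sparing the start codon), rejects proposals that create stops, and
accepts synonymous proposals with probability $\min(1, 1/\omega)$ and
nonsynonymous with $\min(1, \omega)$. The realised
nonsynonymous:synonymous substitution ratio therefore scales with
$\omega$ relative to the neutral site ratio, which is exactly what a
counting estimator measures. This is deliberately *not* a full codon
rate matrix (GY94): it is sufficient for estimator recovery, trivially
seedable, and makes no claim to match ML codon-model expectations.
Each ortholog pair evolves as two independent lineages from one
ancestor (star topology), so pairwise divergence is the sum of two
lineages — and, as a consequence, the four-taxon synthetic tree has a
true internal branch of zero; internal bootstrap values on synthetic
studies are expected to be weak, and topology recovery is instead
validated on additive-distance fixtures.

Default study conditions: 30 genes of 300 codons, 120 proposal events
per lineage (≈4–8% pairwise protein divergence, a plausible scale for
intra-genus comparisons while keeping counting statistics
informative), background $\omega = 0.2$ (typical purifying pressure on
mammalian orthologs) with 3 genes at $\omega = 3$; base composition is
uniform over sense codons. Estimator-recovery simulations use 500
codons and 200 events per lineage over 50 replicates, sizes at which
the counting estimator's sampling spread is narrow enough for banded
assertions (mean recovery of $\omega = 0.2$ within ±30%; positive
calls in ≥90% of $\omega = 3$ replicates).

Planted SSR fixtures use repeat-free random backgrounds (rejection
sampling against a regex scan) and break the single nucleotide on each
side of a planted tract so the planted locus is maximal and exactly
recoverable; `plant_ssr()` itself never touches flanks.

What passing on synthetic data does **not** show: performance on real
assemblies (fragmentation, chimerism, allelic redundancy), robustness
of RBH under paralogy, counting-estimator agreement with ML on real
divergence patterns, or conservation-panel behaviour under real
alignment error. The fixtures validate the *logic* of every stage and
the exact reconstruction of the three reference substitution sites;
they do not validate assembly- or database-dependent headline counts,
which are intrinsically tied to the original sequencing data.

## Reproducibility

Every random choice flows from an integer seed: fixture generation is
byte-identical under a repeated seed, and `run_all()` writes a bundle
(plain TSV plus Newick) that is byte-identical across reruns — run
logs record parameters and counts, never wall-clock time. The numbered
scripts under `analysis/` execute the whole chain on a synthetic
study and check every stage against its truth table as they go.
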