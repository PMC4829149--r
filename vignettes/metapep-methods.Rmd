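---
title: "Methods: peptide-centred metaproteome profiling with metapep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide-centred metaproteome profiling with metapep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapep)
```

## Scope and model

`metapep` analyses shotgun metaproteomics of gut (faecal) samples at the
peptide level. The quantitative unit everywhere is the **spectral count**:
the number of fragmentation spectra matched to an identified peptide, a
standard proxy for protein abundance. Because peptide-to-protein inference
is ambiguous in community samples, all comparisons are made per functional
class (KEGG Orthology group, COG, COG family) or per taxon — never per
protein. The package starts from identified-peptide tables; peptide-spectrum
matching, FDR filtering of identifications, and the BLAST/MEGAN-style
generation of KO/COG annotation maps are upstream and out of scope.

## Taxonomic assignment (LCA)

A peptide's origin is the **lowest common ancestor** (LCA) of all taxa whose
proteomes contain it exactly. Three conventions matter:

* **I/L equating.** Isoleucine and leucine are isobaric and
  indistinguishable by MS/MS, so every `I` becomes `L` before matching —
  identically for query peptides and for map keys. `normalize_peptide()` is
  idempotent; validation accepts the 20 standard residues plus the rare
  translated residues U and O.
* **Missed-cleavage combining.** A peptide with internal K/R sites (not
  followed by P) is split into its fully tryptic fragments
  (`tryptic_fragments()`); each fragment is matched separately and the
  results combined. The default combines by **intersection** with an
  all-fragments-must-match rule — the conservative reading: a peptide is
  only as specific as every one of its constituent fragments, and a
  fragment with no match at all leaves the peptide unassigned.
  `combine = "union"` is available for a permissive reading.
* **Domain partitioning.** The domain class of a peptide is the
  domain-rank ancestor of its LCA. A peptide matched in two or more
  domains has its LCA at or above the domain level and is reported
  `ambiguous`; a peptide with no (or an empty) match set is `unassigned`.
  Per-sample domain percentages are computed over assigned peptides only,
  so bacterial + archaeal + eukaryotic + ambiguous sums to 100. Both
  peptide-weighted (default, for the domain split) and spectrum-weighted
  (for abundance work) variants exist because the weighting used for the
  published domain split is not stated.

Host peptides are selected as those with *at least* a Chordata-level
assignment (`chordata_subset()`): Chordata or a descendant. Requiring
species-level human assignments would discard most host peptides, since
homologous chordate sequences are near-identical; conversely an LCA above
Chordata (e.g. Eukaryota) is not specific enough.

## Functional profiles and filters

`aggregate_profile()` sums spectra per feature per sample. A peptide
mapping to more than one KO contributes its full count to each by default
(winner-set style); `share = "fractional"` splits the count so that mass is
conserved exactly. An explicit `unassigned` row carries spectra with no
mapping at the chosen level, making per-sample accounting auditable. At a
taxonomic rank r, a peptide contributes only if its LCA is at or below r —
a peptide resolved only to a domain contributes to no phylum. Restricted
profiles (`restrict_taxon =`) keep only peptides whose LCA falls inside one
clade, e.g. the KO profile of *Faecalibacterium prausnitzii*.

The abundance filter retains a feature iff its count reaches a bar in at
least one sample (`abundance_filter()`); the conventional bars are 5
spectra for bacterial KOs and 2 for human KOs. Relative percentages of a
filtered matrix are computed over the retained features (post-filter
denominators, matching how filtered-KO heatmap scales are reported).

## Gut metabolic modules

A gut metabolic module (GMM) describes a metabolic capability as
alternative pathways of ordered steps, each step a set of interchangeable
KOs. `score_module()` collapses within-step alternatives by `max` (counting
raw KOs would double-count interchangeable enzymes), defines step coverage
as the fraction of steps with positive abundance, picks the
maximum-coverage pathway (ties: higher median abundance, then lower index,
for determinism), and calls the module **detected iff coverage strictly
exceeds 2/3**; coverage of exactly 2/3 is not detected. Module abundance is
the median of the best pathway's step abundances — zeros included, since
the definition of "median KO abundance in the maximum coverage pathway"
does not exclude undetected steps — and 0 when undetected. These two
readings (step-level coverage; zeros in the median) are the principal
interpretive decisions of the module and are pinned by an exhaustive
enumeration oracle in the tests.

## Rarefaction of accumulated and core functions

All samples of a subject are pooled (a KO is "present" if it has a positive
count in any of the subject's samples, on the **unfiltered** KO matrix). At
each interval n, 1000 bootstrap draws of n subjects are taken **without
replacement** — the stated "all possible combinations" language implies
combination sampling, not resampling — and the accumulation (union) and
core (intersection) counts recorded. Endpoints are exact identities: at
n = 1 both statistics equal the drawn subject's set size; at n = K every
replicate equals the global union and intersection.

## Comparative statistics

* **Peptide clustering**: presence/absence Jaccard distance
  (1 − |A∩B|/|A∪B|) with complete linkage; samples are ordered
  lexicographically first so ties break deterministically.
* **Profile clustering**: 1 − Pearson r between sample columns, complete
  linkage; used for 16S oligoprofiles and KO abundance matrices (the
  distance for the latter is not stated in the source analyses; 1 − r is
  chosen for consistency).
* **Human × bacterial correlation screen**: Spearman rho with mid-rank
  ties over every pair, two-sided p (t approximation for n ≥ 10, exact
  permutation enumeration below), and q-values over the full family.
  Benjamini–Hochberg is the default q-value method (dependency-free,
  conservative); a Storey-style pi0-smoothed variant is available. The hit
  list requires p < 0.05 and q < 0.05; the full table is always emitted.
* **Bacterial/eukaryotic ratio group test**: per-sample ratio of bacterial
  to eukaryotic spectral counts; per-subject time-course trajectories are
  correlated (Pearson), cut into 2 clusters under complete linkage, and the
  2×2 cluster-by-group table tested with a two-sided Fisher exact test
  (exact hypergeometric enumeration, conventional 1 + 1e-7 tie tolerance).
  The cut-at-2 construction is not fully specified in the source analyses
  and is documented here as this package's choice, as is the paired
  two-sided Wilcoxon signed-rank test of TP1-vs-TP2 ratios within the
  probiotic group (the "stringent statistical analysis" is unnamed
  upstream).
* **Shannon diversity**: H = −Σ p ln p on renormalised proportions, zero
  terms dropped.
* **Platform concordance**: per-phylum Pearson r between proteome and 16S
  relative abundances across shared samples (phyla matched by name; a
  phylum present on one platform only is excluded with a warning), with BH
  q-values across phyla and a median/quartile table per phylum per
  platform for split-violin display.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` produces the full input bundle offline. The stated
world (defaults of `generator_config()`): 16 subjects × 3 time points,
8/8 placebo/probiotic with a **null** probiotic effect; 300 bacterial KOs
(the real catalogue of 967 scaled to desk size) of which 100 form a common
core, plus 40 subject-core KOs each; 73 human KOs; 4000 spectra per sample
(exactly, by multinomial construction); 14% eukaryotic, 0.5% archaeal and
1% ambiguous spectra among the taxonomically assigned, and 5% with no
taxonomic match. Personalisation follows a Dirichlet–multinomial
hierarchy: one profile per subject drawn around the common base
(concentration 200 — moderate, chosen so common-core KOs rarely drop out
of a subject entirely), reused across time points under multiplicative
log-normal noise (sd 0.3). Subjects additionally express subject-specific
peptide repertoires (each of a KO's 8 peptides retained with probability
0.6 per subject), which is what makes peptide-level Jaccard clustering
subject-wise. A quarter of bacterial peptides are taxonomically degenerate
(shared within or across phyla) and a tenth are emitted as two-fragment
missed-cleavage forms to exercise the LCA machinery; about 30% of peptide
strings display one L as I. The matched 16S table covers 44 of the 48
samples with a planted log-scale cross-platform correlation of 0.7; the
percent-scale renormalisation attenuates the realised Pearson r slightly,
which the CI-based recovery check absorbs.

What the generator does **not** emulate: real proteome digests (peptides
are random tryptic words), identification FDR, chromatography or spectral
noise, HITChip probe chemistry, or compositional coupling between the
taxonomic and functional layers beyond what the KO→taxon assignment
induces. A green downstream test therefore establishes correctness of the
computation on data with the assumed statistical structure — not
biological validity on real spectra, and not robustness to search-engine
artefacts.

## Numerical choices and degenerate inputs

Percent matrices must sum to 100 per sample within 1e-9. Zero-total sample
columns, empty peptide sets, zero-variance columns (for Pearson distances)
and all-zero abundance vectors (Shannon) are errors naming the offending
sample, not silent drops. A taxon set that is empty after fragment
intersection yields `unassigned`, not an error — expected for chimeric or
degenerate peptides. A sample with zero eukaryotic spectra makes the
bacterial/eukaryotic ratio undefined; the error advises a pseudocount
rather than silently substituting one. Fisher exact p-values use the
conventional relative tie tolerance of 1e-7; seeds are consumed only
through R's RNG so every stochastic routine is reproducible from its
`seed` argument.

## Known limitations

Single-threaded; the LCA loop is O(peptides × tree depth) which is ample
at desk scale but would want memoisation for million-peptide inputs.
Storey's pi0 smoother uses a fixed lambda grid. The CLI's `report`
subcommand emits basic plots (dendrogram, split violins) rather than
publication figures. The rarefaction endpoint counts depend on the real
data's richness and are treated as qualitative shape expectations only.
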