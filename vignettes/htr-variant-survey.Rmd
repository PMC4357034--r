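---
title: "Methods: surveying histone H3 variants with htrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying histone H3 variants with htrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htrscan)
```

This vignette documents the models, parameter choices and deliberate
simplifications behind each stage of the HTR (histone three related) gene
survey. It is the place where design decisions that were genuinely open are
argued; the README shows the surface-level usage.

## Coordinate conventions

Canonical histone numbering is 1-based on the *mature* protein, initiator
Met excluded — the frame in which K4/K9/K27/K36 and the signature positions
31/41/87/90 are universally quoted. Whether a candidate protein retains its
Met is detected during mapping (residue 1 = M aligned immediately upstream
of canonical 1) and the Met is excluded from the N-terminal overhang count.
Genomic coordinates are 1-based inclusive on disk (the GFF3 convention) and
0-based half-open on in-memory gene models; `read_gff3_gene_models()` is
the only conversion point, which keeps off-by-one drift out of the rest of
the code. Intron counts are taken within the CDS only (UTR introns
ignored): the classification criterion concerns the coding gene structure.
Where a gene has several transcripts, the one with the longest total CDS
represents the gene (ties broken by smallest transcript id), mirroring the
removal of predicted alternative splice variants from such surveys.

## Homology scan

The scan runs exact Smith–Waterman local alignment (BLOSUM62, gap open 11,
extend 1 — gapped-BLAST's defaults) of every proteome sequence against the
seed queries, converts scores to e-values with the Karlin–Altschul formula
`E = K · m · n · exp(-lambda · S)` using the standard gapped constants
lambda = 0.267, K = 0.041, and admits hits with `E < 1e-10`. `n` is the
residue total of the *scanned proteome* (per-genome, not cross-species).
Accepted hits join the query set and the scan repeats until a fixpoint, so
divergent family members reachable only through intermediate homologs are
still found; the query set is bounded by the proteome, so termination is
guaranteed. Alignment is exhaustive rather than heuristically seeded —
proteomes at desk scale do not need k-mer prefilters. Six-frame genome
search (the TBLASTN role) is out of scope: input is an annotated proteome.

Three filters then emulate the survey's cleanup. Byte-identical CDS
sequences collapse to the lexicographically smallest gene id (nucleic-acid
redundancy); candidates sharing a gene locus collapse to the locus
representative (isoforms); and candidates whose best alignment covers less
than 80% of the query's histone-fold span are marked incomplete. No
quantitative definition of "incomplete" exists in the survey literature, so
coverage of the fold is used: the fold is taken as query positions 40 to
the C-terminus, since the N-terminal tail is legitimately absent in several
real variant classes and must not count against a candidate.

## Alignment and position mapping

Pairwise alignments are Needleman–Wunsch global with penalized end gaps
(same scoring as the scan). The multiple aligner is classical progressive
alignment: a neighbor-joining guide tree on pairwise p-distances, then
profile–profile merges with sum-of-pairs BLOSUM62 scoring and affine gaps,
ties broken deterministically (diagonal over gap-in-second over
gap-in-first). This replaces the G-INS-i + manual-editing workflow of the
original survey with a reproducible, dependency-free procedure; iterative
consistency refinement is deliberately omitted. H3 families are short
(~135 aa) and highly conserved, where progressive alignment is adequate.

`map_to_reference()` aligns a candidate to the canonical reference and
records, for every canonical position, the candidate residue index (or a
gap). Two derived quantities drive CenH3 detection. The *N-terminal
overhang* is the number of candidate residues upstream of canonical 1; when
the candidate's tail is highly divergent the optimal alignment sometimes
absorbs tail residues against the reference's own N-terminus instead of
leaving them upstream, so the overhang is computed as the maximum of the
direct count and the candidate-index surplus at the last mapped position —
a measure invariant to where the aligner placed the gaps. The *core
identity* is the identity to the reference over canonical 45–135 (gaps
count as mismatches). Candidates mapping fewer than 20 reference positions
are rejected as unmappable.

The bundled reference (`inst/extdata/synthetic_h3_reference.faa`) is a
*synthetic* stand-in generated by `make_reference()`: a random protein with
lysines pinned at 4/9/27/36 and T/Y/H/L at 31/41/87/90. It keeps any real
biological sequence out of the package's ground truth and is meant to be
overridden with a curated mature H3.3 when analysing real genomes.

## Classification rules

The decision procedure is total and ordered:

1. any CenH3 evidence → `CENH3`;
2. A31 F41 S87 A90 and 0 introns → `H3_1`;
3. T31 Y41 H87 L90 and ≥1 intron → `H3_3`;
4. A31 Y41 (S|Q)87 L90 and 0 introns → `H3_1A`;
5. otherwise `H3_LIKE`.

CenH3 evidence outranks signatures because a divergent CenH3 can
accidentally present signature-like residues through alignment gaps, while
clade membership and the tail are positive evidence. A recognized signature
whose intron state contradicts it yields `H3_LIKE` with an explicit
`signature_intron_conflict` flag rather than trusting either source. When
gene models are absent the signature rules run alone (flag
`signature_only`, confidence `medium`) — annotations without intron
information are common. `H3_1A` is assigned wherever its signature and
intronlessness hold: its restriction to nonflowering plants is treated as
an observation about lineages, not a classification rule. The animal
H3.1/H3.3 signatures (A31-S87-V89-M90 vs S31-A87-I89-G90) are available as
an alternative rule set (`ruleset = "animal"`), default off.

CenH3 evidence itself has no quantitative definition in the survey
literature; the package's defaults are an N-terminal overhang of ≥15
residues *and* core identity < 0.75 for the tail heuristic, and bootstrap
support ≥ 70 for the anchored-clade test (the smallest supported
bipartition containing all anchors, required to exclude every known
H3.1/H3.3). All three thresholds are exposed in `cenh3_params()`.

Confidence levels: `high` = signature and intron agree (or CenH3 evidence),
`medium` = signature only, `low` = H3-like by elimination.

## Phylogeny

Distances use pairwise deletion (columns gapped in either member of a pair
are skipped for that pair only) with Poisson correction `d = -ln(1-p)` or
gamma correction `d = alpha((1-p)^(-1/alpha)-1)`, default alpha 1.0. The
JTT+G model used by the original survey is substituted by these corrections:
implementing the JTT exchangeability matrix is out of proportion for a
survey tool, and at histone-level divergences the corrections agree
closely. Maximum-likelihood phylogeny and substitution-model selection are
out of scope entirely — because all-HTR trees have notoriously weak support,
the tree is used only for anchored CenH3 clade detection, which is exactly
the part that is robust.

Neighbor joining is the Saitou–Nei algorithm with deterministic tie-breaks
(smallest index pair) and a conservative treatment of negative branch
lengths: clamped to zero with the deficit moved to the sibling branch, so
path lengths — and therefore exactness on additive matrices — are
preserved. Bootstrap resamples alignment columns with replacement under a
seeded RNG; replicates whose distances saturate are skipped and counted,
and the skip rate is reported. Supports are `100 × bipartition frequency`
across replicate trees.

## Selection analysis

The original survey fitted codon models in HyPhy (global fits over 203 GTR
variants, plus a per-site rate estimator). The package substitutes
fully-implemented counting estimators — the central methodological
substitution of this artifact:

* **Global dN/dS** is Nei–Gojobori (1986): synonymous site counts per codon
  are the expected fraction of synonymous single-nucleotide changes (stop
  targets excluded with renormalization, so sites always sum to 3 per
  codon); observed differences are averaged over all substitution pathways
  between codon pairs, pathways through stop codons excluded with weight
  renormalization (one of the two standard conventions; chosen for
  determinism). Proportions are Jukes–Cantor corrected, pairs with
  p ≥ 3/4 raise a "saturated" error (or return `NA` counts on request),
  and the group estimate is the mean over all unordered pairs.
* **Per-site test** is SLAC-style: ancestral codons by Fitch parsimony on
  the tree (ties resolved lexicographically, so reconstruction is
  reproducible), per-branch synonymous/nonsynonymous changes summed per
  site with the same pathway averaging, and two one-sided binomial tests of
  the observed synonymous share against the site's expected synonymous
  fraction. Because NG86 counts are fractional, the binomial tails are
  computed through the regularized incomplete beta, which is exactly the
  binomial tail at integer counts. A site is `negative` at
  `p_negative < 0.05` (raw p, matching how such surveys report "P < 0.05";
  Benjamini–Hochberg q-values are reported alongside for users who prefer
  FDR control).

Counting methods are conservative at high divergence (parsimony undercounts
multiple hits) and have limited per-site power on small trees; they trade a
little power for complete transparency and testability against brute-force
enumeration. ML codon models (GY94/MG94), branch-site tests and
recombination handling are out of scope.

## Expression analysis

Input matrices are linear-scale, genes × tissues. Genes never reaching the
detection floor (default 1.0) are set aside as not-detected — reported,
never auto-interpreted (they *may* be pseudogenes). Remaining values are
`log2(x+1)`-transformed and median-centered per gene; clustering is average
linkage on `1 − Pearson` distance, the canonical settings of the classic
Cluster 3.0 workflow, whose exact parameters the original survey did not
state. Archetype calls work on the raw linear rows: coefficient of
variation < 0.25 → `constitutive`; mean log2 difference
(dividing − differentiated tissues) > 1.0 → `dividing_high`; otherwise
`heterogeneous`. The dividing/differentiated partition is user-supplied
(roots, stem, seed, embryo vs leaves, endosperm in the grass surveys).

## The synthetic-data generators

`synth_genome()` encodes the class definitions as generative truth: per
class the signature residues and intron plan are planted
(H3.1 A/F/S/A + 0 introns; H3.3 T/Y/H/L + 1–2; H3.1A A/Y/(S|Q)/L + 0;
CenH3 an extended N-tail over an elevated-divergence core; H3-like at least
one signature residue outside both consensuses and/or a truncated N-tail),
a 2% background substitution rate applies outside the protected positions
(4/9/27/31/36/41/87/90), and 20 random decoy proteins fail the homology
threshold. Default counts are 4 genes per class. Two realism choices
deserve note:

* CenH3 genes descend from a *common* diverged ancestor (40% core
  divergence, 25-residue tail) rather than being independently diverged —
  real CenH3s share ancestry, and without it no tree could contain a CenH3
  clade to detect.
* Coding sequences within a genome share descent from one reference CDS,
  with a 10% synonymous churn where the amino acid is unchanged and uniform
  random codons where it differs. Fully independent synonymous codon draws
  would place every paralog pair beyond Jukes–Cantor saturation at
  synonymous sites, which no real gene family shows. Codon *choices* remain
  uniform among synonymous options — codon-usage bias is irrelevant to the
  counting estimators and is not modelled.

What the genome generator does **not** emulate: realistic intron sequence
content or lengths (introns are fixed 80 bp placeholders), intergenic
sequence, gene birth–death histories, or annotation errors. Passing tests
on synthetic genomes therefore demonstrate the pipeline's logic, not its
robustness to messy annotations.

`evolve_codons()` is a continuous-time Gillespie simulation over sense
codons: single-nucleotide changes only, transitions weighted kappa
(default 2), nonsynonymous changes weighted omega, stop codons forbidden,
rates normalized so one unit of branch length is one expected substitution
per codon site at the ancestor's composition. It drives the estimator
recovery tests (omega 0.1/0.5/1.0, 200 codons, pairwise divergence 0.3, 100
replicates — recovery within ±20%) and the per-site power checks.

`synth_expression()` plants constitutive (flat + noise), dividing-high
(+2 log2 in dividing tissues), differentiated-high (the mirror profile —
the seed/embryo/endosperm-high pattern seen in real grass HTR families),
heterogeneous (random tissue effects) and not-detected genes, at noise sd
0.2 on the log2 scale over an eight-tissue panel. The clustering
separation check uses the two anti-correlated archetypes: after per-gene
centering a flat profile is pure noise and *cannot* correlate with
anything, so constitutive genes are validated through the archetype caller
rather than through cluster membership.

## Problem sizes and determinism

The shipped tests and the acceptance script run, per invocation: one
40-gene genome scan with 100 bootstrap replicates; 300 simulated codon
pairs of 200 codons; two 10-taxon × 135-codon site-selection analyses on a
tree of total length 6 expected substitutions per codon site (long enough
that variable sites carry the ≥3 changes a counting test needs for
significance at alpha 0.05); 50 NJ exactness replicates; and a 12-taxon ×
200-replicate bootstrap. These sizes were chosen as the smallest at which
the statistical claims are comfortably identifiable.

Every stochastic component takes an explicit seed, restores the caller's
RNG state, and is reproducible bit-for-bit; ties in NJ joins, Fitch
reconstruction, traceback and report ordering are all broken
deterministically, so a pipeline run is a pure function of (inputs, config,
seed).

## Known limitations

* Scores-only Karlin–Altschul e-values use fixed gapped-BLAST constants
  rather than per-query estimated parameters; e-values are therefore
  approximate (the relative ranking, which drives the threshold, is exact).
* Progressive alignment without refinement can misplace gaps in the
  fast-evolving CenH3 tail; the overhang measure is designed to be robust
  to this, but per-column tail alignments should not be over-interpreted.
* Counting-based selection estimates are downward-biased at high divergence
  and the per-site test has low power on few taxa; both favor false
  negatives over false positives for the purifying-selection claim.
* Only CDS-resident introns are counted; a gene whose only introns sit in
  UTRs is "intronless" here.
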