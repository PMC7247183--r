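---
title: "Methods behind asrfam: a gene-family survey pipeline for polyploid wheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind asrfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`asrfam` packages, as reusable and tested code, the full analysis chain of a
genome-wide gene-family survey in allohexaploid bread wheat, using the ASR
(abscisic acid-, stress- and ripening-induced) family as the running case:
family identification from a proteome, protein physicochemistry, phylogeny
and grouping, tandem/segmental duplication classification across the A/B/D
subgenomes, conserved-motif and promoter-binding-site analysis, and
expression quantification from RNA-seq FPKM tables and qPCR Ct tables.
This vignette records the models, the defaults and why they were chosen,
the numerical choices, and the limits of what the packaged tests show.

## Family identification

The published workflow builds an HMM from seed ASR proteins and searches
the wheat proteome, keeping hits at E ≤ 1e-10 that carry a complete
ABA/WDS domain. `asrfam` implements this stage as a log-odds position
profile rather than a full profile HMM: per-column residue frequencies of
the seed alignment (gap-majority columns dropped, +0.1 pseudocount per
residue) converted to log2 odds against the background, searched by
affine-gap local alignment of profile columns against each protein. The
profile formulation keeps every number in the stage inspectable and
testable while using the same thresholds; no HMM architecture or priors
were published for the original search, so nothing published is lost in
the substitution.

Two rules decide membership, mirroring the original criteria:

* **E-value.** For profile scores in bits we use `E = m·n·2^(-S)` (the
  Karlin-Altschul form with K = 1, λ = ln 2), thresholded at 1e-10. For
  sequence-sequence BLOSUM62 scores the published gapped parameters
  (λ = 0.267, K = 0.041 for open 11 / extend 1) are used instead.
* **Domain completeness.** The aligned span must cover ≥ 80% of the
  profile width; shorter matches are reported with reason
  "incomplete domain". This replaces the web-based domain confirmation of
  the original workflow with an explicit, reproducible rule.

Redundancy removal is exact-duplicate collapse: byte-identical sequences
become one row whose representative is the lexicographically smallest id,
with all member ids retained. The original "self-BLASTP at e ≤ 1e-10"
does not state an identity cutoff for "redundant"; 100% identity is the
conservative reading (the wheat family itself contains a seven-member
group of literally identical proteins, which this rule handles cleanly).

## Protein physicochemistry

`compute_protparam()` reproduces the ExPASy-ProtParam conventions:
average-isotopic residue masses plus one water (18.01524 Da); GRAVY as the
mean Kyte-Doolittle hydropathy; and pI from the Bjellqvist pKa set
(side chains D/E/C/Y/H/K/R plus termini, with residue-specific terminal
overrides). The net-charge function is strictly decreasing in pH, so
bisection on [0, 14] (stopping at |charge| < 1e-4, ≤ 200 iterations) finds
the unique root deterministically. Values are computed at full precision
and rounded only at the reporting layer (2 decimals for kDa and pI,
3 for GRAVY), matching the precision of published family tables. Sequences
with non-standard residues are rejected with positions listed — silently
skipping an X would bias Mw and GRAVY.

The packaged `table1_wheat_asr.tsv` fixture transcribes the published
33-gene wheat ASR family table; `summarize_family()` and
`summarize_chromosomes()` recompute its narrative statistics (mean length
154 aa, mean Mw 16.84 kDa, mean pI 8.05; 12/6/8 genes on 3A/3B/3D within
579.8/207.2*/102.5 kb; 14/8/10 genes per subgenome). The ORF-length
convention includes the stop codon (`orf_bp = 3·(aa_len + 1)`), which the
table itself validates (279 aa ↔ 840 bp). One internal inconsistency of
the source is worth knowing: the mean of the table's GRAVY column is
−1.228, while the narrative rounds it to −1.226; the package reports what
the table gives. (*The published 207.2 kb span for 3B excludes the outlier
TaASR9B; `summarize_chromosomes()` reports the span over all family genes
per chromosome, so its 3B span covers all six.)

## Phylogeny and grouping

`progressive_align()` is a ClustalW-style progressive aligner: guide tree
by neighbor-joining on fractional common 3-mer distances, profiles merged
by global profile-profile alignment (sum-of-pairs BLOSUM62 column scores)
in postorder. The original study aligned in MEGA with unstated parameters;
the package fixes gap open −10 / extend −1 with BLOSUM62 as documented,
configurable defaults. Alignment never edits residues: degapping any MSA
row must reproduce the input exactly, and this is asserted in tests.

Distances support `p`, `poisson`, and `jtt_ml` — the last being the
maximum-likelihood pairwise time under the Jones-Taylor-Thornton model, by
1-D likelihood optimization with the rate matrix eigendecomposed once and
cached. Gap handling is pairwise deletion. The JTT constants are the
published table; the implementation is cross-checked in the test suite
against an independent implementation (phangorn) to ~1e-4.

`nj_tree()` is Saitou-Nei neighbor joining with deterministic tie-breaks
(smallest index pair) and the standard branch-length formulas; negative
estimates are clamped to zero and flagged. On additive matrices the
reconstructed tree metric equals the input exactly (tested on random
4-10-taxon instances). `bootstrap_supports()` resamples alignment columns,
rebuilds NJ per replicate, and reports bipartition frequencies; the
default 1000 replicates match the published setting. One source conflict
is resolved here: the original figure caption says "maximum-likelihood
tree" while the methods text says neighbor-joining — NJ is what is
implemented, following the methods text.

The study reports six phylogenetic groups without stating how they were
delimited. `extract_groups(tree, k)` operationalizes this as removing the
k−1 longest internal edges (ties by edge index), which yields k clades;
a reference mode assigns genes to the group of the nearest labeled leaf
instead. On the family-shaped synthetic data the k = 6 cut recovers the
planted groups exactly, including the seven-member identical group.

## Duplication classification

Homolog pairs come from all-vs-all local alignment under the published
thresholds, applied strictly: E < 1e-20 **and** identity > 75%. Identity
is counted over aligned columns with internal gap columns in the
denominator (local alignments have no end gaps). Same-chromosome homologs
are chained into maximal tandem arrays when consecutive family genes (in
start order) are separated by ≤ 150 kb; separation is measured from the
end of the upstream gene to the start of the downstream gene, a definition
the source leaves open. The "no intervening gene" clause is enforced only
when a full annotation is supplied; with family-only input the result is
flagged `family_only`, because the full wheat annotation is not
redistributable at package scale. Cross-chromosome homolog pairs are
segmental duplicates; genes on unanchored scaffolds are excluded from both
calls and listed separately (mirroring TaASR10U). Tandem counts are
exposed both as arrays and as consecutive pairs, since the published "14
pairs / 23 genes" counting convention is pair-based.

Homoeolog groups are connected components of the homolog graph restricted
to cross-subgenome edges; within a component the canonical member per
subgenome is the gene with the highest mean identity to the other
subgenomes, surplus copies being flagged as expansion copies.

## Motifs and promoter scanning

`discover_motifs()` is MEME-like ZOOPS (zero-or-one occurrence per
sequence) expectation-maximization over widths 6-50 with at most 20
motifs, the published settings. EM is started from the most enriched exact
word (ties lexicographic) rather than random restarts, making discovery
deterministic; the E-step computes per-window site posteriors, the M-step
re-estimates the PWM (+0.1 pseudocount) and the site probability γ.
Because the pseudocount makes the M-step maximize a Dirichlet-penalized
objective, that penalized objective — not the raw likelihood — is the
quantity guaranteed non-decreasing, and it is asserted on every
iteration. Width selection and stopping use a BIC-penalized
log-likelihood ratio against the background-only model with the number of
sequences as the sample size (under ZOOPS each sequence contributes at
most one site observation). Accepted motifs have their sites masked before
the next round, so no two motifs claim overlapping sites. Background
frequencies are the observed residue frequencies of the input set.

`scan_pwm()` replaces the original server-side binding-site prediction
with transparent PWM scanning: every window on both strands scored by
log2 odds, with the score's p-value under the background computed
*exactly* by dynamic-programming convolution of per-column score
distributions (scores discretized to 1e-3 log2-odds units). The default
per-window threshold is p ≤ 1e-4. The server's "e-value ≤ 1e-15, top 12"
settings have no published client-side equivalent, so the global count of
binding sites in the original study is not a comparable quantity; the
per-gene count matrix and hit table are.

Promoters are the 2000 bp upstream of the gene start (reverse-complemented
for minus-strand genes, truncated at contig edges with the realized length
recorded), per the published definition.

## Expression and qPCR

RNA-seq matrices are transformed as log2(FPKM + 1) and rows ordered by
average-linkage hierarchical clustering on Euclidean distances (linkage
configurable; the figure ordering of the original study is not a
quantitative result, so the default favors robustness). Relative qPCR
expression uses the Livak 2^-ΔΔCt method with ΔΔCt computed from
replicate-mean ΔCt values, and a two-sided Welch t-test on replicate ΔCt
(treated vs control); the source says only "Student's t test", and the
unequal-variance form is the safer default, switchable to pooled. Calls
are up/down at fold ≷ 1 with p ≤ 0.05.

## The synthetic-data generator

`generate_family_genome()` emulates exactly the structures the analysis
assumes: homoeolog triads across A/B/D at a target within-triad protein
identity (default 0.96 — homoeologs in hexaploid wheat are typically a few
percent diverged), between-group identity 0.45 (clearly below the 75%
homolog threshold, clearly above random), tandem arrays with spacings
drawn U[5, 200] kb so both sides of the 150-kb rule are exercised,
non-tandem neighbours spaced 250-400 kb, shuffled-decoy non-homologs,
two-exon genes with planted introns (60-400 bp), and promoters with
planted PWM consensus sites at recorded positions. Protein divergence is
i.i.d. per-site JTT substitution with the branch length solved from the
identity target, so phylogenetic distance recovery is model-consistent.
Expression tables are log-normal around group-by-condition means with
optional planted zeros; qPCR tables follow the published treatment design
(NaCl 6/24 h, PEG 6/48 h, leaf and root, 3 replicates) with planted ΔΔCt
effects and replicate noise (sd 0.2 cycles). Every generator is a pure
function of its configuration, seed included.

`paper_shaped_config()` reproduces the *shape* of the wheat family —
33 genes in six groups, a seven-member byte-identical group VI tandem on
3A plus one unanchored copy, triads on chromosome groups 2/3/4, a B/D-only
pair, two solo genes outside arrays — with synthetic sequences. It is a
stand-in, clearly documented as such: the real wheat ASR protein sequences
are supplementary material of the original study and are not
redistributed here. Checks that depend on the real sequences' exact
masses or pI values therefore validate against an independent
ProtParam-convention implementation instead.

What the generator does **not** emulate: realistic intergenic sequence
(repeats, GC structure), indel evolution, sequencing error, annotation
noise, or read-level expression sampling. Passing recovery tests on this
generator shows the algorithms implement their rules correctly, not that
the rules are robust to the messiness of a real genome annotation.

## Numerical choices and problem sizes

* Alignment DP is exact (no k-mer seeding heuristics), implemented in C++;
  traceback ties resolve diagonal > up > left.
* pI bisection: bracket [0, 14], |charge| < 1e-4.
* JTT matrix exponentials via symmetric eigendecomposition, computed once.
* PWM p-values: exact DP at 1e-3 log2-odds granularity.
* NJ negative branch lengths clamped to 0 and flagged.
* Degenerate inputs error early and name the offender (empty FASTA,
  duplicate ids, ragged alignments, pairs with no comparable columns,
  missing qPCR controls, Ct outside (0, 45)).

The test and reproduction runs use desk-scale problem sizes chosen to make
the statistical checks sharp but quick: 20 seeded genomes for duplication
recovery, 100 random additive matrices for NJ, 100 tiny pairs for the
exhaustive alignment oracle, 30 sequences for motif recovery, 200 genes
for the ΔΔCt simulation, and reduced bootstrap replicate counts in unit
tests (the 1000-replicate default is exercised end-to-end by
`run_pipeline()` users).

## Known limitations

No Ka/Ks dating, no synteny-block detection (the duplication rules are
coordinate + identity only, as in the source), no maximum-likelihood tree
search, no rooting, no Gibbs-sampling motif search, no motif-to-motif
comparison, no FPKM computation from raw reads, and no amplification
-efficiency correction in ΔΔCt. The identification stage is exact DP sized
for desk-scale proteomes (thousands of sequences), not a BLAST
replacement.
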