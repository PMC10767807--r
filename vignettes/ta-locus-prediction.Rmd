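---
title: "Predicting toxin–antitoxin loci and their mobile-element associations"
author: "tascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting toxin-antitoxin loci and their mobile-element associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Toxin–antitoxin (TA) loci are two-gene modules in which a stable toxin is
neutralized by a labile cognate antitoxin. They are classified into types
I–VIII by the nature of the antitoxin and its mode of action: types II and
IV–VII pair two proteins; types I and III pair a protein toxin with an RNA
antitoxin; type VIII pairs two RNAs. TA modules are implicated in plasmid
and genomic-island stabilization, phage defence and stress response, and
they travel with mobile genetic elements (MGEs): prophages, genomic
islands, integrative and conjugative elements (ICEs), integrons,
IS/transposon elements and plasmids.

`tascan` predicts TA loci of all eight types in annotated prokaryotic
replicons, computes which MGEs they are associated with, builds the
TA–MGE network including MinHash-based MGE similarity edges, and
summarizes the result. A seeded synthetic-genome generator with full
ground truth makes every stage testable offline.

## The prediction model

Prediction is homology-driven against a reference set of validated toxins
and antitoxins (protein and RNA), followed by rule-based pairing.

**Candidate search.** Each annotated translation is aligned against every
reference protein (Smith–Waterman, BLOSUM62, affine gaps open 11 /
extend 1); each reference RNA is aligned against the replicon sequence on
both strands (match +2 / mismatch −3, gaps open 5 / extend 2). Raw scores
are converted to E-values with Karlin–Altschul statistics (gapped
constants $\lambda = 0.267, K = 0.041$ for protein; $\lambda = 0.625,
K = 0.41$ for nucleotide) purely as a permissive reporting ceiling
(default 0.01). The decisive filter is the **H-value**

$$H = \text{identity} \times \text{coverage}_{\text{query}},$$

with the *reference* as the query; candidates are retained only when
$H > 0.36$ (strictly — the value corresponding to 60% identity over 60%
of the reference). Protein candidates must additionally be 30–500 amino
acids long, bounds inclusive. An optional HMMER3 domain scan
(`hmmsearch`, E ≤ 1e−5) can contribute candidates; by default domain and
alignment evidence combine as OR (a config switch restricts retention to
the alignment criterion, the stringent large-scale mode).

RNA hits that do not reciprocally overlap (≥ 50% each) an annotated RNA
feature synthesize a new feature, because antitoxin sRNAs are rarely
annotated. The synthetic feature spans the full projection of the
reference anchored at the alignment start (fixed length = reference
length): under a substitution-only divergence model this reproduces the
exact genomic span of a diverged copy even when the local alignment trims
mismatched termini.

**Pairing rules.** Candidate toxins and antitoxins of the same type on
the same replicon are paired exhaustively under type-specific rules
(bundled as `rules.tsv`, user-overridable):

| type | toxin / antitoxin | strands | distance window (bp) |
|------|-------------------|---------|-----------------------|
| II, IV–VII | protein / protein | same | [−20, 150] |
| III | protein / RNA | same | [−20, 150] |
| I | protein / RNA | opposite | ≤ 200, overlap unlimited |
| VIII (creTA) | RNA / RNA | either | ≤ 200 |
| VIII (SdsR-RyeA) | RNA / RNA | opposite | < 0 (overlap required) |

The intergenic distance is the signed nearest-edge gap
`max(start) − min(end)` under 0-based half-open coordinates; negative
values are overlap lengths, which is the only reading under which a
window bound of −20 makes sense. Stated windows are inclusive at both
ends; "< 0" is strict. Both gene orders are admissible wherever the
strand constraint allows them, since operons occur in both orientations
and the rules fix none. The locus score is the minimum of the two
partners' H-values — a pair is only as credible as its weaker partner.
When one feature pair is called under several types/families, the
highest score wins (ties: lower type number, then lexicographic family).

**Type VIII variants.** The two validated type VIII systems behave
differently, so the caller selects the variant from the candidates'
family annotation: any partner of the SdsR-RyeA family selects the
overlap-only opposite-strand rule, otherwise the creTA rule applies
(including to same-strand pairs, with the same 200 bp window).

## MGE association and similarity

A TA-associated MGE is an MGE *harboring* a TA locus, or an
IS/transposon (or IS cluster) *flanked by* the locus with an
edge-to-edge interval strictly below 5 kbp. Harboring requires full
containment of the locus span (leftmost to rightmost feature edge); a
locus straddling an MGE edge is not harbored and is flagged. Prophages,
genomic islands, ICEs and integrons associate only by harboring. A
plasmid replicon is itself a mobile element: every locus it carries
yields a harbored link to an implicit whole-replicon plasmid entry.
Every qualifying (locus, MGE) pair emits its own link; a locus inside an
ICE that also has an IS 1 kb away gets two links, and summary tables
count each link separately while "associated loci" counts distinct loci.

MGE sequences are sketched with bottom-$s$ MinHash over canonical k-mers
(k = 21, s = 1000, MurmurHash3-style 64-bit hash, fixed seed 42 — the
usual Mash defaults, since only the method is specified upstream). The
Mash distance is $d = -\frac{1}{k}\ln\frac{2j}{1+j}$ with $j$ the
Jaccard estimate from the bottom-$s$ sketch of the merged hash sets;
$j = 0$ saturates at $d = 1$ rather than $+\infty$ so thresholding stays
bounded. MGEs at $d < 0.01$ (strict) are "similar" and form MGE–MGE
edges of the network. All-pairs comparison is quadratic with sorted-list
merges; no pre-filter is needed at the scales this package targets.

## The synthetic-data generator

`ta_plan()`/`generate_bundle()` emulate the input corpus of a TA survey:
replicons (chromosomes and plasmids) carrying planted TA loci of chosen
type, family, strand configuration, gene order and intergenic distance;
partner sequences are copies of the bundled references diverged to a
requested identity by uniform point substitutions (no indels, so
alignment coverage stays 1 and H tracks identity directly, making the
0.36 boundary steerable); planted MGE intervals harbored around a locus,
at a controlled gap from it, or unrelated, with optional near-identical
copies for the similarity network; and random-codon background ORFs
(default 0.4 per kb, GC 0.5) with no homology to the references.
Elements are laid out with generous margins (≥ 300 bp between unrelated
elements; 1.5 kb leading / 8 kb trailing per locus block) so placements
never interact accidentally. Everything is deterministic given the plan
seed, and the generator emits a ground-truth table stating which planted
loci must be recovered and which TA–MGE links must follow.

The bundled references are synthetic stand-ins with realistic lengths
and residue composition, one pair per family across all eight types
(files named `synthetic_ta_refs_*`); they exercise the machinery but are
not curated biological sequences, and results on them say nothing about
sensitivity to real TA families.

**Calibrated identity regimes.** Near the H = 0.36 boundary the realized
alignment H-value depends on stochastic trimming and gap placement, not
on the plan alone. The generator therefore refuses planted identities in
the ambiguous band — (0.30, 0.45) for proteins, (0.50, 0.70) for RNA —
and the truth model marks RNA partners recoverable only at identity
≥ 0.70: below roughly 60% identity a +2/−3 nucleotide alignment
fragments and H collapses, while protein alignments track identity down
to ~0.35 and fragment below ~0.30. These bands were measured on the
bundled references across seeds.

**What the generator does not emulate.** No indels or rearrangements, no
codon-usage or GC structure, no gene-calling noise, no origin-spanning
features, and no deep antisense overlap between two *fixed* reference
RNAs: the overlapping bases of an RNA–RNA (type VIII) pair cannot match
both references at depth, because in real genomes such pairs share one
locus and the references themselves are antisense-consistent. Planted
type VIII overlaps therefore stay shallow (creTA to −10 bp, SdsR-RyeA
exercised end-to-end at −1 bp) while the deep-overlap window logic is
verified at the caller level with constructed candidates. Protein
partners are unaffected: their translation travels in the annotation, as
in real RefSeq-style inputs. Consequently, passing the planted-recovery
suite demonstrates correct rule logic and filter arithmetic, not
real-world sensitivity or specificity.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; 1-based
  inclusive conversion happens only in the GenBank/GFF3/TSV readers and
  writers. This makes the interval arithmetic at the heart of the caller
  off-by-one-proof, and a round trip preserves every coordinate exactly.
* Circular replicons are read but treated as linear: no pairing across
  the origin (a documented limitation; origin-spanning handling is not
  specified by the upstream method).
* Compound (`join`) CDS locations collapse to their outer span, one span
  per gene for distance purposes.
* Conceptual translations use the bacterial/archaeal code (table 11);
  an internal stop in a forced translation warns and truncates.
* Sketch hashes are stored as fixed-width lowercase hex strings:
  lexicographic order equals numeric order, 64-bit values survive R's
  doubles, and merging is a radix sort away.
* Every numeric threshold lives once, in `ta_defaults()`; stage
  functions reference it through their default arguments and any
  override is echoed to the run manifest.
* Pipeline stages communicate through documented TSVs on disk so each
  stage is independently testable and resumable; `inst/cli/tascan.R`
  exposes them as `simulate`, `predict`, `associate`, `network`,
  `stats`.

## Problem sizes used in the test suite

The standard validation fixture is ~200 kb (a 170 kb chromosome plus a
30 kb plasmid) carrying one planted locus of each TA type and five
planted MGEs; the full pipeline runs on it in well under a minute on one
CPU. The planted-recovery grid covers all types × {min, mid, max}
distance × both admissible strand configurations × identities
{1.0, 0.7} (108 single-locus genomes of ~12 kb), plus twelve
single-violation decoys. Oracle-equivalence checks run the caller
against exhaustive pair enumeration on 100 random candidate tables, the
association stage against the quadratic predicate on random interval
fixtures, the aligner against brute-force dynamic programming on 50
random pairs ≤ 200 aa, and the Jaccard estimator against exact k-mer
enumeration on sequences short enough for the sketch to be lossless.

## Known limitations

* Type I pairing uses proximity and strand only; true antisense overlap
  with the toxin gene is not required, so isolated proximal sRNA hits
  can pair with a toxin they do not silence.
* The H-value formula (identity × reference coverage) is one published
  reading of the combined-score criterion; it is isolated in
  `h_value()` so an alternative can be swapped in.
* E-values from the built-in aligner use raw sequence lengths, not
  BLAST's effective lengths; they are a reporting ceiling, not a
  significance claim.
* The RNA search reports the best non-overlapping placements per
  reference and replicon strand via iterative masking (default cap 8),
  which can miss tandem arrays of many diverged copies.
* No tri-partite TA systems, no promoter/terminator modelling, no
  novel-family discovery beyond best-hit family transfer.
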