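---
title: "Profiling copper-resistance gene repertoires: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling copper-resistance gene repertoires: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copperscan)
```

# Scope

`copperscan` re-implements, as a tested pipeline over synthetic data, a
comparative-genomics workflow for bacterial copper resistance: profile-HMM
homolog search against a curated catalog of copper-associated protein models,
per-system tabulation of the resulting resistome, similarity/length-based
homolog retention, detection of a five-gene *merR–copA* core cluster on
annotated replicons with genomic-island overlap annotation, and qPCR
ΔΔCT expression analysis with reference-gene stability screening. The
numbered scripts under `analysis/` run the four stages in order; every
computation lives in the package and is unit-tested against independent
oracles or planted ground truth.

# The profile-HMM engine

## Model and scoring semantics

A profile HMM here is the plan-7 architecture over the 20 amino acids:
match states $M_1 \ldots M_L$ with emission distributions $m_k$, insert
states with emissions $i_k$, delete states, and per-node transition groups
(M→{M,I,D}, I→{M,I}, D→{M,D}). Scoring is **local Viterbi in log2-odds**:

* the emission score of residue $a$ at match state $k$ is
  $\log_2 m_k(a)/q(a)$ with background $q$;
* transitions contribute $\log_2 p$;
* an alignment may begin and end at any match state, and unaligned flanking
  residues cost zero bits;
* the ambiguity code `X` scores zero bits at any state; other non-standard
  residues are rejected; one-residue alignments are legal.

This is a stand-in for an hmmsearch-style scorer, validated not against any
external program bit-for-bit but against an exhaustive path-enumeration
oracle: on hundreds of random small models (≤ 4 states) and sequences
(≤ 5 residues), the dynamic-programming score must equal the enumerated
maximum to 1e-9. The kernel is a small C++ routine because whole-proteome
scans in interpreted R would be impractically slow at realistic model sizes.

Because flanks are free and every path increment for a fixed sequence prefix
is unchanged by appended residues, the local score is non-decreasing under
sequence extension — a property the suite checks directly.

## E-values

Significance uses the Gumbel survival function,
$E = N\,\bigl(1 - \exp(-e^{-\lambda (s - \mu)})\bigr)$, with the number of
proteins searched as $N$. Model files carry $(\mu, \lambda)$ on the
`STATS LOCAL VITERBI` line when present; otherwise `calibrate_model()` fits
$\mu$ by the method of moments from 200 background-decoy scores with
$\lambda$ fixed at $\ln 2$ (one tail-halving per bit), i.e.
$\hat\mu = \bar s - \gamma/\lambda$ with $\gamma$ the Euler–Mascheroni
constant. This matches the *family* of Viterbi score statistics used by
standard search tools without claiming numeric identity to any of them. The
hit-definition threshold of $10^{-30}$ is applied **inclusively**
(`evalue <= cutoff`). Note that for scores far below $\mu$ the survival
probability saturates at 1 in double precision; strict monotonicity in the
score holds on the representable range.

## HMMER3 ASCII input/output

Profiles are read from and written to the `HMMER3/f` ASCII dialect
(probabilities stored as negative natural logs, `*` for zero). The parser is
hand-written — no installed R package reads this format — and is validated
two ways: a write/read round trip that must reproduce every probability to
1e-9 (the writer emits nine decimals for this reason), and a fixture
produced by `hmmbuild` 3.4 from a synthetic toy alignment
(`inst/extdata/toy_synthetic_hmmbuild34.hmm`). Because the standard format
stores five decimals, distributions from external files sum to one only
approximately; the reader renormalizes rows and transition groups on ingest.

## Profiles from alignments

`build_profile_from_alignment()` turns an alignment into a profile: columns
with gap fraction ≤ 0.5 become match states; emissions are pseudocounted
column frequencies $(c_k(a)+\alpha)/(n_k+20\alpha)$; transitions are
estimated from the observed per-sequence state paths with the same
pseudocount (zero-count groups fall back to uniform). The background
defaults to the alignment's overall residue frequencies with the same
pseudocount, but can be overridden. The override matters for shallow
alignments: a residue absent from a 3-sequence alignment gets a tiny
estimated background, which makes it look *surprising* — and therefore
over-rewarded — wherever it appears. The synthetic-model builder passes the
uniform background, consistent with the generator's uniform residue model.

# Resistome tabulation

The model catalog maps 17 TIGRFAM/COG/Pfam accessions to the four
copper-system categories (Cue, Cus, Cop/Pco, Multisystem). Models whose
reference proteins span systems — the multicopper-oxidase model covering
CueO/PcoA/CopA-oxidase, and the two-component sensor and regulator models
covering CusS/PcoS/CopS and CusR/PcoR/CopR — are Multisystem. The
Cu(I)-translocating P-type ATPase model is carried under Cue, its
chromosomal home system in *E. coli*; the copper-chaperone,
gram-positive-repressor, and remaining transport models sit under Cop/Pco.
Two of these placements (CsoR, CopY) are genuinely conventional: both are
regulators from systems outside the three named operon families, and the
closed four-category scheme forces a choice. The catalog is a plain data
frame serialized as TSV, so any other grouping is one edit away; counts are
always reported per model as well as per category.

Duplicate-hit resolution keeps, for each protein, the hit with the smallest
e-value across models; exact ties break to the lexicographically smallest
accession so results are deterministic. The count unit is therefore
proteins, not raw hits, and after deduplication the category totals sum to
the number of distinct proteins with a passing hit. The e-value sweep
(1e-30 → 1e-10 by default) applies threshold-then-dedup independently per
threshold, matching the pipeline order filter → deduplicate; the number of
distinct hit proteins is non-decreasing as the threshold loosens, which the
suite asserts against a brute-force filter-and-count oracle.

# Homolog retention and the core cluster

## The 45% / 40–150% filter

Candidates for a query protein are retained when they are strictly more
than 45% similar and between 40% and 150% of the query length (both bounds
inclusive). Similarity is defined as the fraction of alignment columns —
gap columns included — whose residue pair has a positive substitution
score, computed on a global Needleman–Wunsch alignment under BLOSUM62 with
affine penalties (open 11, extend 1; a length-$k$ gap costs $11+k$).
The alignment step delegates to `Biostrings::pairwiseAlignment`; scores are
cross-checked against an independent three-matrix (Gotoh) dynamic program
in the tests, and traceback ties resolve to Biostrings' deterministic
traceback.

Two consequences of the gap-inclusive global definition are worth knowing.
First, a candidate at the 0.40 length floor can never exceed ~40%
similarity against the full query, because its ≥ 60 end-gap columns sit in
the denominator — under a local-HSP similarity (the BLASTP convention that
the original analyses presumably used) the same candidate could score much
higher. Second, engineered boundary cases must avoid constructions where
gapping out a poorly matching block beats aligning through it. The original
similarity metric behind the published 71%/67% figures is not recoverable
from the text, so those exact values are not reproduction targets here.

## Cluster detection

The five roles — MerR-family regulator, Cu(I)-translocating P-type ATPase,
cupredoxin-domain protein, DUF2933/conserved hypothetical protein, and
isoprenylcysteine carboxylmethyltransferase — are assigned from annotated
products by case-insensitive keyword rules. A bare "hypothetical protein"
earns the DUF2933 role only contextually, when its immediate neighbours in
gene order carry the cupredoxin and methyltransferase roles; this keeps the
genome's many unrelated hypothetical proteins out of the role set. A
product matching two roles is an error rather than a silent choice.

Detection scans each replicon in coordinate order and forms maximal runs of
role-bearing genes tolerating at most `max_intervening` (default 1)
consecutive role-less genes inside a run. A run is called when it contains
the copA anchor and at least `min_roles` (default 3) distinct roles; "full"
means all five roles present, otherwise the missing roles are reported.
"Immediately upstream" is operationalized as adjacency in gene order,
orientation-agnostic, with strand recorded — published cluster tables show
order, not strand constraints, and `min_roles` is exposed because it is not
stated whether partial clusters were threshold-called or curated.

Genomic-island intervals arrive as BED (0-based half-open; converted and
tested at the boundary against the 1-based GFF3 convention used
internally). The default overlap rule is strict: a cluster is on an island
iff **every** member gene's midpoint falls inside some island interval; a
lenient any-overlap mode exists behind a flag. Replicon class
(chromosome/plasmid) comes from a caller-supplied manifest, never inferred.

# qPCR analysis

Reference-gene stability uses the BestKeeper-style criterion: the sample
standard deviation (n−1) of all CT observations of the candidate across
conditions and replicates, stable iff SD < 1 cycle (strict; an SD of
exactly 1.0 fails). ΔCT is computed per biological replicate as
CT(target) − CT(reference) matched by replicate within condition; the
calibrator is the **mean control ΔCT** (replicate pairing across conditions
is not part of the design), so ΔΔCT = mean(ΔCT treated) − mean(ΔCT
control), fold change $2^{-\Delta\Delta CT}$. Swapping treated and control
negates ΔΔCT exactly, and fold · $2^{\Delta\Delta CT} = 1$ identically.

Significance is normality-gated: Shapiro–Wilk per group, and only if both
groups are consistent with normality (p ≥ 0.05) is a two-sided two-sample
t-test used, otherwise the two-sided Mann–Whitney U. The t branch uses the
**pooled-variance Student t**, a deliberate choice: at the balanced n = 3
designs typical of qPCR, the Welch approximation's Satterthwaite degrees of
freedom make it noticeably conservative (simulated null rejection ≈ 0.028
at α = 0.05), while the pooled t is exact for equal-variance balanced
groups (≈ 0.041 after the gate; the Mann–Whitney fallback can never reject
at 3 vs 3, where its smallest two-sided p is 0.1). Groups smaller than 3
cannot be gated and fall back to Mann–Whitney with a warning; zero-variance
groups fail the gate. No multiple-testing correction is applied by default,
mirroring per-test reporting conventions; Benjamini–Hochberg is available
behind a flag.

# The synthetic-data generators

The generators define the study conditions and carry their own ground
truth; all randomness flows through an explicit seed (default 42) and
identical spec + seed gives byte-identical output.

* **Proteomes** — 100 decoys of 100–900 residues sampled from a uniform
  residue background, plus one planted homolog at 10% per-site substitution
  divergence for each of five catalog families chosen to span the size
  range (a short MerR-family regulator of 135 residues up to the 1047-residue
  RND pump, including a 68-residue chaperone). Divergence is
  substitution-only so Hamming-distance checks are exact binomials.
  Family seed sequences are random but fixed per family seed; profiles are
  built from 3-sequence alignments at 5% within-family divergence with
  pseudocount 1 and calibrated from 200 decoys.
* **Genomes** — a chromosome (40 genes) and a plasmid (25 genes) with genes
  laid out at ~1.05 kb pitch; five planted clusters (2 full, 3 partial with
  different role subsets, mixed strands, some on islands, the plasmid's full
  cluster using the bare-hypothetical DUF2933 variant); island intervals in
  BED cover planted on-island clusters plus a decoy island per replicon.
* **CT tables** — reference CT ~ Normal(15, 0.5) (the half-cycle SD mirrors
  the stability reported for the actual reference genes, comfortably under
  the 1-cycle bound), target CT = 20 − log2FC(condition) + Normal(0, 0.2),
  three biological replicates, effects emulating strong plasmid-variant
  induction (~12-fold at 100 µM and 1 mM, damped at 3 mM) and a
  flat-to-repressed chromosomal copy.

What the generators deliberately do **not** emulate: indels and selection
in homolog evolution, composition bias, operonic co-orientation
constraints, amplification-efficiency differences between assays, or
technical-replicate structure. Passing tests therefore demonstrate that the
pipeline's logic is correct under its stated model, not that the engine
matches any external search tool on real proteomes.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design: 200
path-enumeration cases (models ≤ 4 states, sequences ≤ 5 residues), a
105-protein proteome against 5 models, a 65-gene two-replicon genome, 300
ΔΔCT replicates per planted effect on the grid {−3, 0, 1, 3}, and 2000
null replicates for the type-I calibration. Distribution sums are validated
to 1e-6; round-trip equality to 1e-9; E-value tails use `expm1` to stay
accurate far below 1e-300's worth of survival; deduplication and catalog
ordering are fully deterministic under ties.

# Known limitations

* The Viterbi/Gumbel engine is a contract-faithful stand-in, not a
  re-implementation of any specific search program; per-domain reporting,
  forward-algorithm E-values, and filter heuristics are out of scope.
* Percent similarity is global and gap-inclusive; published similarity
  figures computed from local alignments are not directly comparable.
* One best alignment is reported per (model, protein); multi-domain
  proteins count once.
* Island intervals are consumed, never predicted.
* Verification against the deposited genome assemblies and the released
  model files requires network access and is outside the test suite.
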