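---
title: "Methods: acidic-triad ferroxidase discovery, HGT topology testing and ferroxidase kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acidic-triad ferroxidase discovery, HGT topology testing and ferroxidase kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadminer)
```

# The problem

LPR1-type multicopper oxidases (MCOs) are ferroxidases: they oxidize Fe²⁺
to Fe³⁺ at a substrate site built from three spatially clustered acidic
residues — the *acidic triad* (E269, D370, D462 in Arabidopsis LPR1
numbering). Because each triad residue is embedded in a short conserved
sequence context, LPR1-type ferroxidases can be recognized in raw protein
sequence by three degenerate consensus motifs, without a structure. This
package implements the complete desk workflow around that signature:

1. **motif engine** — compile the consensus motifs, scan proteins, and
   classify triad completeness (3/3, 2/3, 1/3, absent);
2. **homology screen** — apply the published tblastn-style thresholds to
   hit tables, and score candidates with a position-specific scoring
   profile;
3. **phylogenetics** — distance-based, midpoint-rooted, bootstrapped trees
   and a topological test of the horizontal-gene-transfer (HGT) claim that
   the streptophyte sequences form one clade *nested within* a bacterial
   radiation;
4. **kinetics** — ferrozine-assay conversions and Michaelis–Menten fitting;
5. **synthetic data** — seeded generators that emulate every input, so the
   full pipeline is testable offline.

# Motif model

## Grammar and compilation

`compile_pattern()` accepts a PROSITE-like consensus: `[ABC]` is a residue
class, a bare letter a literal, `X` a wildcard, and `X(m-n)` a bounded
wildcard gap. The three built-in motifs are

```{r}
for (m in triad_motifs()) print(m)
```

Each pattern carries exactly one *anchor*: the class holding the triad
residue. Anchor detection looks for the unique class drawn entirely from
{D, E, G, A} that contains at least one acidic residue (D or E). This
picks `[EA]`, `[DE]` and `[DEG]` while skipping classes such as `[DTS]`
that merely contain an acidic letter among chemically unrelated ones; the
rationale is that the triad position degenerates only to the small
residues Ala/Gly across the family, never to polar non-acidic ones.
`anchor_index` overrides the heuristic when compiling custom patterns.
Note the M3 anchor class `[DEG]` admits glycine: a G-anchored match still
counts toward completeness, and the per-anchor `is_acidic` flag records
whether the matched residue is D/E.

## Scanning and the triad call

`scan_sequence()` reports *every* satisfying (start, gap length)
combination — overlaps allowed — with 1-based inclusive coordinates, so
anchor positions line up with residue numbering conventions. Ambiguity
letters (B, J, O, U, Z, X) satisfy only wildcard and gap positions, never
a residue class: a conservative choice that cannot create a triad out of
ambiguous sequence.

`call_triad()` selects the maximum-cardinality subset of motifs whose
anchors can be placed in strictly increasing M1 < M2 < M3 order (the triad
is positional in the fold). Ties are resolved by preferring earlier motifs
and leftmost anchors, making the call deterministic; `enforce_order =
FALSE` relaxes the constraint. A sequence is *considered* a candidate when
it covers at least `min_motifs` motifs (default 2 — at least two of the
three consensus motifs).

The central anchor convention deserves a note: the middle triad residue
sits just upstream of a variable linker (the `X(5-10)` element of M2).
We anchor it at the `[DE]` class immediately preceding the linker; the
alternative reading (a residue inside the linker) is not expressible as a
single-position anchor and is not used.

## MCO hallmarks

`detect_mco_hallmarks()` flags the T1 copper site and the trinuclear
T2/T3 cluster. No published consensus exists for this visual-inspection
step, so the shipped defaults (`HCHX(2-4)H` and `HXHX(1-6)HXH`, generic
His-rich Cu-ligand spacings) are explicitly a configurable extension, not
a reproduction.

# Homology screen

`filter_hits()` applies the printed thresholds literally: `>` thresholds
are strict (coverage 60, identity 30, alignment length 175) and the
e-value "cutoff" is inclusive (≤ 1e-40). Two modes mirror the two screens:
`tblastn` (coverage + e-value + identity) and `profile`
(alignment length + 30% coverage). Every rejected row carries a reason
string, so filtering is auditable.

The published pipeline used a profile HMM built from 14 vascular-plant
LPR1-like sequences. Here `build_profile()` constructs an *ungapped*
position-specific scoring matrix: columns with more than 50% gaps are
dropped and each column scores residue a as
log((c_a + τ·b_a) / (n + τ) / b_a) with pseudocount τ (default 1) and
background b (default uniform). This is a deliberate simplification — no
insert/delete states — chosen because it is fully testable from first
principles; no numerical equivalence to the original HMM scores is
claimed, and the score threshold is plain configuration. `score_sequence()`
slides the profile over all ungapped windows (ties leftmost), and
`screen_candidates()` ranks sequences by best-window score before applying
the alignment-length rule to the match region.

# Phylogenetics

The original trees were maximum-likelihood (RAxML, JTT). The HGT argument,
however, is purely topological — a plant clade nested inside a bacterial
radiation — so this package substitutes a transparent distance pipeline
and documents the substitution: p-distances over shared non-gap columns
(pairwise deletion keeps short synthetic alignments usable), optional
Poisson correction d = −ln(1 − p), and neighbor joining.

The NJ implementation fixes two conventions that standard libraries leave
open: ties in the Q criterion break by the lexicographically smallest pair
of subtree representative labels (full determinism), and a negative branch
length arising at a join is clamped to 0 with the deficit shifted to the
sister branch, preserving the pair's spanned distance. Additive matrices
are recovered exactly (tested to 1e-9). `midpoint_root()` places the root
halfway along the longest leaf-to-leaf path. `bootstrap_support()`
resamples columns with replacement, rebuilds the tree per replicate, and
reports bipartition frequencies for the reference topology; one seed fixes
the whole procedure.

`hgt_consistency()` encodes the claim as two booleans on the rooted tree:
*monophyletic* — the ingroup leaves form exactly one clade — and *nested* —
the remaining leaves do **not** form a single clade, i.e. the ingroup is
not merely the sister group of the whole radiation. Both must hold for a
single-transfer-into-the-radiation reading. Bootstrap support of the
ingroup bipartition is attached when available.

# Kinetics

Ferrozine chelates Fe²⁺; the complex absorbs at 560 nm with
ε₅₆₀ = 25,400 M⁻¹cm⁻¹. `fe2_from_absorbance()` inverts Beer–Lambert
(negative absorbances clamp to 0 with a warning), `oxidation_rate()` takes
the control-minus-sample concentration drop per minute, and
`subtract_background()` removes non-enzymatic activity pointwise, clamping
negative rates to 0 and flagging them rather than dropping points.

`fit_mm()` fits v = V_max·S/(K_M + S) by unweighted nonlinear least
squares (Levenberg–Marquardt, relative-change tolerance 1e-8), pooling
replicates, with starting values from a Hanes–Woolf regression of S/v on
S. Unweighted pooling is a documented choice: with ~5% multiplicative
noise on a 0.5–200 μM grid, weighting changes estimates by far less than
the replicate scatter. Standard errors come from the Jacobian at the
optimum. Noiseless data is recovered to ≤1e-6 relative error; under the
assay-like study conditions (triplicates, 9-point grid, CV 5%) the
Monte-Carlo bias of the fitted K_M is below 5%.

`medium_micromolar()` converts an ICP-MS trace content (μg element per g
dry agar) into the medium contribution:
μM = content × (10 × agar%) / molar mass, reported at full precision and
at the 2 significant figures customary for such measurements.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and a seed
(byte-identical reruns, caller's RNG untouched), and each emits a truth
table sufficient to compute every downstream expectation.

* `gen_triad_sequences()` plants 3/2/1/0 motifs (largest-remainder class
  allocation, so a 20-sequence equal mix is exactly 5/5/5/5) in order at
  non-overlapping positions inside background sequence of length 500 —
  a typical MCO protein length. By default a sequence whose classified
  completeness differs from its planted class (a chance background motif,
  ~0.6% of length-500 draws) is redrawn, so truth and classification agree
  exactly; turn `clean_background = FALSE` to measure spurious-call rates.
* `gen_hit_table()` draws the three filter criteria independently with
  stated pass probabilities, values uniform on either side of each
  threshold.
* `gen_hgt_scenario()` builds a random bacterial backbone (default 4
  clades × 4 leaves), branch lengths `0.3 × U(0.2, 1)` substitutions/site
  (per-branch substitution probability ≤ 0.26), and grafts a plant clade
  (default 6 leaves) as sister to one bacterial clade — never onto the
  root — so the nested-monophyletic topology holds by construction. The
  plant crown uses half the backbone branch scale (`plant_scale = 0.5`):
  the transferred family is young relative to the bacterial radiation,
  and a crown as deep as the backbone would routinely attract the
  midpoint root onto the plant stem, turning a genuinely nested topology
  into an apparent sister arrangement — a rooting artifact, not a signal.
* `evolve_msa()` evolves i.i.d. sites along the tree under the 20-state
  equal-rates model: along a branch of length t a site is replaced with a
  uniform residue with probability 1 − exp(−t). This is the simplest
  process with closed-form expectations (two leaves at path length T
  differ per site with probability (1 − e^(−T))·19/20); it deliberately
  omits JTT-style exchangeabilities, rate heterogeneity and indels.
* `gen_kinetics()` produces v = V_max·S/(K_M+S)·(1+ε), ε ~ N(0, CV), on
  the 0–200 μM assay grid in triplicate, negatives clamped.

Passing tests on these fixtures therefore demonstrate the *logic* of the
pipeline — coordinates, thresholds, topology tests, estimator behavior —
not robustness to alignment error, compositional bias, rate variation or
model misspecification in real data.

# Numerical and design notes

* Coordinates are 1-based with inclusive ends throughout.
* The NJ distance update clamps negative intermediate distances at 0;
  Newick output carries 6-decimal branch lengths, bootstrap supports as
  internal node labels.
* Poisson-corrected distances error out on saturated pairs (p = 1) rather
  than returning infinities.
* `fit_mm()` falls back to median-substrate / 1.2×max-velocity starting
  values when the Hanes–Woolf regression is degenerate, and reports an
  unconverged fit with diagnostics instead of erroring after iteration
  exhaustion.
* Pipeline configuration files are YAML with unknown-key rejection;
  orchestration is exposed as plain R functions (`run_screen()`,
  `run_phylo()`) — the natural interface for an R analysis package —
  with all artifacts written as UTF-8 TSV/JSON/Newick/FASTA.
* Checks that involve simulation use desk-scale sizes chosen once:
  length-500 alignments on ~22-leaf trees for the 200-replicate HGT sweep,
  10⁴-row hit tables, 100-seed kinetics recovery, 1000 random sequences
  for the scanner/oracle equivalence.

# Limitations

* The profile screen is not an HMM; scores are not comparable to hmmer
  bit scores, and no threshold equivalence is claimed.
* NJ on Poisson-corrected p-distances is a stand-in for ML inference; the
  package tests topology claims, not branch-support values of any
  published figure.
* Database-scale counts of LPR1-like proteins depend on database versions
  and curation and are out of scope; so is everything wet-lab, structural
  modeling, and running BLAST/hmmer/MAFFT themselves — only their
  published filtering logic is implemented.
* The shipped `lpr1_like_synthetic.fasta` is a generated stand-in carrying
  the triad signature at the documented coordinates (E269/D370/D462) in
  background sequence; it is for coordinate tests and examples, and is not
  the At1g23010 protein.
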