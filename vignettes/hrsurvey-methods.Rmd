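---
title: "Methods behind the hemerythrin homology survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the hemerythrin homology survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hrsurvey` re-creates, at desk scale, the computational chain used to survey
the oxygen-binding hemerythrin domain across whole proteomes. This vignette
is the package's own account of the models and the choices behind them: what
each stage assumes, which knobs matter, what the synthetic data generator
does and does not emulate, and where the design was genuinely open.

## 1. Pairwise significance: a permutation null with a Gumbel tail

Local alignment scores between unrelated sequences follow an extreme-value
(Gumbel) distribution. Rather than relying on pre-tabulated Karlin–Altschul
parameters, the survey estimates the null *per pair*: the subject sequence
is uniformly permuted (`n_shuffles = 200` by default) and re-aligned, and a
Gumbel is fitted to the shuffle scores by the method of moments,

λ = π / (σ√6),  μ = x̄ − γ/λ  (γ = Euler's constant),

after which `p = 1 − exp(−exp(−λ(S − μ)))`. Permuting preserves the exact
residue composition and length of the subject, so the null controls for
compositional bias — the reason this procedure is trusted for borderline
cases like distant hemerythrin homologs at ~26% identity.

Alignment uses Smith–Waterman with affine gaps under BLOSUM50, gap open −10
and gap extend −2 (a gap of length *k* costs 10 + 2*k*). Two conventions are
deliberately pinned down because the upstream tools leave them ambiguous:

- **Identity denominator.** `identity_percent` divides matched columns by
  *all* aligned columns, gaps included (the FASTA-suite convention); the
  alternative (`identity_denominator = "matched"`) is a function argument,
  not a hidden constant.
- **E() scaling.** For a one-to-one comparison we report
  `expect = p_value` and additionally `p_times_n`. The homology cutoff
  (E() < 10⁻³, strict) is applied to `expect`.
- **Tie-breaks.** Traceback prefers diagonal over subject-gap over
  query-gap, and the smallest (query end, subject end) among equal-scoring
  cells, so alignments are reproducible across platforms.

Unit tests check the DP against exhaustive enumeration of all local
alignments at short lengths and against an independent implementation
(`Biostrings::pairwiseAlignment`) at realistic lengths; the moment fit is
checked by refitting known Gumbel samples (within 5% at n = 10,000).

## 2. The curated profile HMM

The search model is a simplified Plan7 profile: match/insert/delete states
per node, local alignment via uniform entry and exit over match nodes, and
scores in log₂-odds against the LG equilibrium background. From a seed
alignment:

- columns with non-gap occupancy ≥ `match_rule` (default 0.5) become match
  nodes;
- match emissions are Laplace-smoothed counts (`pseudocount = 1`);
- transition probabilities are counted from the observed per-row state
  paths, with pseudocount 1 per transition type; the three transition
  groups (M→{M,I,D}, I→{M,I}, D→{M,D}) each normalize to 1;
- insert emissions equal the background, so inserted residues are
  score-neutral.

**Anchor weighting** is the curated part: at the columns carrying the
iron-coordinating residues (5×His, 1×Glu, 1×Asp), the anchor residue's
count is multiplied by `anchor_weight` (default 5) *before* smoothing. The
weight's default is a package choice — what matters, and what the tests
assert, is the direction: anchor weighting widens the score gap between
anchor-preserving and anchor-violating sequences at equal overall
divergence, which is precisely what separates the oxygen-binding family
from its cation-binding sister family. `anchor_columns()` locates the
anchor columns in a seed alignment by majority residue, without consulting
any simulation truth.

E-values come from a Gumbel fitted to Viterbi bit scores of random
background sequences (`calibrate_evalue()`, n ≥ 100, default 1000), scaled
by the database size. Two coverage notions are computed and named
explicitly, because the word "subject coverage" is used for both in the
field: `reference_coverage` (profile nodes spanned / node count) gates seed
collection at > 95%, and `protein_coverage` (envelope length / protein
length) splits single-domain from long sequences at the strict 85%
boundary (0.85 is single-domain, 0.84 is long).

Viterbi and Forward are verified against exhaustive path enumeration on
tiny models (≤ 3 nodes, ≤ 4 residues, 100 random parameterizations), and
Forward ≥ Viterbi always. `collect_seed()` applies the coverage screen
before shuffle significance — a pure cost optimization with an identical
accepted set — and by default trims each accepted sequence to the matched
interval so that seeds from multi-domain hosts are domain-sized.

## 3. Architectures

Overlapping domain hits on one protein are resolved greedily in ascending
E-value order; a hit is rejected iff its envelope shares ≥ 1 residue with
an accepted one (no tolerance window; `overlap_tolerance` exists as an
explicit knob). Ties break by longer envelope, then lexicographic profile
id. The rule is deliberately simple, and the tests hold it against an
independently coded second implementation on 1000 random hit sets.

Unannotated stretches of ≥ `min_orphan` residues (default 50 — the
literature says only "short orphan elongation", so the number is ours)
count as orphan regions. The focal domain's terminus class is
orphan-aware: it is N-terminal only if *nothing* — neither an accepted
domain nor an orphan region — precedes it, C-terminal symmetrically,
only-domain if both, internal otherwise. Catalogs key on full architecture
strings; copy-number tables key on the focal profile only.

Coordinates are 1-based closed intervals in memory (the R idiom) and at
every file boundary the convention is stated: hit tables are written
1-based inclusive, simulation truth tables 0-based half-open (readers
convert back).

## 4. Alignment and phylogenetics

The progressive aligner is intentionally minimal: k-mer distances (k = 3,
min-normalized shared fraction), UPGMA guide tree, and profile–profile
global alignment with affine gaps, scoring columns by average-of-pairs
substitution score (residue vs gap = gap-extend, gap–gap = 0, "once a gap,
always a gap"). Iterative refinement is deliberately omitted: at the
divergences the survey works with, the homolog sets are alignable in one
pass, and the downstream parameter-recovery tests gate alignment quality —
column-pair recall against the simulation truth is ≥ 90% at 0.3
substitutions/site.

Tree inference is maximum likelihood under LG with 6 discrete gamma
categories. Likelihood, branch-length optimization and NNI search are
delegated to `phangorn` (`pml`/`optim.pml`), the standard R implementation
of Felsenstein pruning; the package's own contributions around it are:

- `discretize_gamma()`: equal-probability categories with category *means*
  (closed-form via the incomplete-gamma identity), so the mean rate is
  exactly 1; checked against numerical quadrature to 1e-6.
- `evolve_along_tree()`: the simulator matches the inference model exactly
  — root drawn from LG equilibrium, per-site gamma category, transitions
  exp(Q*t*r) from a symmetric eigendecomposition of the LG generator
  (rows of P(t) sum to 1 within 1e-10; stationarity and detailed balance
  hold to 1e-12).
- `alrt_support()`: for each internal branch, the statistic
  2(ℓ_best − ℓ_second) where ℓ_second is the better of the branch's two
  NNI alternatives, converted to support through the ½χ²₀ + ½χ²₁ mixture.
  Two open choices were resolved as follows. *Variant*: the parametric
  χ²-mixture (not the SH-like variant). *Re-optimization scope*: branch
  lengths of each NNI alternative are fully re-optimized rather than only
  locally; this can only raise ℓ_second, so supports are conservative,
  never inflated.
- `collapse_low_support()`: contracts internal branches with support
  strictly below the threshold (default 0.6) by hoisting children into the
  parent; the collapsed branch's length is dropped (it was unsupported),
  everything else is preserved, and the operation is idempotent.
- `midpoint_root()`, `is_monophyletic_clade()`, `nj_tree()`, bootstrap
  bipartition frequencies: thin, tested wrappers over `ape`/`phangorn`.

Topology search is NNI-only. The original analysis used the best of NNI
and SPR moves; SPR is omitted here as a deliberate reduction — the
simulation-recovery tests (RF distance 0 to the true 8-taxon topology in
≥ 8/10 seeds at 500 sites, α re-estimated within [0.7, 1.8] when
simulating at α = 1.151) define the quality bar the reduced search must
meet, rather than equivalence to any particular optimizer.

## 5. What the synthetic generator emulates — and what it does not

`make_default_templates()` fixes the study conditions: a 118-residue focal
template with the 7-anchor coordination site (anchors never mutate at the
default `anchor_conservation = 1`; the knob exists because real genomes do
contain coordination-site variants), a sister family sharing the fold
length but resampled at half the non-anchor positions and altered at 3
anchors, and two unrelated decoy domains (60 and 200 residues, < 20%
identity to the focal consensus). Background residues and linkers draw
from LG equilibrium frequencies rather than uniform, keeping decoy score
statistics realistic.

`mutate_from_template()` substitutes each site with probability
1 − exp(−d) for divergence d, drawing the replacement uniformly from the
19 other residues, so the expected changed fraction is exactly 1 − exp(−d);
tree-based evolution uses the full LG process instead. Planted divergences
default to U(0.1, 0.5) in the recovery benchmark and U(0.1, 1.5)
elsewhere — the true divergence distribution of natural homologs is
unknown, so the range is an explicit free parameter. Linker and orphan
lengths are geometric with configurable means (30 and 80): no linker-length
model exists to copy.

The generator does **not** emulate: indel evolution along trees (alignment
columns are homologous by construction), codon-level effects, compositional
heterogeneity across lineages, or realistic taxonomic sampling. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
calibrated under its own model assumptions — not that those assumptions
capture every property of real proteomes.

## 6. Numerical choices and problem sizes

- All randomness flows through explicit per-operation seeds
  (`withr::with_seed`); the pipeline fans a master seed into per-stage
  seeds, so stages are independently rerunnable and a rerun is
  byte-identical.
- Degenerate nulls (zero score variance, e.g. a homopolymer subject) raise
  a typed error naming the cause rather than returning a fake p-value.
- Branch lengths are bracketed at [1e-8, 20] inside the optimizer; NJ's
  occasional negative estimates are clamped to 0 with a message.
- The profile-HMM text format stores 12 significant digits; round-trips
  are lossless at that precision, and bit scores survive a round-trip to
  1e-8.
- Test and benchmark problem sizes were chosen as the smallest that leave
  comfortable statistical margins: 200 planted + 2000 decoys for
  sensitivity/FDR, 10 two-family datasets of 10 tips × 200 sites for
  monophyly, 10 × 500 sites for topology/α recovery, 10,000 draws for the
  Gumbel refit.

## 7. Known limitations

The aligner has no iterative refinement and will lag on sets with long
insertions; the profile HMM is single-hit by default (`multihit = TRUE`
exists but envelopes are resolved greedily, not by posterior decoding);
E-value calibration assumes background-like flanks; the tree machinery is
not meant beyond ~200 tips; and the identity/E() conventions, while
pinned, are conventions — when comparing against numbers produced by other
tool chains, residual convention differences of a few tenths of a percent
identity are expected and documented rather than silently corrected.
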