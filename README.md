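# hrsurvey

Hemerythrins are small (~118-residue) four-helix-bundle proteins whose
oxygen-binding subfamily coordinates a di-iron centre through a fixed set of
seven residues (5 His, 1 Glu, 1 Asp). Tracing where this domain occurs across
bacterial, archaeal and eukaryotic proteomes — alone or fused into larger
signalling proteins — takes a chain of classical sequence-analysis steps:
pairwise significance testing, curated profile-HMM search, domain-architecture
resolution, and maximum-likelihood phylogenetics. `hrsurvey` re-implements
that chain as a single, fully seeded R package, and pairs it with a
synthetic-proteome simulator that plants ground-truthed domain families, so
every stage can be validated against a known answer without downloading any
database.

## What the package computes

- **Shuffle-based alignment significance** (`smith_waterman()`,
  `shuffle_significance()`): affine-gap Smith–Waterman under BLOSUM50 with
  gap penalties −10/−2; the subject is permuted *n* = 200 times, a Gumbel
  distribution is fitted to the shuffle scores by the method of moments
  (λ = π/(σ√6), μ = x̄ − γ/λ), and the observed score *S* is converted to
  `p = 1 − exp(−exp(−λ(S − μ)))`. Pairs with expect value E() < 10⁻³ are
  called homologous.
- **Curated profile HMM** (`build_phmm()`, `viterbi_scan()`,
  `calibrate_evalue()`): match states from alignment columns with ≥ 50%
  occupancy, Laplace-smoothed emissions, and *anchor weighting* — the counts
  of the seven iron-coordinating residues are multiplied by a weight
  (default 5) before normalization, sharpening the model exactly where the
  biology is least forgiving. Scanning is local Viterbi in log₂-odds space
  with uniform entry/exit; E-values come from a Gumbel fit to background
  score nulls.
- **Single-domain vs long classification and architectures**
  (`classify_coverage()`, `resolve_overlaps()`): a protein whose hit covers
  < 85% of its length is "long"; overlapping hits on a protein are resolved
  greedily by ascending E-value; catalogs, per-species copy-number tables,
  presence/absence matrices and function-category summaries follow.
- **Phylogenetics under LG+Γ** (`ml_tree()`, `alrt_support()`,
  `collapse_low_support()`, `midpoint_root()`): NJ start, branch-length and
  NNI optimization, 6 discrete gamma categories, per-branch aLRT supports
  from the ½χ²₀ + ½χ²₁ mixture, collapse of branches with support < 0.6,
  midpoint rooting, monophyly tests and bootstrap.
- **Synthetic proteomes** (`make_default_templates()`,
  `generate_proteome()`, `evolve_along_tree()`): planted hemerythrin
  analogues, a sister family with an altered coordination site, decoy
  domains, multi-domain architectures with linkers and orphan elongations,
  and gap-free alignments evolved along trees under the full LG+Γ CTMC.

`run_pipeline()` chains the stages end to end with one master seed and a
checksummed run manifest; reruns are byte-identical.

## Worked example

```r
library(hrsurvey)
tpl <- make_default_templates(seed = 1)
tpl$hemerythrin
#> Domain template 'hemerythrin': 118 residues, 7 anchors (H25 H54 E58 H73 H77 H106 D111)

templates <- c(list(tpl$hemerythrin, tpl$sister_hhe), tpl$decoys)
prot <- generate_proteome(templates, n_proteins = 80, planting_rate = 0.4,
                          divergence_range = c(0.1, 0.6), seed = 2)
prot
#> Synthetic proteome 'synthetic': 80 proteins, 41 planted domains

refs  <- c(ref = tpl$hemerythrin$consensus)
seeds <- collect_seed(refs, prot, seed = 3)          # E < 1e-5, ref coverage > 95%
aln   <- progressive_align(seeds)
hmm   <- build_phmm(aln, anchors = anchor_columns(aln, tpl$hemerythrin),
                    profile_id = "hemerythrin")
hmm
#> Profile HMM 'hemerythrin': 118 nodes, 7 anchors

calib <- calibrate_evalue(hmm, length = 300, seed = 4)
hits  <- scan_proteome(hmm, prot, calibration = calib, evalue_cutoff = 1e-5)
head(hits[, c("protein_id", "bit_score", "evalue", "protein_coverage",
              "classification")], 4)
#>        protein_id bit_score       evalue protein_coverage classification
#> 1 synthetic_p0001  244.7070 2.344625e-75        0.3687500           long
#> 2 synthetic_p0003  290.3293 1.665821e-89        1.0000000  single_domain
#> 3 synthetic_p0006  267.8044 1.610968e-82        0.8467153           long
#> 4 synthetic_p0007  226.9174 7.708991e-70        0.9915254  single_domain
```

Here every one of the 27 planted proteins passing the seed stage is
recovered with no false hits; bit scores of ~230–290 bits sit 70+ orders of
magnitude below the 10⁻⁵ E-value cutoff, while the `classification` column
separates stand-alone domains from domains embedded in longer proteins at
the 85% coverage boundary.

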