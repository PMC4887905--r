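---
title: "Methods: the mirlsa vector space model for miRNA-disease ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mirlsa vector space model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`mirlsa` treats each miRNA as a "document" whose "words" are the
heterogeneous facts attached to it: curated disease associations,
genomic neighbors, validated mRNA targets, family membership and the
vocabulary of the abstracts that discuss it. The working hypothesis is
distributional: functionally related miRNAs occur in similar contexts,
and contexts shared between a miRNA and a disease are evidence of
association. Latent semantic analysis makes the two comparable: after a
truncated SVD of the combined miRNA-by-feature matrix, both miRNAs
(rows) and diseases (columns of the disease block) have coordinates in
the same r-dimensional space, and relatedness is cosine similarity.

Two modeling assumptions matter. First, all feature blocks are scaled
to [0, 1] so no single block dominates the factorization by unit
choice; the relative *norm* of each block per row (how many nonzero
features a miRNA has in it) still determines its influence, which is
intentional — data-rich miRNAs carry more context. Second, cosine
(not dot product) is used for ranking, so a miRNA with a large profile
is not preferred per se; only the direction of its profile counts.

## The five feature blocks

**Disease block (MD).** Curated associations enter as 1. Every other
entry is the best-match Lin similarity between the column disease and
the miRNA's curated diseases. Lin similarity runs over a MeSH-style
tree-number hierarchy; the information content of a term is estimated
from the association table itself (annotation counts propagated to
ancestors, once per annotation even under multiple parents), because
the association table is the only frequency corpus the method has.
Unannotated terms receive add-one smoothing (probability `1/total`),
which keeps every logarithm finite and preserves the monotonicity
`P(child) <= P(parent)`. Two degenerate cases are fixed by convention:
`sim(x, x) = 1` always, and `sim(x, y) = 0` when both terms have
probability 1 (the ratio of logs is 0/0 there; such terms carry no
information). Best-match (max) aggregation is the default because it
leaves curated entries at exactly 1 and is the standard best-match
semantic propagation; mean aggregation is available
(`build_disease_matrix(aggregate = "mean")`). Propagated entries below
`floor = 0.05` are dropped; this is purely a sparsity artifact and is
configurable.

**Neighbor block (MN).** Co-transcribed miRNA clusters co-express, and
reported co-expression collapses beyond roughly 50 kb. The genomic
distance between two miRNAs (minimum over location pairs of the number
of bases strictly between the closest ends of two same-chromosome
loci, 0 if they overlap; strand ignored; coordinates 1-based inclusive)
is mapped through the sigmoid `1/(1 + exp(k (dist - dist0)))`. The
weight is exactly 0.5 at `dist = dist0` for any positive steepness.
Defaults: `dist0 = 6e4` bp and `k = 2e-4` per bp. The source
literature prints the midpoint once as `6e5` and glosses it as 60 kb in
the same sentence; since the cited biology supports tens of kilobases,
60 kb is the default and `6e5` is available through
`neighbor_params(dist0 = 6e5)`. Weights below `1e-3` are dropped
(sparsity artifact, configurable).

**Target block (MT).** The binary miRNA-target graph is reweighted by
two-step resource allocation (network-based inference). Resources on
each target flow to its miRNAs (share `1/k(target)`) and back (share
`1/k(miRNA)`), giving the weighted one-mode target projection
`W[j, l] = (1/k(t_j)) * sum_i M[i,j] M[i,l] / k(m_i)`; column `l` of
`W` is the composition of target l's new weight, so `W` is asymmetric
and each *row* sums to 1 for any target with at least one miRNA
(conservation: the source target's resource is fully distributed).
`MT = M %*% W` propagates the projection back to miRNA-target pairs,
creating positive entries for never-reported but topologically implied
pairs. `M W` can marginally exceed 1 on dense neighborhoods (e.g. one
miRNA holding every edge of two targets); entries are clamped at 1 to
keep the block on the common [0, 1] scale. The clamp is a block-scale
artifact and does not affect the projection weights themselves.

**Word block (MW).** Abstracts are lowercased, tokenized to alphabetic
runs of at least 3 characters, stop-worded, and TF-IDF weighted with
the smoothed dialect `idf = ln((1 + m)/(1 + df)) + 1`, rows
L2-normalized. The smoothing and the normalization keep the block in
[0, 1] and make every non-empty document row a unit vector, so text
contributes a bounded share of each miRNA's profile.

**Family block (MF).** One-hot membership, raw values retained.

## Dimensionality and querying

The combined matrix is factored with a dense LAPACK SVD (the
deterministic choice at desk scale; an iterative sparse solver would be
needed beyond ~10^4 rows and none is assumed present). The default
retained rank is 400, following the published dimension scan (50 to 500
in steps of 50), capped at `min(m, n) - 1` with a message when the
dataset is smaller; the scan itself is exposed as the `sweep` CLI
subcommand rather than re-run by default. Singular vectors are
sign-canonicalized (largest-magnitude component of each left vector
made positive) so refits are bit-reproducible. Ranking scales both the
miRNA vector (row of `U_r`) and the disease vector (row of `V_r`) by
the singular values before the cosine; this symmetric convention
weights factor l by its variance `sigma_l^2` in the inner product and
is the package's reading of "cosine in the latent space" (the source
does not say whether `V`, `V Sigma`, or a fold-in is queried). Ties are
broken by miRNA id; zero-norm vectors score 0. `fold_in()` projects an
out-of-sample profile as `x' V_r diag(1/sigma) * sigma` for scoring
consistency.

## Evaluation protocol

Per disease: stratified five-fold partition of all miRNAs (positives
and negatives each split as evenly as possible; total sizes differ by
at most 1; deterministic per seed). For each fold the combined matrix
is rebuilt with the held-out miRNAs' information about the queried
disease removed: the association entry *and everything the Lin
propagation derived from it* (the row is recomputed from the remaining
diseases — merely zeroing the single entry would leak through the
propagated similarities), plus the entire word row (text may describe
the very association under test). Masked-matrix refit is used rather
than row deletion with fold-in, so the ranked list still contains the
held-out miRNAs. ROC curves sweep the distinct held-out scores with tie
groups as single steps, making the trapezoidal AUC equal to the
Mann-Whitney concordance probability; a disease's AUC is the mean of
its five fold AUCs (per-fold values are also reported).

**Flagging.** A curated association is putatively false when more than
85% of negatives outrank the miRNA (strict inequality); a non-curated
miRNA is a novel candidate when it outranks more than 85% of the known
positives. The ranking these fractions are read from is a deliberate
choice the source leaves open. `mirlsa` scores each known positive
from the CV fold in which it was held out — its curated entry and its
text removed, so its rank is not self-fulfilling — while candidates are
scored from the full-data model, because none of a candidate's data
derives from the association being judged and its literature trace is
precisely the evidence for novelty (this mirrors how novel candidates
are in practice found already described in papers the database has not
yet curated). A pure pooled-CV ranking, in which candidates are also
stripped of their text, is available with
`run_cv(use_full_for_negatives = FALSE)`.

## The synthetic world

`synth_generate()` plants the structure the method assumes: miRNAs and
diseases are partitioned into co-clusters (default 5); within-cluster
associations are Bernoulli(0.6), cross-cluster Bernoulli(0.02); 20% of
the within-cluster true associations are withheld from the association
file and recorded in `ground_truth.tsv`. Cluster coherence is realized
in every channel: a MeSH-like tree puts same-cluster diseases under a
common subtree (so their Lin similarity is ~0.5 and cross-cluster
similarity 0); cluster members sit on one synthetic chromosome with
gaps uniform in [5 kb, 40 kb] (so sigmoid weights are informative);
families are two per cluster. Words and targets carry *per-disease*
signal inside the cluster mixture: each disease owns a disjoint
vocabulary slice and a 4-gene target signature, and a miRNA's abstract
(about 120 tokens, 80% from the slices of its true diseases, 20%
background) and target set (80% of each true disease's signature, 1%
background noise) are generated from its true — including withheld —
associations. That is the real-world situation the method exploits:
the curated database lags the evidence, but the literature and the
interaction data do not.

What the generator does *not* emulate: heavy-tailed study counts (real
abstracts per miRNA span orders of magnitude), annotation biases toward
well-studied diseases, miRNAs without any cluster identity, and
curation errors other than omission. A green recovery test therefore
establishes that the pipeline separates planted cluster structure from
noise under the stated removals — not that it would reach the same
operating point on a real curated snapshot.

## What the recovery tests do and do not establish

On the default bundle the mean per-disease cross-validated AUC is
about 0.93 (criterion: at least 0.9): held-out positives are separated
from the 160 out-cluster negatives almost perfectly, and the residual
error comes from in-cluster negatives (including withheld-edge miRNAs,
which are *designed* to look positive) and from cross-cluster noise
positives.

Two stated recovery targets are *not* met, by construction of the
world rather than by defect, and the corresponding assertions are left
failing with their measured values printed:

* *Novel-flag recall of withheld associations at least 0.8.* A withheld
  association is a uniform draw from the true associations, so a
  withheld-pair miRNA is statistically exchangeable with a kept-pair
  miRNA in every feature. Under any protocol that scores both the same
  way, the fraction of positives a withheld candidate outranks is
  approximately uniform, so about 15% exceed the 0.85 bar. The
  asymmetric protocol above (positives held out, candidates at full
  data) lifts the measured recall to about 0.35 — the stripping margin
  (~0.14 in cosine) is real but smaller than the within-cluster score
  spread at the 85% quantile. The recall is flat in the retained rank
  (0.27-0.36 across r = 30 to 199), so it is not a dimensionality
  artifact.
* *Withheld pairs in the top decile of the full ranking at least 80% of
  the time.* Measured: 0.33, with 97% in the top quintile and a median
  rank of 25 of 200. The top decile (20 ranks) is occupied by curated
  positives whose explicit entry a withheld candidate lacks.

The same exchangeability logic explains why a *single* saturated
cluster (the degenerate one-cluster generator setting) yields CV AUCs
around 0.7 rather than near 1: with no out-cluster negatives, the only
signal that separates a held-out positive from a same-cluster negative
after the removals is the per-association target signature, which
resource-allocation smearing dilutes.

## Numerical choices and degenerate inputs

* Natural logarithms throughout (the Lin ratio is base-invariant).
* Lin values are clamped to [0, 1] against floating-point drift; the
  mica tie-break is lexicographic for determinism.
* Numerically zero singular values (below `sigma_1 * 1e-12`) are
  dropped with a warning; requesting a rank above `min(m, n) - 1` is an
  error that names the feasible maximum.
* All randomness (fold assignment, the generator) flows through
  explicit seeds and restores the caller's RNG state; two runs with the
  same configuration are byte-identical, which the suite asserts.
* Zero-degree nodes contribute and receive nothing in the projection;
  miRNAs without locations get a zero neighbor row (with a warning) and
  empty abstracts a zero word row.
* Disease names are matched to ontology terms by normalized exact
  string equality; unmatched names stay as ontology orphans with
  similarity 0 to everything (manual curation of name mismatches is out
  of scope).
* The stem-loop merge table is an explicit input; merging unions sets
  and locations, concatenates abstracts, and treats conflicting family
  annotations as a hard error rather than guessing.

## Known limitations

Dense SVD bounds the practical size to a few thousand miRNAs; the
per-fold refit makes cross-validation O(folds) SVDs per disease; the
word pipeline is monolingual and unlemmatized; the evaluation keeps the
"at least 20 associated miRNAs" disease filter of the source protocol,
so small-disease behavior is untested; and the flagging thresholds
(0.85, strict) are conventions of the source method, not calibrated
quantities.
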