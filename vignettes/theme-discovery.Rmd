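---
title: "Theme discovery by projection: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theme discovery by projection: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(themescape)
```

## The model

themescape treats a *theme* as a pair that defines itself: a document set
whose consensus term vector retrieves exactly that set, and a term vector
that is the best one-dimensional summary of those documents. Formally,
documents are sparse tf-idf vectors $u_i$ in the term space, and the
consensus vector of a fixed set $\{u_i\}_{i=1}^m$ is

$$\phi = \operatorname*{argmax}_{\|\phi'\| = 1} \sum_i (u_i, \phi')^2,$$

the first right singular vector of the matrix with rows $u_i$. The package
computes it by the power step
$\phi \leftarrow \mathrm{normalize}\!\left(\sum_i (u_i,\phi)\,u_i\right)$,
whose stationary points are exactly the singular vectors and whose
objective never decreases along the iteration. The equivalent residual view
$\sum_i \|u_i - (u_i,\phi)\phi\|^2 = \sum_i \|u_i\|^2 - \sum_i (u_i,\phi)^2$
is exposed as `projection_residual()` and asserted as an identity in the
test suite.

The theme algorithm wraps this in an outer loop over the *document set*:
starting from a seed document's normalized vector, it scores the whole
collection against $\phi$, keeps the top $m$, refits $\phi$ on them, and
repeats until the top-$m$ set is stable. Because the document set lives in
a finite space and the objective is monotone within each refit, the outer
loop stabilizes in practice within a handful of iterations; a cap and a
cycle guard (below) make termination unconditional. The final theme is
expanded to all documents scoring at least half the top score.

An exact recovery guarantee holds in the *ideal case*: if a document block
$V$ satisfies that every within-block similarity strictly exceeds every
similarity between a block member and an outside document, then a run
seeded in $V$ with $m \le |V|$ never leaves $V$. The synthetic generator
can audit this condition on the vectors it actually produces
(`generate_ideal_corpus()`), which is what makes the recovery tests sharp
rather than aspirational.

## Parameters that matter

* **`m` (core size, default 10).** The number of documents used in each
  consensus update. Small `m` keeps themes focused near the seed; large
  `m` climbs broader peaks and drifts to more general vocabulary. The
  package's acceptance checks reproduce this qualitatively: the mean
  document frequency of the top-5 consensus terms is non-decreasing as
  `m` sweeps 2–40 on corpora with specific block vocabularies over a
  heavy shared background.
* **`expansion_ratio` (default 0.5).** Membership threshold as a fraction
  of the top score — the half-max rule. 1.0 reduces the theme to the
  top-scoring documents only.
* **`overlap_threshold` (default 0.5).** A theme sharing at least this
  fraction of its members with a larger retained theme is redundant. The
  denominator is the *smaller* (candidate) theme — the only reading that
  stays well-defined when sizes differ greatly — and the boundary is
  inclusive on the drop side: exactly half overlap is dropped.
* **`min_theme_size` (default 10).** Themes with fewer expanded members
  are discarded by the every-seed sweep.
* **`min_df` (default 2).** Vocabulary floor; a term occurring in one
  document can never co-occur and only adds noise to $\phi$.
* **`tol` (default 1e-10) / `max_iter` (500).** Inner stopping rule
  $1 - (\phi_{t+1}, \phi_t) < tol$: scale-free and a direct bound on the
  angular change per step.
* **tf-idf scheme.** Default `tf = 1 + log(count)`, `idf = log(N/df)`,
  with a plain `count · idf` alternative (`scheme = "raw"`). Both are
  monotone in count and antitone in df; all correctness checks are
  formula-agnostic (they compare against a direct evaluation of whichever
  scheme is configured).

## Normalization conventions

Document vectors are stored with raw weights plus cached norms. The
*normalized* rows drive seeding, scoring and consensus updates, so each
document contributes equally regardless of length and the seed convention
(the seed's normalized vector is $\phi_0$) extends uniformly. The *raw*
dot products are used for within-theme similarity analysis, where the
retrieval-score scale (values well above 1) is the point. Whether scoring
should use normalized or raw vectors is genuinely open; normalized was
chosen and is flagged here.

## Numerical choices and edge cases

* **Sign.** $\phi$ is reported with its largest-magnitude coordinate
  non-negative; for non-negative inputs this makes $\phi$ entrywise
  non-negative and runs reproducible across platforms.
* **Degenerate starts.** A start orthogonal to the row space (or an
  empty-vector seed) is a named error, never a silent wrong answer.
* **Tied spectrum.** When $\sigma_1 = \sigma_2$ the limit depends on
  $\phi_0$; test matrices are generated under a spectral-gap audit, and
  the behaviour is documented rather than masked.
* **Ties in selection.** Top-$m$ selection breaks score ties by ascending
  document id; greedy partition selection breaks ties randomly under a
  caller-supplied seed; affiliation ties go to the earlier-selected theme.
  Enrichment term ties (equal p-values) break by larger in-cluster count,
  then term name.
* **Cycle guard.** The outer document-set dynamics are finite-state and
  can in principle cycle; if a set recurs from two or more iterations
  back, the run stops at the cycle member with the largest projection
  objective and is flagged. On audited ideal corpora no cycle has been
  observed (the acceptance sweep asserts zero flags).
* **Coherence singularities.** With smoothing $eps = 1/N$, an NPMI pair
  co-occurring in $N-1$ documents makes the denominator
  $-\log(p + eps)$ exactly zero and the pair value infinite; the package
  reproduces the formula faithfully and leaves the interpretation to the
  caller. Marginal probabilities of terms absent from the reference
  corpus are floored at $eps$ (in-vocabulary terms are unaffected, since
  their document fraction is at least $1/N$); a zero-frequency term in
  the UMass denominator is an error, surfaced rather than smoothed.
* **Accuracy as printed.** The best-overlap accuracy takes, for each
  computed cluster, its best-matching reference cluster without a
  one-to-one constraint; an all-singletons partition therefore scores 1.
  Comparisons are only meaningful at a fixed cluster count, which is how
  the measure is used here (the greedy partition fixes $K$).
* **Log bases.** Mutual information uses base 2; coherence uses natural
  logs. NPMI is base-invariant per pair (a ratio of logs); UMass scales
  by a constant.

## Open design points, decided

* **Coherence counts** use the full reference corpus, not per-cluster
  counts — the standard convention for both measures.
* **Enrichment averaging** is macro over the three most significant
  terms within a cluster, then macro over clusters; F is the harmonic
  mean of the averaged P and R.
* **The seed is not forced into the final core**: re-selection is purely
  by score, so a theme may drift away from its seed.
* **CLI evaluation** re-fits the stored themes against the corpus rather
  than trusting the serialized summaries: each theme is a pure function
  of (corpus, configuration, seed id), so the stored seed list and config
  snapshot reconstruct the exact full objects, and a mismatch aborts
  loudly.

## What the synthetic generator does and does not emulate

`generate_corpus()` plants disjoint (or partially overlapping) document
blocks, each drawing tokens from a dedicated vocabulary on top of a shared
background, with Zipf weights inside every vocabulary so document
frequencies are realistically skewed for tf-idf. Controlled-vocabulary
labels (a MeSH stand-in) and reference block labels come along as ground
truth. It does **not** model word order, syntax, topic mixtures within a
document, or abstract-like style; a document belongs to exactly one block.
Passing the recovery tests therefore shows the algorithms are correct
under the model's assumptions — separation, single membership — not that
real literature satisfies those assumptions. On real collections themes
overlap and the pruning and half-max rules, not the Corollary, govern
behaviour.

Default generation conditions (4 blocks of 40 documents, 40 block terms
over a 200-term background, mean length 50, noise rate 0.1) were chosen
once as a plausible miniature of an abstract collection. The audited
ideal-case corpora used by the recovery checks span 300–2,000 documents
and 3–8 blocks with mean length 80, a 300-term background and noise rate
0.02: longer documents cover their block vocabulary well, which is what
makes strict separation attainable at the larger sizes; the same
conditions are used in `scripts/acceptance.R`. The coherence and pruning
oracle checks run on 100 random instances each; the projection/SVD sweep
uses 200 random sparse non-negative matrices up to 20×30 under a
spectral-gap audit. These sizes are the package's own choice of scale at
which the properties are meaningful and quick to verify.

## Known limitations

* Only the first singular vector is computed; no deflation, higher
  components, or randomized sketching.
* The every-seed sweep is quadratic-ish in collection size (one full
  scoring pass per outer iteration per seed); the per-seed independence
  is the intended scaling lever (`cores` in `discover_themes()`), and the
  parallel path is guaranteed bit-identical to serial.
* Tokenization is deliberately simple: lowercased alphanumeric unigrams,
  adjacent bigrams, verbatim controlled terms. No stemming,
  lemmatization, or phrase detection beyond adjacent pairs.
* The half-max expansion uses the score distribution only; it has no
  notion of statistical significance of membership.
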