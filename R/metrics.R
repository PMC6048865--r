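# Evaluation machinery: topic coherence (NPMI, UMass), clustering
# agreement (NMI, best-overlap accuracy), and hypergeometric enrichment
# precision/recall/F over controlled-vocabulary document labels.

# Document and co-occurrence frequencies of a term list in a corpus.
# Terms absent from the corpus vocabulary count as D = 0.
cooccurrence_counts <- function(terms, corpus) {
  stopifnot(inherits(corpus, "theme_corpus"))
  j <- match(terms, corpus$vocab$terms)
  P <- corpus$presence[, j[!is.na(j)], drop = FALSE]
  K <- length(terms)
  Dt <- numeric(K)
  Dt[!is.na(j)] <- Matrix::colSums(P)
  Dtl <- matrix(0, K, K)
  if (ncol(P) > 0L) {
    cp <- as.matrix(Matrix::crossprod(P))
    Dtl[!is.na(j), !is.na(j)] <- cp
  }
  list(Dt = Dt, Dtl = Dtl, N = corpus$vocab$n_docs)
}

#' NPMI topic coherence
#'
#' Normalized pointwise mutual information (the UCI coherence measure)
#' summed over all unordered pairs of the top `K` topic terms:
#' \deqn{\sum_{k=2}^{K}\sum_{l=1}^{k-1}
#'   \frac{\log\frac{p(t_k,t_l)+eps}{p(t_k)\,p(t_l)}}{-\log(p(t_k,t_l)+eps)}}
#' with probabilities estimated as document fractions in the reference
#' corpus and smoothing `eps = 1/N`.  A perfectly associated pair
#' contributes close to +1, an independent pair close to 0.  Marginal
#' probabilities of terms absent from the corpus are floored at `eps`
#' (which leaves in-vocabulary terms untouched, since their document
#' fraction is at least `1/N`).
#'
#' @param terms Ordered character vector of topic terms.
#' @param corpus Reference `theme_corpus` supplying document counts.
#' @param K Number of top terms to use (default: all supplied).
#' @return Scalar coherence (sum over the `K(K-1)/2` pairs).
#' @export
npmi <- function(terms, corpus, K = length(terms)) {
  if (K < 2L) stop("NPMI needs at least 2 terms")
  terms <- terms[seq_len(min(K, length(terms)))]
  if (length(terms) < 2L) stop("NPMI needs at least 2 terms")
  cc <- cooccurrence_counts(terms, corpus)
  eps <- 1 / cc$N
  p <- pmax(cc$Dt / cc$N, eps)
  total <- 0
  for (k in 2:length(terms)) {
    for (l in 1:(k - 1)) {
      pj <- cc$Dtl[k, l] / cc$N
      total <- total + log((pj + eps) / (p[k] * p[l])) / (-log(pj + eps))
    }
  }
  total
}

#' UMass topic coherence
#'
#' Document co-occurrence coherence summed over ordered pairs of the top
#' `K` terms:
#' \deqn{\sum_{k=2}^{K}\sum_{l=1}^{k-1}\log\frac{D(t_k,t_l)+eps}{D(t_k)}}
#' where `D(t)` is document frequency, `D(t_k, t_l)` co-occurrence
#' frequency and `eps = 1/N`.  Intuitively each pair measures the
#' conditional probability of the lower-ranked term given the
#' higher-ranked one.  A term with `D(t_k) = 0` makes the denominator
#' undefined and is an error.
#'
#' @inheritParams npmi
#' @return Scalar coherence.
#' @export
umass <- function(terms, corpus, K = length(terms)) {
  if (K < 2L) stop("UMass needs at least 2 terms")
  terms <- terms[seq_len(min(K, length(terms)))]
  if (length(terms) < 2L) stop("UMass needs at least 2 terms")
  cc <- cooccurrence_counts(terms, corpus)
  if (any(cc$Dt[2:length(terms)] == 0))
    stop("UMass undefined: term with zero document frequency: ",
         terms[which(cc$Dt == 0)[1L]])
  eps <- 1 / cc$N
  total <- 0
  for (k in 2:length(terms)) {
    for (l in 1:(k - 1)) {
      total <- total + log((cc$Dtl[k, l] + eps) / cc$Dt[k])
    }
  }
  total
}

#' Coherence of every theme at several cut-offs
#'
#' @param x A `theme_set`.
#' @param corpus Reference `theme_corpus`.
#' @param K_values Top-term counts to evaluate at.
#' @return Data frame with one row per theme and columns `npmi@K`,
#'   `umass@K`; a `K` exceeding a theme's term support is reported as `NA`.
#' @export
theme_coherence <- function(x, corpus, K_values = c(5L, 10L, 20L)) {
  stopifnot(inherits(x, "theme_set"))
  rows <- lapply(x$themes, function(th) {
    tt <- names(top_terms(th$consensus, max(K_values)))
    tt <- tt[as.numeric(top_terms(th$consensus, max(K_values))) != 0]
    out <- list(seed_id = th$seed_id, size = length(th$member_ids))
    for (K in K_values) {
      out[[paste0("npmi@", K)]] <-
        if (length(tt) >= K) npmi(tt, corpus, K) else NA_real_
      out[[paste0("umass@", K)]] <-
        if (length(tt) >= K) umass(tt, corpus, K) else NA_real_
    }
    as.data.frame(out, check.names = FALSE)
  })
  do.call(rbind, rows)
}

check_same_universe <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("partitions must be named by document id")
  if (length(a) != length(b) || !setequal(names(a), names(b)))
    stop("partitions are over different document universes")
  invisible(TRUE)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information is computed from the joint label counts with base-2
#' logarithms and normalized by the larger of the two cluster entropies:
#' `NMI = MI / max(H(C), H(C'))`.  Identical partitions score 1; a
#' single-cluster partition carries no information and scores 0 (except
#' when both sides are single clusters, where 1 is returned).  The measure
#' is symmetric and invariant to label renaming.
#'
#' @param C,Cprime Named vectors/factors of cluster labels over the same
#'   document universe.
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(C, Cprime) {
  check_same_universe(C, Cprime)
  Cprime <- Cprime[names(C)]
  tab <- table(as.character(C), as.character(Cprime))
  N <- sum(tab)
  pij <- tab / N
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  mi <- 0
  for (i in seq_along(pi_)) {
    for (j in seq_along(p_j)) {
      if (pij[i, j] > 0)
        mi <- mi + pij[i, j] * log2(pij[i, j] / (pi_[i] * p_j[j]))
    }
  }
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hmax <- max(H(pi_), H(p_j))
  if (hmax == 0) return(1)
  unname(mi / hmax)
}

#' Best-overlap clustering accuracy
#'
#' For each computed cluster, counts the documents in its best-matching
#' reference cluster and divides the total by `N`:
#' \deqn{AC = \frac{\sum_i \max_j |c_i \cap c'_j|}{N}.}
#' No one-to-one matching is imposed, so the measure rewards fine
#' partitions (an all-singletons partition scores 1 against any
#' reference); comparisons are only meaningful at a fixed cluster count.
#'
#' @param C Named computed partition.
#' @param Cref Named reference partition over the same universe.
#' @return Scalar in `(0, 1]`.
#' @export
clustering_accuracy <- function(C, Cref) {
  check_same_universe(C, Cref)
  Cref <- Cref[names(C)]
  tab <- table(as.character(C), as.character(Cref))
  sum(apply(tab, 1L, max)) / sum(tab)
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K_t, n)`: drawing `n` documents
#' (a cluster) from a collection of `N` in which `K_t` carry the term, the
#' probability of seeing `k` or more term carriers by chance.  Computed
#' through the stable log-space tail of [stats::phyper()].
#'
#' @param k Observed in-cluster term count.
#' @param n Cluster size.
#' @param K_t Collection-wide term count.
#' @param N Collection size.
#' @param log Return the log p-value (useful for extreme tails that
#'   underflow on the probability scale).
#' @return p-value in `(0, 1]` (or its log); vectorized over its arguments.
#' @export
hypergeom_pvalue <- function(k, n, K_t, N, log = FALSE) {
  bad <- k < 0 | n < 0 | K_t < 0 | k > pmin(n, K_t) | n > N | K_t > N
  if (any(bad))
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, K_t) <= N)")
  lp <- stats::phyper(k - 1, K_t, N - K_t, n, lower.tail = FALSE, log.p = TRUE)
  if (log) lp else exp(lp)
}

#' Enrichment-based precision/recall/F of a partition
#'
#' For each cluster, every controlled-vocabulary term carried by its
#' documents is scored by [hypergeom_pvalue()]; the three most significant
#' terms (ties broken by larger in-cluster count, then term name) define
#' the cluster's precision (fraction of cluster documents carrying the
#' term) and recall (fraction of the term's documents inside the cluster),
#' macro-averaged over the three terms.  Cluster values are then averaged
#' over clusters and F is the harmonic mean of the averaged P and R.
#' Clusters whose documents carry no terms are excluded (with a message).
#'
#' @param partition Named vector/factor of cluster labels.
#' @param term_sets Named list mapping each document id to its (possibly
#'   empty) character vector of controlled-vocabulary terms.
#' @param n_top Number of most-significant terms per cluster.
#' @return List with `per_cluster` (data frame: cluster, P, R, F, the top
#'   terms and their p-values) and `overall` (named vector P, R, F).
#' @export
enrichment_prf <- function(partition, term_sets, n_top = 3L) {
  if (is.null(names(partition))) stop("partition must be named by document id")
  missing_docs <- setdiff(names(partition), names(term_sets))
  if (length(missing_docs) > 0L)
    stop("no term set for document: ", missing_docs[[1L]])
  N <- length(partition)
  term_sets <- lapply(term_sets[names(partition)], unique)
  coll_counts <- table(unlist(term_sets, use.names = FALSE))

  labs <- as.character(partition)
  clusters <- sort(unique(labs))
  rows <- list()
  skipped <- 0L
  for (cl in clusters) {
    ids <- names(partition)[labs == cl]
    in_counts <- table(unlist(term_sets[ids], use.names = FALSE))
    if (length(in_counts) == 0L) { skipped <- skipped + 1L; next }
    terms <- names(in_counts)
    k <- as.integer(in_counts)
    Kt <- as.integer(coll_counts[terms])
    p <- hypergeom_pvalue(k, length(ids), Kt, N)
    ord <- order(p, -k, terms, method = "radix")
    top <- ord[seq_len(min(n_top, length(ord)))]
    prec <- k[top] / length(ids)
    rec <- k[top] / Kt[top]
    P <- mean(prec); R <- mean(rec)
    rows[[cl]] <- data.frame(
      cluster = cl, size = length(ids), P = P, R = R,
      F = if (P + R > 0) 2 * P * R / (P + R) else 0,
      top_terms = paste(terms[top], collapse = ";"),
      p_values = paste(signif(p[top], 4), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    message(skipped, " cluster(s) with no controlled-vocabulary terms excluded")
  if (length(rows) == 0L) stop("no cluster has any controlled-vocabulary terms")
  per_cluster <- do.call(rbind, rows)
  rownames(per_cluster) <- NULL
  P <- mean(per_cluster$P); R <- mean(per_cluster$R)
  list(per_cluster = per_cluster,
       overall = c(P = P, R = R,
                   F = if (P + R > 0) 2 * P * R / (P + R) else 0))
}
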