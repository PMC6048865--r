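# Independent brute-force oracles.  These recount or enumerate from
# scratch and never share code with the implementation paths they check.

# document frequency / co-occurrence recount from raw per-document term sets
oracle_npmi <- function(terms, doc_sets) {
  N <- length(doc_sets)
  eps <- 1 / N
  K <- length(terms)
  total <- 0
  for (k in 2:K) {
    for (l in 1:(k - 1)) {
      Dk <- sum(vapply(doc_sets, function(s) terms[k] %in% s, TRUE))
      Dl <- sum(vapply(doc_sets, function(s) terms[l] %in% s, TRUE))
      Dkl <- sum(vapply(doc_sets,
                        function(s) terms[k] %in% s && terms[l] %in% s, TRUE))
      pk <- max(Dk / N, eps)
      pl <- max(Dl / N, eps)
      pkl <- Dkl / N
      total <- total + log((pkl + eps) / (pk * pl)) / (-log(pkl + eps))
    }
  }
  total
}

oracle_umass <- function(terms, doc_sets) {
  N <- length(doc_sets)
  eps <- 1 / N
  K <- length(terms)
  total <- 0
  for (k in 2:K) {
    for (l in 1:(k - 1)) {
      Dk <- sum(vapply(doc_sets, function(s) terms[k] %in% s, TRUE))
      Dkl <- sum(vapply(doc_sets,
                        function(s) terms[k] %in% s && terms[l] %in% s, TRUE))
      total <- total + log((Dkl + eps) / Dk)
    }
  }
  total
}

# NMI from explicit document-set intersections (no contingency table call)
oracle_nmi <- function(a, b) {
  ids <- names(a)
  b <- b[ids]
  N <- length(ids)
  A <- split(ids, as.character(a))
  B <- split(ids, as.character(b))
  mi <- 0
  for (x in A) {
    for (y in B) {
      nij <- length(intersect(x, y))
      if (nij > 0)
        mi <- mi + (nij / N) * log2(nij * N / (length(x) * length(y)))
    }
  }
  ent <- function(parts) -sum(vapply(parts, function(x) {
    p <- length(x) / N
    p * log2(p)
  }, 0))
  hmax <- max(ent(A), ent(B))
  if (hmax == 0) 1 else mi / hmax
}

oracle_accuracy <- function(a, b) {
  ids <- names(a)
  b <- b[ids]
  A <- split(ids, as.character(a))
  B <- split(ids, as.character(b))
  total <- 0
  for (x in A) {
    best <- 0
    for (y in B) best <- max(best, length(intersect(x, y)))
    total <- total + best
  }
  total / length(ids)
}

# upper-tail hypergeometric by direct pmf summation in log space
# (log-sum-exp of the enumerated terms, so extreme tails stay finite)
oracle_log_hyper <- function(k, n, K_t, N) {
  hi <- min(n, K_t)
  if (k > hi) return(-Inf)
  j <- k:hi
  lt <- lchoose(K_t, j) + lchoose(N - K_t, n - j) - lchoose(N, n)
  m <- max(lt)
  m + log(sum(exp(lt - m)))
}

# quadratic redundancy filter on (size-sorted) member-id sets
oracle_prune <- function(members, threshold) {
  ord <- order(-lengths(members), names(members), method = "radix")
  members <- members[ord]
  kept <- character()
  for (nm in names(members)) {
    drop <- FALSE
    for (km in kept) {
      ov <- sum(members[[nm]] %in% members[[km]]) / length(members[[nm]])
      if (ov >= threshold) {
        drop <- TRUE
        break
      }
    }
    if (!drop) kept <- c(kept, nm)
  }
  kept
}

# element-by-element tf-idf from counts (default log-scaled scheme)
oracle_tfidf_entry <- function(count, df, n_docs) {
  if (count == 0) return(0)
  (1 + log(count)) * log(n_docs / df)
}

random_partition <- function(ids, k) {
  stats::setNames(factor(sample(paste0("c", seq_len(k)), length(ids),
                                replace = TRUE)), ids)
}
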