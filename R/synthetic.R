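# Synthetic corpora with planted themes.  Each block of documents draws
# its tokens from a dedicated block vocabulary on top of a shared
# background vocabulary, with Zipf-weighted term probabilities, so every
# algorithm and metric can be exercised against exact ground truth.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a planted-theme corpus
#'
#' @param n_blocks Number of planted document blocks (themes).
#' @param block_sizes Documents per block (recycled to `n_blocks`).
#' @param block_vocab_size Dedicated terms per block.
#' @param background_vocab_size Terms in the shared background vocabulary.
#' @param doc_length Mean document length in tokens (Poisson, floor 5).
#' @param noise_rate Probability that a token is drawn from the background
#'   vocabulary instead of the block vocabulary.
#' @param overlap_rate Fraction of each block's vocabulary shared with the
#'   preceding block (0 = fully disjoint block vocabularies).
#' @param seed RNG seed making generation deterministic.
#' @return An object of class `planted_spec`.
#' @export
planted_spec <- function(n_blocks = 4L, block_sizes = 40L,
                         block_vocab_size = 40L,
                         background_vocab_size = 200L,
                         doc_length = 50, noise_rate = 0.1,
                         overlap_rate = 0, seed = 1L) {
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  block_sizes <- rep_len(as.integer(block_sizes), n_blocks)
  if (any(block_sizes < 1L)) stop("block sizes must be >= 1")
  if (block_vocab_size < 1L || background_vocab_size < 1L)
    stop("vocabulary sizes must be >= 1")
  if (noise_rate < 0 || noise_rate >= 1) stop("noise_rate must be in [0, 1)")
  if (overlap_rate < 0 || overlap_rate >= 1) stop("overlap_rate must be in [0, 1)")
  shared <- floor(overlap_rate * block_vocab_size)
  if (shared >= block_vocab_size)
    stop("overlap_rate leaves no dedicated terms per block")
  structure(
    list(n_blocks = as.integer(n_blocks), block_sizes = block_sizes,
         block_vocab_size = as.integer(block_vocab_size),
         background_vocab_size = as.integer(background_vocab_size),
         doc_length = doc_length, noise_rate = noise_rate,
         overlap_rate = overlap_rate, seed = seed),
    class = "planted_spec")
}

zipf_weights <- function(V) 1 / seq_len(V)

#' Generate a planted-theme corpus
#'
#' Each document belongs to one block; each of its tokens comes from the
#' shared background vocabulary with probability `noise_rate` and from the
#' block vocabulary otherwise, with Zipf-weighted term probabilities
#' inside each vocabulary (producing the skewed document frequencies
#' tf-idf weighting expects).  Every document also carries a
#' controlled-vocabulary label set (a MeSH stand-in): its block's marker
#' term with probability 0.95 plus, with probability 0.3, one term from a
#' small pool shared by all blocks.
#'
#' @param spec A [planted_spec()].
#' @return List with `docs` (data frame in the [read_corpus()] layout,
#'   `ref_label` = block) and `truth` (class `ground_truth`: `labels`
#'   named by doc id, `block_vocab`, `background_vocab`, `tokens` — the
#'   exact multiset drawn per document — token source counts and
#'   `expected_themes`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  with_seed(spec$seed, {
    B <- spec$n_blocks
    Vb <- spec$block_vocab_size
    shared <- floor(spec$overlap_rate * Vb)
    own <- lapply(seq_len(B), function(b)
      sprintf("blk%02dw%03d", b, seq_len(Vb)))
    block_vocab <- own
    if (shared > 0L && B > 1L) {
      for (b in 2:B) {
        block_vocab[[b]] <- c(utils::head(block_vocab[[b - 1L]], shared),
                              utils::tail(own[[b]], Vb - shared))
      }
    }
    background <- sprintf("bg%04d", seq_len(spec$background_vocab_size))
    mesh_pool <- sprintf("common%02d", 1:5)

    n <- sum(spec$block_sizes)
    doc_ids <- sprintf("d%05d", seq_len(n))
    labels <- rep(sprintf("B%02d", seq_len(B)), spec$block_sizes)
    texts <- character(n)
    tokens <- vector("list", n)
    vocab_terms <- vector("list", n)
    n_block_tok <- 0L
    n_noise_tok <- 0L
    blk_of <- rep(seq_len(B), spec$block_sizes)

    for (i in seq_len(n)) {
      b <- blk_of[[i]]
      L <- max(5L, stats::rpois(1L, spec$doc_length))
      n_noise <- stats::rbinom(1L, L, spec$noise_rate)
      tok <- c(
        sample(block_vocab[[b]], L - n_noise, replace = TRUE,
               prob = zipf_weights(Vb)),
        if (n_noise > 0L)
          sample(background, n_noise, replace = TRUE,
                 prob = zipf_weights(spec$background_vocab_size)))
      tok <- sample(tok)
      tokens[[i]] <- tok
      texts[[i]] <- paste(tok, collapse = " ")
      n_block_tok <- n_block_tok + (L - n_noise)
      n_noise_tok <- n_noise_tok + n_noise
      vt <- character()
      if (stats::runif(1) < 0.95) vt <- sprintf("mesh%02d", b)
      if (stats::runif(1) < 0.3) vt <- c(vt, sample(mesh_pool, 1L))
      vocab_terms[[i]] <- vt
    }

    docs <- data.frame(doc_id = doc_ids, text = texts, ref_label = labels,
                       stringsAsFactors = FALSE)
    docs$vocab_terms <- vocab_terms
    truth <- structure(
      list(labels = stats::setNames(labels, doc_ids),
           block_vocab = stats::setNames(block_vocab,
                                         sprintf("B%02d", seq_len(B))),
           background_vocab = background,
           tokens = stats::setNames(tokens, doc_ids),
           n_block_tokens = n_block_tok, n_noise_tokens = n_noise_tok,
           expected_themes = B, spec = spec),
      class = "ground_truth")
    list(docs = docs, truth = truth)
  })
}

#' Audit the ideal-case separation condition
#'
#' Checks, on the corpus's unit-normalized tf-idf vectors, that every
#' within-block pairwise similarity strictly exceeds every similarity
#' between a block member and any outside document — the hypothesis under
#' which a theme seeded inside a block is guaranteed to stay inside it.
#'
#' @param corpus A `theme_corpus`.
#' @param labels Named block labels covering the corpus documents.
#' @return List with `pass`, `min_within`, `max_cross` and a per-block
#'   data frame of the two extremes.
#' @export
audit_separation <- function(corpus, labels) {
  stopifnot(inherits(corpus, "theme_corpus"))
  labels <- labels[corpus$doc_ids]
  if (anyNA(labels)) stop("labels do not cover the corpus")
  G <- as.matrix(Matrix::tcrossprod(corpus$Xn))
  blocks <- sort(unique(as.character(labels)))
  rows <- lapply(blocks, function(b) {
    idx <- which(labels == b)
    W <- G[idx, idx, drop = FALSE]
    min_within <- if (length(idx) > 1L)
      min(W[upper.tri(W)]) else Inf
    max_cross <- if (length(idx) < nrow(G))
      max(G[idx, -idx, drop = FALSE]) else -Inf
    data.frame(block = b, min_within = min_within, max_cross = max_cross,
               stringsAsFactors = FALSE)
  })
  per_block <- do.call(rbind, rows)
  list(pass = all(per_block$min_within > per_block$max_cross),
       min_within = min(per_block$min_within),
       max_cross = max(per_block$max_cross),
       per_block = per_block)
}

#' Generate an audited ideal-case corpus
#'
#' Draws corpora from `spec` until the realised corpus passes
#' [audit_separation()] on the tf-idf vectors actually produced by the
#' corpus pipeline (the separation condition is stated on the represented
#' space, not on raw token sets).  Each retry uses a fresh seed derived
#' from the spec's.
#'
#' @param spec A [planted_spec()]; keep `noise_rate` low enough that the
#'   separation condition is attainable.
#' @param config [token_config()] used to vectorize candidate corpora.
#' @param scheme tf-idf scheme, see [compute_tfidf()].
#' @param max_attempts Regeneration cap before giving up.
#' @return List with `docs`, `truth`, the vectorized `corpus`, the `audit`
#'   result and `attempts`.
#' @export
generate_ideal_corpus <- function(spec, config = token_config(min_df = 2L),
                                  scheme = "lognorm", max_attempts = 20L) {
  stopifnot(inherits(spec, "planted_spec"))
  for (attempt in seq_len(max_attempts)) {
    sp <- spec
    sp$seed <- spec$seed + (attempt - 1L)
    gen <- generate_corpus(sp)
    corpus <- build_corpus(gen$docs, config, scheme)
    audit <- audit_separation(corpus, gen$truth$labels)
    if (audit$pass) {
      return(list(docs = gen$docs, truth = gen$truth, corpus = corpus,
                  audit = audit, attempts = attempt))
    }
  }
  stop("separation audit failed ", max_attempts,
       " times; lower noise_rate (or overlap_rate) in the spec")
}

#' Reference partition from ground truth
#'
#' @param truth A `ground_truth` object.
#' @return Factor of block labels named by document id, suitable for
#'   [nmi()] and [clustering_accuracy()].
#' @export
labeled_partition <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  stats::setNames(factor(truth$labels), names(truth$labels))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$labels), "documents in",
      x$expected_themes, "planted blocks\n")
  invisible(x)
}
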