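# Small in-code fixtures shared across test files.

docs_frame <- function(texts, ids = sprintf("d%02d", seq_along(texts)),
                       labels = NULL, vocab_terms = NULL) {
  df <- data.frame(doc_id = ids, text = texts,
                   ref_label = labels %||% rep(NA_character_, length(texts)),
                   stringsAsFactors = FALSE)
  df$vocab_terms <- vocab_terms %||% rep(list(character()), length(texts))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny two-block corpus with clearly separated vocabularies
tiny_block_corpus <- function(min_df = 1L) {
  texts <- c("apple banana cherry apple", "banana cherry apple date",
             "apple cherry banana", "xray yankee zulu xray",
             "yankee zulu xray whiskey", "zulu xray yankee")
  build_corpus(docs_frame(texts),
               token_config(min_df = min_df, min_token_length = 2L))
}

# random sparse non-negative matrix with an audited spectral gap
random_gap_matrix <- function(max_n = 20L, max_p = 30L, min_gap = 1e-3) {
  repeat {
    n <- sample(3:max_n, 1L)
    p <- sample(4:max_p, 1L)
    M <- matrix(stats::rbinom(n * p, 1L, 0.3) * stats::runif(n * p), n, p)
    if (sum(M) == 0) next
    d <- svd(M, nu = 0L, nv = 0L)$d
    if (length(d) >= 2L && (d[1] - d[2]) > min_gap * d[1]) return(M)
  }
}

unit_vec <- function(i, p) {
  v <- numeric(p)
  v[i] <- 1
  v
}

# minimal stand-in theme carrying only what set-level operations need
stub_theme <- function(seed_id, member_ids) {
  structure(list(seed_id = seed_id, core_ids = utils::head(member_ids, 2L),
                 member_ids = member_ids, scores = NULL, consensus = NULL,
                 outer_iterations = 1L, converged = TRUE, cycle = FALSE),
            class = "theme")
}
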