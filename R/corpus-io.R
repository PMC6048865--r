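# Reading, writing, tokenizing and vectorizing document collections.
#
# A collection on disk is either JSON-lines (one object per line with keys
# doc_id, text, optional vocab_terms, optional ref_label) or a headerless
# three-column TSV (doc_id <TAB> label <TAB> text), UTF-8 throughout.

# Reserved characters keeping the three term sources disjoint: unigrams are
# alphanumeric-only, bigrams contain the joiner, controlled-vocabulary terms
# carry the prefix.  Document-frequency statistics must never conflate the
# bigram "breast cancer" with any unigram.
BIGRAM_SEP <- "_"
VOCAB_TERM_PREFIX <- "#"

#' Read a document collection
#'
#' Reads a collection of documents from JSON-lines or tab-separated text.
#' Records whose text is empty after whitespace normalization are dropped
#' (with a message giving the count); duplicate document ids and malformed
#' records are errors.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` (one JSON object per line with keys `doc_id`,
#'   `text`, optional `vocab_terms`, optional `ref_label`) or `"tsv"`
#'   (headerless `doc_id<TAB>label<TAB>text`).
#' @return A data frame with columns `doc_id`, `text`, `ref_label`
#'   (`NA` when absent) and a list column `vocab_terms`, one row per
#'   admitted document, input order preserved.
#' @export
read_corpus <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("corpus file is empty: ", path)

  if (format == "jsonl") {
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      obj <- tryCatch(
        jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
        error = function(e) stop("malformed JSONL record at line ", i, ": ",
                                 conditionMessage(e), call. = FALSE)
      )
      if (is.null(obj$doc_id) || is.null(obj$text))
        stop("malformed JSONL record at line ", i,
             ": missing doc_id or text", call. = FALSE)
      recs[[i]] <- list(
        doc_id = as.character(obj$doc_id),
        text = as.character(obj$text),
        vocab_terms = as.character(obj$vocab_terms %||% character()),
        ref_label = if (is.null(obj$ref_label)) NA_character_
                    else as.character(obj$ref_label)
      )
    }
    docs <- data.frame(
      doc_id = vapply(recs, `[[`, "", "doc_id"),
      text = vapply(recs, `[[`, "", "text"),
      ref_label = vapply(recs, `[[`, "", "ref_label"),
      stringsAsFactors = FALSE
    )
    docs$vocab_terms <- lapply(recs, `[[`, "vocab_terms")
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad) > 0L)
      stop("malformed TSV record at line ", bad[[1L]],
           ": expected doc_id<TAB>label<TAB>text", call. = FALSE)
    docs <- data.frame(
      doc_id = vapply(parts, `[[`, "", 1L),
      text = vapply(parts, function(p) paste(p[-(1:2)], collapse = "\t"), ""),
      ref_label = vapply(parts, `[[`, "", 2L),
      stringsAsFactors = FALSE
    )
    docs$ref_label[docs$ref_label == ""] <- NA_character_
    docs$vocab_terms <- rep(list(character()), nrow(docs))
  }

  dup <- docs$doc_id[duplicated(docs$doc_id)]
  if (length(dup) > 0L)
    stop("duplicate doc_id in corpus: ", dup[[1L]], call. = FALSE)

  empty <- !nzchar(trimws(docs$text))
  if (any(empty)) {
    message("dropping ", sum(empty), " document(s) with empty text")
    docs <- docs[!empty, , drop = FALSE]
    rownames(docs) <- NULL
  }
  docs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a document collection
#'
#' Inverse of [read_corpus()]: writes one record per document in the chosen
#' dialect.  `write_corpus` followed by `read_corpus` is the identity on
#' admitted records.
#'
#' @param docs Data frame as returned by [read_corpus()] (columns `doc_id`,
#'   `text`, optional `ref_label` and list column `vocab_terms`).
#' @param path Output path.
#' @param format `"jsonl"` or `"tsv"`.  The TSV dialect cannot carry
#'   `vocab_terms`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (is.null(docs$ref_label)) docs$ref_label <- NA_character_
  if (is.null(docs$vocab_terms)) docs$vocab_terms <- rep(list(character()), nrow(docs))
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(docs)), function(i) {
      rec <- list(doc_id = docs$doc_id[[i]], text = docs$text[[i]])
      vt <- docs$vocab_terms[[i]]
      if (length(vt) > 0L) rec$vocab_terms <- vt
      if (!is.na(docs$ref_label[[i]])) rec$ref_label <- docs$ref_label[[i]]
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, "")
  } else {
    lab <- ifelse(is.na(docs$ref_label), "", docs$ref_label)
    lines <- paste(docs$doc_id, lab, gsub("[\t\n]", " ", docs$text), sep = "\t")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Tokenization configuration
#'
#' Controls how document text is converted into terms.  Three disjoint term
#' sources are available: unigrams, adjacent-pair bigrams (formed after
#' stopword and length filtering, joined by a reserved separator), and
#' per-document controlled-vocabulary terms (e.g. MeSH-like labels, carried
#' verbatim with a reserved prefix).
#'
#' @param use_unigrams,use_bigrams,use_vocab_terms Which term sources to
#'   emit; at least one must be `TRUE`.
#' @param stopwords Character vector of stopwords (compared after
#'   lowercasing when `lowercase = TRUE`).
#' @param lowercase Lowercase text before tokenizing.
#' @param min_token_length Minimum unigram length in characters.
#' @param min_df Minimum document frequency for a term to enter the
#'   vocabulary.  Terms occurring in a single document cannot co-occur and
#'   only add noise to the consensus vector, hence the default of 2.
#' @return An object of class `token_config`.
#' @export
token_config <- function(use_unigrams = TRUE, use_bigrams = FALSE,
                         use_vocab_terms = FALSE,
                         stopwords = character(), lowercase = TRUE,
                         min_token_length = 2L, min_df = 2L) {
  if (!isTRUE(use_unigrams) && !isTRUE(use_bigrams) && !isTRUE(use_vocab_terms))
    stop("at least one term source (unigrams, bigrams, vocab_terms) must be enabled")
  if (min_df < 1L) stop("min_df must be >= 1")
  structure(
    list(use_unigrams = isTRUE(use_unigrams),
         use_bigrams = isTRUE(use_bigrams),
         use_vocab_terms = isTRUE(use_vocab_terms),
         stopwords = as.character(stopwords),
         lowercase = isTRUE(lowercase),
         min_token_length = as.integer(min_token_length),
         min_df = as.integer(min_df)),
    class = "token_config")
}

#' Tokenize one document
#'
#' @param text Document text (title and abstract concatenated).
#' @param config A [token_config()].
#' @param vocab_terms Optional character vector of controlled-vocabulary
#'   terms attached to the document.
#' @return Character vector of term tokens (a multiset: repeats allowed).
#' @export
tokenize <- function(text, config = token_config(), vocab_terms = character()) {
  if (config$lowercase) text <- tolower(text)
  raw <- strsplit(text, "[^[:alnum:]]+")[[1L]]
  raw <- raw[nzchar(raw)]
  keep <- nchar(raw) >= config$min_token_length & !(raw %in% config$stopwords)
  uni <- raw[keep]
  out <- character()
  if (config$use_unigrams) out <- uni
  if (config$use_bigrams && length(uni) >= 2L) {
    out <- c(out, paste(uni[-length(uni)], uni[-1L], sep = BIGRAM_SEP))
  }
  if (config$use_vocab_terms && length(vocab_terms) > 0L) {
    out <- c(out, paste0(VOCAB_TERM_PREFIX, vocab_terms))
  }
  out
}

#' Build a vocabulary from tokenized documents
#'
#' Document frequency counts documents containing a term at least once, not
#' token occurrences.  Terms below `min_df` are removed; `n_docs` counts all
#' documents, including those left with no retained terms.
#'
#' @param token_list List of character vectors, one per document.
#' @param min_df Minimum document frequency.
#' @return An object of class `vocabulary`: list with `terms` (sorted),
#'   `df` (named integer vector) and `n_docs`.
#' @export
build_vocabulary <- function(token_list, min_df = 2L) {
  if (length(token_list) == 0L) stop("cannot build a vocabulary from zero documents")
  df_tab <- table(unlist(lapply(token_list, unique), use.names = FALSE))
  df <- as.integer(df_tab)
  names(df) <- names(df_tab)
  df <- df[df >= min_df]
  df <- df[order(names(df), method = "radix")]
  structure(list(terms = names(df), df = df, n_docs = length(token_list)),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("Vocabulary:", length(x$terms), "terms over", x$n_docs, "documents\n")
  invisible(x)
}

#' tf-idf document-term matrix
#'
#' Computes sparse tf-idf weights `w(t, d) = tf(count) * idf(df, N)` for the
#' configured scheme.  The default scheme uses `tf = 1 + log(count)` and
#' `idf = log(N / df)`; the `"raw"` alternative uses `tf = count` with the
#' same idf.  Terms outside the vocabulary are skipped; a term present in
#' every document has idf 0 and therefore weight 0.
#'
#' @param token_list List of per-document token vectors (same tokenization
#'   the vocabulary was built from).
#' @param vocab A [build_vocabulary()] result.
#' @param doc_ids Character vector of document ids (row names).
#' @param scheme `"lognorm"` (default) or `"raw"`.
#' @return A [Matrix::dgCMatrix-class] with one row per document and one
#'   column per vocabulary term.
#' @export
compute_tfidf <- function(token_list, vocab, doc_ids,
                          scheme = c("lognorm", "raw")) {
  scheme <- match.arg(scheme)
  n <- length(token_list)
  stopifnot(length(doc_ids) == n)
  V <- length(vocab$terms)
  idf <- log(vocab$n_docs / as.numeric(vocab$df))

  ii <- vector("list", n)
  jj <- vector("list", n)
  xx <- vector("list", n)
  for (d in seq_len(n)) {
    cnt <- table(token_list[[d]])
    j <- match(names(cnt), vocab$terms)
    ok <- !is.na(j)
    if (!any(ok)) next
    j <- j[ok]
    tf <- as.numeric(cnt)[ok]
    if (scheme == "lognorm") tf <- 1 + log(tf)
    w <- tf * idf[j]
    nz <- w != 0
    ii[[d]] <- rep.int(d, sum(nz))
    jj[[d]] <- j[nz]
    xx[[d]] <- w[nz]
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n, V), dimnames = list(doc_ids, vocab$terms))
}

#' Build an analysis-ready corpus
#'
#' Runs the full vectorization pipeline: tokenize every document, build the
#' vocabulary, compute tf-idf weights, and cache the unit-normalized view
#' used by the theme algorithms.  Document vectors are stored with raw
#' weights plus their Euclidean norms; normalized rows are used for scoring
#' and consensus updates so each document contributes equally, while raw
#' dot products remain available for within-theme similarity analysis.
#'
#' @param docs Data frame as returned by [read_corpus()].
#' @param config A [token_config()].
#' @param scheme tf-idf scheme, see [compute_tfidf()].
#' @return An object of class `theme_corpus`.
#' @export
build_corpus <- function(docs, config = token_config(), scheme = c("lognorm", "raw")) {
  scheme <- match.arg(scheme)
  if (nrow(docs) == 0L) stop("empty document collection")
  if (anyDuplicated(docs$doc_id)) stop("duplicate doc_id in collection")
  if (is.null(docs$vocab_terms)) docs$vocab_terms <- rep(list(character()), nrow(docs))
  if (is.null(docs$ref_label)) docs$ref_label <- rep(NA_character_, nrow(docs))

  token_list <- lapply(seq_len(nrow(docs)), function(i) {
    tokenize(docs$text[[i]], config, docs$vocab_terms[[i]])
  })
  vocab <- build_vocabulary(token_list, min_df = config$min_df)
  dtm <- compute_tfidf(token_list, vocab, docs$doc_id, scheme)

  # binary presence matrix over the vocabulary: coherence statistics count
  # documents containing a term regardless of its tf-idf weight (which can
  # legitimately be zero for ubiquitous terms)
  pres_idx <- lapply(seq_along(token_list), function(d) {
    j <- match(unique(token_list[[d]]), vocab$terms)
    j[!is.na(j)]
  })
  presence <- Matrix::sparseMatrix(
    i = rep.int(seq_along(pres_idx), lengths(pres_idx)),
    j = unlist(pres_idx), x = 1,
    dims = dim(dtm), dimnames = dimnames(dtm))

  norms <- sqrt(Matrix::rowSums(dtm^2))
  scale <- ifelse(norms > 0, 1 / norms, 0)
  Xn <- Matrix::Diagonal(x = scale) %*% dtm
  Xn <- methods::as(Xn, "CsparseMatrix")
  dimnames(Xn) <- dimnames(dtm)

  structure(
    list(doc_ids = docs$doc_id, dtm = dtm, Xn = Xn, norms = norms,
         presence = presence, vocab = vocab,
         vocab_terms = stats::setNames(docs$vocab_terms, docs$doc_id),
         ref_labels = stats::setNames(docs$ref_label, docs$doc_id),
         config = config, scheme = scheme),
    class = "theme_corpus")
}

#' @export
print.theme_corpus <- function(x, ...) {
  cat("Theme corpus:", length(x$doc_ids), "documents,",
      length(x$vocab$terms), "terms\n")
  cat("  tf-idf scheme:", x$scheme, " min_df:", x$config$min_df, "\n")
  src <- c("unigrams", "bigrams", "vocab_terms")[c(x$config$use_unigrams,
                                                   x$config$use_bigrams,
                                                   x$config$use_vocab_terms)]
  cat("  term sources:", paste(src, collapse = ", "), "\n")
  invisible(x)
}
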