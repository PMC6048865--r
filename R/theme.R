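# The theme algorithm: interleave consensus-vector updates with top-m
# document re-selection from the whole collection, then expand by the
# half-max rule.  A theme is the dual object (document set, term vector).

#' Theme-algorithm control parameters
#'
#' @param m Core size: number of top-scoring documents used in each
#'   consensus update.  Small `m` keeps a theme focused near its seed;
#'   large `m` drifts towards broader, more general subjects.
#' @param min_theme_size Themes with fewer expanded members are discarded
#'   by [discover_themes()].
#' @param expansion_ratio Fraction of the top document score required for
#'   membership in the expanded theme (0.5 = the half-max rule).
#' @param max_outer_iter Cap on outer (document re-selection) iterations.
#' @param overlap_threshold A theme sharing at least this fraction of its
#'   members with a larger retained theme is pruned as redundant.
#' @param tol,max_iter Inner projection-algorithm settings, see
#'   [run_projection()].
#' @return An object of class `theme_control`.
#' @export
theme_control <- function(m = 10L, min_theme_size = 10L,
                          expansion_ratio = 0.5, max_outer_iter = 100L,
                          overlap_threshold = 0.5,
                          tol = 1e-10, max_iter = 500L) {
  if (m < 2L) stop("m must be >= 2")
  if (expansion_ratio <= 0 || expansion_ratio > 1)
    stop("expansion_ratio must be in (0, 1]")
  if (overlap_threshold <= 0 || overlap_threshold > 1)
    stop("overlap_threshold must be in (0, 1]")
  if (max_outer_iter < 1L) stop("max_outer_iter must be >= 1")
  structure(
    list(m = as.integer(m), min_theme_size = as.integer(min_theme_size),
         expansion_ratio = expansion_ratio,
         max_outer_iter = as.integer(max_outer_iter),
         overlap_threshold = overlap_threshold,
         tol = tol, max_iter = as.integer(max_iter)),
    class = "theme_control")
}

#' Score all documents against a term vector
#'
#' `score(d) = (u_d, phi)` on unit-normalized document vectors, so a
#' document whose vector is parallel to `phi` scores 1 (Cauchy--Schwarz)
#' and a document sharing no terms with `phi`'s support scores 0.
#'
#' @param corpus A `theme_corpus`.
#' @param phi Numeric vector over the corpus vocabulary.
#' @return Named numeric vector of scores, one per document.
#' @export
score_documents <- function(corpus, phi) {
  stopifnot(inherits(corpus, "theme_corpus"))
  if (length(phi) != ncol(corpus$Xn))
    stop("dimension mismatch between phi and corpus vocabulary")
  stats::setNames(as.vector(corpus$Xn %*% as.numeric(phi)), corpus$doc_ids)
}

#' Select the top-m scoring documents
#'
#' Ties are broken by ascending document id so the selection is
#' deterministic.
#'
#' @param scores Named numeric vector of document scores.
#' @param m Number of documents to select.
#' @return Character vector of `m` document ids, best first.
#' @export
select_top_m <- function(scores, m) {
  if (length(scores) < m)
    stop("cannot select top ", m, " from ", length(scores), " documents")
  ord <- order(-scores, names(scores), method = "radix")
  names(scores)[ord[seq_len(m)]]
}

#' Fit a theme from a seed document
#'
#' Starting from the seed's normalized tf-idf vector as the initial term
#' vector, the theme algorithm repeats: score every document in the
#' collection against the current consensus vector, select the top-`m`,
#' and run the projection algorithm on that document set to update the
#' consensus vector.  The outer loop stops when the selected document set
#' repeats the previous one (a fixed point).  If the set sequence enters a
#' longer cycle, the set with the largest projection objective in the
#' cycle is kept and the run is flagged.  The final theme is expanded to
#' every document scoring at least `expansion_ratio` times the top score.
#'
#' @param corpus A `theme_corpus`.
#' @param seed_id Document id of the seed.
#' @param control A [theme_control()].
#' @return An object of class `theme`: list with `seed_id`, `core_ids`
#'   (the top-`m` set), `member_ids` (expanded, sorted by descending
#'   score), `scores` (all documents), `consensus` (the
#'   `consensus_vector`), `outer_iterations`, `converged` and `cycle`.
#' @export
run_theme <- function(corpus, seed_id, control = theme_control()) {
  stopifnot(inherits(corpus, "theme_corpus"))
  m <- control$m
  if (length(corpus$doc_ids) < m)
    stop("collection smaller than m = ", m)
  row <- match(seed_id, corpus$doc_ids)
  if (is.na(row)) stop("seed document not found: ", seed_id)
  if (corpus$norms[[row]] == 0)
    stop("degenerate seed (empty tf-idf vector): ", seed_id)

  phi <- as.vector(corpus$Xn[row, ])
  keys <- character()
  sets <- list()
  phis <- list()
  objs <- numeric()
  converged <- FALSE
  cycle <- FALSE
  iters <- 0L
  D <- character()

  for (it in seq_len(control$max_outer_iter)) {
    iters <- it
    scores <- score_documents(corpus, phi)
    D <- select_top_m(scores, m)
    key <- paste(sort(D), collapse = "\r")
    hit <- match(key, keys)
    if (!is.na(hit)) {
      if (hit == length(keys)) {
        converged <- TRUE            # stable document set
      } else {
        # the set sequence cycles; keep the best set by the projection
        # objective, the algorithm's own criterion
        cycle <- TRUE
        converged <- TRUE
        span <- hit:length(keys)
        best <- span[[which.max(objs[span])]]
        D <- sets[[best]]
        phi <- phis[[best]]
      }
      break
    }
    proj <- run_projection(corpus$Xn[match(D, corpus$doc_ids), , drop = FALSE],
                           phi0 = phi, tol = control$tol,
                           max_iter = control$max_iter)
    phi <- as.numeric(proj)
    keys <- c(keys, key)
    sets[[length(sets) + 1L]] <- D
    phis[[length(phis) + 1L]] <- phi
    objs <- c(objs, attr(proj, "objective"))
  }

  final_scores <- score_documents(corpus, phi)
  core_ids <- select_top_m(final_scores, m)
  thr <- control$expansion_ratio * max(final_scores)
  member <- final_scores[final_scores >= thr]
  member_ids <- names(member)[order(-member, names(member), method = "radix")]

  core_rows <- corpus$Xn[match(core_ids, corpus$doc_ids), , drop = FALSE]
  consensus <- structure(stats::setNames(phi, corpus$vocab$terms),
                         class = "consensus_vector",
                         iterations = NA_integer_, converged = converged,
                         objective = projection_objective(core_rows, phi))

  structure(
    list(seed_id = seed_id, core_ids = core_ids, member_ids = member_ids,
         scores = final_scores, consensus = consensus,
         outer_iterations = iters, converged = converged, cycle = cycle,
         control = control),
    class = "theme")
}

#' @export
print.theme <- function(x, n = 10L, ...) {
  cat("Theme seeded at", x$seed_id, "-", length(x$member_ids), "documents",
      sprintf("(core %d, %d outer iteration%s%s%s)\n",
              length(x$core_ids), x$outer_iterations,
              if (x$outer_iterations == 1L) "" else "s",
              if (x$converged) "" else ", NOT converged",
              if (x$cycle) ", cycle resolved" else ""))
  tt <- top_terms(x$consensus, n)
  cat("Top terms:", paste(names(tt), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.theme <- function(object, ...) object$consensus

#' @export
predict.theme <- function(object, corpus, ...) {
  score_documents(corpus, as.numeric(object$consensus))
}

#' @export
residuals.theme <- function(object, corpus, ...) {
  rows <- corpus$Xn[match(object$member_ids, corpus$doc_ids), , drop = FALSE]
  phi <- as.numeric(object$consensus)
  s <- as.vector(rows %*% phi)
  stats::setNames(Matrix::rowSums(rows^2) - 2 * s^2 + s^2 * sum(phi^2),
                  object$member_ids)
}

#' Discover themes from every seed
#'
#' Runs [run_theme()] once per seed document.  Each theme depends only on
#' its seed and the corpus, so the sweep is order-independent and safe to
#' parallelise; results are merged in a canonical order (decreasing size,
#' ties by seed id) regardless of execution order.  Themes smaller than
#' `min_theme_size` are discarded and, when `prune = TRUE`, redundant
#' themes are removed with [prune_redundant()].
#'
#' @param corpus A `theme_corpus`.
#' @param control A [theme_control()].
#' @param prune Remove redundant themes after the sweep.
#' @param seeds Seed document ids (default: every document).
#' @param cores Number of worker processes (forked; 1 = serial).
#' @return An object of class `theme_set`.
#' @export
discover_themes <- function(corpus, control = theme_control(), prune = TRUE,
                            seeds = NULL, cores = 1L) {
  stopifnot(inherits(corpus, "theme_corpus"))
  if (is.null(seeds)) seeds <- corpus$doc_ids
  runner <- function(sid) {
    tryCatch(run_theme(corpus, sid, control),
             error = function(e) structure(
               list(seed_id = sid, message = conditionMessage(e)),
               class = "theme_error"))
  }
  results <- if (cores > 1L) {
    parallel::mclapply(seeds, runner, mc.cores = cores)
  } else {
    lapply(seeds, runner)
  }
  failed <- vapply(results, inherits, TRUE, "theme_error")
  errors <- lapply(results[failed], function(e) e[c("seed_id", "message")])
  themes <- results[!failed]
  themes <- themes[vapply(themes, function(th) length(th$member_ids), 0L) >=
                     control$min_theme_size]
  ts <- canonical_theme_order(themes)
  out <- structure(list(themes = ts, control = control,
                        n_seeds = length(seeds), pruned = FALSE,
                        seed_errors = errors),
                   class = "theme_set")
  if (prune) out <- prune_redundant(out, control$overlap_threshold)
  out
}

canonical_theme_order <- function(themes) {
  if (length(themes) == 0L) return(themes)
  sizes <- vapply(themes, function(th) length(th$member_ids), 0L)
  seeds <- vapply(themes, function(th) th$seed_id, "")
  themes[order(-sizes, seeds, method = "radix")]
}

#' Prune redundant themes
#'
#' Themes are scanned from the largest to the smallest; a theme is dropped
#' when it shares at least `overlap_threshold` of its members with an
#' already-retained (larger or equal) theme.  The denominator is the size
#' of the smaller (candidate) theme and the threshold is inclusive on the
#' drop side: exactly half overlap at the default 0.5 is dropped.
#'
#' @param x A `theme_set` or a list of `theme` objects.
#' @param overlap_threshold Drop threshold in (0, 1].
#' @return A pruned object of the same class, canonical order preserved.
#' @export
prune_redundant <- function(x, overlap_threshold = 0.5) {
  themes <- if (inherits(x, "theme_set")) x$themes else x
  themes <- canonical_theme_order(themes)
  kept <- list()
  for (th in themes) {
    redundant <- FALSE
    for (big in kept) {
      ov <- length(intersect(big$member_ids, th$member_ids)) /
        length(th$member_ids)
      if (ov >= overlap_threshold) { redundant <- TRUE; break }
    }
    if (!redundant) kept[[length(kept) + 1L]] <- th
  }
  if (inherits(x, "theme_set")) {
    x$themes <- kept
    x$pruned <- TRUE
    x
  } else kept
}

#' @export
print.theme_set <- function(x, n = 10L, ...) {
  cat("Theme set:", length(x$themes), "themes from", x$n_seeds, "seeds",
      if (x$pruned) "(pruned)" else "(unpruned)", "\n")
  if (length(x$seed_errors) > 0L)
    cat("  ", length(x$seed_errors), "seed(s) failed\n")
  df <- summary(x)
  print(utils::head(df, n))
  if (nrow(df) > n) cat("  ...", nrow(df) - n, "more themes\n")
  invisible(x)
}

#' @export
summary.theme_set <- function(object, n_terms = 5L, ...) {
  data.frame(
    rank = seq_along(object$themes),
    seed_id = vapply(object$themes, function(th) th$seed_id, ""),
    size = vapply(object$themes, function(th) length(th$member_ids), 0L),
    outer_iterations = vapply(object$themes, function(th) th$outer_iterations, 0L),
    converged = vapply(object$themes, function(th) th$converged, TRUE),
    top_terms = vapply(object$themes, function(th)
      paste(names(top_terms(th$consensus, n_terms)), collapse = " / "), ""),
    stringsAsFactors = FALSE)
}

#' @export
plot.theme_set <- function(x, ...) {
  sizes <- vapply(x$themes, function(th) length(th$member_ids), 0L)
  graphics::barplot(sizes, names.arg = seq_along(sizes),
                    xlab = "theme rank", ylab = "documents",
                    main = "Theme sizes", ...)
  invisible(x)
}

#' Greedy theme-based partition
#'
#' Selects `K` themes greedily — first the theme with the highest total
#' document score, then repeatedly the theme maximizing the increment in
#' the sum over documents of their best score against a selected theme —
#' and affiliates every document with its highest-scoring selected theme.
#' Ties in the greedy selection are broken randomly under `seed`;
#' affiliation ties go to the earlier-selected theme.  Documents scoring 0
#' against every selected theme are assigned to the selected theme with
#' the highest total score.
#'
#' @param x A `theme_set` with at least `K` themes.
#' @param corpus The `theme_corpus` the themes were fitted on.
#' @param K Number of clusters.
#' @param seed Integer seed for random tie-breaking.
#' @return A factor of cluster labels (selected themes' seed ids) named by
#'   document id, with exactly `K` levels.
#' @export
greedy_partition <- function(x, corpus, K, seed = 1L) {
  stopifnot(inherits(x, "theme_set"), inherits(corpus, "theme_corpus"))
  themes <- x$themes
  if (K > length(themes))
    stop("K = ", K, " exceeds the number of themes (", length(themes), ")")
  S <- vapply(themes, function(th) unname(th$scores[corpus$doc_ids]),
              numeric(length(corpus$doc_ids)))
  S <- matrix(S, nrow = length(corpus$doc_ids))

  pick_max <- function(v) {
    cand <- which(v == max(v))
    if (length(cand) == 1L) return(cand)
    cand[[sample.int(length(cand), 1L)]]
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  totals <- colSums(S)
  selected <- pick_max(totals)
  best <- S[, selected[[1L]]]
  while (length(selected) < K) {
    remaining <- setdiff(seq_along(themes), selected)
    gains <- vapply(remaining, function(j) sum(pmax(best, S[, j])), 0)
    j <- remaining[[pick_max(gains)]]
    selected <- c(selected, j)
    best <- pmax(best, S[, j])
  }

  labels <- vapply(themes[selected], function(th) th$seed_id, "")
  # affiliation: argmax over selected themes, ties to the earlier pick
  assign_idx <- rep.int(1L, nrow(S))
  cur <- S[, selected[[1L]]]
  for (k in seq_along(selected)[-1L]) {
    sk <- S[, selected[[k]]]
    better <- sk > cur
    assign_idx[better] <- k
    cur[better] <- sk[better]
  }
  fallback <- which.max(colSums(S[, selected, drop = FALSE]))
  assign_idx[cur == 0] <- fallback
  factor(labels[assign_idx], levels = labels) |>
    stats::setNames(corpus$doc_ids)
}

#' Mean within-theme pairwise similarity
#'
#' Average over all unordered member pairs of the raw (unnormalized)
#' tf-idf dot product — the retrieval score one member would assign the
#' other as a query.
#'
#' @param theme A `theme`.
#' @param corpus The `theme_corpus` it was fitted on.
#' @return Scalar mean pairwise similarity.
#' @export
within_theme_similarity <- function(theme, corpus) {
  ids <- theme$member_ids
  n <- length(ids)
  if (n < 2L) stop("within-theme similarity needs at least 2 members")
  M <- corpus$dtm[match(ids, corpus$doc_ids), , drop = FALSE]
  G <- Matrix::tcrossprod(M)
  (sum(G) - sum(Matrix::diag(G))) / (n * (n - 1))
}

#' Serialize a theme set to JSON
#'
#' Writes one record per theme: seed id, size, expanded members with their
#' scores, the top 10 consensus terms with weights, and convergence
#' information, plus a snapshot of the control parameters.
#'
#' @param x A `theme_set`.
#' @param path Output path.
#' @param n_terms Number of top consensus terms to store per theme.
#' @return `path`, invisibly.
#' @export
write_theme_set <- function(x, path, n_terms = 10L) {
  stopifnot(inherits(x, "theme_set"))
  recs <- lapply(x$themes, function(th) {
    tt <- top_terms(th$consensus, n_terms)
    list(seed_id = th$seed_id,
         size = length(th$member_ids),
         member_ids = th$member_ids,
         member_scores = unname(th$scores[th$member_ids]),
         core_ids = th$core_ids,
         top_terms = as.list(tt),
         outer_iterations = th$outer_iterations,
         converged = th$converged,
         cycle = th$cycle)
  })
  payload <- list(version = package_version_string(),
                  control = unclass(x$control),
                  n_seeds = x$n_seeds, pruned = x$pruned,
                  themes = recs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized theme set
#'
#' @param path A file written by [write_theme_set()].
#' @return A list with `control`, `pruned`, `n_seeds` and `themes` (each a
#'   list with the serialized fields).  Consensus vectors are restored only
#'   as their stored top terms.
#' @export
read_theme_set <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  payload$themes <- lapply(payload$themes, function(th) {
    th$member_ids <- as.character(unlist(th$member_ids))
    th$core_ids <- as.character(unlist(th$core_ids))
    th$member_scores <- as.numeric(unlist(th$member_scores))
    th$top_terms <- unlist(th$top_terms)
    th
  })
  payload
}

package_version_string <- function() {
  paste0("themescape ", as.character(utils::packageVersion("themescape")))
}
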