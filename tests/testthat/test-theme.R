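test_that("document scores are the normalized-row dot products", {
  corpus <- tiny_block_corpus()
  phi <- as.numeric(run_projection(corpus$Xn[1:3, , drop = FALSE]))
  s <- score_documents(corpus, phi)
  Xn <- as.matrix(corpus$Xn)
  for (d in seq_along(s)) {
    expect_equal(unname(s[d]), sum(Xn[d, ] * phi), tolerance = 1e-12)
  }
  # a document vector parallel to phi scores exactly 1
  expect_equal(unname(score_documents(corpus, as.numeric(corpus$Xn[1, ]))[1]),
               1, tolerance = 1e-12)
  # a document outside phi's support scores 0
  phi_b1 <- as.numeric(corpus$Xn[1, ])
  expect_equal(unname(score_documents(corpus, phi_b1)["d04"]), 0)
})

test_that("top-m selection is score-ordered with ascending-id tie-breaks", {
  expect_equal(select_top_m(c(a = 3, b = 2, c = 1), 2L), c("a", "b"))
  expect_equal(select_top_m(c(z = 1, b = 1, k = 1), 2L), c("b", "k"))
  expect_error(select_top_m(c(a = 1), 2L), "cannot select")
  set.seed(11)
  s <- stats::setNames(round(stats::runif(40), 2), sprintf("d%02d", 1:40))
  full_sort <- names(s)[order(-s, names(s))]
  expect_equal(select_top_m(s, 7L), full_sort[1:7])
})

test_that("a theme seeded in a planted block stays inside the block", {
  gi <- generate_ideal_corpus(planted_spec(n_blocks = 3L, block_sizes = 30L,
                                           noise_rate = 0.05, seed = 19L))
  ctl <- theme_control(m = 10L)
  for (seed_doc in gi$corpus$doc_ids[c(1, 15, 31, 45, 61, 90)]) {
    th <- run_theme(gi$corpus, seed_doc, ctl)
    expect_true(all(gi$truth$labels[th$member_ids] ==
                      gi$truth$labels[[seed_doc]]))
    expect_true(th$converged)
    expect_true(all(th$core_ids %in% th$member_ids))
    expect_length(th$core_ids, 10L)
  }
})

test_that("a block of identical documents is its own fixed point", {
  texts <- c(rep("alpha beta gamma delta", 4),
             "omicron pi rho sigma", "tau upsilon phi chi",
             "omicron tau sigma chi")
  corpus <- build_corpus(docs_frame(texts), token_config(min_df = 1L))
  th <- run_theme(corpus, "d01", theme_control(m = 4L, min_theme_size = 2L))
  expect_setequal(th$core_ids, c("d01", "d02", "d03", "d04"))
  # consensus is the common direction of the duplicated block
  expect_equal(unname(th$scores[c("d01", "d02", "d03", "d04")]),
               rep(1, 4), tolerance = 1e-9)
})

test_that("converged themes are self-consistent fixed points", {
  gi <- generate_ideal_corpus(planted_spec(n_blocks = 4L, block_sizes = 25L,
                                           noise_rate = 0.05, seed = 23L))
  ctl <- theme_control(m = 10L)
  for (seed_doc in gi$corpus$doc_ids[c(3, 40, 70, 99)]) {
    th <- run_theme(gi$corpus, seed_doc, ctl)
    phi <- as.numeric(th$consensus)
    expect_equal(select_top_m(score_documents(gi$corpus, phi), ctl$m),
                 th$core_ids)
    rows <- gi$corpus$Xn[match(th$core_ids, gi$corpus$doc_ids), , drop = FALSE]
    refit <- run_projection(rows, phi0 = phi)
    expect_gte(abs(sum(as.numeric(refit) * phi)), 1 - 1e-8)
  }
})

test_that("degenerate seeds and unknown seeds are named errors", {
  docs <- docs_frame(c("aa bb cc", "aa bb dd", "zz yy xx", "qq ww ee"))
  corpus <- build_corpus(docs, token_config(min_df = 1L))
  expect_error(run_theme(corpus, "nope", theme_control(m = 2L)), "nope")
  # min_df = 2 empties documents with only singleton terms
  corpus2 <- build_corpus(docs, token_config(min_df = 2L))
  expect_error(run_theme(corpus2, "d03", theme_control(m = 2L)),
               "d03")
})

test_that("discover_themes output is independent of document order", {
  gen <- generate_corpus(planted_spec(n_blocks = 3L, block_sizes = 15L,
                                      noise_rate = 0.05, seed = 29L))
  ctl <- theme_control(m = 8L, min_theme_size = 5L)
  c1 <- build_corpus(gen$docs, token_config())
  set.seed(1)
  perm <- sample(nrow(gen$docs))
  c2 <- build_corpus(gen$docs[perm, , drop = FALSE], token_config())
  t1 <- discover_themes(c1, ctl)
  t2 <- discover_themes(c2, ctl)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_theme_set(t1, f1)
  write_theme_set(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("min_theme_size larger than the collection empties the sweep", {
  corpus <- tiny_block_corpus()
  ts <- discover_themes(corpus, theme_control(m = 2L, min_theme_size = 7L))
  expect_length(ts$themes, 0L)
})

test_that("pruning drops half-or-more overlap with a larger theme", {
  a <- stub_theme("s1", sprintf("d%02d", 1:10))
  b_low <- stub_theme("s2", c(sprintf("d%02d", 1:2), sprintf("x%02d", 1:4)))
  # 2 of 6 members inside the larger theme: below threshold, kept
  expect_length(prune_redundant(list(a, b_low), 0.5), 2L)
  # exactly half inside: the boundary is inclusive on the drop side
  b_half <- stub_theme("s2", c(sprintf("d%02d", 1:3), sprintf("x%02d", 1:3)))
  expect_length(prune_redundant(list(a, b_half), 0.5), 1L)
  # two identical themes: the first (smaller seed id) survives
  dup <- prune_redundant(list(stub_theme("s2", sprintf("d%02d", 1:5)),
                              stub_theme("s1", sprintf("d%02d", 1:5))), 0.5)
  expect_length(dup, 1L)
  expect_equal(dup[[1]]$seed_id, "s1")
})

test_that("pruning matches the quadratic-filter oracle on random sets", {
  set.seed(37)
  for (rep in 1:30) {
    n_themes <- sample(3:12, 1)
    pool <- sprintf("d%03d", 1:40)
    members <- lapply(seq_len(n_themes), function(i)
      sample(pool, sample(3:20, 1)))
    names(members) <- sprintf("s%02d", seq_len(n_themes))
    themes <- Map(stub_theme, names(members), members)
    kept <- prune_redundant(unname(themes), 0.5)
    expect_equal(sort(vapply(kept, function(t) t$seed_id, "")),
                 sort(oracle_prune(members, 0.5)))
    # retained pairwise overlap bound holds exactly
    for (i in seq_along(kept)) {
      for (j in seq_along(kept)) {
        if (i >= j) next
        small <- kept[[j]]$member_ids
        expect_lt(length(intersect(kept[[i]]$member_ids, small)) /
                    length(small), 0.5)
      }
    }
  }
})

test_that("greedy partition recovers disjoint planted blocks", {
  gi <- generate_ideal_corpus(planted_spec(n_blocks = 2L, block_sizes = 20L,
                                           noise_rate = 0.05, seed = 43L))
  ts <- discover_themes(gi$corpus, theme_control(m = 8L, min_theme_size = 5L))
  part <- greedy_partition(ts, gi$corpus, K = 2L, seed = 1L)
  ref <- labeled_partition(gi$truth)
  expect_equal(nmi(part, ref), 1)
  expect_equal(clustering_accuracy(part, ref), 1)
  expect_equal(nlevels(part), 2L)
  expect_error(greedy_partition(ts, gi$corpus, K = 50L, seed = 1L), "exceeds")
})

test_that("the greedy coverage objective is non-decreasing in K", {
  gen <- generate_corpus(planted_spec(n_blocks = 4L, block_sizes = 12L,
                                      noise_rate = 0.2, seed = 47L))
  corpus <- build_corpus(gen$docs)
  ts <- discover_themes(corpus, theme_control(m = 5L, min_theme_size = 3L),
                        prune = FALSE)
  S <- vapply(ts$themes, function(th) unname(th$scores[corpus$doc_ids]),
              numeric(length(corpus$doc_ids)))
  objective <- function(part) {
    sel <- match(levels(part), vapply(ts$themes, function(t) t$seed_id, ""))
    sum(apply(S[, sel, drop = FALSE], 1, max))
  }
  objs <- vapply(seq_len(min(5L, length(ts$themes))), function(K)
    objective(greedy_partition(ts, corpus, K, seed = 1L)), 0)
  expect_true(all(diff(objs) >= -1e-9))
})

test_that("within-theme similarity is the mean raw pairwise dot product", {
  corpus <- tiny_block_corpus()
  th <- stub_theme("d01", c("d01", "d02", "d03"))
  M <- as.matrix(corpus$dtm[1:3, ])
  acc <- 0
  for (i in 1:2) for (j in (i + 1):3) acc <- acc + sum(M[i, ] * M[j, ])
  expect_equal(within_theme_similarity(th, corpus), acc / 3,
               tolerance = 1e-12)
  # identical documents: similarity equals their shared squared norm
  dup <- build_corpus(docs_frame(c("aa bb", "aa bb", "cc dd", "cc ee")),
                      token_config(min_df = 1L))
  th2 <- stub_theme("d01", c("d01", "d02"))
  expect_equal(within_theme_similarity(th2, dup),
               sum(as.matrix(dup$dtm)[1, ]^2), tolerance = 1e-12)
  # disjoint support pairs score zero
  th3 <- stub_theme("d01", c("d01", "d03"))
  expect_equal(within_theme_similarity(th3, dup), 0)
  expect_error(within_theme_similarity(stub_theme("d01", "d01"), dup),
               "at least 2")
})

test_that("theme accessors expose the consensus vector and scores", {
  gi <- generate_ideal_corpus(planted_spec(n_blocks = 2L, block_sizes = 15L,
                                           noise_rate = 0.05, seed = 53L))
  th <- run_theme(gi$corpus, gi$corpus$doc_ids[[1]], theme_control(m = 6L))
  expect_s3_class(coef(th), "consensus_vector")
  expect_equal(sum(coef(th)^2), 1, tolerance = 1e-10)
  expect_equal(predict(th, gi$corpus), th$scores)
  res <- residuals(th, gi$corpus)
  expect_true(all(res >= -1e-10))
  expect_named(res, th$member_ids)
})
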