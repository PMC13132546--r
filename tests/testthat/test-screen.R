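fake_table <- function(lists) {
  lists <- lapply(lists, function(syms) {
    if (is.data.frame(syms)) return(syms)
    data.frame(symbol = syms, entrez = NA_integer_,
               r = rep(0.9, length(syms)), rank = seq_along(syms),
               n_pairs = 50L, stringsAsFactors = FALSE)
  })
  as_codependency_table(lists)
}

test_that("overlap scores count distinct supporting seeds", {
  one <- fake_table(list(S1 = c("A", "B", "C")))
  sc <- overlap_scores(one)
  expect_equal(sort(sc$symbol), c("A", "B", "C"))
  expect_equal(sc$score, c(1L, 1L, 1L))

  disjoint <- fake_table(list(S1 = c("A", "B"), S2 = c("C", "D")))
  expect_true(all(overlap_scores(disjoint)$score == 1L))

  shared <- fake_table(list(S1 = c("A", "B"), S2 = c("A", "C"),
                            S3 = c("A", "B")))
  sc3 <- overlap_scores(shared)
  expect_equal(sc3$score[sc3$symbol == "A"], 3L)
  expect_equal(sc3$score[sc3$symbol == "B"], 2L)
  expect_equal(sc3$score[sc3$symbol == "C"], 1L)
  # sorted by score desc then symbol
  expect_equal(sc3$symbol, c("A", "B", "C"))
})

test_that("overlap scores satisfy conservation and the seed-count bound", {
  sim <- simulate_effect_matrix(25, 60, noise_sd = 1, rng_seed = 31)
  seeds <- seed_list(sprintf("G%03d", 1:6))
  tab <- build_codependency_table(sim$matrix, seeds, k = 8, min_pairs = 10)
  sc <- overlap_scores(tab)
  expect_equal(sum(sc$score), sum(vapply(tab, nrow, integer(1))))
  expect_true(max(sc$score) <= length(seeds$symbol))
  expect_true(all(sc$score >= 1L))
})

test_that("planted-module screen recovers the module, matching the intersection oracle", {
  sim <- simulate_effect_matrix(
    40, 100, modules = list(module_spec(1:6, loading = 1)),
    noise_sd = 0.5, rng_seed = 77)
  seeds <- seed_list(sprintf("G%03d", 1:4))
  tab <- build_codependency_table(sim$matrix, seeds, k = 5)
  sc <- overlap_scores(tab)
  want <- oracle_overlap_counts(unclass(tab))
  got <- structure(sc$score, names = paste(sc$symbol, sc$entrez, sep = "|"))
  expect_mapequal(as.list(got), as.list(want))
  # the two non-seed module members are supported by all 4 seed lists
  expect_true(all(sc$score[sc$symbol %in% c("G005", "G006")] == 4L))
})

test_that("score cutoff honors the attained-score definition and its oracle", {
  expect_equal(score_cutoff(c(1, 1, 5), top_fraction = 0.34), 5L)
  expect_warning(cut_all <- score_cutoff(c(2, 2, 2), top_fraction = 0.2),
                 "max")
  expect_equal(cut_all, 3L)
  set.seed(99)
  for (i in 1:10) {
    scores <- sample(1:12, 200, replace = TRUE, prob = 1 / (1:12))
    tf <- runif(1, 0.02, 0.3)
    expect_equal(suppressWarnings(score_cutoff(scores, tf)),
                 suppressWarnings(oracle_score_cutoff(scores, tf)))
  }
})

test_that("screen results report the achieved top fraction and candidate set", {
  tab <- fake_table(list(S1 = c("A", "B", "X"), S2 = c("A", "S1", "X"),
                         S3 = c("A", "D", "S1")))
  res <- run_screen(tab, cutoff = 2)
  expect_s3_class(res, "screen_result")
  expect_equal(res$cutoff, 2L)
  expect_equal(res$top_fraction_achieved,
               mean(res$records$score >= 2))
  hits <- candidate_hits(res, exclude_seeds = FALSE)
  expect_equal(sort(hits$symbol), c("A", "S1", "X"))
  # excluding seeds removes exactly the seed-symbol rows
  hits2 <- candidate_hits(res, exclude_seeds = TRUE)
  expect_equal(setdiff(hits$symbol, hits2$symbol), "S1")
  # cutoff above the maximum score: empty candidate table
  res9 <- run_screen(tab, cutoff = 9)
  expect_equal(nrow(candidate_hits(res9)), 0L)
  # derived cutoff path
  res_tf <- suppressWarnings(run_screen(tab, cutoff = NULL, top_fraction = 0.2))
  expect_equal(res_tf$cutoff,
               suppressWarnings(score_cutoff(res_tf$records, 0.2)))
})

test_that("raising k never lowers scores; raising the cutoff never grows the candidate set", {
  sim <- simulate_effect_matrix(
    30, 80, modules = list(module_spec(1:5, loading = 0.9)),
    noise_sd = 0.7, rng_seed = 13)
  seeds <- seed_list(sprintf("G%03d", 1:4))
  sc_small <- overlap_scores(build_codependency_table(sim$matrix, seeds, k = 4))
  sc_big <- overlap_scores(build_codependency_table(sim$matrix, seeds, k = 10))
  m <- match(sc_small$symbol, sc_big$symbol)
  expect_false(anyNA(m))
  expect_true(all(sc_big$score[m] >= sc_small$score))
  res <- run_screen(sim$matrix, seeds, k = 10, cutoff = 2)
  n_by_cutoff <- vapply(1:5, function(cut) {
    res$cutoff <- cut
    nrow(candidate_hits(res))
  }, integer(1))
  expect_true(all(diff(n_by_cutoff) <= 0))
})

test_that("screen outputs serialize with a deterministic order", {
  tab <- fake_table(list(S1 = c("B", "A"), S2 = c("B", "A")))
  res <- run_screen(tab, cutoff = 1)
  dir <- withr::local_tempdir()
  write_screen_result(res, dir)
  tbl <- read_result_table(file.path(dir, "scores.tsv"))
  expect_equal(tbl$symbol, c("A", "B"))  # tie on score, symbol ascending
  expect_true(file.exists(file.path(dir, "screen_params.cfg")))
})
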