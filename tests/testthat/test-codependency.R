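test_that("pairwise correlation matches identity, antisymmetry and the textbook formula", {
  x <- c(1, 2, 3, 4)
  em <- make_em(cbind(x, -x, c(2, 1, 4, 3)), symbols = c("A", "NEG", "B"))
  expect_equal(pairwise_correlation(em, "A", "A", min_pairs = 3), 1)
  expect_equal(pairwise_correlation(em, "A", "NEG", min_pairs = 3), -1)
  # hand-computed: sum of cross-deviations 3, both sums of squares 5 -> 3/5
  expect_equal(pairwise_correlation(em, "A", "B", min_pairs = 3), 0.6)
  expect_equal(oracle_pearson(x, c(2, 1, 4, 3)), 0.6)
})

test_that("pairwise correlation returns NA for sparse or constant profiles", {
  vals <- cbind(c(1, 2, 3, NA, NA), c(1, NA, NA, 2, 3), rep(1, 5),
                c(5, 4, 3, 2, 1))
  em <- suppressWarnings(make_em(vals, symbols = c("A", "B", "CONST", "D")))
  expect_true(is.na(pairwise_correlation(em, "A", "B", min_pairs = 3)))
  expect_true(is.na(pairwise_correlation(em, "CONST", "D", min_pairs = 3)))
  expect_error(pairwise_correlation(em, "A", "NOPE", min_pairs = 3), "NOPE")
})

test_that("correlations are symmetric and invariant to positive affine maps", {
  set.seed(11)
  sim <- simulate_effect_matrix(12, 40, noise_sd = 1, missing_rate = 0.1,
                                rng_seed = 11)
  em <- sim$matrix
  syms <- em$genes$symbol
  for (pair in list(c(1, 2), c(3, 9), c(5, 12))) {
    a <- syms[pair[1]]; b <- syms[pair[2]]
    expect_identical(pairwise_correlation(em, a, b, min_pairs = 5),
                     pairwise_correlation(em, b, a, min_pairs = 5))
  }
  em2 <- em
  em2$values[, 3] <- 2.5 * em2$values[, 3] + 7
  for (j in c(1, 5, 10)) {
    expect_equal(pairwise_correlation(em2, syms[3], syms[j], min_pairs = 5),
                 pairwise_correlation(em, syms[3], syms[j], min_pairs = 5),
                 tolerance = 1e-12)
  }
})

test_that("top-k handles small universes and perfect correlates", {
  set.seed(3)
  vals <- matrix(rnorm(5 * 20), ncol = 5)
  vals[, 2] <- vals[, 1]  # duplicate of the first profile
  em <- make_em(vals, symbols = c("SEED", "TWIN", "C", "D", "E"))
  top <- top_k_codependencies(em, "SEED", k = 10, min_pairs = 5)
  expect_equal(nrow(top), 4L)  # whole universe minus self
  expect_equal(top$symbol[1], "TWIN")
  expect_equal(top$r[1], 1)
  expect_false("SEED" %in% top$symbol)
  expect_equal(top$rank, 1:4)
})

test_that("top-k equals the exhaustive full-sort oracle on synthetic matrices", {
  sim <- simulate_effect_matrix(
    30, 50, modules = list(module_spec(1:5, loading = 0.8)),
    noise_sd = 0.6, missing_rate = 0.05, rng_seed = 19)
  em <- sim$matrix
  for (seed in c("G001", "G007", "G025")) {
    for (ranking in c("absolute", "signed_positive")) {
      got <- top_k_codependencies(em, seed, k = 5, ranking = ranking,
                                  min_pairs = 10)
      want <- oracle_top_k(em, seed, k = 5, ranking = ranking, min_pairs = 10)
      expect_equal(got$symbol, want$symbol)
      expect_equal(got$r, want$r, tolerance = 1e-12)
    }
  }
})

test_that("codependency tables skip absent seeds and respect symmetry", {
  set.seed(5)
  vals <- matrix(rnorm(6 * 30), ncol = 6)
  vals[, 2] <- vals[, 1]
  em <- make_em(vals, symbols = c("A", "B", "C", "D", "E", "F"))
  expect_warning(
    tab <- build_codependency_table(em, seed_list(c("A", "B", "ZZZ")),
                                    k = 3, min_pairs = 5),
    "ZZZ")
  expect_named(tab, c("A", "B"))
  expect_equal(attr(tab, "skipped_seeds"), "ZZZ")
  # identical profiles: same partners apart from the mutual exclusion
  expect_equal(setdiff(tab$A$symbol, "B"), setdiff(tab$B$symbol, "A"))
  expect_error(build_codependency_table(em, seed_list("NOPE")), "none of the seed")
  one <- build_codependency_table(em, seed_list("C"), k = 2, min_pairs = 5)
  expect_length(one, 1L)
})

test_that("precomputed per-seed top-k lists reproduce the correlation path", {
  sim <- simulate_effect_matrix(20, 40, noise_sd = 1, rng_seed = 23)
  seeds <- seed_list(c("G001", "G002", "G003"))
  tab <- build_codependency_table(sim$matrix, seeds, k = 6, min_pairs = 10)
  dir <- withr::local_tempdir()
  write_codependency_table(tab, dir)
  paths <- file.path(dir, paste0("codep_", names(tab), ".tsv"))
  names(paths) <- names(tab)
  tab2 <- read_precomputed_codependency(paths, k = 6)
  expect_equal(names(tab2), names(tab))
  for (s in names(tab)) {
    expect_equal(tab2[[s]]$symbol, tab[[s]]$symbol)
    expect_equal(tab2[[s]]$r, signif(tab[[s]]$r, 6))
  }
  # and the screen gives identical scores from either representation
  s1 <- run_screen(tab)
  s2 <- run_screen(tab2)
  expect_equal(s2$records$score, s1$records$score)
  expect_equal(s2$records$symbol, s1$records$symbol)
})
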