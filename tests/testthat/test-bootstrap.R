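toy_records <- function() {
  rec <- make_records(cov = c(0.95, 0.9, 0.8, 0.7, 0.6),
                      modp = c(0.6, 0.7, 0.75, 0.8, 0.85),
                      members = c("A", "A;B", "B;C", "A;B;C", "C"))
  rec$is_pareto <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  rec
}

test_that("observed composition counts models and averages sizes", {
  rec <- toy_records()
  obs <- observed_composition(rec)
  # front: {A}, {A,B}, {C} -> sizes 1, 2, 1
  expect_equal(obs$per_model, c(A = 2, B = 1, C = 1))
  expect_equal(obs$mean_size, 4 / 3)
  expect_equal(sum(obs$per_model), sum(c(1, 2, 1)))   # conservation

  sizes <- make_records(cov = c(0.9, 0.8, 0.7), modp = c(0.7, 0.8, 0.9),
                        members = c("A", "A;B", "B;C"))
  sizes$is_pareto <- TRUE
  expect_equal(observed_composition(sizes)$mean_size, 5 / 3,
               tolerance = 1e-12)

  single <- make_records(0.9, 0.9, members = "A;B")
  single$is_pareto <- TRUE
  obs1 <- observed_composition(single)
  expect_equal(obs1$per_model, c(A = 1, B = 1))
  expect_equal(obs1$mean_size, 2)

  rec$is_pareto <- FALSE
  expect_error(observed_composition(rec), "no Pareto")
})

test_that("shuffles preserve the front size and are seed-deterministic", {
  rec <- toy_records()
  n1 <- shuffle_null(rec, n_iter = 50, seed = 9)
  n2 <- shuffle_null(rec, n_iter = 50, seed = 9)
  expect_identical(n1, n2)
  expect_true(all(rowSums(n1$counts > 0) >= 1))
  # each shuffle samples exactly 3 records; total membership per
  # iteration is the sum of the three sampled record sizes, which for
  # sizes {1, 2, 2, 3, 1} lies in [4, 7]
  totals <- rowSums(n1$counts)
  expect_true(all(totals >= 4 & totals <= 7))

  # a model present in every record has a constant null count
  allA <- make_records(cov = c(0.9, 0.8, 0.7), modp = c(0.6, 0.7, 0.8),
                       members = c("A", "A;B", "A;C"))
  allA$is_pareto <- c(TRUE, TRUE, FALSE)
  nullA <- shuffle_null(allA, n_iter = 30, seed = 2)
  expect_true(all(nullA$counts[, "A"] == 2))
})

test_that("null per-model frequencies match the sampling expectation", {
  panel <- small_panel(seed = 15L, n = 200L)
  rec <- annotate_pareto(evaluate_all(panel$table, panel$labels,
                                      schemes = c("majority", "ba")))
  null <- shuffle_null(rec, n_iter = 10000, seed = 4)
  k <- sum(rec$is_pareto)
  mem <- strsplit(rec$members, ";", fixed = TRUE)
  for (m in colnames(null$counts)) {
    appear <- mean(vapply(mem, function(x) m %in% x, logical(1)))
    expected <- k * appear   # hypergeometric mean under uniform sampling
    expect_lt(abs(mean(null$counts[, m]) - expected), 0.1)
  }
})

test_that("exceedance is one-sided and inclusive of equality", {
  expect_equal(exceedance(1, c(2, 3, 4), "le"), 0)
  expect_equal(exceedance(5, c(5, 5, 5), "le"), 1)
  expect_equal(exceedance(5, c(5, 5, 5), "ge"), 1)
  expect_equal(exceedance(3, c(1, 2, 3, 4), "ge"), 0.5)
})

test_that("empirical exceedances match exact enumeration on a toy front", {
  rec <- toy_records()
  k <- sum(rec$is_pareto)
  obs <- observed_composition(rec)
  # exact oracle: enumerate all C(5, 3) = 10 equally likely label
  # assignments and tally the composition statistics directly
  mem <- strsplit(rec$members, ";", fixed = TRUE)
  subsets <- utils::combn(nrow(rec), k, simplify = FALSE)
  models <- c("A", "B", "C")
  exact_counts <- t(vapply(subsets, function(idx) {
    vapply(models, function(m)
      sum(vapply(mem[idx], function(x) m %in% x, logical(1))), numeric(1))
  }, numeric(3)))
  exact_sizes <- vapply(subsets, function(idx)
    mean(lengths(mem[idx])), numeric(1))

  null <- shuffle_null(rec, n_iter = 20000, seed = 7)
  for (j in seq_along(models)) {
    for (dir in c("le", "ge")) {
      expect_equal(exceedance(obs$per_model[[j]], null$counts[, j], dir),
                   exceedance(obs$per_model[[j]], exact_counts[, j], dir),
                   tolerance = 0.02,
                   info = sprintf("model %s, %s", models[j], dir))
    }
  }
  expect_equal(exceedance(obs$mean_size, null$mean_sizes, "le"),
               exceedance(obs$mean_size, exact_sizes, "le"),
               tolerance = 0.02)
})

test_that("the report is reproducible and calls tails at the 5% level", {
  rec <- toy_records()
  r1 <- bootstrap_pareto(rec, n_iter = 400, seed = 12)
  r2 <- bootstrap_pareto(rec, n_iter = 400, seed = 12)
  expect_identical(r1$report, r2$report)
  expect_equal(nrow(r1$report), 4L)   # 3 models + mean size
  expect_true(all(r1$report$exceedance >= 0 & r1$report$exceedance <= 1))
  expect_equal(r1$report$significant, r1$report$exceedance < 0.05)
  # a statistic at its null mode is not a tail event
  mode_rows <- abs(r1$report$observed - r1$report$null_mean) < 0.5
  expect_true(all(r1$report$exceedance[mode_rows] > 0.05))
})
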