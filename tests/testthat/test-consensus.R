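four_models <- c("m1", "m2", "m3", "m4")

test_that("weight derivation matches the member metrics of each scheme", {
  ex <- ba_weighting_example()
  maj <- derive_weights(consensus_spec(four_models, "majority"),
                        ex$table, ex$labels)
  expect_equal(unname(maj), rep(1, 4))

  ba <- derive_weights(consensus_spec(four_models, "ba"),
                       ex$table, ex$labels)
  expect_equal(ba, c(m1 = 0.8, m2 = 0.75, m3 = 0.65, m4 = 0.6))
  expect_equal(sum(ba), 2.8)

  # modified-score1 weights are BA weights times member coverages,
  # recomputed independently per member
  panel <- small_panel(seed = 21L, n = 200L)
  ids <- colnames(panel$table)
  w_ba <- derive_weights(consensus_spec(ids, "ba"),
                         panel$table, panel$labels)
  w_ms1 <- derive_weights(consensus_spec(ids, "mod_score1"),
                          panel$table, panel$labels)
  covs <- vapply(ids, function(m) coverage(unclass(panel$table)[, m]),
                 numeric(1))
  expect_equal(w_ms1, w_ba * covs)

  expect_error(derive_weights(consensus_spec(ids, "knn"),
                              panel$table, panel$labels), "per-chemical")
})

test_that("the weighted-majority AD rule counts equality as inside", {
  w <- c(m1 = 0.8, m2 = 0.75, m3 = 0.65, m4 = 0.6)
  expect_false(in_consensus_ad(w, c(FALSE, TRUE, FALSE, TRUE)))  # 1.35 < 1.4
  expect_true(in_consensus_ad(w, c(TRUE, FALSE, FALSE, TRUE)))   # 1.40 >= 1.4
  expect_true(in_consensus_ad(w, c(TRUE, FALSE, TRUE, FALSE)))   # 1.45 > 1.4
  expect_true(in_consensus_ad(w, rep(TRUE, 4)))
  set.seed(5)
  for (trial in 1:10) {
    wr <- stats::runif(5, 0.1, 1)
    expect_true(in_consensus_ad(wr, rep(TRUE, 5)))
  }
})

test_that("weighted votes compare summed weights with a documented tie-break", {
  w <- c(m1 = 0.8, m2 = 0.75, m3 = 0.65, m4 = 0.6)
  preds <- c(m1 = "active", m2 = "inactive", m3 = "active", m4 = "inactive")
  expect_equal(weighted_vote(w, preds), "active")       # 1.45 > 1.35

  expect_equal(weighted_vote(c(mX = 1), c(mX = "inactive")), "inactive")

  even <- c(a = 1, b = 1, c = 1, d = 1)
  split <- c(a = "active", b = "active", c = "inactive", d = "inactive")
  expect_equal(weighted_vote(even, split), "active")
  expect_equal(weighted_vote(even, split, tie_break = "inactive"),
               "inactive")

  # out-of-domain members cast no vote
  expect_equal(weighted_vote(w, c(m1 = "out_of_domain", m2 = "inactive",
                                  m3 = "active", m4 = "out_of_domain")),
               "inactive")  # 0.65 < 0.75
  expect_error(weighted_vote(w, rep("out_of_domain", 4)), "no in-domain")
})

test_that("kNN weights decrease with descriptor-space distance", {
  set.seed(33)
  refA <- matrix(0, nrow = 15, ncol = 3)       # all at the origin
  refB <- matrix(5, nrow = 15, ncol = 3)       # far cluster
  w <- knn_weights(rep(0, 3), list(A = refA, B = refB), k = 5)
  expect_equal(unname(w[1, "A"]), 1)           # d = 0 limit
  expect_lt(w[1, "B"], w[1, "A"])

  # identical reference sets give equal weights (vote reduces to majority)
  ref <- matrix(stats::rnorm(60), ncol = 3)
  w2 <- knn_weights(c(1, 0, -1), list(A = ref, B = ref), k = 4)
  expect_equal(unname(w2[1, "A"]), unname(w2[1, "B"]))

  expect_error(knn_weights(rep(0, 2), list(A = refA), k = 5), "dimension")
  expect_error(knn_weights(rep(0, 3), list(A = refA), k = 50), "k = 50")
})

test_that("kNN mean distances match an exhaustive pairwise sort", {
  set.seed(44)
  for (trial in 1:5) {
    ref <- matrix(stats::rnorm(20 * 4), ncol = 4)
    q <- stats::rnorm(4)
    k <- sample(1:12, 1)
    # oracle: all 20 distances, fully sorted
    d_all <- sort(apply(ref, 1, function(r) sqrt(sum((r - q)^2))))
    d_oracle <- mean(d_all[seq_len(k)])
    w <- knn_weights(q, list(A = ref), k = k)
    expect_equal(unname(w[1, "A"]), 1 / (1 + d_oracle), tolerance = 1e-12)
  }
})

test_that("run_consensus composes AD rule and vote per chemical", {
  ex <- ba_weighting_example()
  spec <- consensus_spec(four_models, "ba")
  out <- run_consensus(spec, ex$table, ex$labels, newdata = ex$queries)
  expect_equal(out, ex$expected)

  # consensus outcome is out_of_domain exactly where the AD rule fails
  panel <- small_panel(seed = 55L, n = 150L)
  ids <- colnames(panel$table)
  sp2 <- consensus_spec(ids, "modp")
  w <- derive_weights(sp2, panel$table, panel$labels)
  pred <- run_consensus(sp2, panel$table, panel$labels)
  for (chem in sample(rownames(panel$table), 40)) {
    flags <- unclass(panel$table)[chem, ids] != "out_of_domain"
    expect_equal(pred[[chem]] == "out_of_domain",
                 !in_consensus_ad(w, flags))
  }
  # if every member covers a chemical, the consensus covers it
  all_in <- rowSums(unclass(panel$table) == "out_of_domain") == 0
  expect_true(all(pred[all_in] != "out_of_domain"))
})

test_that("single-member specs are passthroughs of the component model", {
  panel <- small_panel(seed = 66L, n = 120L)
  for (m in colnames(panel$table)) {
    out <- run_consensus(consensus_spec(m, "component"),
                         panel$table, panel$labels)
    expect_equal(unname(out), unname(unclass(panel$table)[, m]))
  }
})

test_that("a duplicated component model yields the component's predictions", {
  panel <- small_panel(seed = 67L, n = 120L)
  tab <- unclass(panel$table)
  dup <- prediction_table(cbind(tab[, c("m1", "m2")],
                                m2b = tab[, "m2"]))
  base <- unclass(panel$table)[, "m2"]
  for (scheme in c("majority", "ba", "modp")) {
    out <- run_consensus(consensus_spec(c("m2", "m2b"), scheme),
                         dup, panel$labels)
    expect_equal(unname(out), unname(base))
  }
})

test_that("member order does not change consensus predictions", {
  panel <- small_panel(seed = 68L, n = 150L)
  ids <- colnames(panel$table)
  for (scheme in c("majority", "ba", "knn")) {
    a <- run_consensus(consensus_spec(ids, scheme),
                       panel$table, panel$labels,
                       descriptors = panel$descriptors)
    b <- run_consensus(consensus_spec(rev(ids), scheme),
                       panel$table, panel$labels,
                       descriptors = panel$descriptors)
    expect_equal(a, b)
  }
})

test_that("majority is the special case of equal member metrics", {
  ex <- ba_weighting_example()
  tab <- unclass(ex$table)
  # two copies of the same model: every statistic scheme gives equal
  # weights, so all schemes agree with plain majority
  pair <- prediction_table(cbind(x = tab[, "m1"], y = tab[, "m1"],
                                 z = tab[, "m2"]))
  maj <- run_consensus(consensus_spec(c("x", "y", "z"), "majority"),
                       pair, ex$labels)
  for (scheme in c("ba", "mod_score1", "predictivity", "modp")) {
    w <- derive_weights(consensus_spec(c("x", "y"), scheme), pair,
                        ex$labels)
    expect_equal(w[["x"]], w[["y"]])
  }
  expect_equal(length(maj), nrow(tab))
})
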