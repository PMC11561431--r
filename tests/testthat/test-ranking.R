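# a small numeric-matrix world keeps the forest tests independent of the
# questionnaire plumbing
toy_matrix <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(sample(1:5, n * p, TRUE), n, p,
              dimnames = list(NULL, sprintf("v%02d", seq_len(p))))
  x
}

test_that("a perfectly separable toy is classified almost perfectly", {
  x <- toy_matrix(500, 4, 1)
  oc <- factor(ifelse(x[, 1] <= 2, "positive", "neutral_negative"),
               levels = c("positive", "neutral_negative"))
  fit <- fit_forest(x, oc, ranking_config(n_trees = 300, seed = 2))
  expect_gte(fit$metrics$auc, 0.98)
  expect_lt(fit$metrics$pmc, 0.05)
})

test_that("pure-noise predictors give chance-level AUC and ~zero importance", {
  x <- toy_matrix(2000, 6, 3)
  set.seed(4)
  oc <- factor(sample(c("positive", "neutral_negative"), 2000, TRUE,
                      prob = c(0.76, 0.24)),
               levels = c("positive", "neutral_negative"))
  fit <- fit_forest(x, oc, ranking_config(n_trees = 1000, seed = 5))
  expect_lt(abs(fit$metrics$auc - 0.5), 0.05)
  imp <- permutation_importance(fit)
  expect_true(all(abs(imp$entries$importance) < 0.005))
})

test_that("OOB metrics satisfy the pmc/sens/spec/prevalence identity", {
  d <- synthetic_design(n_respondents = 800, n_clusters = 2,
                        items_per_cluster = c(3, 3), n_noise_items = 2,
                        effect = c(1.5, 1), seed = 6)
  sim <- generate_responses(d)
  resp <- harmonize_responses(sim$responses, sim$codebook)
  oc <- dichotomize_intention(resp$intention)
  fit <- fit_forest(resp, oc, ranking_config(n_trees = 300, seed = 7))
  m <- fit$metrics
  votes <- fit$oob_votes
  seen <- rowSums(votes) > 0
  prev <- mean(fit$y[seen] == 0)
  expect_equal(m$pmc, prev * (1 - m$sens) + (1 - prev) * (1 - m$spec),
               tolerance = 1e-12)
  expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
})

test_that("fixed seeds make fit, metrics, and ranking bit-reproducible", {
  x <- toy_matrix(300, 5, 8)
  oc <- factor(ifelse(x[, 2] + x[, 3] <= 5, "positive", "neutral_negative"),
               levels = c("positive", "neutral_negative"))
  cfg <- ranking_config(n_trees = 200, seed = 9)
  r1 <- permutation_importance(fit_forest(x, oc, cfg))
  r2 <- permutation_importance(fit_forest(x, oc, cfg))
  expect_identical(r1$entries, r2$entries)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("duplicating the signal column splits its importance", {
  set.seed(10)
  n <- 1500
  x1 <- matrix(c(sample(1:5, n, TRUE), sample(1:5, n, TRUE)), n, 2,
               dimnames = list(NULL, c("signal", "filler")))
  oc <- factor(ifelse(x1[, "signal"] + rnorm(n, sd = 0.5) <= 2.5,
                      "positive", "neutral_negative"),
               levels = c("positive", "neutral_negative"))
  cfg <- ranking_config(n_trees = 400, seed = 11)
  base <- permutation_importance(fit_forest(x1, oc, cfg))
  base_imp <- base$entries$importance[base$entries$item == "signal"]

  x2 <- cbind(x1, signal_copy = x1[, "signal"])
  dup <- permutation_importance(fit_forest(x2, oc, cfg))
  for (it in c("signal", "signal_copy")) {
    expect_lt(dup$entries$importance[dup$entries$item == it], base_imp)
  }
})

test_that("ranking is sorted with deterministic tie-breaks and ranks 1..p", {
  x <- toy_matrix(200, 6, 12)
  oc <- factor(ifelse(x[, 1] <= 3, "positive", "neutral_negative"),
               levels = c("positive", "neutral_negative"))
  r <- permutation_importance(fit_forest(x, oc,
                                         ranking_config(n_trees = 150,
                                                        seed = 13)))
  e <- r$entries
  expect_equal(e$rank, seq_len(nrow(e)))
  expect_true(all(diff(e$importance) <= 0))
  ties <- split(e$item, e$importance)
  expect_true(all(vapply(ties, function(v) !is.unsorted(v), TRUE)))
})

test_that("select_determinants honors top_k and rejects bad values", {
  x <- toy_matrix(200, 6, 14)
  oc <- factor(ifelse(x[, 1] <= 3, "positive", "neutral_negative"),
               levels = c("positive", "neutral_negative"))
  r <- permutation_importance(fit_forest(x, oc,
                                         ranking_config(n_trees = 150,
                                                        seed = 15)))
  expect_equal(select_determinants(r, 6), r$entries$item)
  expect_length(select_determinants(r, 3), 3)
  expect_error(select_determinants(r, 7), "top_k")
  expect_error(select_determinants(r, 0), "top_k")
})

test_that("degenerate inputs are refused", {
  x <- toy_matrix(50, 3, 16)
  oc_one <- factor(rep("positive", 50),
                   levels = c("positive", "neutral_negative"))
  expect_error(fit_forest(x, oc_one, ranking_config(n_trees = 100)),
               "single class")
  expect_error(ranking_config(n_trees = 50), "n_trees")
})

test_that("plot_vir writes a dot chart file", {
  x <- toy_matrix(150, 3, 17)
  oc <- factor(ifelse(x[, 1] <= 3, "positive", "neutral_negative"),
               levels = c("positive", "neutral_negative"))
  r <- permutation_importance(fit_forest(x, oc,
                                         ranking_config(n_trees = 100,
                                                        seed = 18)))
  f <- withr::local_tempfile(fileext = ".pdf")
  plot_vir(r, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
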