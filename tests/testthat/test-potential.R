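grp <- function(pos, neg) {
  factor(rep(c("positive", "neutral_negative"), c(pos, neg)),
         levels = c("positive", "neutral_negative"))
}

test_that("cohens_d: hand-computed worked examples and sign convention", {
  g <- grp(3, 3)
  # positive group {1,2,3}, neutral/negative {2,3,4}: pooled SD 1, d = 1
  res <- cohens_d(c(1, 2, 3, 2, 3, 4), g)
  expect_equal(res$d, 1, tolerance = 1e-15)
  expect_equal(res$se, sqrt(1 / 3 + 1 / 3 + 1 / 12))
  expect_equal(res$ci, res$d + c(-1, 1) * qnorm(0.975) * res$se)

  # identical distributions -> d = 0
  expect_equal(cohens_d(c(1, 2, 3, 1, 2, 3), g)$d, 0)

  # favorable (lower) scores in the positive group give positive d
  expect_gt(cohens_d(c(1, 1, 2, 4, 4, 5), g)$d, 0)
  expect_lt(cohens_d(c(4, 4, 5, 1, 1, 2), g)$d, 0)
})

test_that("cohens_d refuses degenerate groups", {
  expect_error(cohens_d(c(1, 2, 3), grp(1, 2)), "at least 2")
  expect_error(cohens_d(c(2, 2, 2, 2), grp(2, 2)), "pooled SD")
})

test_that("mean_ci is the t interval", {
  res <- mean_ci(1:5)
  expect_equal(res$mean, 3)
  half <- qt(0.975, 4) * sd(1:5) / sqrt(5)
  expect_equal(res$ci, c(3 - half, 3 + half))
  expect_equal(res$ci, c(1.0368, 4.9632), tolerance = 1e-4)

  expect_equal(mean_ci(rep(2, 10))$ci, c(2, 2)) # zero-width for constants
  expect_error(mean_ci(3), "at least 2")

  # width shrinks as 1/sqrt(n)
  set.seed(1)
  w <- vapply(c(100, 400, 1600), function(n) {
    ci <- mean_ci(rnorm(n))$ci
    ci[2] - ci[1]
  }, 0)
  expect_equal(w[1] / w[2], 2, tolerance = 0.3)
  expect_equal(w[2] / w[3], 2, tolerance = 0.3)
})

test_that("compute_pci follows |1 - mean| * d^2 with its zeros and bounds", {
  expect_equal(round(compute_pci(2.81, 0.78), 2), 1.10)
  expect_equal(round(compute_pci(2.12, 0.68), 2), 0.52)
  expect_equal(compute_pci(1, 0.9), 0)
  expect_equal(compute_pci(3, 0), 0)
  expect_error(compute_pci(0.5, 1), "1-5")
  expect_error(compute_pci(5.2, 1), "1-5")

  # strictly increasing in mean at fixed d and in |d| at fixed mean
  means <- seq(1.1, 5, by = 0.3)
  expect_true(all(diff(compute_pci(means, 0.7)) > 0))
  ds <- seq(0.1, 1.5, by = 0.1)
  expect_true(all(diff(vapply(ds, compute_pci, 0, mean = 2.5)) > 0))
  expect_equal(compute_pci(2.5, -0.6), compute_pci(2.5, 0.6))
})

test_that("change_potential_table emits consistent, PCI-sorted records", {
  d <- synthetic_design(n_respondents = 600, n_clusters = 2,
                        items_per_cluster = c(3, 2), n_noise_items = 0,
                        effect = c(1.5, 0.8), seed = 9)
  sim <- generate_responses(d)
  resp <- harmonize_responses(sim$responses, sim$codebook)
  oc <- dichotomize_intention(resp$intention)
  assignment <- setNames(
    as.integer(factor(sim$true_assignment)),
    names(sim$true_assignment)
  )
  tab <- change_potential_table(resp, oc, assignment)

  expect_equal(nrow(tab), 5 + 2) # one record per item plus per cluster
  expect_equal(sum(tab$level == "cluster"), 2)

  # PCI internal consistency to machine precision
  expect_true(all(abs(tab$pci - abs(1 - tab$mean) * tab$d^2) < 1e-12))

  # intervals bracket their point estimates
  expect_true(all(tab$d_lo <= tab$d & tab$d <= tab$d_hi))
  expect_true(all(tab$pos_lo <= tab$mean_pos & tab$mean_pos <= tab$pos_hi))

  # items sorted by pci descending within each cluster, cluster row last
  for (cl in unique(tab$cluster)) {
    block <- tab[tab$cluster == cl, ]
    expect_equal(block$level[nrow(block)], "cluster")
    items <- block$pci[block$level == "item"]
    expect_true(all(diff(items) <= 0))
  }

  # cluster score is the respondent-level mean of member items
  mem <- names(assignment)[assignment == 1]
  expect_equal(tab$mean[tab$entity == "cluster_1"],
               mean(rowMeans(resp[mem])))
})

test_that("estimated d is unbiased for a planted group shift", {
  b <- calibrate_effect(0.8, loading = 0.85)
  ds <- vapply(1:10, function(s) {
    d <- synthetic_design(n_respondents = 2000, n_clusters = 1,
                          items_per_cluster = 2, n_noise_items = 0,
                          effect = b, seed = 300 + s)
    sim <- generate_responses(d)
    oc <- dichotomize_intention(sim$responses$intention)
    cohens_d(sim$responses$b1_i1, oc)$d
  }, 0)
  expect_lt(abs(mean(ds) - 0.8), 0.05)
})

test_that("plot_ciber renders both levels deterministically", {
  d <- synthetic_design(n_respondents = 300, n_clusters = 2,
                        items_per_cluster = c(2, 2), n_noise_items = 0,
                        effect = c(1.5, 1), seed = 10)
  sim <- generate_responses(d)
  resp <- harmonize_responses(sim$responses, sim$codebook)
  oc <- dichotomize_intention(resp$intention)
  assignment <- setNames(as.integer(factor(sim$true_assignment)),
                         names(sim$true_assignment))
  tab <- change_potential_table(resp, oc, assignment)

  f1 <- withr::local_tempfile(fileext = ".pdf")
  f2 <- withr::local_tempfile(fileext = ".pdf")
  plot_ciber(tab, resp, oc, assignment, level = "item", file = f1, seed = 3)
  plot_ciber(tab, resp, oc, assignment, level = "cluster", file = f2,
             seed = 3)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  expect_true(file.exists(f2) && file.size(f2) > 0)

  p1 <- plot_ciber(tab, resp, oc, assignment, level = "item", seed = 3)
  p2 <- plot_ciber(tab, resp, oc, assignment, level = "item", seed = 3)
  expect_s3_class(p1, "gtable")
  expect_error(plot_ciber(tab[0, ], resp, oc, assignment, level = "item"),
               "no records")
})
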