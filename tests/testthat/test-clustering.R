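likert_frame <- function(n, seed, blocks = list(c("a1", "a2"), c("b1", "b2"))) {
  set.seed(seed)
  disc <- function(l) findInterval(l, c(-1.2, -0.4, 0.4, 1.2)) + 1L
  cols <- list()
  for (b in seq_along(blocks)) {
    f <- rnorm(n)
    for (nm in blocks[[b]]) {
      cols[[nm]] <- disc(0.9 * f + sqrt(1 - 0.81) * rnorm(n))
    }
  }
  tibble::as_tibble(cols)
}

test_that("Spearman dissimilarity: duplicates, mirrors, and independence", {
  df <- likert_frame(400, 1)
  df$a1_copy <- df$a1
  df$a1_mirror <- 6L - df$a1
  set.seed(2)
  df$noise1 <- sample(1:5, 400, TRUE)
  df$noise2 <- sample(1:5, 400, TRUE)

  D <- spearman_dissimilarity(df, names(df))
  expect_equal(D["a1", "a1_copy"], 0)
  expect_equal(D["a1", "a1_mirror"], 0) # |rho| = 1 for the reversed item
  expect_lt(abs(D["noise1", "noise2"] - 1), 0.1)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)
  expect_equal(unname(diag(D)), rep(0, ncol(df)))
})

test_that("Spearman dissimilarity matches a rank-then-correlate oracle on ties", {
  df <- likert_frame(150, 3)
  D <- spearman_dissimilarity(df, names(df))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(D[i, j],
                   1 - abs(spearman_oracle(df[[i]], df[[j]])),
                   tolerance = 1e-12)
    }
  }
})

test_that("constant items are rejected by name", {
  df <- likert_frame(50, 4)
  df$flat <- 3L
  expect_error(spearman_dissimilarity(df, names(df)), "flat")
})

test_that("D is invariant under strictly monotone transformations", {
  df <- likert_frame(200, 5)
  D1 <- spearman_dissimilarity(df, names(df))
  warped <- tibble::as_tibble(lapply(df, function(v) exp(v) + v^3))
  D2 <- spearman_dissimilarity(warped, names(warped))
  expect_equal(unclass(D1), unclass(D2), tolerance = 1e-12)
})

test_that("UPGMA reproduces hand-traced merge sequences", {
  labs <- c("a", "b", "c")
  D <- matrix(c(0, 0.1, 0.8, 0.1, 0, 0.8, 0.8, 0.8, 0), 3, 3,
              dimnames = list(labs, labs))
  hc <- average_linkage(D)
  expect_equal(hc$height, c(0.1, 0.8))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1)) # {a,b} first
  # average linkage reproduces its own ultrametric here -> ccc = 1
  expect_equal(cophenetic_correlation(D, hc), 1, tolerance = 1e-12)

  # block-diagonal: two tight blocks, last merge at the cross dissimilarity
  labs6 <- letters[1:6]
  D6 <- matrix(0.9, 6, 6, dimnames = list(labs6, labs6))
  D6[1:3, 1:3] <- 0.1
  D6[4:6, 4:6] <- 0.1
  diag(D6) <- 0
  hc6 <- average_linkage(D6)
  expect_equal(hc6$height[5], 0.9)
  expect_equal(partition_signature(cutree(hc6, 2)),
               c("a,b,c", "d,e,f"))
})

test_that("all-equal dissimilarities chain deterministically at one height", {
  labs <- letters[1:4]
  D <- matrix(0.4, 4, 4, dimnames = list(labs, labs))
  diag(D) <- 0
  hc <- average_linkage(D)
  expect_equal(hc$height, rep(0.4, 3))
  # lexicographic tie-break: a+b first, then (ab)+c, then +d
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
})

test_that("merge sequence matches the brute-force recompute-all oracle", {
  for (p in c(4, 5, 6, 7)) {
    for (seed in 1:5) {
      D <- random_dissimilarity(p, seed * 100 + p)
      hc <- average_linkage(D)
      oracle <- brute_force_upgma(D)
      expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
      expect_equal(model_partitions(hc), oracle$partitions)
    }
  }
})

test_that("UPGMA agrees with stats::hclust on untied dissimilarities", {
  for (seed in 1:5) {
    D <- random_dissimilarity(8, seed)
    mine <- average_linkage(D)
    ref <- stats::hclust(as.dist(D), method = "average")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
    for (k in 2:7) {
      expect_equal(partition_signature(cutree(mine, k)),
                   partition_signature(cutree(ref, k)))
    }
  }
})

test_that("cutting at k and k+1 yields nested partitions", {
  D <- random_dissimilarity(9, 42)
  hc <- average_linkage(D)
  for (k in 2:7) {
    coarse <- cutree(hc, k)
    fine <- cutree(hc, k + 1)
    # each fine cluster sits inside exactly one coarse cluster
    expect_true(all(vapply(split(coarse, fine),
                           function(v) length(unique(v)) == 1, TRUE)))
  }
})

test_that("ultrametric input is reproduced exactly and ccc = 1", {
  D <- ultrametric_D()
  hc <- average_linkage(D)
  coph <- as.matrix(cophenetic(hc))[rownames(D), colnames(D)]
  expect_equal(coph, D, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cophenetic_correlation(D, hc), 1, tolerance = 1e-12)
  expect_error(cophenetic_correlation(D[1:2, 1:2], hc), "at least 3")
})

test_that("compactness/separation curve covers k = 2..p-1 with hand values", {
  labs6 <- letters[1:6]
  D6 <- matrix(0.9, 6, 6, dimnames = list(labs6, labs6))
  D6[1:3, 1:3] <- 0.1
  D6[4:6, 4:6] <- 0.1
  diag(D6) <- 0
  hc <- average_linkage(D6)
  curve <- compactness_separation_curve(D6, hc)
  expect_equal(curve$k, 2:5)
  two <- curve[curve$k == 2, ]
  expect_equal(two$compactness, 0.1)
  expect_equal(two$separation, 0.9)
  expect_equal(optimal_k(curve), 2)

  # forcing the blocks together (k fixed below the block count) is visible
  # in the raw-D compactness after merging: recompute at a 1-cluster-like
  # cut by pairing blocks in a 4-item example
  labs4 <- letters[1:4]
  D4 <- matrix(0.9, 4, 4, dimnames = list(labs4, labs4))
  D4[1:2, 1:2] <- 0.1; D4[3:4, 3:4] <- 0.1; diag(D4) <- 0
  hc4 <- average_linkage(D4)
  curve4 <- compactness_separation_curve(D4, hc4)
  expect_equal(curve4$compactness[curve4$k == 3], 0.1)
  expect_equal(curve4$separation[curve4$k == 3], 0.1)
  expect_equal(curve4$compactness[curve4$k == 2], 0.1)
  expect_equal(curve4$separation[curve4$k == 2], 0.9)
})

test_that("featureless dissimilarity ties resolve to the smallest k", {
  labs <- letters[1:5]
  D <- matrix(0.5, 5, 5, dimnames = list(labs, labs))
  diag(D) <- 0
  hc <- average_linkage(D)
  curve <- compactness_separation_curve(D, hc)
  expect_equal(length(unique(curve$compactness - curve$separation)), 1)
  expect_equal(optimal_k(curve), 2)
})

test_that("cluster profiles: singletons, duplicates, respondent-mean stats", {
  df <- likert_frame(300, 6)
  df$solo <- df$a1
  assignment <- c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L, solo = 3L)
  prof <- profile_clusters(df, assignment)
  expect_equal(nrow(prof), 3)
  solo <- prof[prof$cluster == 3, ]
  expect_equal(solo$mean_clus, mean(df$solo))
  expect_equal(solo$sd_clus, sd(df$solo))
  expect_true(is.na(solo$rho_clus))

  dup <- profile_clusters(df, c(a1 = 1L, solo = 1L)) # identical columns
  expect_equal(dup$rho_clus, 1)
  expect_equal(dup$sd_clus, sd(df$a1))
  expect_equal(dup$mean_clus, mean(df$a1))

  c1 <- prof[prof$cluster == 1, ]
  scores <- rowMeans(df[c("a1", "a2")])
  expect_equal(c1$mean_clus, mean(scores))
  expect_equal(c1$sd_clus, sd(scores))
})

test_that("cluster_determinants assembles a consistent solution", {
  df <- likert_frame(500, 7, blocks = list(c("a1", "a2", "a3"),
                                           c("b1", "b2"),
                                           c("c1", "c2")))
  sol <- cluster_determinants(df, names(df))
  expect_equal(sol$k, 3)
  expect_equal(partition_signature(sol$assignment),
               c("a1,a2,a3", "b1,b2", "c1,c2"))
  expect_gte(sol$ccc, 0.9)
  expect_equal(sol$separation,
               sol$curve$separation[sol$curve$k == sol$k])

  f <- withr::local_tempfile(fileext = ".pdf")
  plot_dendrogram(sol$dendrogram, sol$k, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
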