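# Independent oracles and small fixture builders shared across tests.

# Brute-force UPGMA: recompute the mean pairwise dissimilarity between every
# cluster pair from the ORIGINAL matrix at every step. Returns the merge
# heights and, per step, the partition as a set of sorted member-label sets.
brute_force_upgma <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq(i + 1, length(clusters))) {
        dij <- mean(D[clusters[[i]], clusters[[j]]])
        if (dij < best_d - 1e-12) {
          best <- c(i, j); best_d <- dij
        } else if (abs(dij - best_d) <= 1e-12) {
          cand <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
          cur <- sort(c(min(clusters[[best[1]]]), min(clusters[[best[2]]])))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merged
    clusters <- clusters[-best[2]]
    partitions[[length(partitions) + 1]] <-
      unname(sort(vapply(clusters,
                         function(m) paste(sort(m), collapse = ","), "")))
  }
  list(heights = heights, partitions = partitions)
}

# partition sequence implied by an hclust-style model, same encoding
model_partitions <- function(hc) {
  p <- length(hc$labels)
  lapply((p - 1):1, function(k) {
    a <- stats::cutree(hc, k)
    unname(sort(vapply(split(names(a), a),
                       function(m) paste(sort(m), collapse = ","), "")))
  })
}

# canonical form of a flat partition for label-free comparison
partition_signature <- function(assign) {
  unname(sort(vapply(split(names(assign), assign),
                     function(m) paste(sort(m), collapse = ","), "")))
}

random_dissimilarity <- function(p, seed) {
  set.seed(seed)
  D <- matrix(0, p, p)
  D[upper.tri(D)] <- runif(p * (p - 1) / 2, 0.05, 1)
  D <- D + t(D)
  dimnames(D) <- list(letters[seq_len(p)], letters[seq_len(p)])
  D
}

# an exactly ultrametric dissimilarity: two tight blocks joined high up
ultrametric_D <- function() {
  labs <- c("a", "b", "c", "d", "e")
  D <- matrix(0.9, 5, 5, dimnames = list(labs, labs))
  D[1:2, 1:2] <- 0.1
  D[3:5, 3:5] <- 0.3
  D[3:4, 3:4] <- 0.2
  diag(D) <- 0
  D
}

# Spearman oracle: midrank both columns, then Pearson
spearman_oracle <- function(x, y) {
  cor(rank(x), rank(y))
}

# small Likert fixture with a planted 2-block structure, written as CSV
write_likert_fixture <- function(dir, n = 200, seed = 99) {
  set.seed(seed)
  f1 <- rnorm(n); f2 <- rnorm(n)
  disc <- function(l) findInterval(l, c(-1.2, -0.4, 0.4, 1.2)) + 1L
  df <- tibble::tibble(
    respondent = seq_len(n),
    q1 = disc(0.9 * f1 + sqrt(1 - 0.81) * rnorm(n)),
    q2 = disc(0.9 * f1 + sqrt(1 - 0.81) * rnorm(n)),
    q3 = disc(0.9 * f2 + sqrt(1 - 0.81) * rnorm(n)),
    q4 = disc(0.9 * f2 + sqrt(1 - 0.81) * rnorm(n)),
    region = sample(c("N", "S"), n, TRUE),
    willing = disc(-f1 + 0.5 * rnorm(n))
  )
  cb <- tibble::tibble(
    id = c("q1", "q2", "q3", "q4", "region", "willing"),
    label = c("Item 1", "Item 2", "Item 3", "Item 4", "Region",
              "Willingness"),
    role = c(rep("predictor", 4), "demographic", "outcome"),
    scale = c(rep("likert5", 4), "categorical", "likert5"),
    reverse_coded = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  data_path <- file.path(dir, "responses.csv")
  cb_path <- file.path(dir, "codebook.csv")
  readr::write_csv(df, data_path)
  readr::write_csv(cb, cb_path)
  list(data = data_path, codebook = cb_path, df = df, cb = cb)
}

# printed determinant selection table: per entity the published mean score,
# Cohen's d, and 2-decimal PCI (used as arithmetic-identity inputs)
published_selection_table <- function() {
  tibble::tribble(
    ~cluster, ~level,    ~mean, ~d,    ~pci,
    "C1",     "item",    2.15,  0.66,  0.51,
    "C1",     "item",    2.09,  0.60,  0.40,
    "C1",     "cluster", 2.12,  0.68,  0.52,
    "C2",     "item",    2.21,  0.89,  0.96,
    "C2",     "item",    2.23,  0.83,  0.84,
    "C2",     "item",    2.17,  0.84,  0.83,
    "C2",     "cluster", 2.20,  0.99,  1.20,
    "C3",     "item",    2.13,  0.71,  0.56,
    "C3",     "item",    2.38,  0.55,  0.41,
    "C3",     "cluster", 2.25,  0.70,  0.62,
    "C4",     "item",    2.42,  1.10,  1.70,
    "C4",     "cluster", 2.42,  1.10,  1.70,
    "C5",     "item",    2.86,  0.72,  0.97,
    "C5",     "item",    2.87,  0.66,  0.82,
    "C5",     "item",    2.85,  0.62,  0.71,
    "C5",     "item",    2.68,  0.65,  0.71,
    "C5",     "cluster", 2.81,  0.78,  1.10,
    "C6",     "item",    2.09,  0.76,  0.63,
    "C6",     "item",    1.97,  0.76,  0.56,
    "C6",     "cluster", 2.03,  0.84,  0.73,
    "C7",     "item",    2.74,  0.57,  0.56,
    "C7",     "item",    3.00,  0.46,  0.43,
    "C7",     "cluster", 2.87,  0.55,  0.56,
    "C8",     "item",    2.33,  0.69,  0.63,
    "C8",     "cluster", 2.33,  0.69,  0.63,
    "C9",     "item",    2.26,  0.85,  0.91,
    "C9",     "item",    2.31,  0.84,  0.91,
    "C9",     "item",    2.47,  0.73,  0.79,
    "C9",     "cluster", 2.35,  0.89,  1.10
  )
}
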