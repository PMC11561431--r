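#' Spearman-correlation dissimilarity between determinants
#'
#' `D[i, j] = 1 - |rho_ij]`, with rho the Spearman rank correlation (midranks
#' for ties, which Likert data produces in abundance). Determinants that
#' move together — in either direction, since the absolute value is taken —
#' are similar; an item and its mirror image (v, 6 - v) have D = 0.
#'
#' @param responses Harmonized response table.
#' @param items Character vector of item ids (at least 2).
#' @return A symmetric matrix of class `dissimilarity_matrix` with entries
#'   in \[0, 1\] and zero diagonal.
#' @export
spearman_dissimilarity <- function(responses, items) {
  if (length(items) < 2) stop("need at least 2 items", call. = FALSE)
  missing_items <- setdiff(items, names(responses))
  if (length(missing_items) > 0) {
    stop("item(s) not in the data: ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(responses[items])
  storage.mode(x) <- "double"
  if (nrow(x) < 3) stop("need at least 3 respondents", call. = FALSE)
  constant <- items[apply(x, 2, function(v) length(unique(v)) == 1)]
  if (length(constant) > 0) {
    stop("Spearman correlation undefined for constant item(s): ",
         paste(constant, collapse = ", "), call. = FALSE)
  }
  rho <- cor(x, method = "spearman")
  D <- 1 - abs(rho)
  D[D < 0] <- 0 # guard tiny negative round-off
  diag(D) <- 0
  dimnames(D) <- list(items, items)
  class(D) <- c("dissimilarity_matrix", class(D))
  D
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Starting from singletons, repeatedly merges the two clusters with the
#' smallest mean pairwise dissimilarity between their members, recording
#' merge heights. Ties are broken deterministically toward the candidate
#' pair whose member ids are lexicographically smallest. The result is a
#' standard `hclust` object (so [stats::cutree()] and
#' [stats::cophenetic()] apply), with the original dissimilarity attached.
#'
#' Average linkage on a general dissimilarity is in principle not
#' guaranteed to produce nondecreasing merge heights; a violation triggers
#' a warning rather than silent reordering.
#'
#' @param D A [spearman_dissimilarity()] matrix (any symmetric
#'   dissimilarity matrix with zero diagonal works).
#' @return An object of classes `dendrogram_model` and `hclust`.
#' @export
average_linkage <- function(D) {
  D <- unclass(D)
  p <- nrow(D)
  if (is.null(p) || p < 2) stop("need at least 2 items", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(p))

  # active cluster state
  members <- as.list(seq_len(p))         # original item indices
  node_id <- -seq_len(p)                 # hclust convention: -i singleton
  first_label <- labels                  # lexicographic tie-break key
  d <- D                                 # current between-cluster means
  active <- rep(TRUE, p)

  merge <- matrix(0L, p - 1, 2)
  height <- numeric(p - 1)

  for (step in seq_len(p - 1)) {
    act <- which(active)
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(act)[-length(act)]) {
      for (jj in seq((ii + 1), length(act))) {
        i <- act[ii]; j <- act[jj]
        dij <- d[i, j]
        if (dij < best_d - 1e-12) {
          best <- c(i, j); best_d <- dij
        } else if (abs(dij - best_d) <= 1e-12) {
          # tie: lexicographically smallest pair of leading member labels
          cand <- sort(c(first_label[i], first_label[j]))
          cur <- sort(c(first_label[best[1]], first_label[best[2]]))
          if (cand[1] < cur[1] ||
              (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(i, j); best_d <- min(best_d, dij)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(node_id[i], node_id[j]))
    height[step] <- d[i, j]

    ni <- length(members[[i]]); nj <- length(members[[j]])
    for (k in act) {
      if (k == i || k == j) next
      # Lance-Williams update for the unweighted average of raw pairs
      d[i, k] <- d[k, i] <- (ni * d[i, k] + nj * d[j, k]) / (ni + nj)
    }
    members[[i]] <- c(members[[i]], members[[j]])
    node_id[i] <- step
    first_label[i] <- min(first_label[i], first_label[j])
    active[j] <- FALSE
  }

  if (any(diff(height) < -1e-10)) {
    warning("non-monotone merge heights; the dendrogram inverts", call. = FALSE)
  }

  hc <- structure(
    list(merge = merge, height = height, order = dendrogram_order(merge),
         labels = labels, method = "average",
         call = match.call(), dist.method = "spearman 1-|rho|"),
    class = c("dendrogram_model", "hclust")
  )
  attr(hc, "D") <- D
  hc
}

# leaf order by left-to-right traversal of the merge tree
dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Cophenetic correlation coefficient of a dendrogram
#'
#' Pearson correlation between the original pairwise dissimilarities and
#' the cophenetic distances (the merge height at which each pair first
#' joins). Values near 1 mean the tree faithfully represents the
#' dissimilarity structure.
#'
#' @param D The dissimilarity matrix the dendrogram was built from.
#' @param dendrogram An [average_linkage()] model.
#' @return A single correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(D, dendrogram) {
  D <- unclass(D)
  p <- nrow(D)
  if (p < 3) stop("cophenetic correlation needs at least 3 items",
                  call. = FALSE)
  coph <- cophenetic(dendrogram)
  d0 <- as.dist(D)
  if (sd(coph) == 0 || sd(d0) == 0) return(1)
  cor(d0, coph)
}

#' Compactness and separation over all cut levels
#'
#' For every number of clusters k from 2 to p - 1 the dendrogram is cut
#' into k clusters; compactness is the maximum dissimilarity between two
#' items within any cluster and separation the minimum dissimilarity
#' between items of different clusters — both read from the original
#' dissimilarity matrix, not the cophenetic distances.
#'
#' @param D Dissimilarity matrix.
#' @param dendrogram An [average_linkage()] model of `D`.
#' @return Tibble with columns `k`, `compactness`, `separation`.
#' @export
compactness_separation_curve <- function(D, dendrogram) {
  D <- unclass(D)
  p <- nrow(D)
  if (p < 3) stop("need at least 3 items for a nondegenerate curve",
                  call. = FALSE)
  ks <- 2:(p - 1)
  res <- lapply(ks, function(k) {
    assign <- cutree(dendrogram, k)
    same <- outer(assign, assign, "==")
    ut <- upper.tri(D)
    within <- D[ut & same]
    between <- D[ut & !same]
    tibble::tibble(
      k = k,
      compactness = if (length(within) > 0) max(within) else 0,
      separation = min(between)
    )
  })
  dplyr::bind_rows(res)
}

#' Choose the number of clusters
#'
#' Selects the k minimizing the difference compactness - separation, i.e.
#' the cut whose tightest guarantee (every within-cluster dissimilarity at
#' most `compactness`, every between-cluster dissimilarity at least
#' `separation`) leaves the widest margin between clusters. Ties go to the
#' smaller k (parsimony).
#'
#' @param curve A [compactness_separation_curve()] tibble.
#' @return The chosen k.
#' @export
optimal_k <- function(curve) {
  if (nrow(curve) == 0) stop("empty curve", call. = FALSE)
  gap <- curve$compactness - curve$separation
  best <- which(gap <= min(gap) + 1e-12)
  curve$k[best[1]] # curve is ordered by k ascending
}

#' Per-cluster profiles
#'
#' For each cluster, the member items, the mean and SD over respondents of
#' the per-respondent mean of member-item scores (mean_clus, sd_clus), and
#' the average pairwise Spearman correlation among members (rho_clus;
#' omitted as NA for singletons).
#'
#' @param responses Harmonized response table.
#' @param assignment Named integer vector (item -> cluster id), as from
#'   [stats::cutree()].
#' @return Tibble with one row per cluster.
#' @export
profile_clusters <- function(responses, assignment) {
  items <- names(assignment)
  missing_items <- setdiff(items, names(responses))
  if (length(missing_items) > 0) {
    stop("item(s) not in the data: ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  ids <- sort(unique(assignment))
  res <- lapply(ids, function(cl) {
    mem <- items[assignment == cl]
    scores <- rowMeans(responses[mem])
    rho <- if (length(mem) >= 2) {
      r <- cor(as.matrix(responses[mem]), method = "spearman")
      mean(r[upper.tri(r)])
    } else {
      NA_real_
    }
    tibble::tibble(cluster = cl, n_items = length(mem),
                   items = paste(mem, collapse = ";"),
                   mean_clus = mean(scores), sd_clus = sd(scores),
                   rho_clus = rho)
  })
  dplyr::bind_rows(res)
}

#' Full cluster solution for a set of determinants
#'
#' Convenience wrapper running [spearman_dissimilarity()],
#' [average_linkage()], the compactness/separation rule, and
#' [profile_clusters()] in one call.
#'
#' @param responses Harmonized response table.
#' @param items Determinant item ids.
#' @param k Number of clusters; `NULL` (default) applies [optimal_k()].
#' @return A list of class `cluster_solution`: `k`, `assignment`,
#'   `dendrogram`, `D`, `ccc`, `compactness`, `separation`, `curve`,
#'   `profiles`.
#' @export
cluster_determinants <- function(responses, items, k = NULL) {
  D <- spearman_dissimilarity(responses, items)
  dend <- average_linkage(D)
  curve <- compactness_separation_curve(D, dend)
  if (is.null(k)) k <- optimal_k(curve)
  if (k < 2 || k > length(items) - 1) {
    stop("`k` must lie in 2..p-1", call. = FALSE)
  }
  assignment <- cutree(dend, k)
  row <- curve[curve$k == k, ]
  structure(
    list(k = k, assignment = assignment, dendrogram = dend, D = D,
         ccc = cophenetic_correlation(D, dend),
         compactness = row$compactness, separation = row$separation,
         curve = curve,
         profiles = profile_clusters(responses, assignment)),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Determinant cluster solution\n")
  cat(sprintf("  k = %d clusters over %d items | CCC %.3f\n",
              x$k, length(x$assignment), x$ccc))
  cat(sprintf("  compactness %.3f, separation %.3f\n",
              x$compactness, x$separation))
  print(x$profiles)
  invisible(x)
}

#' Plot the cluster dendrogram
#'
#' Tree with the dissimilarity on the y-axis and items on the x-axis;
#' cluster borders are drawn at the chosen k.
#'
#' @param dendrogram An [average_linkage()] model.
#' @param k Number of clusters to outline (`NULL` for no borders).
#' @param file Optional output file (`.pdf` recommended); `NULL` plots to
#'   the active device.
#' @return Invisibly, the dendrogram.
#' @export
plot_dendrogram <- function(dendrogram, k = NULL, file = NULL) {
  draw <- function() {
    graphics::plot(dendrogram, hang = -1, xlab = "", sub = "",
                   ylab = "D (1 - |Spearman rho|)",
                   main = "Determinant cluster dendrogram")
    if (!is.null(k) && k >= 2) {
      stats::rect.hclust(dendrogram, k = k, border = "steelblue")
    }
  }
  if (is.null(file)) {
    draw()
  } else {
    grDevices::pdf(file, width = 8, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  }
  invisible(dendrogram)
}
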