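#' Specify a synthetic questionnaire design
#'
#' Describes a latent-factor world from which Likert questionnaire data with
#' a known block-correlation structure and a known intention signal can be
#' generated. Each of the `n_clusters` determinant blocks is driven by its
#' own independent standard-normal factor; every item in block `k` is a
#' discretized version of `loading[k] * f_k + sqrt(1 - loading[k]^2) * e`
#' (plus a common location shift that skews the 5-point distribution), and
#' the intention latent is `sum(effect[k] * f_k) + e`. Noise items are
#' discretized independent normals.
#'
#' The defaults emulate a consumer-panel questionnaire study: ~3000
#' respondents, 9 correlated determinant blocks totalling 22 signal items,
#' 38 pure-noise filler items (60 Likert items in all), a positive-intention
#' prevalence of 76%, and right-skewed item distributions with means a
#' little above 2 on the 1 (most favorable) to 5 (least favorable) scale.
#'
#' @param n_respondents Number of respondents.
#' @param n_clusters Number of correlated item blocks (true K).
#' @param items_per_cluster Integer vector of length `n_clusters`; each
#'   entry at least 2.
#' @param n_noise_items Number of items unrelated to anything.
#' @param loading Factor loading in (0, 1), recycled to `n_clusters`. The
#'   latent within-block correlation is `loading^2`.
#' @param effect Contribution of each block factor to the intention latent,
#'   recycled to `n_clusters`. Zero disconnects a block from intention.
#' @param target_positive_rate Fraction of respondents dichotomized as
#'   having a positive intention, in (0, 1).
#' @param thresholds Four strictly ascending cut points on the latent scale
#'   mapping the continuous item latent to categories 1-5.
#' @param latent_shift Location shift of the item latents; negative values
#'   skew responses toward the favorable (low) end of the scale.
#' @param seed Integer seed; the same seed and design give a bit-identical
#'   dataset.
#' @return An object of class `synthetic_design`.
#' @seealso [generate_responses()]
#' @export
synthetic_design <- function(n_respondents = 3000,
                             n_clusters = 9,
                             items_per_cluster = c(2, 3, 2, 2, 4, 2, 2, 2, 3),
                             n_noise_items = 38,
                             loading = 0.85,
                             effect = c(2.2, 2.8, 1.6, 4.0, 2.0, 2.4, 1.2, 1.8, 2.6),
                             target_positive_rate = 0.76,
                             thresholds = c(-1.2, -0.4, 0.4, 1.2),
                             latent_shift = -0.4,
                             seed = 1L) {
  check_count(n_respondents, "n_respondents", min = 1)
  check_count(n_clusters, "n_clusters", min = 1)
  if (length(items_per_cluster) != n_clusters) {
    stop("`items_per_cluster` must have length `n_clusters` (",
         n_clusters, "), got ", length(items_per_cluster), call. = FALSE)
  }
  if (any(items_per_cluster < 2)) {
    stop("`items_per_cluster`: every block needs at least 2 items",
         call. = FALSE)
  }
  check_count(n_noise_items, "n_noise_items", min = 0)
  loading <- rep_len(loading, n_clusters)
  effect <- rep_len(effect, n_clusters)
  if (any(loading <= 0 | loading >= 1)) {
    stop("`loading` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(target_positive_rate) || length(target_positive_rate) != 1 ||
      target_positive_rate <= 0 || target_positive_rate >= 1) {
    stop("`target_positive_rate` must be a single number in (0, 1)",
         call. = FALSE)
  }
  if (length(thresholds) != 4 || any(diff(thresholds) <= 0)) {
    stop("`thresholds` must be 4 strictly ascending cut points",
         call. = FALSE)
  }
  check_count(seed, "seed", min = -2^31 + 1)
  structure(
    list(
      n_respondents = as.integer(n_respondents),
      n_clusters = as.integer(n_clusters),
      items_per_cluster = as.integer(items_per_cluster),
      n_noise_items = as.integer(n_noise_items),
      loading = loading,
      effect = effect,
      target_positive_rate = target_positive_rate,
      thresholds = thresholds,
      latent_shift = latent_shift,
      seed = as.integer(seed)
    ),
    class = "synthetic_design"
  )
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("Synthetic questionnaire design\n")
  cat("  respondents:       ", x$n_respondents, "\n")
  cat("  item blocks (K):   ", x$n_clusters,
      " [", paste(x$items_per_cluster, collapse = ", "), "] items\n", sep = "")
  cat("  noise items:       ", x$n_noise_items, "\n")
  cat("  loadings:          ", paste(round(x$loading, 3), collapse = ", "), "\n")
  cat("  intention effects: ", paste(round(x$effect, 3), collapse = ", "), "\n")
  cat("  target positive:   ", x$target_positive_rate, "\n")
  invisible(x)
}

discretize_latent <- function(latent, thresholds) {
  findInterval(latent, thresholds) + 1L
}

#' Generate a synthetic questionnaire dataset
#'
#' Draws respondents from the latent-factor world described by a
#' [synthetic_design()]: correlated Likert blocks, independent noise items,
#' one unrelated categorical demographic, and a 5-level intention item whose
#' dichotomization (levels 1-2 = positive) hits the design's target positive
#' rate up to rounding.
#'
#' @param design A [synthetic_design()].
#' @return A list of class `synthetic_dataset` with elements
#'   * `responses`: tibble of respondent id, item columns (`b<k>_i<j>` for
#'     block items, `noise<j>` for fillers), `demo_group`, and `intention`;
#'   * `codebook`: a matching [codebook()] tibble;
#'   * `true_assignment`: named character vector, item -> block label or
#'     `"noise"`;
#'   * `true_effects`: named numeric vector of block intention effects;
#'   * `realized_positive_rate`: achieved fraction of positive intentions;
#'   * `design`: the input design.
#' @export
generate_responses <- function(design) {
  if (!inherits(design, "synthetic_design")) {
    stop("`design` must be a `synthetic_design` object", call. = FALSE)
  }
  n <- design$n_respondents
  K <- design$n_clusters

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(design$seed)

  factors <- matrix(rnorm(n * K), n, K)

  item_names <- character(0)
  assignment <- character(0)
  cols <- list()
  for (k in seq_len(K)) {
    a <- design$loading[k]
    for (j in seq_len(design$items_per_cluster[k])) {
      latent <- a * factors[, k] + sqrt(1 - a^2) * rnorm(n) +
        design$latent_shift
      nm <- sprintf("b%d_i%d", k, j)
      cols[[nm]] <- discretize_latent(latent, design$thresholds)
      item_names <- c(item_names, nm)
      assignment <- c(assignment, sprintf("b%d", k))
    }
  }
  for (j in seq_len(design$n_noise_items)) {
    latent <- rnorm(n) + design$latent_shift
    nm <- sprintf("noise%d", j)
    cols[[nm]] <- discretize_latent(latent, design$thresholds)
    item_names <- c(item_names, nm)
    assignment <- c(assignment, "noise")
  }
  names(assignment) <- item_names

  demo <- sample(c("A", "B", "C", "D"), n, replace = TRUE)

  # intention latent: low values = willing, because low item scores are the
  # favorable end and both are driven by the same factors
  intention_latent <- as.vector(factors %*% design$effect) + rnorm(n)
  cut <- threshold_for_rate(-intention_latent, design$target_positive_rate)
  positive <- -intention_latent > cut
  # split the two sides into the 5 ordered labels (proportions within each
  # side are presentation plumbing; only the 1-2 vs 3-5 split matters)
  intention <- integer(n)
  pos_cut <- quantile(intention_latent[positive], 0.45, type = 1)
  intention[positive] <- ifelse(intention_latent[positive] <= pos_cut, 1L, 2L)
  neg_lat <- intention_latent[!positive]
  neg_cuts <- quantile(neg_lat, c(0.6, 0.85), type = 1)
  intention[!positive] <-
    3L + findInterval(neg_lat, neg_cuts, left.open = TRUE)

  responses <- tibble::as_tibble(c(
    list(respondent = seq_len(n)),
    cols,
    list(demo_group = demo, intention = intention)
  ))

  cb <- tibble::tibble(
    id = c(item_names, "demo_group", "intention"),
    label = c(item_names, "Demographic group", "Intention to participate"),
    role = c(rep("predictor", length(item_names)), "demographic", "outcome"),
    scale = c(rep("likert5", length(item_names)), "categorical", "likert5"),
    reverse_coded = FALSE
  )

  structure(
    list(
      responses = responses,
      codebook = codebook(cb),
      true_assignment = assignment,
      true_effects = setNames(design$effect, sprintf("b%d", seq_len(K))),
      realized_positive_rate = mean(positive),
      design = design
    ),
    class = "synthetic_dataset"
  )
}

#' Cut point dichotomizing a latent score at a target rate
#'
#' Returns a threshold such that the fraction of `scores` strictly above it
#' equals `rate` to within `1/length(scores)`.
#'
#' @param scores Numeric vector of latent scores.
#' @param rate Target fraction above the cut, in (0, 1).
#' @return A single numeric cut point.
#' @export
threshold_for_rate <- function(scores, rate) {
  if (!is.numeric(scores) || length(scores) == 0) {
    stop("`scores` must be a nonempty numeric vector", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0 || rate >= 1) {
    stop("`rate` must be a single number in (0, 1)", call. = FALSE)
  }
  s <- sort(scores)
  n <- length(s)
  if (s[1] == s[n]) {
    stop("`scores` is constant; no cut point can separate it", call. = FALSE)
  }
  m <- round(rate * n) # number of scores to fall strictly above the cut
  m <- min(max(m, 1L), n - 1L)
  lo <- s[n - m]
  hi <- s[n - m + 1]
  if (lo < hi) {
    return((lo + hi) / 2)
  }
  # tied boundary: use the tied value itself; "strictly above" then excludes
  # the whole tie group, the closest achievable count
  lo
}

# ---- analytic effect-size calibration --------------------------------------

# Expected Cohen's d of a single block item at infinite n, by 1-D quadrature
# over the block factor f. `effect_ss` is the total sum of squared intention
# effects (including this block's), so the intention latent has variance
# effect_ss + 1.
expected_item_d <- function(effect, loading, effect_ss = effect^2,
                            rate = 0.76,
                            thresholds = c(-1.2, -0.4, 0.4, 1.2),
                            latent_shift = -0.4) {
  a <- loading
  s <- sqrt(1 - a^2)
  sd_t <- sqrt(effect_ss + 1)
  t_cut <- qnorm(1 - rate) * sd_t # positive intention: -T > cut, T < -cut
  resid_sd <- sqrt(effect_ss - effect^2 + 1)

  cat_probs <- function(f) {
    z <- outer(c(-Inf, thresholds, Inf), a * f + latent_shift, "-") / s
    pn <- pnorm(z)
    pn[-1, , drop = FALSE] - pn[-6, , drop = FALSE] # 5 x length(f)
  }
  p_pos <- function(f) pnorm((-t_cut - effect * f) / resid_sd)

  moment <- function(power, positive) {
    g <- function(f) {
      pr <- cat_probs(f)
      ex <- colSums(pr * (1:5)^power)
      w <- if (positive) p_pos(f) else 1 - p_pos(f)
      ex * w * dnorm(f)
    }
    integrate(g, -9, 9, rel.tol = 1e-10)$value
  }

  m1_pos <- moment(1, TRUE) / rate
  m2_pos <- moment(2, TRUE) / rate
  m1_neg <- moment(1, FALSE) / (1 - rate)
  m2_neg <- moment(2, FALSE) / (1 - rate)
  v_pos <- m2_pos - m1_pos^2
  v_neg <- m2_neg - m1_neg^2
  pooled <- sqrt(rate * v_pos + (1 - rate) * v_neg)
  (m1_neg - m1_pos) / pooled
}

#' Calibrate a block's intention effect to a target Cohen's d
#'
#' Finds, by root search on an exact large-n quadrature of the latent model,
#' the intention effect that makes a single item of a block attain a given
#' expected Cohen's d between the positive and neutral/negative intention
#' groups.
#'
#' @param target_d Desired expected Cohen's d for one block item.
#' @param loading Block factor loading.
#' @param other_effect_ss Sum of squared intention effects of all other
#'   blocks (0 for a single-block design).
#' @param rate,thresholds,latent_shift As in [synthetic_design()].
#' @return The calibrated effect (a single positive number).
#' @export
calibrate_effect <- function(target_d, loading = 0.85, other_effect_ss = 0,
                             rate = 0.76,
                             thresholds = c(-1.2, -0.4, 0.4, 1.2),
                             latent_shift = -0.4) {
  f <- function(b) {
    expected_item_d(b, loading, effect_ss = b^2 + other_effect_ss,
                    rate = rate, thresholds = thresholds,
                    latent_shift = latent_shift) - target_d
  }
  ceiling_d <- expected_item_d(1e4, loading,
                               effect_ss = 1e8 + other_effect_ss,
                               rate = rate, thresholds = thresholds,
                               latent_shift = latent_shift)
  if (target_d >= ceiling_d) {
    stop("target_d = ", target_d, " exceeds the attainable ceiling ",
         round(ceiling_d, 3), " at loading ", loading, call. = FALSE)
  }
  uniroot(f, c(1e-4, 1e3), tol = 1e-8)$root
}

# ---- RNG bookkeeping -------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) ||
      x < min) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  invisible(x)
}
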