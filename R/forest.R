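#' Configuration of the random-forest determinant screen
#'
#' @param n_trees Number of trees (at least 100; default 1000).
#' @param predictors_per_split `"auto"` for `floor(sqrt(p))`, or a count.
#' @param top_k How many top-ranked predictors to select as determinants
#'   (default 20).
#' @param seed Integer seed for the bootstrap and permutation streams.
#' @return A list of class `ranking_config`.
#' @export
ranking_config <- function(n_trees = 1000, predictors_per_split = "auto",
                           top_k = 20, seed = 1L) {
  check_count(n_trees, "n_trees", min = 100)
  if (!identical(predictors_per_split, "auto")) {
    check_count(predictors_per_split, "predictors_per_split", min = 1)
  }
  check_count(top_k, "top_k", min = 1)
  check_count(seed, "seed", min = -2^31 + 1)
  structure(list(n_trees = as.integer(n_trees),
                 predictors_per_split = predictors_per_split,
                 top_k = as.integer(top_k), seed = as.integer(seed)),
            class = "ranking_config")
}

#' Build the numeric predictor matrix for the forest
#'
#' Likert items enter as numeric scores 1-5; categorical and binary
#' demographics are one-hot encoded (one indicator per level). Follow-up
#' items and the outcome are excluded.
#'
#' @param responses Harmonized response table.
#' @param cb Codebook; defaults to the attached one.
#' @return Numeric matrix with an attribute `item_of` mapping each column
#'   back to its source item.
#' @export
build_predictor_matrix <- function(responses,
                                   cb = attr(responses, "codebook")) {
  if (is.null(cb)) stop("no codebook available", call. = FALSE)
  cb <- codebook(cb)
  preds <- cb[cb$role %in% c("predictor", "demographic"), ]
  if (nrow(preds) == 0) stop("no predictor columns declared", call. = FALSE)

  cols <- list()
  item_of <- character(0)
  for (i in seq_len(nrow(preds))) {
    item <- preds$id[i]
    v <- responses[[item]]
    if (preds$scale[i] == "likert5") {
      cols[[item]] <- as.numeric(v)
      item_of <- c(item_of, item)
    } else {
      levs <- sort(unique(as.character(v)))
      for (lv in levs) {
        nm <- paste0(item, "=", lv)
        cols[[nm]] <- as.numeric(as.character(v) == lv)
        item_of <- c(item_of, item)
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  attr(x, "item_of") <- setNames(item_of, colnames(x))
  x
}

#' Fit the random-forest intention classifier
#'
#' Trains a random forest of classification trees on the predictor matrix
#' with the dichotomized intention as the outcome and reports out-of-bag
#' (OOB) performance: the probability of misclassification (pmc),
#' sensitivity (correct prediction probability among positive-intention
#' respondents), specificity (among neutral/negative respondents), and the
#' AUC of the OOB positive-vote fraction.
#'
#' @param responses Harmonized response table (or a plain numeric matrix of
#'   predictors).
#' @param outcome Factor from [dichotomize_intention()], one value per row.
#' @param config A [ranking_config()].
#' @param cb Codebook (ignored when `responses` is already a matrix).
#' @return A list of class `detana_forest` with elements `metrics` (pmc,
#'   sens, spec, auc), `oob_votes`, `x`, `y`, `config`, and the fitted
#'   forest handle.
#' @export
fit_forest <- function(responses, outcome, config = ranking_config(),
                       cb = attr(responses, "codebook")) {
  x <- if (is.matrix(responses)) responses else
    build_predictor_matrix(responses, cb)
  if (ncol(x) == 0) stop("no predictors to train on", call. = FALSE)
  if (anyNA(x)) stop("predictor matrix contains missing values",
                     call. = FALSE)
  outcome <- as.factor(outcome)
  if (nrow(x) != length(outcome)) {
    stop("outcome length does not match the number of rows", call. = FALSE)
  }
  if (nlevels(droplevels(outcome)) < 2) {
    stop("outcome has a single class; nothing to classify", call. = FALSE)
  }
  y <- as.integer(outcome) - 1L # 0 = first level ("positive")

  mtry <- if (identical(config$predictors_per_split, "auto")) {
    max(1L, floor(sqrt(ncol(x))))
  } else {
    min(as.integer(config$predictors_per_split), ncol(x))
  }

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)
  handle <- rf_fit(x, y, config$n_trees, mtry, 1L)
  votes <- rf_oob_votes(handle, x)

  total <- rowSums(votes)
  seen <- total > 0
  pred <- ifelse(votes[, 2] > votes[, 1], 1L, 0L) # tie -> class 0
  conf <- table(factor(y[seen], levels = 0:1),
                factor(pred[seen], levels = 0:1))
  n_pos <- sum(conf[1, ])
  n_neg <- sum(conf[2, ])
  sens <- conf[1, 1] / n_pos
  spec <- conf[2, 2] / n_neg
  pmc <- (conf[1, 2] + conf[2, 1]) / sum(conf)

  # AUC of the OOB positive-vote fraction, rank-based (midranks for ties)
  score <- votes[seen, 1] / total[seen]
  pos <- y[seen] == 0L
  r <- rank(score)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))

  structure(
    list(handle = handle, x = x, y = y,
         outcome_levels = levels(outcome),
         oob_votes = votes, config = config, mtry = mtry,
         metrics = list(pmc = unname(pmc), sens = unname(sens),
                        spec = unname(spec), auc = unname(auc)),
         item_of = attr(x, "item_of")),
    class = "detana_forest"
  )
}

#' @export
print.detana_forest <- function(x, ...) {
  m <- x$metrics
  cat("Random-forest intention classifier\n")
  cat(sprintf("  %d trees, mtry %d, %d predictors, %d respondents\n",
              x$config$n_trees, x$mtry, ncol(x$x), nrow(x$x)))
  cat(sprintf("  OOB pmc %.3f | sens %.3f | spec %.3f | AUC %.3f\n",
              m$pmc, m$sens, m$spec, m$auc))
  invisible(x)
}

#' Permutation variable importance ranking
#'
#' For each predictor, its value is replaced tree-by-tree with a randomly
#' drawn value from its own distribution (a permutation of the tree's
#' out-of-bag rows) and the importance is the mean resulting increase in
#' the misclassification probability over trees. Predictors are ranked by
#' importance descending, ties broken by id ascending.
#'
#' One-hot indicator columns are aggregated back to their source item by
#' summing their importances.
#'
#' @param fit A [fit_forest()] object.
#' @param seed Seed for the permutation stream (defaults to the fit's
#'   seed plus 1).
#' @return A list of class `importance_ranking` with `entries` (tibble of
#'   item, importance, rank), `metrics`, and `elbow` (the rank after which
#'   the largest relative importance drop occurs, reported for
#'   transparency only).
#' @export
permutation_importance <- function(fit, seed = fit$config$seed + 1L) {
  stopifnot(inherits(fit, "detana_forest"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  imp <- rf_perm_importance(fit$handle, fit$x, fit$y)
  names(imp) <- colnames(fit$x)

  if (!is.null(fit$item_of)) {
    imp <- tapply(imp, fit$item_of[names(imp)], sum)
  }
  entries <- tibble::tibble(item = names(imp), importance = as.numeric(imp))
  entries <- entries[order(-entries$importance, entries$item), ]
  entries$rank <- seq_len(nrow(entries))

  pos <- entries$importance[entries$importance > 0]
  elbow <- if (length(pos) >= 2) {
    drops <- pos[-length(pos)] / pos[-1]
    which.max(drops)
  } else {
    NA_integer_
  }

  structure(list(entries = entries, metrics = fit$metrics,
                 elbow = as.integer(elbow)),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, n = 10, ...) {
  cat("Variable importance ranking (increase in pmc under permutation)\n")
  print(utils::head(x$entries, n))
  if (nrow(x$entries) > n) cat("... ", nrow(x$entries) - n, " more\n")
  invisible(x)
}

#' Select the top-ranked determinants
#'
#' @param ranking An [permutation_importance()] ranking.
#' @param top_k Number of determinants to keep.
#' @return Character vector of item ids, best first.
#' @export
select_determinants <- function(ranking, top_k = 20) {
  stopifnot(inherits(ranking, "importance_ranking"))
  p <- nrow(ranking$entries)
  check_count(top_k, "top_k", min = 1)
  if (top_k > p) {
    stop("`top_k` (", top_k, ") exceeds the number of predictors (", p, ")",
         call. = FALSE)
  }
  ranking$entries$item[seq_len(top_k)]
}

#' Plot the variable importance ranking
#'
#' Dot chart with items on the y-axis (most important on top) and the
#' increase in pmc on a zero-anchored x-axis.
#'
#' @param ranking An [permutation_importance()] ranking.
#' @param file Optional output file (any device [ggplot2::ggsave()]
#'   understands, e.g. `.pdf`); when `NULL` the plot object is returned
#'   without writing.
#' @param top_n Show only the first `top_n` entries (default: all).
#' @return The ggplot object, invisibly when written to `file`.
#' @export
plot_vir <- function(ranking, file = NULL, top_n = NULL) {
  stopifnot(inherits(ranking, "importance_ranking"))
  df <- ranking$entries
  if (nrow(df) == 0) stop("empty ranking", call. = FALSE)
  if (!is.null(top_n)) df <- utils::head(df, top_n)
  df$item <- factor(df$item, levels = rev(df$item))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$importance,
                                        y = .data$item)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::expand_limits(x = 0) +
    ggplot2::labs(x = "Increase in pmc", y = NULL,
                  title = "Variable importance ranking") +
    ggplot2::theme_minimal()
  if (is.null(file)) return(p)
  ggplot2::ggsave(file, p, width = 7,
                  height = max(2, 0.25 * nrow(df) + 1.5))
  invisible(p)
}
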