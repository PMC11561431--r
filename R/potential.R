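#' Cohen's d between intention groups
#'
#' The standardized difference between the mean score of the
#' neutral/negative-intention group and the positive-intention group,
#' divided by the pooled standard deviation
#' `sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`. Because 1 is the
#' favorable end of the scale, d is positive whenever the
#' positive-intention group scores more favorably (lower). The 95% CI uses
#' the large-sample normal approximation with
#' `SE(d) = sqrt(1/n1 + 1/n2 + d^2 / (2(n1+n2)))`.
#'
#' @param scores Numeric vector of item or cluster scores.
#' @param group Factor from [dichotomize_intention()] (levels `positive`,
#'   `neutral_negative`), one value per score.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `d`, `ci` (length-2 vector), `se`, and the group
#'   sizes.
#' @export
cohens_d <- function(scores, group, conf_level = 0.95) {
  group <- as.factor(group)
  if (!all(c("positive", "neutral_negative") %in% levels(group))) {
    stop("`group` must have levels positive and neutral_negative",
         call. = FALSE)
  }
  pos <- scores[group == "positive"]
  neg <- scores[group == "neutral_negative"]
  n1 <- length(pos); n2 <- length(neg)
  if (n1 < 2 || n2 < 2) {
    stop("both intention groups need at least 2 members (got ",
         n1, " and ", n2, ")", call. = FALSE)
  }
  pooled <- sqrt(((n1 - 1) * stats::var(pos) + (n2 - 1) * stats::var(neg)) /
                   (n1 + n2 - 2))
  if (pooled == 0) stop("zero pooled SD; d is undefined", call. = FALSE)
  d <- (mean(neg) - mean(pos)) / pooled
  se <- sqrt(1 / n1 + 1 / n2 + d^2 / (2 * (n1 + n2)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(d = d, ci = c(d - z * se, d + z * se), se = se, n_pos = n1,
       n_neg = n2)
}

#' Mean with a t-based confidence interval
#'
#' @param scores Numeric vector (length at least 2).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `mean`, `ci`, `sd`, `n`.
#' @export
mean_ci <- function(scores, conf_level = 0.95) {
  n <- length(scores)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  m <- mean(scores)
  s <- sd(scores)
  half <- qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
  list(mean = m, ci = c(m - half, m + half), sd = s, n = n)
}

#' Potential for Change Index
#'
#' `PCI = |1 - mean| * d^2`: the room for improvement of an item or
#' cluster (distance of its mean from 1, the most favorable score) times
#' the squared Cohen's d of its association with intention, which
#' penalizes weakly associated determinants. PCI is 0 exactly when the
#' mean is already at the favorable end or when d is 0.
#'
#' @param mean Mean score on the 1-5 scale.
#' @param d Cohen's d.
#' @return The PCI at full precision (round to 2 decimals for reporting).
#' @export
compute_pci <- function(mean, d) {
  if (any(mean < 1 | mean > 5)) {
    stop("`mean` must lie on the 1-5 scale", call. = FALSE)
  }
  abs(1 - mean) * d^2
}

#' Change-potential table for determinants and clusters
#'
#' One record per selected item and one per cluster (the cluster score of
#' a respondent is the mean of their member-item scores): overall mean and
#' SD, group means with 95% CIs, Cohen's d with 95% CI, and the PCI.
#' Within each cluster block, item rows are sorted by PCI descending with
#' the cluster row last.
#'
#' @param responses Harmonized response table.
#' @param outcome Factor from [dichotomize_intention()].
#' @param assignment Named vector (item -> cluster id), e.g. from a
#'   [cluster_determinants()] solution.
#' @return Tibble with columns `entity`, `level` (`item`/`cluster`),
#'   `cluster`, `mean`, `sd`, `mean_pos`, `pos_lo`, `pos_hi`, `mean_neg`,
#'   `neg_lo`, `neg_hi`, `d`, `d_lo`, `d_hi`, `pci`.
#' @export
change_potential_table <- function(responses, outcome, assignment) {
  outcome <- as.factor(outcome)
  items <- names(assignment)
  missing_items <- setdiff(items, names(responses))
  if (length(missing_items) > 0) {
    stop("item(s) not in the data: ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }

  record <- function(entity, level, cluster, scores) {
    overall <- mean_ci(scores)
    pos <- mean_ci(scores[outcome == "positive"])
    neg <- mean_ci(scores[outcome == "neutral_negative"])
    eff <- cohens_d(scores, outcome)
    tibble::tibble(
      entity = entity, level = level, cluster = cluster,
      mean = overall$mean, sd = overall$sd,
      mean_pos = pos$mean, pos_lo = pos$ci[1], pos_hi = pos$ci[2],
      mean_neg = neg$mean, neg_lo = neg$ci[1], neg_hi = neg$ci[2],
      d = eff$d, d_lo = eff$ci[1], d_hi = eff$ci[2],
      pci = compute_pci(overall$mean, eff$d)
    )
  }

  blocks <- lapply(sort(unique(assignment)), function(cl) {
    mem <- items[assignment == cl]
    rows <- dplyr::bind_rows(lapply(mem, function(it) {
      record(it, "item", cl, as.numeric(responses[[it]]))
    }))
    rows <- rows[order(-rows$pci, rows$entity), ]
    cluster_row <- record(paste0("cluster_", cl), "cluster", cl,
                          rowMeans(responses[mem]))
    dplyr::bind_rows(rows, cluster_row)
  })
  dplyr::bind_rows(blocks)
}

#' CIBER-style plot of determinant relevance
#'
#' Confidence-interval-based estimation of relevance: the left panel shows
#' each entity's score distribution as jittered dots colored by intention
#' group, with 95% CI diamonds for the two group means; the right panel
#' shows the 95% CI of Cohen's d. Item plots are ordered by the importance
#' ranking, cluster plots by dendrogram order.
#'
#' @param records A [change_potential_table()] tibble.
#' @param responses Harmonized response table (for the score dots).
#' @param outcome Factor from [dichotomize_intention()].
#' @param assignment Item -> cluster assignment used for the records.
#' @param level Plot `"item"` or `"cluster"` records.
#' @param order Character vector of entity ids giving the top-to-bottom
#'   order (e.g. the VIR item order, or cluster labels in dendrogram
#'   order); default keeps table order.
#' @param file Optional output file; `NULL` returns the plot object.
#' @param seed Seed for the jitter, so a written figure is reproducible.
#' @return The ggplot object, invisibly when written to `file`.
#' @export
plot_ciber <- function(records, responses, outcome, assignment,
                       level = c("item", "cluster"), order = NULL,
                       file = NULL, seed = 1L) {
  level <- match.arg(level)
  recs <- records[records$level == level, ]
  if (nrow(recs) == 0) stop("no records at level ", level, call. = FALSE)
  if (is.null(order)) order <- recs$entity
  recs <- recs[match(order, recs$entity), ]
  recs <- recs[!is.na(recs$entity), ]
  outcome <- as.factor(outcome)

  entity_scores <- function(entity, cluster) {
    if (level == "item") {
      as.numeric(responses[[entity]])
    } else {
      mem <- names(assignment)[assignment == cluster]
      rowMeans(responses[mem])
    }
  }

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  dots <- dplyr::bind_rows(lapply(seq_len(nrow(recs)), function(i) {
    s <- entity_scores(recs$entity[i], recs$cluster[i])
    keep <- sample.int(length(s), min(length(s), 400)) # cap overplotting
    tibble::tibble(entity = recs$entity[i], score = s[keep],
                   group = outcome[keep])
  }))
  lv <- rev(recs$entity)
  dots$entity <- factor(dots$entity, levels = lv)
  recs$entity_f <- factor(recs$entity, levels = lv)

  means <- tidyr::pivot_longer(
    recs[c("entity", "mean_pos", "pos_lo", "pos_hi",
           "mean_neg", "neg_lo", "neg_hi")],
    cols = -"entity", names_to = "what", values_to = "value"
  )
  means$group <- ifelse(grepl("pos", means$what), "positive",
                        "neutral_negative")
  means$stat <- sub(".*(mean|lo|hi).*", "\\1",
                    sub("mean_(pos|neg)", "mean", means$what))
  means <- tidyr::pivot_wider(means[c("entity", "group", "stat", "value")],
                              names_from = "stat", values_from = "value")
  means$entity <- factor(means$entity, levels = lv)

  cols <- c(positive = "#2e7d32", neutral_negative = "#6a1b9a")
  left <- ggplot2::ggplot() +
    ggplot2::geom_jitter(
      data = dots,
      ggplot2::aes(x = .data$score, y = .data$entity, color = .data$group),
      width = 0.15, height = 0.22, alpha = 0.15, size = 0.6
    ) +
    ggplot2::geom_errorbarh(
      data = means,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, y = .data$entity,
                   color = .data$group),
      height = 0.35, linewidth = 0.9
    ) +
    ggplot2::geom_point(
      data = means,
      ggplot2::aes(x = .data$mean, y = .data$entity, color = .data$group),
      shape = 18, size = 3
    ) +
    ggplot2::scale_color_manual(values = cols) +
    ggplot2::coord_cartesian(xlim = c(1, 5)) +
    ggplot2::labs(x = "Score (1 = most favorable)", y = NULL,
                  color = "Intention") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")

  right <- ggplot2::ggplot(recs) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$d_lo, xmax = .data$d_hi,
                   y = .data$entity_f),
      height = 0.35, linewidth = 0.9, color = "grey30"
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$d, y = .data$entity_f),
                        shape = 18, size = 3, color = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::labs(x = "Cohen's d (95% CI)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())

  p <- combine_panels(left, right, widths = c(2.2, 1))
  if (is.null(file)) return(p)
  grDevices::pdf(file, width = 9, height = max(2.5, 0.45 * nrow(recs) + 2))
  on.exit(grDevices::dev.off(), add = TRUE)
  grid::grid.draw(p)
  invisible(p)
}

# side-by-side layout of two ggplots without an extra dependency
combine_panels <- function(left, right, widths = c(2, 1)) {
  gl <- ggplot2::ggplotGrob(left)
  gr <- ggplot2::ggplotGrob(right)
  maxh <- grid::unit.pmax(gl$heights, gr$heights)
  gl$heights <- maxh
  gr$heights <- maxh
  panel_row(gl, gr, widths)
}

panel_row <- function(gl, gr, widths) {
  g <- gtable::gtable(
    widths = grid::unit(widths, "null"),
    heights = grid::unit(1, "null")
  )
  g <- gtable::gtable_add_grob(g, gl, t = 1, l = 1)
  gtable::gtable_add_grob(g, gr, t = 1, l = 2)
}
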