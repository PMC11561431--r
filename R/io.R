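#' Validate a questionnaire codebook
#'
#' A codebook declares, for every column of a response table, its `id`,
#' human-readable `label`, `role` (`predictor`, `outcome`, `followup`, or
#' `demographic`), `scale` (`likert5`, `categorical`, or `binary`) and
#' whether the raw item is `reverse_coded` (so that after harmonization 1 is
#' always the most favorable answer and 5 the least favorable).
#'
#' @param x A data frame with columns `id`, `label`, `role`, `scale`,
#'   `reverse_coded` (`label` is optional and defaults to `id`).
#' @return The validated codebook as a tibble of class `detana_codebook`.
#' @export
codebook <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"label" %in% names(x)) x$label <- x$id
  needed <- c("id", "label", "role", "scale", "reverse_coded")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("codebook lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[needed]
  x$reverse_coded <- as.logical(x$reverse_coded)
  roles <- c("predictor", "outcome", "followup", "demographic")
  scales <- c("likert5", "categorical", "binary")
  if (any(!x$role %in% roles)) {
    stop("unknown role(s): ",
         paste(unique(x$role[!x$role %in% roles]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!x$scale %in% scales)) {
    stop("unknown scale(s): ",
         paste(unique(x$scale[!x$scale %in% scales]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$id)) {
    stop("codebook ids must be unique; duplicated: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (sum(x$role == "outcome") != 1) {
    stop("codebook must declare exactly one outcome item, found ",
         sum(x$role == "outcome"), call. = FALSE)
  }
  if (any(x$reverse_coded & x$scale != "likert5")) {
    stop("only likert5 items can be reverse coded", call. = FALSE)
  }
  class(x) <- c("detana_codebook", class(x))
  x
}

#' Read a codebook from CSV or JSON
#'
#' @param path Path to a CSV file (columns as in [codebook()]) or a JSON
#'   file holding an array of per-item records.
#' @return A validated codebook.
#' @export
read_codebook <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
  } else {
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  codebook(x)
}

outcome_item <- function(cb) cb$id[cb$role == "outcome"]

likert_items <- function(cb) cb$id[cb$scale == "likert5"]

#' Read and harmonize a questionnaire response table
#'
#' Reads a respondent-by-item CSV, checks every column against the
#' codebook, maps reverse-coded Likert items through `v -> 6 - v` so that 1
#' is always the most favorable end, and drops incomplete respondents
#' (any missing predictor, demographic, or outcome value), keeping only
#' completers for analysis. Follow-up items, asked only of a subgroup, may
#' be missing without causing a drop.
#'
#' @param path CSV file with a header row of item ids (an optional
#'   `respondent` id column is carried through).
#' @param cb A [codebook()].
#' @param sep Field separator, `","` by default (use `";"` for
#'   semicolon-delimited exports).
#' @return A tibble of harmonized responses with attributes `n_started`
#'   (rows read), `n_dropped` (incomplete rows removed) and `codebook`.
#' @export
read_responses <- function(path, cb, sep = ",") {
  cb <- codebook(cb)
  raw <- readr::read_delim(path, delim = sep, show_col_types = FALSE,
                           progress = FALSE)
  harmonize_responses(raw, cb)
}

#' Harmonize an in-memory response table against a codebook
#'
#' @param raw Data frame of raw responses.
#' @param cb A [codebook()].
#' @return As [read_responses()].
#' @export
harmonize_responses <- function(raw, cb) {
  cb <- codebook(cb)
  raw <- tibble::as_tibble(raw)
  id_col <- intersect("respondent", names(raw))
  data_cols <- setdiff(names(raw), id_col)

  unknown <- setdiff(data_cols, cb$id)
  if (length(unknown) > 0) {
    stop("column(s) not declared in the codebook: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(cb$id, data_cols)
  if (outcome_item(cb) %in% absent) {
    stop("outcome column `", outcome_item(cb), "` is missing from the data",
         call. = FALSE)
  }
  if (length(absent) > 0) {
    stop("codebook item(s) absent from the data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  n_started <- nrow(raw)
  for (item in likert_items(cb)) {
    v <- raw[[item]]
    if (!is.numeric(v)) {
      stop("likert5 column `", item, "` is not numeric", call. = FALSE)
    }
    bad <- which(!is.na(v) & (v < 1 | v > 5 | v != round(v)))
    if (length(bad) > 0) {
      stop("value ", v[bad[1]], " out of the 1-5 range in column `", item,
           "`, row ", bad[1], call. = FALSE)
    }
    raw[[item]] <- as.integer(v)
  }
  for (item in cb$id[cb$reverse_coded]) {
    raw[[item]] <- 6L - raw[[item]]
  }

  required <- cb$id[cb$role %in% c("predictor", "demographic", "outcome")]
  complete <- stats::complete.cases(raw[required])
  out <- raw[complete, c(id_col, cb$id)]
  if (nrow(out) == 0) stop("no complete responses remain", call. = FALSE)
  attr(out, "n_started") <- n_started
  attr(out, "n_dropped") <- n_started - nrow(out)
  attr(out, "codebook") <- cb
  out
}

#' Dichotomize the 5-level intention item
#'
#' Respondents answering at the two most favorable levels ("very willing"
#' or "willing"; harmonized codes 1 and 2) are classified as having a
#' positive intention; "neutral", "unwilling" and "very unwilling" (codes
#' 3-5) as neutral/negative.
#'
#' @param raw Integer codes 1-5 or the level labels above (case and
#'   whitespace insensitive, e.g. `"Very willing"`).
#' @return Factor with levels `positive`, `neutral_negative`.
#' @export
dichotomize_intention <- function(raw) {
  if (is.character(raw) || is.factor(raw)) {
    labels <- c("very willing" = 1L, "willing" = 2L, "neutral" = 3L,
                "unwilling" = 4L, "very unwilling" = 5L)
    key <- tolower(trimws(as.character(raw)))
    unknown <- setdiff(unique(key[!is.na(key)]), names(labels))
    if (length(unknown) > 0) {
      stop("unmapped intention level(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    raw <- labels[key]
  }
  if (any(!is.na(raw) & !(raw %in% 1:5))) {
    stop("intention codes must lie in 1-5", call. = FALSE)
  }
  factor(ifelse(raw <= 2, "positive", "neutral_negative"),
         levels = c("positive", "neutral_negative"))
}

#' Per-item descriptive statistics
#'
#' For Likert items, the n, mean and sample (n-1) SD; for categorical and
#' binary items, level counts and proportions. If the codebook declares a
#' likert5 outcome, an extra pair of rows reports the proportions of the
#' dichotomized intention classes.
#'
#' @param responses A harmonized response table from [read_responses()] or
#'   [harmonize_responses()].
#' @param cb Codebook; defaults to the one attached to `responses`.
#' @return A tibble with columns `item`, `scale`, `level`, `n`, `mean`,
#'   `sd`, `proportion` (`level`/`proportion` are `NA` for Likert rows;
#'   `mean`/`sd` for categorical rows).
#' @export
describe_items <- function(responses, cb = attr(responses, "codebook")) {
  if (is.null(cb)) stop("no codebook available", call. = FALSE)
  cb <- codebook(cb)
  if (nrow(responses) == 0) stop("empty response table", call. = FALSE)

  rows <- lapply(seq_len(nrow(cb)), function(i) {
    item <- cb$id[i]
    v <- responses[[item]]
    v <- v[!is.na(v)]
    if (cb$scale[i] == "likert5") {
      tibble::tibble(item = item, scale = "likert5", level = NA_character_,
                     n = length(v), mean = mean(v), sd = sd(v),
                     proportion = NA_real_)
    } else {
      tab <- table(v)
      tibble::tibble(item = item, scale = cb$scale[i],
                     level = names(tab), n = as.integer(tab),
                     mean = NA_real_, sd = NA_real_,
                     proportion = as.numeric(tab) / length(v))
    }
  })
  out <- dplyr::bind_rows(rows)

  oc <- outcome_item(cb)
  if (cb$scale[cb$id == oc] == "likert5") {
    cls <- dichotomize_intention(responses[[oc]])
    tab <- table(cls)
    out <- dplyr::bind_rows(out, tibble::tibble(
      item = paste0(oc, "_class"), scale = "binary",
      level = names(tab), n = as.integer(tab),
      mean = NA_real_, sd = NA_real_,
      proportion = as.numeric(tab) / length(cls)
    ))
  }
  out
}
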