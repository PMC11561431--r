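#' Configuration of a full determinant-analysis run
#'
#' A run executes the four analysis stages in order: descriptives,
#' random-forest ranking, determinant clustering, and change-potential
#' assessment — on either an existing dataset (`data` + `codebook` paths)
#' or on data simulated from a [synthetic_design()].
#'
#' @param output_dir Directory for artifacts (created if needed).
#' @param data,codebook_path Paths to a response CSV and its codebook;
#'   both `NULL` to simulate instead.
#' @param design A [synthetic_design()] used when no data is given.
#' @param ranking A [ranking_config()].
#' @param k Number of clusters; `NULL` applies the compactness/separation
#'   rule.
#' @param seed Master seed; each stage derives its own stream from it.
#' @param plots Write figure files (PDF)?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, data = NULL, codebook_path = NULL,
                            design = synthetic_design(),
                            ranking = ranking_config(), k = NULL,
                            seed = 1L, plots = TRUE) {
  if (is.null(data) != is.null(codebook_path)) {
    stop("`data` and `codebook_path` must be given together", call. = FALSE)
  }
  if (!is.null(data)) {
    for (p in c(data, codebook_path)) {
      if (!file.exists(p)) stop("path not found: ", p, call. = FALSE)
    }
  }
  check_count(seed, "seed", min = -2^31 + 1)
  structure(list(output_dir = output_dir, data = data,
                 codebook_path = codebook_path, design = design,
                 ranking = ranking, k = k, seed = as.integer(seed),
                 plots = isTRUE(plots)),
            class = "pipeline_config")
}

meta_header <- function(stage, seed, hash) {
  c(sprintf("# detana %s", as.character(utils::packageVersion("detana"))),
    sprintf("# stage: %s", stage),
    sprintf("# seed: %d", seed),
    sprintf("# hash: %s", hash))
}

write_csv_meta <- function(x, path, stage, seed, hash) {
  writeLines(meta_header(stage, seed, hash), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
}

read_csv_meta <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

stage_hash <- function(...) rlang::hash(list(...))

#' Run the determinant-analysis pipeline
#'
#' Executes simulate/load, describe, rank, cluster, and potential in
#' order, writing every artifact (CSV tables with a commented metadata
#' header, JSON metrics, PDF figures) plus a `manifest.json` recording the
#' seed, stage hashes, and file checksums. Stages whose inputs are
#' unchanged since the manifest in `output_dir` was written are reused
#' from disk instead of recomputed, so changing e.g. `top_k` only reruns
#' the ranking and everything downstream.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory, the manifest, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  prev <- if (file.exists(out("manifest.json"))) {
    jsonlite::fromJSON(out("manifest.json"), simplifyVector = FALSE)
  } else {
    NULL
  }
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("detana")),
                   stages = list())
  upstream_fresh <- FALSE

  cached <- function(stage, hash, files) {
    if (upstream_fresh || is.null(prev)) return(FALSE)
    rec <- prev$stages[[stage]]
    !is.null(rec) && identical(rec$hash, hash) &&
      all(file.exists(vapply(files, out, "")))
  }
  record <- function(stage, hash, files, computed) {
    manifest$stages[[stage]] <<- list(
      hash = hash, computed = computed,
      files = as.list(tools::md5sum(vapply(files, out, "")))
    )
    if (computed) upstream_fresh <<- TRUE
  }

  run_stage <- function(stage, hash, files, compute, reload) {
    if (cached(stage, hash, files)) {
      res <- reload()
      record(stage, hash, files, FALSE)
    } else {
      res <- tryCatch(compute(), error = function(e) {
        stop("stage `", stage, "` failed: ", conditionMessage(e),
             call. = FALSE)
      })
      record(stage, hash, files, TRUE)
    }
    res
  }

  # ---- stage: data (simulate or load) --------------------------------------
  if (is.null(config$data)) {
    design <- config$design
    design$seed <- config$seed
    h <- stage_hash("simulate", design)
    dat <- run_stage(
      "data", h, c("data.csv", "codebook.csv", "truth.json"),
      compute = function() {
        sim <- generate_responses(design)
        write_csv_meta(sim$responses, out("data.csv"), "data",
                       config$seed, h)
        write_csv_meta(as_tibble(unclass(sim$codebook)[
          c("id", "label", "role", "scale", "reverse_coded")
        ]), out("codebook.csv"), "data", config$seed, h)
        jsonlite::write_json(
          list(true_assignment = as.list(sim$true_assignment),
               true_effects = as.list(sim$true_effects),
               realized_positive_rate = sim$realized_positive_rate),
          out("truth.json"), auto_unbox = TRUE, digits = NA
        )
        sim
      },
      reload = function() {
        cb <- codebook(read_csv_meta(out("codebook.csv")))
        list(responses = harmonize_responses(read_csv_meta(out("data.csv")),
                                             cb),
             codebook = cb)
      }
    )
    responses <- harmonize_responses(dat$responses, dat$codebook)
    cb <- dat$codebook
  } else {
    cb <- read_codebook(config$codebook_path)
    h <- stage_hash("load", unname(tools::md5sum(config$data)),
                    unname(tools::md5sum(config$codebook_path)))
    responses <- read_responses(config$data, cb)
    record("data", h, character(0),
           is.null(prev) || !identical(prev$stages$data$hash, h))
  }
  outcome <- dichotomize_intention(responses[[outcome_item(cb)]])

  # ---- stage: describe -----------------------------------------------------
  h_desc <- stage_hash("describe", manifest$stages$data$hash)
  descriptives <- run_stage(
    "describe", h_desc, "descriptives.csv",
    compute = function() {
      d <- describe_items(responses, cb)
      write_csv_meta(d, out("descriptives.csv"), "describe",
                     config$seed, h_desc)
      d
    },
    reload = function() read_csv_meta(out("descriptives.csv"))
  )

  # ---- stage: rank ---------------------------------------------------------
  rk <- config$ranking
  rk$seed <- config$seed + 1L
  rank_files <- c("vir.csv", "metrics.json",
                  if (config$plots) "vir.pdf")
  h_rank <- stage_hash("rank", manifest$stages$data$hash, rk, config$plots)
  ranking <- run_stage(
    "rank", h_rank, rank_files,
    compute = function() {
      fit <- fit_forest(responses, outcome, rk, cb)
      r <- permutation_importance(fit)
      write_csv_meta(r$entries, out("vir.csv"), "rank", config$seed, h_rank)
      jsonlite::write_json(c(r$metrics, list(elbow = r$elbow)),
                           out("metrics.json"), auto_unbox = TRUE,
                           digits = NA)
      if (config$plots) plot_vir(r, out("vir.pdf"))
      r
    },
    reload = function() {
      m <- jsonlite::fromJSON(out("metrics.json"))
      structure(list(entries = read_csv_meta(out("vir.csv")),
                     metrics = m[c("pmc", "sens", "spec", "auc")],
                     elbow = m$elbow),
                class = "importance_ranking")
    }
  )
  determinants <- select_determinants(
    ranking, min(rk$top_k, nrow(ranking$entries)))

  # ---- stage: cluster ------------------------------------------------------
  clus_files <- c("clusters.json", "curve.csv",
                  if (config$plots) "dendrogram.pdf")
  h_clus <- stage_hash("cluster", h_rank, determinants, config$k,
                       config$plots)
  solution <- run_stage(
    "cluster", h_clus, clus_files,
    compute = function() {
      sol <- cluster_determinants(responses, determinants, k = config$k)
      jsonlite::write_json(
        list(k = sol$k, ccc = sol$ccc, compactness = sol$compactness,
             separation = sol$separation,
             assignment = as.list(sol$assignment),
             profiles = sol$profiles),
        out("clusters.json"), auto_unbox = TRUE, digits = NA
      )
      write_csv_meta(sol$curve, out("curve.csv"), "cluster",
                     config$seed, h_clus)
      if (config$plots) plot_dendrogram(sol$dendrogram, sol$k,
                                        out("dendrogram.pdf"))
      sol
    },
    reload = function() {
      cl <- jsonlite::fromJSON(out("clusters.json"))
      list(k = cl$k, ccc = cl$ccc, compactness = cl$compactness,
           separation = cl$separation,
           assignment = unlist(cl$assignment),
           profiles = tibble::as_tibble(cl$profiles),
           curve = read_csv_meta(out("curve.csv")))
    }
  )

  # ---- stage: potential ----------------------------------------------------
  pot_files <- c("change_potential.csv",
                 if (config$plots) c("ciber_items.pdf",
                                     "ciber_clusters.pdf"))
  h_pot <- stage_hash("potential", h_clus)
  records <- run_stage(
    "potential", h_pot, pot_files,
    compute = function() {
      tab <- change_potential_table(responses, outcome, solution$assignment)
      write_csv_meta(tab, out("change_potential.csv"), "potential",
                     config$seed, h_pot)
      if (config$plots) {
        plot_ciber(tab, responses, outcome, solution$assignment,
                   level = "item", order = intersect(determinants,
                                                    tab$entity),
                   file = out("ciber_items.pdf"), seed = config$seed + 2L)
        plot_ciber(tab, responses, outcome, solution$assignment,
                   level = "cluster",
                   order = paste0("cluster_", unique(
                     solution$assignment[dendrogram_item_order(solution)])),
                   file = out("ciber_clusters.pdf"),
                   seed = config$seed + 3L)
      }
      tab
    },
    reload = function() read_csv_meta(out("change_potential.csv"))
  )

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(dir = config$output_dir, manifest = manifest,
                 responses = responses, codebook = cb, outcome = outcome,
                 descriptives = descriptives, ranking = ranking,
                 determinants = determinants, solution = solution,
                 records = records))
}

dendrogram_item_order <- function(solution) {
  dend <- solution$dendrogram
  if (!is.null(dend)) {
    dend$labels[dend$order]
  } else {
    names(solution$assignment)
  }
}

#' Render a markdown summary report of a pipeline run
#'
#' Assembles the run's artifacts — sample size and descriptives, model
#' metrics, the chosen number of clusters with compactness/separation and
#' CCC, the change-potential table, and pointers to the figure files —
#' into a single markdown document. Missing artifacts are listed as
#' absent; the report renders regardless. Rebuilding the report from the
#' same run directory reproduces it byte for byte.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @param file Output path; defaults to `report.md` inside `run_dir`.
#' @return The output path, invisibly.
#' @export
summary_report <- function(run_dir, file = file.path(run_dir, "report.md")) {
  art <- function(f) file.path(run_dir, f)
  if (!file.exists(art("manifest.json"))) {
    stop("no manifest.json in ", run_dir, call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(art("manifest.json"),
                                 simplifyVector = FALSE)
  lines <- c("# Determinant analysis report", "",
             sprintf("Package detana %s, master seed %d.",
                     manifest$version, manifest$seed), "")
  absent <- character(0)

  fmt_tab <- function(df, digits = 3) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                   format = "fg"))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "),
                                           "|"))
    c(header, sep, body)
  }

  if (file.exists(art("descriptives.csv"))) {
    d <- read_csv_meta(art("descriptives.csv"))
    n <- max(d$n, na.rm = TRUE)
    lines <- c(lines, "## Sample", "",
               sprintf("%d completers analyzed; %d descriptive rows.",
                       n, nrow(d)), "")
    cls <- d[grepl("_class$", d$item), c("item", "level", "n", "proportion")]
    if (nrow(cls) > 0) lines <- c(lines, fmt_tab(cls), "")
  } else {
    absent <- c(absent, "descriptives.csv")
  }

  if (file.exists(art("metrics.json")) && file.exists(art("vir.csv"))) {
    m <- jsonlite::fromJSON(art("metrics.json"))
    vir <- read_csv_meta(art("vir.csv"))
    lines <- c(lines, "## Determinant ranking", "",
               sprintf(paste("Random-forest out-of-bag estimates: pmc %.3f,",
                             "sensitivity %.3f, specificity %.3f, AUC %.3f."),
                       m$pmc, m$sens, m$spec, m$auc), "",
               fmt_tab(utils::head(vir, 20)), "")
  } else {
    absent <- c(absent, "metrics.json / vir.csv")
  }

  if (file.exists(art("clusters.json"))) {
    cl <- jsonlite::fromJSON(art("clusters.json"))
    lines <- c(lines, "## Determinant clusters", "",
               sprintf(paste("k = %d clusters (compactness %.3f,",
                             "separation %.3f), CCC %.3f."),
                       cl$k, cl$compactness, cl$separation, cl$ccc), "",
               fmt_tab(tibble::as_tibble(cl$profiles)), "")
  } else {
    absent <- c(absent, "clusters.json")
  }

  if (file.exists(art("change_potential.csv"))) {
    tab <- read_csv_meta(art("change_potential.csv"))
    lines <- c(lines, "## Change potential", "",
               fmt_tab(tab[c("entity", "level", "cluster", "mean", "sd",
                             "d", "d_lo", "d_hi", "pci")]), "")
  } else {
    absent <- c(absent, "change_potential.csv")
  }

  figures <- c("vir.pdf", "dendrogram.pdf", "ciber_items.pdf",
               "ciber_clusters.pdf")
  have <- figures[file.exists(vapply(figures, art, ""))]
  if (length(have) > 0) {
    lines <- c(lines, "## Figures", "", paste0("- ", have), "")
  }
  if (length(absent) > 0) {
    lines <- c(lines, "## Absent artifacts", "", paste0("- ", absent), "")
  }
  writeLines(lines, file)
  invisible(file)
}
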