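#' Assemble a pipeline configuration
#'
#' Collects every setting the end-to-end pipeline needs. Defaults follow
#' the empirical setup the package was designed around: study period
#' 24 Jan 2020 - 3 Sep 2020 anchored at the 12 Dec 2019 outbreak start,
#' vocabulary pruning at absolute frequency 4 and 80% document frequency,
#' a topic grid of 5-30 in steps of 1, and 7-day windows.
#'
#' @param input Path to the metadata file (or `NULL` when `records` are
#'   passed to [run_pipeline()] directly).
#' @param dialect `"cord19_csv"` or `"jsonl"`.
#' @param period A [study_period()].
#' @param min_abs_freq,max_rel_df Vocabulary pruning thresholds.
#' @param k Fixed topic count, or `NULL` to select over `k_grid`.
#' @param k_grid Candidate topic counts when `k` is `NULL`.
#' @param seed Integer seed for every random element.
#' @param max_iter,tol NMF solver settings.
#' @param stability_runs,stability_frac,stability_depth Stability
#'   diagnostic settings.
#' @param w_days,n_windows Window geometry (`n_windows = NULL` covers the
#'   period).
#' @param theta_cv,min_sign_changes,amp_frac Type-classification
#'   thresholds; see [classify_type()].
#' @param alpha Significance level for trend tests.
#' @param out_dir Output directory for artifacts, or `NULL` for none.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            dialect = c("cord19_csv", "jsonl"),
                            period = study_period("2020-01-24", "2020-09-03",
                                                  "2019-12-12"),
                            min_abs_freq = 4, max_rel_df = 0.8,
                            k = NULL, k_grid = 5:30,
                            seed = 42L, max_iter = 200L, tol = 1e-6,
                            stability_runs = 10, stability_frac = 0.8,
                            stability_depth = 10,
                            w_days = 7, n_windows = NULL,
                            theta_cv = 0.5, min_sign_changes = 3,
                            amp_frac = 0.25, alpha = 0.05,
                            out_dir = NULL) {
  dialect <- match.arg(dialect)
  structure(
    list(input = input, dialect = dialect, period = period,
         min_abs_freq = min_abs_freq, max_rel_df = max_rel_df,
         k = k, k_grid = k_grid, seed = as.integer(seed),
         max_iter = max_iter, tol = tol,
         stability_runs = stability_runs, stability_frac = stability_frac,
         stability_depth = stability_depth,
         w_days = w_days, n_windows = n_windows,
         theta_cv = theta_cv, min_sign_changes = min_sign_changes,
         amp_frac = amp_frac, alpha = alpha, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a JSON file
#'
#' Flat JSON object whose keys match the arguments of
#' [pipeline_config()]; dates are given as the keys `start_date`,
#' `end_date`, `outbreak_start`.
#'
#' @param path Path to the JSON config.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  period <- study_period(
    raw$start_date %||% "2020-01-24",
    raw$end_date %||% "2020-09-03",
    raw$outbreak_start %||% "2019-12-12"
  )
  args <- raw[setdiff(names(raw),
                      c("start_date", "end_date", "outbreak_start"))]
  args$period <- period
  do.call(pipeline_config, args)
}

#' Run the full research-priorities pipeline
#'
#' Executes read, filter, preprocess, topic-number selection (when no
#' fixed `k` is configured), NMF fit, document assignment, the RPM metric
#' suite, and classification. When `config$out_dir` is set, writes
#' `diagnostics.csv` (one row per candidate k), `rpm.csv`,
#' `priorities.csv`, `top_terms.csv` and a `manifest.json` echoing the
#' configuration and seed; identical config + seed reproduces every
#' artifact byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param records Optionally a pre-loaded record tibble (skips reading
#'   `config$input`).
#' @return Invisibly, a list with `records`, `term_matrix`, `diagnostics`
#'   (or `NULL`), `model`, `assignments`, `probabilities`, `partition`,
#'   `rpm`, `priorities`, `report`.
#' @export
run_pipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(records)) {
    records <- stage("read", read_metadata(config$input, config$dialect))
  }
  records <- stage("filter", filter_records(records, config$period))
  if (nrow(records) == 0) stop("pipeline stage 'filter' removed all records",
                               call. = FALSE)
  tokens <- stage("tokenize", tokenize_abstracts(records))
  vocab <- stage("vocabulary",
                 build_vocabulary(tokens, config$min_abs_freq,
                                  config$max_rel_df))
  tm <- stage("tfidf", build_tfidf(tokens, vocab))

  diagnostics <- NULL
  k <- config$k
  if (is.null(k)) {
    diagnostics <- stage("select_k", select_k(
      tm, k_grid = config$k_grid, n_runs = config$stability_runs,
      sample_frac = config$stability_frac, depth = config$stability_depth,
      seed = config$seed, max_iter = config$max_iter, tol = config$tol))
    k <- attr(diagnostics, "k_selected")
  }
  model <- stage("fit", suppressWarnings(
    fit_nmf(tm, k, seed = config$seed, max_iter = config$max_iter,
            tol = config$tol)))
  assignments <- stage("assign", assign_documents(model))
  probabilities <- stage("probabilities", doc_topic_probability(model))
  partition <- stage("windows",
                     partition_windows(config$period, config$w_days,
                                       config$n_windows))
  rpm <- stage("rpm", rpm_table(assignments, probabilities, records,
                                partition, config$period$outbreak_start))
  priorities <- stage("classify", classify_priorities(
    rpm, alpha = config$alpha, theta_cv = config$theta_cv,
    min_sign_changes = config$min_sign_changes,
    amp_frac = config$amp_frac))
  hotspots <- top_terms(model, depth = 5)
  report <- priority_report(priorities, hotspots)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(diagnostics)) {
      write_k_selection(diagnostics, file.path(config$out_dir,
                                               "diagnostics.csv"))
    }
    write_rpm_table(rpm, file.path(config$out_dir, "rpm.csv"))
    write_priority_report(report, file.path(config$out_dir,
                                            "priorities.csv"))
    utils::write.csv(as.data.frame(hotspots),
                     file.path(config$out_dir, "top_terms.csv"),
                     row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("litprior")),
      r_version = R.version.string,
      seed = config$seed, k = k,
      config = config[setdiff(names(config), "period")],
      period = list(start_date = format(config$period$start_date),
                    end_date = format(config$period$end_date),
                    outbreak_start = format(config$period$outbreak_start))
    )
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }

  invisible(list(
    records = records, term_matrix = tm, diagnostics = diagnostics,
    model = model, assignments = assignments,
    probabilities = probabilities, partition = partition, rpm = rpm,
    priorities = priorities, report = report
  ))
}
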