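#' Assemble (or read) a pipeline run configuration
#'
#' A run configuration names the construct, the experiment and control FASTQ
#' pairs, the filter thresholds, whether to composition-normalize, and the
#' output directory. It can be built in code or read from a YAML file with
#' the same field names; the configuration used is always echoed verbatim
#' into the output directory.
#'
#' @param experiment_r1,experiment_r2 Experiment FASTQ paths.
#' @param control_r1,control_r2 Matched no-extension control FASTQ paths.
#' @param out_dir Output directory.
#' @param construct A [construct_spec()], or a path to a construct YAML file
#'   (default: the package's placeholder construct).
#' @param min_mean_q,min_base_q,max_disagreements,min_overlap,search_window
#'   Read-processing thresholds, see [extract_pairs()].
#' @param normalize Apply composition normalization from the control
#'   (default TRUE).
#' @param seed Recorded in the log for provenance (the analysis itself is
#'   deterministic).
#' @return A `run_config` object.
#' @export
run_config <- function(experiment_r1, experiment_r2, control_r1, control_r2,
                       out_dir, construct = construct_spec(),
                       min_mean_q = 30, min_base_q = 20,
                       max_disagreements = 0, min_overlap = 10,
                       search_window = 3, normalize = TRUE, seed = NULL) {
  if (is.character(construct)) construct <- read_construct(construct)
  stopifnot(inherits(construct, "construct_spec"))
  cfg <- list(
    experiment_r1 = experiment_r1, experiment_r2 = experiment_r2,
    control_r1 = control_r1, control_r2 = control_r2,
    out_dir = out_dir, construct = construct,
    min_mean_q = min_mean_q, min_base_q = min_base_q,
    max_disagreements = max_disagreements, min_overlap = min_overlap,
    search_window = search_window, normalize = isTRUE(normalize), seed = seed
  )
  for (f in c("experiment_r1", "experiment_r2", "control_r1", "control_r2")) {
    if (!is.character(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !file.exists(cfg[[f]])) {
      abort(paste0("`", f, "` does not point to an existing file"),
            class = "nerpeseq_config_error")
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML run configuration.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "nerpeseq_config_error")
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$construct) && is.list(y$construct)) {
    y$construct <- do.call(construct_spec, y$construct)
  }
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Extracts template-product pairs from the control and experiment read
#' pairs, derives composition-normalization factors from the control
#' template, computes the full statistics bundle, and writes all artifacts to
#' `config$out_dir`: accepted pair TSVs, filter reports (JSON + text), every
#' statistics table, `summary.json`, the echoed configuration, and a log.
#' Identical inputs and configuration produce byte-identical summaries.
#'
#' @param config A [run_config()] (or a path to a YAML config file).
#' @return The `nerpe_stats` bundle, invisibly, with the experiment and
#'   control filter reports attached as attributes.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  logf("nerpeseq ", as.character(utils::packageVersion("nerpeseq")),
       if (!is.null(config$seed)) paste0(" | seed ", config$seed))
  yaml::write_yaml(
    c(
      lapply(unclass(config)[setdiff(names(config), "construct")], identity),
      list(construct = unclass(config$construct))
    ),
    file.path(config$out_dir, "config_echo.yaml")
  )
  xp <- function(r1, r2, label) {
    pr <- extract_pairs_fastq(
      r1, r2, config$construct,
      min_mean_q = config$min_mean_q, min_base_q = config$min_base_q,
      max_disagreements = config$max_disagreements,
      min_overlap = config$min_overlap,
      search_window = config$search_window
    )
    rep <- filter_report(pr)
    logf(label, ": ", attr(rep, "total"), " read pairs, ",
         nrow(pr), " accepted (",
         paste0(rep$reason[-1], "=", rep$count[-1], collapse = ", "), ")")
    if (nrow(pr) == 0L) {
      abort(paste0("no ", label, " reads survived filtering"),
            class = "nerpeseq_data_error")
    }
    pr
  }
  ctrl <- xp(config$control_r1, config$control_r2, "control")
  expr <- xp(config$experiment_r1, config$experiment_r2, "experiment")
  stats <- nerpe_statistics(expr, control_pairs = ctrl,
                            normalize = config$normalize,
                            template_len = config$construct$template_len)
  write_pairs(expr, file.path(config$out_dir, "pairs.tsv"))
  write_pairs(ctrl, file.path(config$out_dir, "control_pairs.tsv"))
  write_filter_report(filter_report(expr),
                      file.path(config$out_dir, "filter_report_experiment"))
  write_filter_report(filter_report(ctrl),
                      file.path(config$out_dir, "filter_report_control"))
  write_stats(stats, config$out_dir)
  logf("yield ", format(stats$yield_fraction),
       " | error frequency ", format(stats$error_frequency))
  attr(stats, "filter_report_experiment") <- filter_report(expr)
  attr(stats, "filter_report_control") <- filter_report(ctrl)
  invisible(stats)
}

write_filter_report <- function(rep, stem) {
  obj <- as.list(stats::setNames(rep$count, rep$reason))
  obj$total <- attr(rep, "total")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), paste0(stem, ".json"))
  writeLines(
    c(sprintf("%-24s %d", "total", attr(rep, "total")),
      sprintf("%-24s %d", rep$reason, rep$count)),
    paste0(stem, ".txt")
  )
  invisible(stem)
}

#' Compare two pipeline summaries
#'
#' Reads two `summary.json` files (or takes two `nerpe_stats` bundles) and
#' tabulates per-statistic deltas and ratios over the scalar summaries —
#' yield, error frequency, class fractions, trimer medians and extremes.
#'
#' @param a,b Paths to `summary.json` files, or `nerpe_stats` objects.
#' @param labels Length-2 character labels for the two runs.
#' @return A tibble with columns `statistic`, the two values, `delta`
#'   (`b - a`) and `ratio` (`b / a`).
#' @export
compare_runs <- function(a, b, labels = c("a", "b")) {
  load_scalars <- function(x) {
    if (inherits(x, "nerpe_stats")) {
      s <- as.list(glance(x))
      s$schema <- "nerpeseq/summary/1"
    } else {
      if (!file.exists(x)) {
        abort(paste0("summary file not found: ", x),
              class = "nerpeseq_config_error")
      }
      j <- jsonlite::fromJSON(x)
      if (is.null(j$schema) || is.null(j$scalars)) {
        abort("not a nerpeseq summary JSON", class = "nerpeseq_schema_error")
      }
      s <- j$scalars
      s$schema <- j$schema
    }
    s
  }
  sa <- load_scalars(a)
  sb <- load_scalars(b)
  if (!identical(sa$schema, sb$schema)) {
    abort("summary schema versions differ", class = "nerpeseq_schema_error")
  }
  keep <- function(s) {
    s <- s[vapply(s, function(v) is.numeric(v) && length(v) == 1L, TRUE)]
    vapply(s, as.numeric, 0)
  }
  va <- keep(sa)
  vb <- keep(sb)
  if (!identical(names(va), names(vb))) {
    abort("summaries report different statistics",
          class = "nerpeseq_schema_error")
  }
  tibble::tibble(
    statistic = names(va),
    !!labels[1] := unname(va),
    !!labels[2] := unname(vb),
    delta = unname(vb - va),
    ratio = unname(vb / va)
  )
}
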