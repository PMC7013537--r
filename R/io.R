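#' Read incidents from CSV or JSONL
#'
#' The CSV schema is long format, one row per sample, with columns
#' `incident_id`, `label` (`FALL`, `BEND`, or empty), `t_s` (seconds) and
#' `h_m` (meters). The JSONL alternative holds one object per line with
#' fields `id`, `label` (or null), and parallel `t_s`/`h_m` arrays. Every
#' incident is validated; violations are reported with the incident id and
#' the offending file rows.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension, the default), `"csv"`, or
#'   `"jsonl"`.
#' @return List of [incident] objects (empty, with a warning, for an empty
#'   file).
#' @export
read_incidents <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  }
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (file.size(path) == 0L ||
      (format == "csv" && length(readLines(path, n = 2L)) < 2L)) {
    warning(sprintf("%s holds no incidents", path), call. = FALSE)
    return(list())
  }
  if (format == "csv") .read_incidents_csv(path) else .read_incidents_jsonl(path)
}

.read_incidents_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(incident_id = "character",
                                label = "character"))
  need <- c("incident_id", "label", "t_s", "h_m")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  if (!is.numeric(df$t_s) || !is.numeric(df$h_m))
    stop(sprintf("%s: t_s and h_m must be numeric", path), call. = FALSE)
  ids <- unique(df$incident_id)
  lapply(ids, function(id) {
    rows <- which(df$incident_id == id)
    lab <- setdiff(unique(df$label[rows]), c("", NA))
    if (length(lab) > 1L)
      stop(sprintf("incident '%s' (rows %d-%d): conflicting labels %s",
                   id, min(rows) + 1L, max(rows) + 1L,
                   paste(lab, collapse = "/")), call. = FALSE)
    tryCatch(
      incident(id, df$t_s[rows], df$h_m[rows],
               label = if (length(lab)) lab else NA_character_),
      error = function(e)
        stop(sprintf("%s (file rows %d-%d)", conditionMessage(e),
                     min(rows) + 1L, max(rows) + 1L), call. = FALSE))
  })
}

.read_incidents_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning(sprintf("%s holds no incidents", path), call. = FALSE)
    return(list())
  }
  lapply(seq_along(lines), function(i) {
    obj <- jsonlite::fromJSON(lines[i])
    tryCatch(
      incident(obj$id, obj$t_s, obj$h_m,
               label = if (is.null(obj$label)) NA_character_ else obj$label),
      error = function(e)
        stop(sprintf("%s (line %d)", conditionMessage(e), i),
             call. = FALSE))
  })
}

#' Write incidents to CSV or JSONL
#'
#' Deterministic output: fixed column order, 6-decimal float formatting,
#' `\n` line endings, labels written verbatim and missing labels as an
#' empty field — identical datasets produce byte-identical files.
#'
#' @param incidents List of [incident] objects.
#' @param path Output file.
#' @inheritParams read_incidents
#' @return `path`, invisibly.
#' @export
write_incidents <- function(incidents, path,
                            format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  }
  if (format == "csv") {
    rows <- lapply(incidents, function(x) {
      data.frame(incident_id = x$id,
                 label = ifelse(is.na(x$label), "", x$label),
                 t_s = sprintf("%.6f", x$t),
                 h_m = sprintf("%.6f", x$h),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines("incident_id,label,t_s,h_m", con)
    writeLines(paste(df$incident_id, df$label, df$t_s, df$h_m, sep = ","),
               con)
  } else {
    lines <- vapply(incidents, function(x) {
      jsonlite::toJSON(list(id = x$id,
                            label = if (is.na(x$label)) NULL else x$label,
                            t_s = round(x$t, 6), h_m = round(x$h, 6)),
                       auto_unbox = TRUE, digits = NA, null = "null")
    }, "")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Save or load a fitted classifier as JSON
#'
#' Model files are plain structured JSON holding every field of the CM-I or
#' CM-II model, so runs are reproducible and diffable.
#'
#' @param model A `"cm1"` or `"cm2"` model.
#' @param path JSON file path.
#' @return `write_model`: `path`, invisibly. `read_model`: the model.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "cm1")) {
    obj <- list(type = "cm1", r = model$r,
                fall = unclass(model$fall), bend = unclass(model$bend))
  } else if (inherits(model, "cm2")) {
    obj <- list(type = "cm2", checkpoints = model$checkpoints,
                t_fall_ref = model$t_fall_ref,
                t_bend_ref = model$t_bend_ref)
  } else {
    stop("model must be of class cm1 or cm2", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  switch(obj$type,
    cm1 = cm1_model(
      normal_time_model(obj$fall$mu, obj$fall$sigma, obj$fall$support,
                        if (is.null(obj$fall$n_obs)) NA else obj$fall$n_obs),
      normal_time_model(obj$bend$mu, obj$bend$sigma, obj$bend$support,
                        if (is.null(obj$bend$n_obs)) NA else obj$bend$n_obs)),
    cm2 = cm2_model(obj$checkpoints, obj$t_fall_ref, obj$t_bend_ref),
    stop(sprintf("unknown model type '%s' in %s", obj$type, path),
         call. = FALSE))
}

#' Canonical fixture datasets
#'
#' Builds two seeded in-memory datasets used throughout the test suite and
#' examples:
#' * `full` — 86 incidents (41 falls, 45 lean-overs) at the default study
#'   conditions with reduced height noise (0.002 m);
#' * `mini` — 10 noise-free incidents (5 per class) with fixed durations
#'   spread across the class supports, whose trajectories follow the
#'   kinematic profiles exactly (closed-form checks).
#'
#' @param seed Integer seed for the `full` dataset (default 408).
#' @return List with elements `full` and `mini`, each a list of
#'   [incident]s.
#' @export
make_fixtures <- function(seed = 408L) {
  full <- generate_dataset(simulation_config(height_noise_sd = 0.002,
                                             seed = seed))
  t_fall <- c(1.50, 1.68, 1.86, 2.04, 2.22)
  t_bend <- c(2.70, 2.92, 3.14, 3.36, 3.58)
  mini <- c(
    lapply(seq_along(t_fall), function(i)
      simulate_fall(1.72, t_fall[i], id = sprintf("MF%02d", i))),
    lapply(seq_along(t_bend), function(i)
      simulate_bend(1.72, t_bend[i], id = sprintf("MB%02d", i))))
  list(full = full, mini = mini)
}

#' Run configuration for the command-line interface
#'
#' A single structured YAML file drives CLI runs, so that the explicit
#' choice between the two published PDF parameterizations
#' (`parameter_set: section3 | table3`, see [pdf_params()]) is always
#' recorded. Any subset of the defaults may be overridden.
#'
#' @return `default_run_config()`: the default configuration list.
#' @export
default_run_config <- function() {
  list(parameter_set = "section3",
       sigma_as = "variance",
       simulation = list(n_fall = 41L, n_bend = 45L, h0 = 1.72,
                         sample_rate = 30, height_noise_sd = 0.005,
                         seed = 1L),
       classifier = list(model = "cm2", K = 20L),
       evaluation = list(k = 10L, iterations = 100L, seed = 1L))
}

#' @param path YAML file overriding any subset of the defaults.
#' @rdname default_run_config
#' @return `read_run_config()`: the merged configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    merge2 <- function(base, over) {
      for (nm in names(over)) {
        base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
          merge2(base[[nm]], over[[nm]]) else over[[nm]]
      }
      base
    }
    cfg <- merge2(cfg, user)
  }
  if (!cfg$parameter_set %in% c("section3", "table3"))
    stop("parameter_set must be 'section3' or 'table3'", call. = FALSE)
  cfg
}

#' @param cfg A run configuration list from [read_run_config()].
#' @rdname default_run_config
#' @return `sim_config_from_run()`: the [simulation_config()] a run
#'   configuration resolves to.
#' @export
sim_config_from_run <- function(cfg) {
  ps <- pdf_params(cfg$parameter_set, cfg$sigma_as)
  s <- cfg$simulation
  simulation_config(n_fall = s$n_fall, n_bend = s$n_bend, h0 = s$h0,
                    sample_rate = s$sample_rate,
                    fall_model = ps$fall, bend_model = ps$bend,
                    height_noise_sd = s$height_noise_sd, seed = s$seed)
}
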