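# ---- parameter file I/O and experiment plumbing -----------------------------

params_to_list <- function(p) {
  circ <- p$circadian
  cl <- list(amplitude = circ$amplitude, period = 2 * pi / circ$omega,
             phase = circ$phase, harmonics = circ$harmonics)
  if (inherits(p, "pr_switch_params")) {
    list(model = "pr_switch",
         Q_max = p$Q_max, theta = p$theta, sigma = p$sigma,
         nu_vm = p$nu_vm, nu_mv = p$nu_mv, nu_vh = p$nu_vh,
         D0_v = p$D0_v, A = p$A, chi = p$chi, mu_h = p$mu_h, tau = p$tau,
         asymptote_form = p$asymptote_form, Q_half = p$Q_half,
         mu_sat = p$mu_sat, Q_bar = p$Q_bar, V_th = p$V_th, circadian = cl)
  } else if (inherits(p, "pr_params")) {
    list(model = "pr",
         Q_max = p$Q_max, theta = p$theta, sigma = p$sigma,
         nu_vm = p$nu_vm, nu_mv = p$nu_mv, nu_vh = p$nu_vh,
         D0_v = p$D0_v, A = p$A, chi = p$chi, mu_h = p$mu_h, tau = p$tau,
         asymptote_form = p$asymptote_form, Q_half = p$Q_half,
         mu_sat = p$mu_sat, circadian = cl)
  } else if (inherits(p, "two_process_params")) {
    list(model = "two_process",
         mu = p$mu, H0_plus = p$H0_plus, H0_minus = p$H0_minus,
         chi_w = p$chi_w, chi_s = p$chi_s,
         lower_asymptote = p$lower_asymptote, circadian = cl)
  } else stop("params_to_list: unsupported object", call. = FALSE)
}

list_to_params <- function(l) {
  if (is.null(l$model))
    stop("parameter file: missing required field 'model'", call. = FALSE)
  need <- function(nm) {
    if (is.null(l[[nm]]))
      stop(sprintf("parameter file: missing required field '%s'", nm), call. = FALSE)
    l[[nm]]
  }
  cl <- need("circadian")
  circ <- circadian_waveform(amplitude = cl$amplitude,
                             period = if (is.null(cl$period)) 24 else cl$period,
                             phase = if (is.null(cl$phase)) 0 else cl$phase,
                             harmonics = if (is.null(cl$harmonics)) 1 else cl$harmonics)
  switch(l$model,
    two_process = two_process_params(
      mu = need("mu"), H0_plus = need("H0_plus"), H0_minus = need("H0_minus"),
      chi_w = need("chi_w"), chi_s = need("chi_s"), circadian = circ,
      lower_asymptote = if (is.null(l$lower_asymptote)) 0 else l$lower_asymptote),
    pr = pr_params(
      Q_max = need("Q_max"), theta = need("theta"), sigma = need("sigma"),
      nu_vm = need("nu_vm"), nu_mv = need("nu_mv"), nu_vh = need("nu_vh"),
      D0_v = need("D0_v"), A = need("A"), chi = need("chi"),
      mu_h = need("mu_h"), tau = need("tau"), circadian = circ,
      asymptote_form = if (is.null(l$asymptote_form)) "linear" else l$asymptote_form,
      Q_half = if (is.null(l$Q_half)) 1 else l$Q_half, mu_sat = l$mu_sat),
    pr_switch = pr_switch_params(
      Q_max = need("Q_max"), theta = need("theta"), sigma = need("sigma"),
      nu_vm = need("nu_vm"), nu_mv = need("nu_mv"), nu_vh = need("nu_vh"),
      D0_v = need("D0_v"), A = need("A"), chi = need("chi"),
      mu_h = need("mu_h"), tau = need("tau"), circadian = circ,
      asymptote_form = if (is.null(l$asymptote_form)) "linear" else l$asymptote_form,
      Q_half = if (is.null(l$Q_half)) 1 else l$Q_half, mu_sat = l$mu_sat,
      Q_bar = need("Q_bar"), V_th = need("V_th")),
    stop(sprintf("parameter file: unknown model '%s'", l$model), call. = FALSE))
}

# minimal flat TOML (sections, key = value, numbers/strings/booleans/arrays)
toml_write <- function(l, path) {
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
  lines <- character(0)
  scalars <- l[!vapply(l, is.list, logical(1))]
  for (nm in names(scalars)) {
    v <- scalars[[nm]]
    if (is.null(v)) next
    val <- if (length(v) > 1L) paste0("[", paste(fmt(v), collapse = ", "), "]")
    else fmt(v)
    lines <- c(lines, sprintf("%s = %s", nm, val))
  }
  for (nm in names(l)[vapply(l, is.list, logical(1))]) {
    lines <- c(lines, sprintf("[%s]", nm))
    for (k in names(l[[nm]])) {
      v <- l[[nm]][[k]]
      if (is.null(v)) next
      val <- if (length(v) > 1L) paste0("[", paste(fmt(v), collapse = ", "), "]")
      else fmt(v)
      lines <- c(lines, sprintf("%s = %s", k, val))
    }
  }
  writeLines(lines, path)
}

toml_read <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); section <- NULL
  parse_val <- function(s) {
    s <- trimws(s)
    if (startsWith(s, "[")) {
      inner <- sub("^\\[", "", sub("\\]$", "", s))
      parts <- trimws(strsplit(inner, ",")[[1L]])
      return(vapply(parts, function(x) parse_val(x), numeric(1), USE.NAMES = FALSE))
    }
    if (startsWith(s, '"')) return(gsub('"', "", s))
    if (s %in% c("true", "false")) return(s == "true")
    as.numeric(s)
  }
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      section <- sub("^\\[", "", sub("\\]$", "", ln))
      out[[section]] <- list()
    } else {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1L]]
      key <- trimws(kv[1L]); val <- parse_val(kv[2L])
      if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
    }
  }
  out
}

#' Read and write model parameter files
#'
#' Parameter sets are stored as flat key-value files with the field names of
#' the parameter constructors plus a \code{model} tag
#' (\code{"two_process"}, \code{"pr"} or \code{"pr_switch"}) and a
#' \code{circadian} sub-table. The dialect follows the file extension:
#' \code{.yaml}/\code{.yml}, \code{.json} or \code{.toml}. Reading validates
#' through the constructors, so a missing field or an invalid value (e.g. a
#' non-positive time constant) produces an error naming the field.
#'
#' @param p Parameter object (\code{two_process_params}, \code{pr_params} or
#'   \code{pr_switch_params}).
#' @param path File path; extension selects the dialect.
#' @return \code{read_params} returns the parameter object;
#'   \code{write_params} returns \code{path} invisibly.
#' @export
write_params <- function(p, path) {
  l <- params_to_list(p)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(l, path, precision = 15),
    json = jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    toml = toml_write(l, path),
    stop(sprintf("write_params: unsupported extension '%s'", ext), call. = FALSE))
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_params: no such file '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  l <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    toml = toml_read(path),
    stop(sprintf("read_params: unsupported extension '%s'", ext), call. = FALSE))
  list_to_params(l)
}

# ---- result export ----------------------------------------------------------

#' Export simulation results
#'
#' \code{write_timeseries_csv} writes the tidy state time series
#' (\code{time_h, H, V_v, V_m, Q_v, Q_m, state}; potential/rate columns are
#' \code{NA} for two-process runs). \code{write_pattern} writes the
#' transition-event CSV (\code{time_h, transition}) and a JSON summary with
#' \code{episodes_per_day}, \code{period_days} and \code{daily_sleep_h}.
#'
#' @param sim A \code{sleep_sim}.
#' @param path Output CSV path.
#' @return The path(s), invisibly.
#' @export
write_timeseries_csv <- function(sim, path) {
  ts <- sim$timeseries
  for (col in c("V_v", "V_m", "Q_v", "Q_m"))
    if (is.null(ts[[col]])) ts[[col]] <- NA_real_
  ts <- ts[, c("time_h", "H", "V_v", "V_m", "Q_v", "Q_m", "state")]
  utils::write.csv(ts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @param json_path Path for the JSON summary (default: \code{path} with the
#'   extension replaced by \code{.json}).
#' @export
write_pattern <- function(sim, path, json_path = NULL) {
  utils::write.csv(sim$pattern$events, path, row.names = FALSE)
  if (is.null(json_path)) json_path <- sub("\\.[^.]*$", ".json", path)
  s <- classify_pattern(sim$pattern)
  jsonlite::write_json(list(episodes_per_day = s$episodes_per_day,
                            period_days = s$period_days,
                            daily_sleep_h = s$daily_sleep_h,
                            converged = s$converged, regime = s$regime),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, json_path))
}

# ---- experiment runner ------------------------------------------------------

resolve_params <- function(model, params, overrides = NULL) {
  p <- if (is.null(params) || identical(params, "human_default")) {
    switch(model,
           two_process = two_process_human(),
           pr = pr_human(),
           pr_switch = pr_switch_human(),
           stop(sprintf("run_experiment: unknown model '%s'", model), call. = FALSE))
  } else if (is.character(params)) read_params(params)
  else params
  if (!is.null(overrides) && length(overrides)) {
    l <- params_to_list(p)
    for (nm in names(overrides)) {
      if (!nm %in% names(l) || nm == "model")
        stop(sprintf("run_experiment: unknown parameter override '%s'", nm),
             call. = FALSE)
      l[[nm]] <- overrides[[nm]]
    }
    p <- list_to_params(l)
  }
  p
}

#' Run a configured experiment
#'
#' Executes one of the package's experiment types from a configuration list
#' and writes all outputs, a resolved copy of the configuration, and a
#' manifest with file checksums, into the output directory. The dynamics are
#' deterministic, so identical configurations produce identical outputs.
#'
#' Recognised configuration fields (unknown fields are an error):
#' \describe{
#'   \item{experiment}{one of \code{"simulate"}, \code{"map"}, \code{"scan"},
#'     \code{"grazing"}, \code{"effort"}, \code{"equivalence"}}
#'   \item{model}{\code{"two_process"}, \code{"pr"} or \code{"pr_switch"}}
#'   \item{params}{path to a parameter file, or \code{"human_default"}}
#'   \item{overrides}{named list of parameter overrides}
#'   \item{out_dir}{output directory (created if needed)}
#'   \item{options}{experiment-specific options: \code{t_span_days},
#'     \code{n_grid}, \code{param}, \code{values}, \code{bracket},
#'     \code{days}}
#'   \item{verbose}{logical}
#' }
#'
#' @param cfg Configuration list (or path to a YAML/JSON config file).
#' @return Invisibly, the manifest data frame (file, md5).
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) {
    ext <- tolower(tools::file_ext(cfg))
    cfg <- switch(ext,
      yaml = , yml = yaml::read_yaml(cfg),
      json = jsonlite::read_json(cfg, simplifyVector = TRUE),
      stop("run_experiment: config file must be YAML or JSON", call. = FALSE))
  }
  allowed <- c("experiment", "model", "params", "overrides", "out_dir",
               "options", "verbose")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop(sprintf("run_experiment: unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  experiment <- match.arg(cfg$experiment,
                          c("simulate", "map", "scan", "grazing", "effort",
                            "equivalence"))
  model <- if (is.null(cfg$model)) "two_process" else cfg$model
  out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opt <- if (is.null(cfg$options)) list() else cfg$options
  verbose <- isTRUE(cfg$verbose)
  say <- function(...) if (verbose) message(sprintf(...))

  p <- resolve_params(model, cfg$params, cfg$overrides)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  t0 <- Sys.time()
  if (experiment == "simulate") {
    days <- if (is.null(opt$t_span_days)) 15 else opt$t_span_days
    say("phase=simulate model=%s span_days=%g", model, days)
    sim <- if (inherits(p, "two_process_params"))
      simulate_two_process(p, t_span = 24 * days)
    else simulate_pr(p, t_span = 24 * days)
    add(write_timeseries_csv(sim, file.path(out_dir, "timeseries.csv")))
    add(write_pattern(sim, file.path(out_dir, "events.csv"),
                      file.path(out_dir, "summary.json")))
  } else if (experiment == "map") {
    if (!inherits(p, "two_process_params"))
      stop("run_experiment: the return map is built for the two-process model",
           call. = FALSE)
    n_grid <- if (is.null(opt$n_grid)) 96 else opt$n_grid
    say("phase=map n_grid=%d", n_grid)
    rm_ <- build_return_map(p, n_grid = n_grid)
    utils::write.csv(rm_$grid, file.path(out_dir, "return_map.csv"),
                     row.names = FALSE)
    add(file.path(out_dir, "return_map.csv"))
    jsonlite::write_json(list(discontinuities = rm_$discontinuities,
                              fixed_points = rm_$fixed_points),
                         file.path(out_dir, "map_annotations.json"),
                         digits = NA, dataframe = "rows")
    add(file.path(out_dir, "map_annotations.json"))
  } else if (experiment == "scan") {
    if (is.null(opt$param) || is.null(opt$values))
      stop("run_experiment: scan needs options$param and options$values",
           call. = FALSE)
    say("phase=scan param=%s n=%d", opt$param, length(opt$values))
    sc <- scan_parameter(p, opt$param, as.numeric(opt$values),
                         transient_days = if (is.null(opt$transient_days)) 30
                         else opt$transient_days,
                         max_period = if (is.null(opt$max_period)) 16
                         else opt$max_period)
    utils::write.csv(sc$summary, file.path(out_dir, "scan.csv"),
                     row.names = FALSE)
    add(file.path(out_dir, "scan.csv"))
    rast <- do.call(rbind, lapply(seq_along(sc$intervals), function(i)
      if (nrow(sc$intervals[[i]]))
        cbind(value = sc$summary$value[i], sc$intervals[[i]]) else NULL))
    utils::write.csv(rast, file.path(out_dir, "intervals.csv"),
                     row.names = FALSE)
    add(file.path(out_dir, "intervals.csv"))
    jsonlite::write_json(sc$critical, file.path(out_dir, "critical.json"),
                         digits = NA, dataframe = "rows")
    add(file.path(out_dir, "critical.json"))
  } else if (experiment == "grazing") {
    if (is.null(opt$param) || is.null(opt$bracket))
      stop("run_experiment: grazing needs options$param and options$bracket",
           call. = FALSE)
    say("phase=grazing param=%s", opt$param)
    gz <- locate_grazing(p, opt$param, as.numeric(opt$bracket))
    jsonlite::write_json(list(param = gz$param, critical = gz$critical,
                              episodes = as.list(gz$episodes),
                              certificate = gz$certificate),
                         file.path(out_dir, "grazing.json"),
                         auto_unbox = TRUE, digits = NA)
    add(file.path(out_dir, "grazing.json"))
  } else if (experiment == "effort") {
    if (!inherits(p, "pr_params") || inherits(p, "pr_switch_params"))
      stop("run_experiment: effort requires the sigmoid PR model", call. = FALSE)
    days <- if (is.null(opt$days)) 4 else opt$days
    say("phase=effort days=%g", days)
    wec <- wake_effort_compare(p, days = days)
    utils::write.csv(wec$series, file.path(out_dir, "effort.csv"),
                     row.names = FALSE)
    add(file.path(out_dir, "effort.csv"))
    jsonlite::write_json(list(linear = wec$relation$linear,
                              quadratic = wec$relation$quadratic,
                              rel_rms = wec$relation$rel_rms,
                              day_ends = wec$day_ends),
                         file.path(out_dir, "effort_relation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    add(file.path(out_dir, "effort_relation.json"))
  } else if (experiment == "equivalence") {
    if (!inherits(p, "pr_params"))
      stop("run_experiment: equivalence starts from the PR model", call. = FALSE)
    say("phase=equivalence")
    cal <- calibrate_switch_from_pr(p)
    add(write_params(cal$switch, file.path(out_dir, "pr_switch_params.yaml")))
    add(write_params(cal$two_process, file.path(out_dir, "two_process_params.yaml")))
    jsonlite::write_json(list(fold_drives = as.list(cal$fold_drives),
                              extrema = cal$extrema,
                              max_abs_transition_diff_h = cal$report$max_abs_diff_h,
                              mean_abs_transition_diff_h = cal$report$mean_abs_diff_h,
                              transitions = cal$report$transitions),
                         file.path(out_dir, "equivalence_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    add(file.path(out_dir, "equivalence_report.json"))
  }
  say("phase=done elapsed=%.2fs", as.numeric(Sys.time() - t0, units = "secs"))

  # resolved config + manifest
  resolved <- list(experiment = experiment, model = model,
                   params = params_to_list(p), options = opt)
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
  add(file.path(out_dir, "resolved_config.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}
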