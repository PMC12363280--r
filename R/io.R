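# Shared readers/writers and the end-to-end pipeline.
#
# CSV conventions: decimal point ".", UTF-8, mandatory header row; times
# in hours and masses in micrograms at the file boundary (SI internally).
# Scalar metadata travel as leading comment lines of the form
# "# key = value".

parse_header_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(\\S+)", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- as.numeric(m[3L])
  }
  meta
}

read_csv_with_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body_start <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))[1L]
  if (is.na(body_start)) stop("`", path, "` contains no data", call. = FALSE)
  df <- utils::read.csv(text = paste(lines[body_start:length(lines)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  # data row i of `df` sits on file line body_start + i (header is on
  # body_start), so body_start is the offset for error reporting
  list(data = df, meta = parse_header_meta(lines),
       row_offset = body_start)
}

check_numeric_column <- function(df, col, path, offset) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
  if (length(bad)) {
    stop("`", path, "`: non-numeric or missing `", col, "` on line(s) ",
         paste(bad + offset, collapse = ", "), call. = FALSE)
  }
  v
}

#' Read a release dataset from CSV
#'
#' Two schemas are recognised by their header. Supernatant mode
#' (`time_h, replicate_id, mass_ug`) holds per-interval masses and
#' requires the loaded mass, either as a `# m_initial_ug = <x>` comment
#' line or via the `m_initial` argument; it returns a list of
#' [supernatant_series()], one per replicate. Curve mode
#' (`time_h, cumulative_percent`) returns a single [release_curve()]
#' (loaded mass from `# m_infinity_ug = <x>` if present, else percentages
#' double as masses with a loading of 100). Malformed rows are reported
#' with their line numbers.
#'
#' @param path CSV file path.
#' @param m_initial Loaded mass in micrograms (supernatant mode); overrides
#'   the file header.
#' @return A list of [supernatant_series()] or a [release_curve()].
#' @export
read_release_csv <- function(path, m_initial = NULL) {
  parsed <- read_csv_with_meta(path)
  df <- parsed$data
  off <- parsed$row_offset
  if (all(c("time_h", "replicate_id", "mass_ug") %in% names(df))) {
    time_h <- check_numeric_column(df, "time_h", path, off)
    mass <- check_numeric_column(df, "mass_ug", path, off)
    neg <- which(mass < 0)
    if (length(neg)) {
      stop("`", path, "`: negative mass on line(s) ",
           paste(neg + off, collapse = ", "), call. = FALSE)
    }
    m0 <- m_initial %||% parsed$meta$m_initial_ug
    if (is.null(m0)) {
      stop("supernatant-mode file needs `# m_initial_ug = <x>` in the ",
           "header or an `m_initial` argument", call. = FALSE)
    }
    out <- lapply(split(seq_len(nrow(df)), df$replicate_id), function(i) {
      if (is.unsorted(time_h[i], strictly = TRUE)) {
        stop("`", path, "`: non-monotone times within replicate at line(s) ",
             paste(i + off, collapse = ", "), call. = FALSE)
      }
      supernatant_series(time_h[i], mass[i], m0)
    })
    return(out)
  }
  if (all(c("time_h", "cumulative_percent") %in% names(df))) {
    time_h <- check_numeric_column(df, "time_h", path, off)
    pct <- check_numeric_column(df, "cumulative_percent", path, off)
    if (is.unsorted(time_h)) {
      stop("`", path, "`: `time_h` must be non-decreasing", call. = FALSE)
    }
    m_inf <- parsed$meta$m_infinity_ug %||% 100
    return(release_curve(time_h, pct / 100 * m_inf, m_inf))
  }
  stop("`", path, "`: header matches neither ",
       "(time_h, replicate_id, mass_ug) nor (time_h, cumulative_percent)",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a release curve to CSV
#'
#' Columns `time_h`, `cumulative_mass_ug`, `cumulative_percent`, with the
#' loading recorded as a `# m_infinity_ug` header line so the file round
#' trips through [read_release_csv()].
#'
#' @param curve A [release_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# m_infinity_ug = %.15g", curve$m_infinity), con)
  utils::write.csv(
    data.frame(time_h = curve$times,
               cumulative_mass_ug = curve$cumulative_mass,
               cumulative_percent = curve$cumulative_percent),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write supernatant replicates to CSV
#'
#' Long format `time_h, replicate_id, mass_ug` with a `# m_initial_ug`
#' header; the inverse of [read_release_csv()]'s supernatant mode.
#'
#' @param replicates List of [supernatant_series()] sharing one loading.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_supernatant_csv <- function(replicates, path) {
  stopifnot(length(replicates) >= 1L,
            all(vapply(replicates, inherits, logical(1),
                       "supernatant_series")))
  m0 <- replicates[[1L]]$m_initial
  df <- do.call(rbind, lapply(seq_along(replicates), function(i) {
    data.frame(time_h = replicates[[i]]$times, replicate_id = i,
               mass_ug = replicates[[i]]$masses)
  }))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# m_initial_ug = %.15g", m0), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a concentration profile to CSV
#'
#' Columns `z_m`, `c`, one row per node.
#'
#' @param profile A [concentration_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(z_m = profile$z, c = profile$c), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the synthetic-data-to-parameter-recovery
#' pipeline with documented defaults. Unknown keys are rejected before any
#' computation.
#'
#' @param geometry A [hydrogel_geometry()].
#' @param disc A [discretization()].
#' @param truth Generating [transport_params()].
#' @param c_initial Initial concentration (ug/m^3; see [ug_per_ml()]).
#' @param schedule Observation times (h).
#' @param noise A [noise_model()].
#' @param n_replicates Replicates to simulate.
#' @param free_params Parameters the inverse stage estimates.
#' @param ga A [ga_config()].
#' @param kp_window_h Korsmeyer-Peppas fitting window (h).
#' @param seed Master seed of the synthetic stage.
#' @param ... Unknown keys; any entry here is an error.
#' @return An object of class `release_config`.
#' @export
release_config <- function(geometry = hydrogel_geometry(),
                           disc = discretization(),
                           truth = reference_truth("alginate", "0.4")$params,
                           c_initial = ug_per_ml(0.4),
                           schedule = release_schedules()$static,
                           noise = noise_model(),
                           n_replicates = 3L,
                           free_params = c("d_eff", "k"),
                           ga = ga_config(),
                           kp_window_h = 6,
                           seed = 1L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(geometry, "hydrogel_geometry"),
            inherits(disc, "discretization"),
            inherits(noise, "noise_model"),
            inherits(ga, "ga_config"))
  truth <- as_transport_params(truth)
  structure(list(geometry = geometry, disc = disc, truth = truth,
                 c_initial = c_initial, schedule = schedule, noise = noise,
                 n_replicates = as.integer(n_replicates),
                 free_params = free_params, ga = ga,
                 kp_window_h = kp_window_h, seed = as.integer(seed)),
            class = "release_config")
}

#' Read a pipeline configuration from a plain key-value file
#'
#' Lines of the form `key = value` (\code{#} comments and blank lines
#' ignored) populate a [release_config()]. Scalar keys: `radius`,
#' `height` (m), `n_nodes`, `dt` (s), `d_eff`, `k`, `c_eq`, `c_initial`
#' (SI), `relative_sd`, `n_replicates`, `population_size`, `generations`,
#' `ga_seed`, `kp_window_h`, `seed`; `free_params` is a comma-separated
#' list. Unknown keys are rejected before any computation.
#'
#' @param path Configuration file path.
#' @return A [release_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("`", path, "`: malformed line(s): ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  }
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  known <- c("radius", "height", "n_nodes", "dt", "d_eff", "k", "c_eq",
             "c_initial", "relative_sd", "n_replicates",
             "population_size", "generations", "ga_seed", "kp_window_h",
             "seed", "free_params")
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("`", path, "`: unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  num <- function(key, default) {
    if (key %in% names(vals)) as.numeric(vals[[key]]) else default
  }
  free <- if ("free_params" %in% names(vals)) {
    trimws(strsplit(vals[["free_params"]], ",")[[1L]])
  } else c("d_eff", "k")
  defaults <- reference_truth("alginate", "0.4")
  release_config(
    geometry = hydrogel_geometry(num("radius", 3.25e-3),
                                 num("height", 5e-3)),
    disc = discretization(num("n_nodes", 31), num("dt", 300)),
    truth = transport_params(num("d_eff", defaults$params$d_eff),
                             num("k", defaults$params$k),
                             num("c_eq", defaults$params$c_eq)),
    c_initial = num("c_initial", defaults$c_initial),
    noise = noise_model(num("relative_sd", 0.05)),
    n_replicates = num("n_replicates", 3),
    free_params = free,
    ga = ga_config(population_size = num("population_size", 60),
                   generations = num("generations", 80),
                   seed = num("ga_seed", 1)),
    kp_window_h = num("kp_window_h", 6),
    seed = num("seed", 1))
}

#' Run the full synthetic-release analysis pipeline
#'
#' Generates a synthetic static dataset, assembles the mean cumulative
#' curve across replicates, fits the Korsmeyer-Peppas power law per
#' replicate, and estimates the transport parameters on the mean curve by
#' the genetic algorithm. Deterministic for a fixed configuration. A
#' failing stage aborts with the stage named.
#'
#' @param config A [release_config()].
#' @return An object of class `release_report`: list with `dataset`,
#'   `mean_curve`, `kp` (per-replicate fits plus `n_mean`, `n_sd`,
#'   `mechanism`), `fit` (a `fit_result`), `truth`, `seed` and `version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "release_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dataset <- stage("synth", generate_static(
    config$truth, config$geometry, config$c_initial, config$schedule,
    config$noise, config$n_replicates, config$seed, config$disc))

  curves <- stage("assemble",
                  lapply(dataset$replicates, cumulative_from_supernatants))
  mean_mass <- rowMeans(vapply(curves, function(cv) cv$cumulative_mass,
                               numeric(length(curves[[1L]]$times))))
  mean_curve <- stage("assemble",
                      release_curve(curves[[1L]]$times, mean_mass,
                                    dataset$curve_truth$m_infinity))

  kp_fits <- stage("kp_fit", lapply(curves, fit_korsmeyer_peppas,
                                    window_h = config$kp_window_h))
  n_vals <- vapply(kp_fits, function(f) f$n, numeric(1))
  kp <- list(fits = kp_fits, n_mean = mean(n_vals),
             n_sd = stats::sd(n_vals),
             mechanism = classify_mechanism(mean(n_vals)))

  fit <- stage("ga_fit", estimate_transport(
    mean_curve, config$geometry, config$disc, config$c_initial,
    free_params = config$free_params, fixed = config$truth,
    config = config$ga))

  structure(list(dataset = dataset, mean_curve = mean_curve, kp = kp,
                 fit = fit, truth = config$truth, seed = config$seed,
                 version = as.character(utils::packageVersion("relkin"))),
            class = "release_report")
}

#' @export
print.release_report <- function(x, ...) {
  cat("== release pipeline report (relkin", x$version, ") ==\n")
  cat(sprintf("seed %d; %d replicates; final release %.2f%%\n",
              x$seed, length(x$dataset$replicates),
              max(x$mean_curve$cumulative_percent)))
  cat(sprintf("Korsmeyer-Peppas: n = %.3f +/- %.3f -> %s\n",
              x$kp$n_mean, x$kp$n_sd, x$kp$mechanism))
  cat(sprintf(
    "recovered d_eff = %.4g m^2/s (truth %.4g), k = %.4g m/s (truth %.4g)\n",
    x$fit$params$d_eff, x$truth$d_eff, x$fit$params$k, x$truth$k))
  cat(sprintf("fit R^2 = %.4f, sse = %.4g\n", x$fit$r_squared, x$fit$sse))
  invisible(x)
}
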