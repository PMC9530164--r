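#' Load a run configuration
#'
#' Reads a flat `key = value` configuration file (or takes the same keys as
#' a named list) and returns a fully validated [assembly_config()] plus run
#' plumbing.  Unknown keys are a hard error, as are out-of-range values;
#' validation messages name the offending key.
#'
#' Recognised keys: `mode`, `beta`, `attempts`, `seed`,
#' `producer_fraction`, `second_resource_prob`, `alpha_min`, `alpha_max`,
#' `eta_min`, `eta_max`, `k`, `invader_biomass`, `record_every_attempt`,
#' `extinction_threshold`, `feasibility_tol`, `stability_tol`, `rtol`,
#' `atol`, `output_dir`.
#'
#' @param path path to a config file, or `NULL`.
#' @param overrides named list of values overriding the file (CLI flags).
#' @return list of class `run_config` with elements `assembly` (an
#'   `assembly_config`) and `output_dir`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("cannot parse config line: ", ln)
      vals[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  for (k in names(overrides)) vals[[k]] <- overrides[[k]]

  known <- c("mode", "beta", "attempts", "seed", "producer_fraction",
             "second_resource_prob", "alpha_min", "alpha_max", "eta_min",
             "eta_max", "k", "invader_biomass", "record_every_attempt",
             "extinction_threshold", "feasibility_tol", "stability_tol",
             "rtol", "atol", "output_dir")
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))

  num <- function(key, default) {
    if (is.null(vals[[key]])) return(default)
    x <- suppressWarnings(as.numeric(vals[[key]]))
    if (is.na(x)) stop("configuration key `", key, "` is not numeric")
    x
  }
  lgl <- function(key, default) {
    if (is.null(vals[[key]])) return(default)
    isTRUE(as.logical(vals[[key]]))
  }
  args <- list(
    mode = if (is.null(vals$mode)) "treelike" else as.character(vals$mode),
    beta = num("beta", 0.75),
    attempts = num("attempts", 1e5),
    seed = num("seed", 1),
    producer_fraction = num("producer_fraction", 1/3),
    alpha_range = c(num("alpha_min", 0.05), num("alpha_max", 0.5)),
    eta_range = c(num("eta_min", 0.01), num("eta_max", 1)),
    k = num("k", 1),
    invader_biomass = num("invader_biomass", 1e-10),
    record_every_attempt = lgl("record_every_attempt", FALSE),
    extinction_threshold = num("extinction_threshold", 1e-12),
    feasibility_tol = num("feasibility_tol", 1e-14),
    stability_tol = num("stability_tol", 1e-10),
    rtol = num("rtol", 1e-9),
    atol = num("atol", 1e-14))
  if (!is.null(vals$second_resource_prob))
    args$second_resource_prob <- num("second_resource_prob", NULL)
  assembly <- tryCatch(do.call(assembly_config, args),
                       error = function(e) stop("invalid configuration: ",
                                                conditionMessage(e),
                                                call. = FALSE))
  structure(list(assembly = assembly,
                 output_dir = if (is.null(vals$output_dir)) "."
                              else as.character(vals$output_dir)),
            class = "run_config")
}

#' Run an assembly simulation and write its artifacts
#'
#' Executes [evolve()] and writes, under `dir`:
#' `events.csv` (one row per attempt), `eigenvalues.csv` (one row per
#' recorded eigenvalue), `metrics.json`, `final_web.json`, and
#' `config.json` (the exact resolved configuration).  Re-running with the
#' same configuration and seed reproduces the CSV payloads byte for byte.
#'
#' @param config an [assembly_config()] or `run_config`.
#' @param dir output directory (created if missing).
#' @param progress print per-1000-attempt progress.
#' @return the `evolution_history`, invisibly.
#' @export
run_assembly <- function(config, dir, progress = FALSE) {
  if (inherits(config, "run_config")) config <- config$assembly
  stopifnot(inherits(config, "assembly_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hist <- evolve(config, progress = progress)

  ev <- hist$records
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(hist$eigenvalues, file.path(dir, "eigenvalues.csv"),
                   row.names = FALSE)
  write_web_json(hist$final_web, file.path(dir, "final_web.json"))
  m <- evolution_metrics(hist)
  jsonlite::write_json(
    list(success_rate = success_rate(hist),
         richness_histogram = as.list(m$richness_histogram),
         treelike_fraction = m$treelike_fraction,
         n_recorded_webs = nrow(hist$recorded_webs),
         n_non_convergent = sum(ev$non_convergent)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(hist)
}

#' Summarise an eigenvalue table
#'
#' The analysis counterpart of [run_assembly()]: reads (or takes) an
#' eigenvalue table, restricts to one richness, and writes the scaled
#' real-part histogram, the complex-plane histogram and a JSON summary.
#'
#' @param eigenvalues a data frame with columns `richness`, `re`, `im`, or a
#'   path to an `eigenvalues.csv` written by [run_assembly()].
#' @param richness species richness to select (`NULL` keeps everything).
#' @param bins number of histogram bins along each axis.
#' @param dir output directory, or `NULL` to skip writing.
#' @return list with `summary`, `real_part` (data frame), `complex_plane`.
#' @export
analyze_spectra <- function(eigenvalues, richness = NULL, bins = 100L,
                            dir = NULL) {
  if (is.character(eigenvalues))
    eigenvalues <- utils::read.csv(eigenvalues)
  stopifnot(all(c("re", "im") %in% names(eigenvalues)))
  if (!is.null(richness))
    eigenvalues <- eigenvalues[eigenvalues$richness == richness, ]
  if (nrow(eigenvalues) == 0L) stop("no eigenvalues selected")
  ev <- complex(real = eigenvalues$re, imaginary = eigenvalues$im)
  rp <- real_part_distribution(ev, bins = bins)
  cp <- complex_plane_histogram(ev, re_bins = bins, im_bins = bins)
  summ <- list(n_eigenvalues = length(ev),
               purely_real_fraction = purely_real_fraction(ev),
               max_re = max(Re(ev)), min_re = min(Re(ev)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rp, file.path(dir, "realpart_hist.csv"),
                     row.names = FALSE)
    grid <- expand.grid(ri = seq_len(bins), ii = seq_len(bins))
    utils::write.csv(
      data.frame(re_left = cp$re_breaks[grid$ri],
                 re_right = cp$re_breaks[grid$ri + 1L],
                 im_left = cp$im_breaks[grid$ii],
                 im_right = cp$im_breaks[grid$ii + 1L],
                 count = cp$counts[cbind(grid$ri, grid$ii)]),
      file.path(dir, "complex_hist.csv"), row.names = FALSE)
    jsonlite::write_json(summ, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(summary = summ, real_part = rp, complex_plane = cp)
}
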