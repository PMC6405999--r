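#' Plain-text run configuration
#'
#' Configurations are `key = value` text files: one pair per line, `#`
#' comments allowed, commas splitting vector values, numbers auto-typed.
#' Every stochastic output of the command drivers is a pure function of
#' (config, seed), and a config round-trips losslessly through
#' `write_run_config()` / `read_run_config()`.
#'
#' @param path file path.
#' @param config named list of values.
#' @return `read_run_config()` a named list; `write_run_config()` the path,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(.fmt9(config[[k]]), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# fixed 9-significant-digit formatting for all floating-point output
.fmt9 <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 9, format = "g") else as.character(x)
}

.build_from_config <- function(config, seed) {
  defaults <- list(topology = "cylinder", width = 50, height = 50,
                   labels = "gradient", label_p = 0.5, b = 8, w = 1,
                   mu = 0.001, pattern = NULL, n = 101)
  cfg <- modifyList(defaults, config)
  graph <- switch(as.character(cfg$topology),
    cylinder = build_cylinder(cfg$width, cfg$height),
    torus = build_torus(cfg$width, cfg$height),
    line = build_line(cfg$n),
    ring = build_ring(cfg$n),
    erdos_renyi = build_erdos_renyi(cfg$n, cfg$label_p_edge %||% 0.1, seed),
    stop("unknown topology: ", cfg$topology))
  labels <- switch(as.character(cfg$labels),
    gradient = assign_labels_gradient(graph, seed = seed),
    uniform = assign_labels_uniform(graph, p = cfg$label_p, seed = seed),
    single_minority = assign_labels_line(graph$n, "single_minority"),
    repeated_pattern = assign_labels_line(graph$n, "repeated_pattern",
                                          pattern = cfg$pattern),
    stop("unknown label spec: ", cfg$labels))
  list(cfg = cfg, graph = graph, labels = labels,
       params = model_params(cfg$b, cfg$w, cfg$mu))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command drivers: run, scan, boundary
#'
#' The working functions behind the command-line script shipped in
#' `inst/cli/tagdilemma`. `cmd_run()` simulates one parameter point from the
#' all-defector initialisation and writes an observable time series (CSV), a
#' final-state JSON (labels, strategies, topology spec, seed) and optionally
#' a PNG strategy snapshot. `cmd_scan()` drives [phase_scan()], writes the
#' result CSV plus a JSON metadata sidecar, and resumes from a partial CSV
#' without recomputing finished cells. `cmd_boundary()` writes the
#' transition-line table for a label pattern sweep and, for the single-green
#' line, the (w, b) table of chain, closed-form and Monte-Carlo ratios.
#'
#' @param config named list (see [read_run_config()]) or path to a config
#'   file. Keys shared by all commands: `seed`, `out_dir`. `cmd_run`:
#'   topology/label keys of the builders plus `b`, `w`, `mu`, `n_events`,
#'   `record_every`, `snapshot` (0/1). `cmd_scan`: `b_grid`, `w_grid`,
#'   `width`, `height`, `mu`, `transient_steps`, `n_samples`,
#'   `sample_window`. `cmd_boundary`: `pattern`, `w_grid`, `b`, `n`,
#'   `mc_events` (0 disables the Monte-Carlo column).
#' @return Invisibly, the paths written.
#' @export
cmd_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- modifyList(list(seed = 1, out_dir = ".", n_events = 1e5,
                         record_every = 1e3, snapshot = 0), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  .check_writable(cfg$out_dir)
  built <- .build_from_config(cfg, seed = cfg$seed)
  st <- sim_state(built$graph, built$labels, strategies = .S_DEFECT,
                  seed = cfg$seed)
  sample_at <- seq(cfg$record_every, cfg$n_events, by = cfg$record_every)
  st <- run_events(st, built$params, cfg$n_events, sample_at = sample_at)
  series <- attr(st, "samples")
  series$discrimination_index <- series$coop_green + series$coop_blue
  ts_path <- file.path(cfg$out_dir, "timeseries.csv")
  .write_csv9(series, ts_path)
  state_path <- file.path(cfg$out_dir, "final_state.json")
  jsonlite::write_json(list(
    topology = built$graph$topology, dims = as.list(built$graph$dims),
    seed = cfg$seed, t = st$t,
    params = unclass(built$params),
    labels = st$labels, strategies = st$strategies),
    state_path, auto_unbox = TRUE, digits = NA)
  paths <- c(ts_path, state_path)
  if (isTRUE(cfg$snapshot == 1)) {
    snap_path <- file.path(cfg$out_dir, "snapshot.png")
    grDevices::png(snap_path, width = 640, height = 640)
    plot(st)
    grDevices::dev.off()
    paths <- c(paths, snap_path)
  }
  invisible(paths)
}

#' @rdname cmd_run
#' @export
cmd_scan <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- modifyList(list(seed = 1, out_dir = ".", b_grid = c(2, 8),
                         w_grid = c(0.01, 1), width = 50, height = 50,
                         mu = 0.001, transient_steps = 5e6, n_samples = 20,
                         sample_window = 1e7), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  .check_writable(cfg$out_dir)
  csv_path <- file.path(cfg$out_dir, "scan.csv")
  done <- if (file.exists(csv_path)) read.csv(csv_path) else NULL
  proto <- scan_protocol(cfg$transient_steps, cfg$n_samples, cfg$sample_window)
  res <- phase_scan(cfg$b_grid, cfg$w_grid, cfg$width, cfg$height, cfg$mu,
                    protocol = proto, base_seed = cfg$seed)
  if (!is.null(done) && nrow(done)) {
    key <- function(d) paste(.fmt9(d$b), .fmt9(d$w))
    fresh <- res[!key(res) %in% key(done), , drop = FALSE]
    out <- rbind(done[intersect(names(done), names(res))],
                 as.data.frame(fresh)[names(done)])
  } else {
    out <- as.data.frame(res)
  }
  .write_csv9(out, csv_path)
  meta_path <- file.path(cfg$out_dir, "scan_meta.json")
  jsonlite::write_json(c(attr(res, "meta"),
                         list(cell_seeds = res$seed, resumed = !is.null(done))),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, meta_path))
}

#' @rdname cmd_run
#' @export
cmd_boundary <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- modifyList(list(seed = 1, out_dir = ".", pattern = "single",
                         w_grid = c(0.1, 0.3, 0.5), b = 5, n = 41,
                         mc_events = 0), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  .check_writable(cfg$out_dir)
  paths <- character(0)
  if (!identical(cfg$pattern, "single")) {
    tl <- data.frame(pattern = paste(cfg$pattern, collapse = ""),
                     w = cfg$w_grid,
                     b_star = vapply(cfg$w_grid, function(w)
                       as.numeric(transition_line(cfg$pattern, w)), numeric(1)))
    p <- file.path(cfg$out_dir, "transition_line.csv")
    .write_csv9(tl, p)
    paths <- c(paths, p)
  } else {
    labels <- assign_labels_line(cfg$n, "single_minority")
    rows <- lapply(cfg$w_grid, function(w) {
      if (w == 0) {
        chain_ratio <- 1  # fitness-blind imitation: exactly unbiased walk
      } else {
        chain_ratio <- stationary_ratio(boundary_chain(labels, cfg$b, w),
                                        method = "plateau")
      }
      row <- data.frame(w = w, b = cfg$b, chain_ratio = chain_ratio,
                        closed_form_ratio = closed_form_ratio(w, cfg$b),
                        mc_ratio = NA_real_, mc_se = NA_real_)
      if (cfg$mc_events > 0) {
        mc <- monte_carlo_boundary(labels, model_params(cfg$b, w, 0),
                                   n_events = cfg$mc_events, seed = cfg$seed)
        row$mc_ratio <- mc$ratio; row$mc_se <- mc$se
      }
      row
    })
    p <- file.path(cfg$out_dir, "boundary_ratios.csv")
    .write_csv9(do.call(rbind, rows), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.check_writable <- function(dir) {
  if (file.access(dir, 2L) != 0L) stop("output directory not writable: ", dir)
}

# CSV with header, fixed column order, 9 significant digits
.write_csv9 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmt9)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}
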