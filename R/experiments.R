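#' Normalized mean payoff (donation fraction)
#'
#' The fraction of realized directed donations out of all possible ones:
#' `D / E`, where `D` counts directed pairs `i -> j` with `S_i(lambda_j) = 1`
#' and `E` is the total number of directed neighbour pairs. Identical to the
#' mean payoff divided by `E * (b - 1) / n`, which is why it is the natural
#' `[0, 1]` observable of the phase diagram: 1 under full cooperation, 0
#' under full defection.
#'
#' @param state a `sim_state`.
#' @return A fraction in `[0, 1]`.
#' @export
normalized_mean_payoff <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  e <- state$graph$ptr[state$graph$n + 1L]
  if (e == 0L) stop("graph has no edges; normalized mean payoff undefined")
  donations_cpp(state$graph$ptr, state$graph$idx, state$labels,
                state$strategies) / e
}

#' Strategy shares
#'
#' Fractions of agents holding each of the four strategies, in the fixed
#' order cooperate-all, cooperate-green, cooperate-blue, defect-all.
#'
#' @param state a `sim_state`.
#' @return Named numeric vector of four fractions summing to 1.
#' @export
strategy_shares <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  setNames(tabulate(state$strategies, 4L) / state$graph$n,
           names(strategy_codes()))
}

#' Discrimination index
#'
#' Combined share of the two label-conditional (discriminating) strategies,
#' cooperate-only-with-green and cooperate-only-with-blue. Near 1 when the
#' population is dominated by discriminating behaviour, near 0 when the
#' symmetric strategies (full cooperation or full defection) prevail.
#'
#' @param state a `sim_state`.
#' @return A fraction in `[0, 1]`.
#' @export
discrimination_index <- function(state) {
  sh <- strategy_shares(state)
  unname(sh[["coop_green"]] + sh[["coop_blue"]])
}

#' Measurement protocol for stationary observables
#'
#' The protocol of the phase scan: initialise every agent as a defector, run
#' a transient of `transient_steps` update events, then record observables at
#' `n_samples` evenly spaced events across a window of `sample_window`
#' further events. Defaults are the desk scale used throughout the package
#' (50 x 50 lattice companions: 5e6-event transient, 20 samples over 1e7
#' events, i.e. 2000 sweeps of transient at that size); all fields are plain
#' numbers, so larger protocols are a constructor call away.
#'
#' @param transient_steps events discarded before sampling.
#' @param n_samples number of evenly spaced samples.
#' @param sample_window events spanned by the samples.
#' @return An object of class `scan_protocol`.
#' @export
scan_protocol <- function(transient_steps = 5e6, n_samples = 20,
                          sample_window = 1e7) {
  stopifnot(transient_steps >= 0, n_samples >= 1, sample_window >= n_samples)
  structure(list(transient_steps = as.numeric(transient_steps),
                 n_samples = as.integer(n_samples),
                 sample_window = as.numeric(sample_window)),
            class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf("scan protocol: transient %g events, %d samples over %g events\n",
              x$transient_steps, x$n_samples, x$sample_window))
  invisible(x)
}

#' Run the measurement protocol at one parameter point
#'
#' Initialises all strategies to defect-all, runs the transient, then
#' records the normalized mean payoff and strategy shares at the protocol's
#' sample times and returns their mean and dispersion. For lattices with a
#' gradient axis the shares are also reported separately for the bottom
#' (blue-majority) and top (green-majority) halves of the final state, since
#' the hierarchical phases are regional.
#'
#' @param params a [model_params()] object.
#' @param graph a `population_graph`.
#' @param labels label field for the graph.
#' @param protocol a [scan_protocol()].
#' @param seed optional integer seed for the run.
#' @return An object of class `point_result`: a list with `mean_payoff_norm`,
#'   `sd_payoff_norm`, `sem_payoff_norm`, `shares` (means across samples),
#'   `discrimination_index`, `samples` (the per-sample data frame),
#'   `regional_shares` (or `NULL`), and the final `state`.
#' @export
run_point <- function(params, graph, labels, protocol = scan_protocol(),
                      seed = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(graph, "population_graph"),
            inherits(protocol, "scan_protocol"))
  st <- sim_state(graph, labels, strategies = .S_DEFECT, seed = seed)
  n_ev <- protocol$transient_steps + protocol$sample_window
  sample_at <- protocol$transient_steps +
    round(seq_len(protocol$n_samples) * protocol$sample_window / protocol$n_samples)
  st <- run_events(st, params, n_ev, sample_at = sample_at)
  samples <- attr(st, "samples")
  sh <- colMeans(samples[, names(strategy_codes()), drop = FALSE])
  regional <- NULL
  if (identical(graph$topology, "cylinder")) {
    h <- graph$dims[["height"]]; w <- graph$dims[["width"]]
    row <- rep(0:(h - 1L), each = w)
    bottom <- row < h / 2          # blue-majority end is row 0
    regional <- rbind(
      blue_majority_half = tabulate(st$strategies[bottom], 4L) / sum(bottom),
      green_majority_half = tabulate(st$strategies[!bottom], 4L) / sum(!bottom))
    colnames(regional) <- names(strategy_codes())
  }
  structure(list(
    params = params, protocol = protocol, seed = seed,
    mean_payoff_norm = mean(samples$payoff_norm),
    sd_payoff_norm = sd(samples$payoff_norm),
    sem_payoff_norm = sd(samples$payoff_norm) / sqrt(nrow(samples)),
    shares = sh,
    discrimination_index = unname(sh[["coop_green"]] + sh[["coop_blue"]]),
    regional_shares = regional,
    samples = samples,
    state = st), class = "point_result")
}

#' @export
print.point_result <- function(x, ...) {
  cat(sprintf("point result: b = %g, w = %g, mu = %g\n",
              x$params$b, x$params$w, x$params$mu))
  cat(sprintf("  normalized mean payoff: %.4f (sd %.4f over %d samples)\n",
              x$mean_payoff_norm, x$sd_payoff_norm, nrow(x$samples)))
  cat("  mean shares:",
      paste(sprintf("%s %.3f", names(x$shares), x$shares), collapse = ", "), "\n")
  cat(sprintf("  discrimination index: %.3f\n", x$discrimination_index))
  invisible(x)
}

#' Phase scan over cooperation benefit and selection pressure
#'
#' Runs [run_point()] independently at every cell of the `b_grid` x `w_grid`
#' grid on a gradient-label cylinder. A fresh label field is generated at
#' every grid point (from a per-cell seed derived from `base_seed`), so
#' results are not tied to one random label realisation. Cells that error
#' are recorded with `NA` observables and the scan continues.
#'
#' @param b_grid,w_grid numeric parameter grids (the `w` axis of the phase
#'   diagram spans orders of magnitude, so a log-spaced `w_grid` is the
#'   natural choice).
#' @param width,height cylinder dimensions.
#' @param mu mutation rate (constant across the scan).
#' @param protocol a [scan_protocol()].
#' @param base_seed integer; per-cell seeds are `base_seed + cell index`.
#' @return An object of class `scan_result`: a data frame (one row per cell:
#'   `b`, `w`, `seed`, `mean_payoff_norm`, `sd_payoff_norm`, the four share
#'   columns, `discrimination_index`, `error`) with the scan settings in
#'   `attr(, "meta")`.
#' @export
phase_scan <- function(b_grid, w_grid, width = 50, height = 50, mu = 0.001,
                       protocol = scan_protocol(), base_seed = 1) {
  stopifnot(length(b_grid) >= 1, length(w_grid) >= 1)
  graph <- build_cylinder(width, height)
  grid <- expand.grid(b = b_grid, w = w_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cell_seed <- as.integer(base_seed) + k
    row <- data.frame(b = grid$b[k], w = grid$w[k], seed = cell_seed,
                      mean_payoff_norm = NA_real_, sd_payoff_norm = NA_real_,
                      coop_all = NA_real_, coop_green = NA_real_,
                      coop_blue = NA_real_, defect_all = NA_real_,
                      discrimination_index = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      labels <- assign_labels_gradient(graph, seed = cell_seed)
      run_point(model_params(grid$b[k], grid$w[k], mu), graph, labels,
                protocol, seed = cell_seed)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$mean_payoff_norm <- res$mean_payoff_norm
      row$sd_payoff_norm <- res$sd_payoff_norm
      row[names(strategy_codes())] <- as.list(res$shares)
      row$discrimination_index <- res$discrimination_index
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- list(width = width, height = height, mu = mu,
                            protocol = unclass(protocol), base_seed = base_seed)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' @export
print.scan_result <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("phase scan: %d cells on a %d x %d gradient cylinder (mu = %g)\n",
              nrow(x), meta$width, meta$height, meta$mu))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Phase-diagram heat map of a scan result
#'
#' Plots the normalized mean payoff over the `(w, b)` grid as an image,
#' `w` on a log axis when the grid spans more than one order of magnitude.
#'
#' @param x a `scan_result`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.scan_result <- function(x, ...) {
  b <- sort(unique(x$b)); w <- sort(unique(x$w))
  z <- matrix(NA_real_, length(w), length(b))
  for (k in seq_len(nrow(x))) {
    z[match(x$w[k], w), match(x$b[k], b)] <- x$mean_payoff_norm[k]
  }
  logw <- length(w) > 1 && max(w) / min(w) > 10
  xs <- if (logw) log10(w) else w
  graphics::image(xs, b, z, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = if (logw) "log10(selection pressure w)" else "selection pressure w",
                  ylab = "cooperation benefit b",
                  main = "normalized mean payoff", zlim = c(0, 1), ...)
  invisible(x)
}

# Fig-style strategy colour code: yellow coop-all, green coop-green,
# blue coop-blue, purple defect-all
strategy_palette <- function() {
  c(coop_all = "#F5D300", coop_green = "#2E8B57",
    coop_blue = "#2060C8", defect_all = "#6A0DAD")
}

#' Strategy snapshot of a lattice state
#'
#' Renders the strategy field of a lattice state with the standard colour
#' code (yellow cooperate-all, green cooperate-green, blue cooperate-blue,
#' purple defect-all). Rows follow the gradient axis, row 0 (all blue
#' labels) at the bottom.
#'
#' @param x a `sim_state` on a cylinder or torus.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.sim_state <- function(x, ...) {
  if (!x$graph$topology %in% c("cylinder", "torus")) {
    stop("snapshot plotting is defined for lattice topologies")
  }
  w <- x$graph$dims[["width"]]; h <- x$graph$dims[["height"]]
  z <- matrix(x$strategies, nrow = w)  # column r holds row r of the lattice
  graphics::image(seq_len(w), seq_len(h), z, col = strategy_palette(),
                  zlim = c(0.5, 4.5), xlab = "lattice column",
                  ylab = "lattice row (gradient axis)", ...)
  invisible(x)
}
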