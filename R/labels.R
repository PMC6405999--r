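#' Gradient label field on a lattice with an open axis
#'
#' Assigns each agent a green label independently with probability
#' `r / (height - 1)` where `r` is the agent's row along the gradient axis,
#' counted from the all-blue end. Row 0 is therefore entirely blue and the
#' top row entirely green; the expected overall green fraction is 1/2 and
#' within the greener half it is about 3/4, which is what makes the regional
#' majority structure of the phase diagram possible.
#'
#' @param graph a `population_graph` with a gradient axis (`cylinder`; a
#'   non-periodic axis is required, so tori and rings are rejected).
#' @param seed optional integer seed; with a fixed seed the field is
#'   reproducible.
#' @return Integer label vector (0 = blue, 1 = green), one entry per agent.
#' @examples
#' g <- build_cylinder(10, 5)
#' table(assign_labels_gradient(g, seed = 1))
#' @export
assign_labels_gradient <- function(graph, seed = NULL) {
  stopifnot(inherits(graph, "population_graph"))
  if (!identical(graph$topology, "cylinder")) {
    stop("gradient labels need a topology with an open gradient axis (cylinder)")
  }
  w <- graph$dims[["width"]]; h <- graph$dims[["height"]]
  if (h < 2L) stop("gradient axis needs at least 2 rows")
  if (!is.null(seed)) set.seed(seed)
  row <- rep(0:(h - 1L), each = w)           # row-major agent order
  p_green <- row / (h - 1)
  as.integer(runif(graph$n) < p_green)
}

#' Uniform random label field
#'
#' Every agent is green independently with probability `p`.
#'
#' @param graph a `population_graph`.
#' @param p probability of a green label.
#' @param seed optional integer seed.
#' @return Integer label vector (0 = blue, 1 = green).
#' @export
assign_labels_uniform <- function(graph, p = 0.5, seed = NULL) {
  stopifnot(inherits(graph, "population_graph"),
            is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  as.integer(runif(graph$n) < p)
}

#' Deterministic label fields for one-dimensional lines
#'
#' Two patterned fields used by the boundary analysis. `"single_minority"`
#' puts one green agent at the middle index `floor(n/2) + 1` of an otherwise
#' blue line (it needs `n >= 7` so the biased window of the boundary walk,
#' three steps to either side of the green agent, fits on the line).
#' `"repeated_pattern"` tiles `pattern` along the line, truncating the last
#' repetition if `n` is not a multiple of the pattern length.
#'
#' @param n line length.
#' @param kind `"single_minority"` or `"repeated_pattern"`.
#' @param pattern label sequence to tile, as integer codes (0/1) or
#'   characters (`"G"`/`"B"`, `"green"`/`"blue"`). Required for
#'   `"repeated_pattern"`.
#' @return Integer label vector (0 = blue, 1 = green) of length `n`.
#' @examples
#' assign_labels_line(7, "single_minority")
#' assign_labels_line(6, "repeated_pattern", pattern = c("G", "B"))
#' @export
assign_labels_line <- function(n, kind = c("single_minority", "repeated_pattern"),
                               pattern = NULL) {
  n <- as.integer(n)
  kind <- match.arg(kind)
  if (kind == "single_minority") {
    if (is.na(n) || n < 7L) stop("single_minority needs n >= 7")
    labs <- rep(.L_BLUE, n)
    labs[n %/% 2L + 1L] <- .L_GREEN
    return(labs)
  }
  if (is.null(pattern) || length(pattern) < 1L) {
    stop("repeated_pattern needs a non-empty pattern")
  }
  if (is.na(n) || n < 1L) stop("n must be positive")
  pat <- .as_label_codes(pattern)
  rep_len(pat, n)
}
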