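#' Population graphs
#'
#' All population topologies are stored as undirected adjacency lists with
#' no self-loops, plus a compressed (CSR) copy used by the C++ event loop.
#' `build_cylinder()` is the reference topology: a `width x height` square
#' lattice with von-Neumann 4-neighbourhoods, periodic only along the width
#' so that the two extreme rows (the ends of the label gradient) stay open;
#' agents in those two rows have degree 3, all others degree 4. Rows are the
#' gradient axis and are indexed `0:(height - 1)` from the all-blue end.
#'
#' @param width number of columns (the periodic direction), `>= 3`.
#' @param height number of rows (the gradient axis), `>= 2`.
#' @return An object of class `population_graph` with fields `n`, `adj`
#'   (list of 1-based integer neighbour vectors), `topology`, `dims`, and the
#'   CSR vectors `ptr`/`idx` (0-based) used internally.
#' @examples
#' g <- build_cylinder(6, 4)
#' table(lengths(g$adj))
#' @export
build_cylinder <- function(width, height) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || width < 3L) stop("cylinder width must be >= 3")
  if (is.na(height) || height < 2L) stop("cylinder height must be >= 2")
  .lattice_graph(width, height, wrap_w = TRUE, wrap_h = FALSE,
                 topology = "cylinder")
}

#' Auxiliary topologies: torus, line, ring, Erdos-Renyi
#'
#' Standard constructions used for robustness checks and the one-dimensional
#' boundary analysis. The torus is the fully periodic square lattice (all
#' degree 4); the line is an open path (end agents degree 1); the ring a
#' cycle (all degree 2). `build_erdos_renyi()` draws each edge independently
#' with probability `p`; isolated vertices and disconnected components are
#' permitted but flagged in `$meta`.
#'
#' @param width,height lattice dimensions for the torus.
#' @param n number of agents for line / ring / random graphs.
#' @param p edge probability for the random graph.
#' @param seed optional integer seed making the random edge set reproducible.
#' @return A `population_graph`.
#' @examples
#' build_ring(10)
#' @export
build_torus <- function(width, height) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || width < 3L || is.na(height) || height < 3L) {
    stop("torus dimensions must both be >= 3")
  }
  .lattice_graph(width, height, wrap_w = TRUE, wrap_h = TRUE,
                 topology = "torus")
}

#' @rdname build_torus
#' @export
build_line <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("a line needs at least 2 agents")
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- c(i - 1L, i + 1L)[c(i > 1L, i < n)]
  .new_graph(adj, topology = "line", dims = n)
}

#' @rdname build_torus
#' @export
build_ring <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("a ring needs at least 3 agents")
  adj <- lapply(seq_len(n), function(i) {
    c((i - 2L) %% n + 1L, i %% n + 1L)
  })
  .new_graph(adj, topology = "ring", dims = n)
}

#' @rdname build_torus
#' @export
build_erdos_renyi <- function(n, p, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("need at least 2 agents")
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  # one Bernoulli draw per unordered pair, fixed (i < j) order for determinism
  for (i in seq_len(n - 1L)) {
    js <- which(runif(n - i) < p) + i
    if (length(js)) {
      adj[[i]] <- c(adj[[i]], as.integer(js))
      for (j in js) adj[[j]] <- c(adj[[j]], i)
    }
  }
  g <- .new_graph(adj, topology = "erdos_renyi", dims = n)
  g$meta <- list(p = p, seed = seed,
                 n_isolated = sum(lengths(adj) == 0L),
                 connected = .is_connected(adj))
  g
}

.lattice_graph <- function(width, height, wrap_w, wrap_h, topology) {
  n <- width * height
  id <- function(r, c) r * width + c + 1L  # row-major, 0-based row/col
  adj <- vector("list", n)
  for (r in 0:(height - 1L)) {
    for (c0 in 0:(width - 1L)) {
      nb <- integer(0)
      # horizontal (width direction)
      if (wrap_w) {
        nb <- c(nb, id(r, (c0 - 1L) %% width), id(r, (c0 + 1L) %% width))
      } else {
        if (c0 > 0L) nb <- c(nb, id(r, c0 - 1L))
        if (c0 < width - 1L) nb <- c(nb, id(r, c0 + 1L))
      }
      # vertical (gradient axis)
      if (wrap_h) {
        nb <- c(nb, id((r - 1L) %% height, c0), id((r + 1L) %% height, c0))
      } else {
        if (r > 0L) nb <- c(nb, id(r - 1L, c0))
        if (r < height - 1L) nb <- c(nb, id(r + 1L, c0))
      }
      adj[[id(r, c0)]] <- sort(unique(nb))
    }
  }
  .new_graph(adj, topology = topology, dims = c(width = width, height = height))
}

.new_graph <- function(adj, topology, dims) {
  n <- length(adj)
  deg <- lengths(adj)
  idx <- if (n > 0L) as.integer(unlist(adj, use.names = FALSE)) - 1L else integer(0)
  ptr <- c(0L, cumsum(deg))
  structure(list(n = n, adj = adj, topology = topology, dims = dims,
                 ptr = as.integer(ptr), idx = idx),
            class = "population_graph")
}

.is_connected <- function(adj) {
  n <- length(adj)
  if (n == 0L) return(TRUE)
  seen <- logical(n); seen[1L] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.population_graph <- function(x, ...) {
  dims <- if (length(x$dims) > 1L) paste(x$dims, collapse = " x ") else x$dims
  cat(sprintf("population graph: %s, %d agents (%s), degrees %s\n",
              x$topology, x$n, dims,
              paste(range(lengths(x$adj)), collapse = "-")))
  invisible(x)
}
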