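# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Evaluate an expression under a temporary RNG state
#'
#' If `seed` is NULL the expression runs under the current RNG stream;
#' otherwise the global RNG state is saved, the seed applied, and the state
#' restored afterwards, so seeded calls are reproducible without disturbing
#' the caller's stream.
#' @noRd
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Kahn topological sort of arcs over `nodes`; returns node order or NULL if
# the arc set contains a directed cycle.
topo_sort <- function(nodes, arcs) {
  n <- length(nodes)
  if (n == 0L) return(character(0))
  indeg <- setNames(integer(n), nodes)
  adj <- setNames(vector("list", n), nodes)
  if (nrow(arcs) > 0L) {
    for (i in seq_len(nrow(arcs))) {
      u <- arcs[i, 1L]; v <- arcs[i, 2L]
      indeg[[v]] <- indeg[[v]] + 1L
      adj[[u]] <- c(adj[[u]], v)
    }
  }
  queue <- nodes[indeg == 0L]
  out <- character(0)
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    out <- c(out, u)
    for (v in adj[[u]]) {
      indeg[[v]] <- indeg[[v]] - 1L
      if (indeg[[v]] == 0L) queue <- c(queue, v)
    }
  }
  if (length(out) < n) NULL else out
}

# Boolean reachability matrix (strict: diagonal FALSE) of a DAG given as a
# two-column character matrix of arcs over `nodes`.
reach_matrix <- function(nodes, arcs) {
  n <- length(nodes)
  reach <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (n == 0L || nrow(arcs) == 0L) return(reach)
  adj <- reach
  adj[cbind(arcs[, 1L], arcs[, 2L])] <- TRUE
  order <- topo_sort(nodes, arcs)
  if (is.null(order)) stop("reach_matrix requires an acyclic arc set")
  # accumulate descendants in reverse topological order
  for (u in rev(order)) {
    kids <- nodes[adj[u, ]]
    reach[u, ] <- adj[u, ]
    for (k in kids) reach[u, ] <- reach[u, ] | reach[k, ]
  }
  reach
}

as_arc_matrix <- function(arcs) {
  if (is.null(arcs) || (is.data.frame(arcs) && nrow(arcs) == 0L))
    return(matrix(character(0), 0L, 2L))
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs[, 1:2])
  if (length(arcs) == 0L) return(matrix(character(0), 0L, 2L))
  storage.mode(arcs) <- "character"
  matrix(arcs, ncol = 2L, dimnames = NULL)
}

arc_keys <- function(arcs) {
  arcs <- as_arc_matrix(arcs)
  if (nrow(arcs) == 0L) return(character(0))
  paste(arcs[, 1L], arcs[, 2L], sep = "\r")
}
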