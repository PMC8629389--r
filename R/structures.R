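#' Population graph
#'
#' A `graph_structure` is the arena on which the evolutionary process runs:
#' a symmetric, non-negatively weighted graph whose nodes are individuals and
#' whose edges encode both interaction (who receives goods from whom) and
#' dispersal (where offspring can be placed). Nodes are indexed `0..N-1`.
#'
#' Construction validates the invariants the downstream Markov chains rely
#' on: symmetry, zero diagonal, strictly positive row sums (no isolated
#' node), and connectedness -- fixation is undefined across disconnected
#' components, so a disconnected matrix is a hard error.
#'
#' @param W square numeric matrix of edge weights; `W[i, j] >= 0`,
#'   `W[i, j] == W[j, i]` (tolerance `1e-9`), zero diagonal.
#' @return An object of class `graph_structure` with elements `N` (number of
#'   nodes) and `W` (the weight matrix, symmetrized to remove round-off).
#' @seealso [make_cycle()], [make_star()], [read_adjacency()], [step_matrix()]
#' @examples
#' g <- graph_structure(matrix(c(0, 2, 0, 2, 0, 1, 0, 1, 0), 3, 3))
#' step_matrix(g)
#' @export
graph_structure <- function(W) {
  W <- as.matrix(W)
  if (!is.numeric(W) || nrow(W) != ncol(W))
    stop_socfix("adjacency matrix must be a square numeric matrix")
  N <- nrow(W)
  if (N < 2L) stop_socfix("a population graph needs at least 2 nodes")
  if (any(!is.finite(W)) || any(W < 0))
    stop_socfix("edge weights must be finite and non-negative")
  if (max(abs(W - t(W))) > 1e-9)
    stop_socfix("adjacency matrix is not symmetric (tolerance 1e-9)")
  W <- (W + t(W)) / 2
  if (any(diag(W) != 0))
    stop_socfix("self-loops are not allowed (diagonal must be zero)")
  if (any(rowSums(W) <= 0))
    stop_socfix("every node must have at least one neighbor")
  if (!is_connected(W))
    stop_socfix("graph is disconnected; fixation is undefined across components")
  structure(list(N = N, W = unname(W)), class = "graph_structure")
}

# breadth-first reachability on the support of W
is_connected <- function(W) {
  N <- nrow(W)
  seen <- logical(N)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(W[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.graph_structure <- function(x, ...) {
  cat(sprintf("graph_structure: %d nodes, %d edges%s\n",
              x$N, sum(x$W > 0) / 2,
              if (all(x$W %in% c(0, 1))) "" else " (weighted)"))
  invisible(x)
}

#' Cycle graph
#'
#' Periodic structure in which every individual has exactly two neighbors,
#' node `i` being linked to `(i +/- 1) mod N` with weight 1. The smallest
#' cycle, `N = 3`, coincides with the complete graph on three nodes.
#'
#' @param N population size, an integer `>= 3`.
#' @return A [graph_structure()].
#' @export
make_cycle <- function(N) {
  N <- check_size(N)
  W <- matrix(0, N, N)
  i <- seq_len(N)
  W[cbind(i, i %% N + 1L)] <- 1
  W[cbind(i %% N + 1L, i)] <- 1
  graph_structure(W)
}

#' Star graph
#'
#' Heterogeneous structure with one central hub connected to `N - 1` leaf
#' nodes. By package convention the hub is node 0 (row/column 1 of the
#' weight matrix). For `N = 3` the star coincides with the path on three
#' nodes.
#'
#' @inheritParams make_cycle
#' @return A [graph_structure()].
#' @export
make_star <- function(N) {
  N <- check_size(N)
  W <- matrix(0, N, N)
  W[1, -1] <- 1
  W[-1, 1] <- 1
  graph_structure(W)
}

check_size <- function(N) {
  if (length(N) != 1L || !is.finite(N) || N != round(N) || N < 3)
    stop_socfix("population size N must be a single integer >= 3")
  as.integer(N)
}

#' Read an adjacency matrix from a text file
#'
#' Reads a whitespace-delimited square numeric matrix and validates it as a
#' population graph. Symmetry is checked to a tolerance of `1e-9`; any
#' violation of the graph invariants is an error.
#'
#' @param file path to a plain-text file holding the matrix.
#' @return A [graph_structure()].
#' @export
read_adjacency <- function(file) {
  W <- as.matrix(utils::read.table(file, header = FALSE))
  dimnames(W) <- NULL
  if (!is.numeric(W))
    stop_socfix("adjacency file must contain only numbers")
  graph_structure(W)
}

#' One-step random-walk matrix
#'
#' Returns the row-stochastic matrix `p[i, j] = w[i, j] / sum_k w[i, k]`,
#' the probability of moving from `i` to `j` in one step of a random walk on
#' the graph. This matrix defines how ff-goods are split among neighbors,
#' how cf-goods recipients are drawn, and where Birth-death offspring land.
#'
#' @param g a [graph_structure()].
#' @return An `N x N` row-stochastic matrix.
#' @export
step_matrix <- function(g) {
  stopifnot(inherits(g, "graph_structure"))
  g$W / rowSums(g$W)
}
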