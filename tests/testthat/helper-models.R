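# Shared fixtures: all built in code at test time.

# random symmetric connected unweighted graph on n nodes
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    W <- matrix(stats::rbinom(n * n, 1, p), n, n)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    diag(W) <- 0
    g <- tryCatch(graph_structure(W), error = function(e) NULL)
    if (!is.null(g)) return(g)
  }
}

# single-mutant configuration: one producer at 0-based `node`
single_C <- function(N, node = 0L) {
  x <- rep(FALSE, N)
  x[node + 1L] <- TRUE
  x
}

# lump a full-configuration kernel row onto cycle cluster sizes
lump_row_cycle <- function(kfull, state_idx, N) {
  nC <- vapply(strsplit(kfull$labels, ""), function(z) sum(z == "C"), 0L)
  lumped <- tapply(kfull$P[state_idx, ], nC, sum)
  out <- numeric(N + 1L)
  out[as.integer(names(lumped)) + 1L] <- lumped
  out
}

# is the producer set of a full-space label a single contiguous arc?
is_arc_label <- function(label, N) {
  v <- strsplit(label, "")[[1]] == "C"
  k <- sum(v)
  if (k == 0L || k == N) return(TRUE)
  sum(v & !c(v[-1], v[1])) == 1L   # number of C-run right endpoints (cyclic)
}

# lump a full star kernel row onto (hub trait, leaf producer count) states
lump_row_star <- function(kfull, state_idx, N) {
  msn <- vapply(strsplit(kfull$labels, ""), function(z)
    (z[1] == "C") * N + sum(z[-1] == "C") + 1, 0)
  lumped <- tapply(kfull$P[state_idx, ], msn, sum)
  out <- numeric(2L * N)
  out[as.integer(names(lumped))] <- lumped
  out
}

# full-space state index of a trait string
full_state_index <- function(kfull, label) which(kfull$labels == label)
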