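# Monte Carlo trajectory sampler: an independent stochastic realization of
# the same update rules the exact kernels encode. cf recipients are drawn
# afresh, concretely, at every update step.

#' Simulate one trajectory to fixation
#'
#' Runs the evolutionary process from configuration `x0` until one trait
#' fixes or `max_steps` elapse. For cf goods every producer draws a concrete
#' recipient at each step; for dB updating the dying individual is uniform
#' and its neighbors compete proportionally to fecundity; for Bd updating
#' the reproducer is drawn proportionally to fecundity over the whole
#' population and its offspring replaces a neighbor drawn with the
#' random-walk probabilities.
#'
#' @param g a [graph_structure()].
#' @param rule `"dB"` or `"Bd"`.
#' @param s a [goods_scheme()].
#' @param m a [fecundity_map()] with `mode = "reproduction"`.
#' @param x0 starting trait configuration (`"C"`/`"D"` character or logical).
#' @param seed integer seed; `NULL` continues from the current RNG state
#'   (used by [mc_fixation()], which seeds once for the whole batch).
#' @param max_steps censoring horizon, `> 0`.
#' @param keep_path if `TRUE`, also return the visited configurations as a
#'   logical matrix (rows = steps incl. start, TRUE = producer).
#' @return list with `outcome` (`"fixed_C"`, `"fixed_D"` or `"censored"`),
#'   `steps`, and optionally `path`.
#' @export
simulate_fixation <- function(g, rule = c("dB", "Bd"), s, m, x0,
                              seed = NULL, max_steps = 1e6, keep_path = FALSE) {
  rule <- match.arg(rule)
  require_reproduction(m)
  stopifnot(max_steps > 0)
  if (!is.null(seed)) set.seed(seed)
  eng <- sim_engine(g, rule, s, m)
  eng(as_traits(x0, g$N), max_steps, keep_path)
}

#' Replicate fixation simulations
#'
#' Runs `nrep` independent trajectories from `x0` under one seed and
#' tallies outcomes. Censored runs are reported, never silently dropped;
#' the fixation fraction and its binomial standard error are computed over
#' all replicates.
#'
#' @inheritParams simulate_fixation
#' @param nrep number of replicates.
#' @param seed integer seed for the whole batch.
#' @return An object of class `mc_fixation`: counts `n_fixed_C`,
#'   `n_fixed_D`, `n_censored`, the producer-fixation `fraction`, its
#'   binomial `se`, and `nrep`.
#' @export
mc_fixation <- function(g, rule = c("dB", "Bd"), s, m, x0, nrep,
                        seed = NULL, max_steps = 1e6) {
  rule <- match.arg(rule)
  require_reproduction(m)
  if (!is.null(seed)) set.seed(seed)
  eng <- sim_engine(g, rule, s, m)
  x0 <- as_traits(x0, g$N)
  out <- integer(3L)  # fixed_C, fixed_D, censored
  for (r in seq_len(nrep)) {
    res <- eng(x0, max_steps, FALSE)
    k <- match(res$outcome, c("fixed_C", "fixed_D", "censored"))
    out[k] <- out[k] + 1L
  }
  frac <- out[1L] / nrep
  structure(list(n_fixed_C = out[1L], n_fixed_D = out[2L],
                 n_censored = out[3L], nrep = nrep,
                 fraction = frac, se = sqrt(frac * (1 - frac) / nrep)),
            class = "mc_fixation")
}

#' @export
print.mc_fixation <- function(x, ...) {
  cat(sprintf("mc_fixation: %d runs, fixed_C %d, fixed_D %d, censored %d\n",
              x$nrep, x$n_fixed_C, x$n_fixed_D, x$n_censored))
  cat(sprintf("  producer fixation fraction %.5f (binomial SE %.5f)\n",
              x$fraction, x$se))
  invisible(x)
}

# Builds a closure that advances one trajectory; all structure-dependent
# quantities are precomputed once so the per-step work is a handful of
# vectorized operations.
sim_engine <- function(g, rule, s, m) {
  N <- g$N
  W <- g$W
  P <- step_matrix(g)
  delta <- m$delta
  nbr <- lapply(seq_len(N), function(i) which(W[i, ] > 0))
  deg <- lengths(nbr)
  nbr_flat <- unlist(nbr)
  nbr_off <- c(0L, cumsum(deg))[seq_len(N)]
  cumP <- lapply(seq_len(N), function(i) cumsum(P[i, nbr[[i]]]))
  uniformP <- all(vapply(seq_len(N),
                         function(i) max(abs(P[i, nbr[[i]]] - 1 / deg[i])) < 1e-12,
                         NA))
  bW <- s$b * W          # pp receipts
  btP <- s$b * t(P)      # ff receipts
  cost_vec <- if (s$kind == "pp") s$c * rowSums(W) else rep(s$c, N)

  pick_neighbor <- function(i) {
    if (uniformP) {
      nbr_flat[nbr_off[i] + sample.int(deg[i], 1L)]
    } else {
      nbr[[i]][findInterval(stats::runif(1L), cumP[[i]]) + 1L]
    }
  }

  payoffs <- function(xc) {
    if (s$kind == "pp") return(drop(crossprod(bW, xc)) - cost_vec * xc)
    if (s$kind == "ff") return(drop(btP %*% xc) - cost_vec * xc)
    pr <- which(xc)
    if (!length(pr)) return(numeric(N))
    if (uniformP) {
      rec <- nbr_flat[nbr_off[pr] + ceiling(stats::runif(length(pr)) * deg[pr])]
    } else {
      rec <- vapply(pr, pick_neighbor, 0L)
    }
    u <- s$b * tabulate(rec, N)
    u[pr] <- u[pr] - s$c
    u
  }

  function(xc, max_steps, keep_path) {
    nC <- sum(xc)
    path <- if (keep_path) list(xc) else NULL
    step <- 0L
    while (nC > 0L && nC < N && step < max_steps) {
      step <- step + 1L
      if (rule == "dB") {
        die <- sample.int(N, 1L)
        cmp <- nbr[[die]]
        if (length(cmp) == 1L) {
          winner <- cmp
        } else {
          u <- payoffs(xc)[cmp]
          w <- exp(delta * (u - max(u)))
          winner <- cmp[sample.int(length(cmp), 1L, prob = w)]
        }
        if (xc[die] != xc[winner]) {
          nC <- nC + if (xc[winner]) 1L else -1L
          xc[die] <- xc[winner]
          if (keep_path) path[[length(path) + 1L]] <- xc
        }
      } else {
        u <- payoffs(xc)
        w <- exp(delta * (u - max(u)))
        parent <- sample.int(N, 1L, prob = w)
        child <- pick_neighbor(parent)
        if (xc[child] != xc[parent]) {
          nC <- nC + if (xc[parent]) 1L else -1L
          xc[child] <- xc[parent]
          if (keep_path) path[[length(path) + 1L]] <- xc
        }
      }
    }
    outcome <- if (nC == N) "fixed_C" else if (nC == 0L) "fixed_D" else "censored"
    res <- list(outcome = outcome, steps = step)
    if (keep_path)
      res$path <- matrix(unlist(path), ncol = N, byrow = TRUE)
    res
  }
}
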