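# Fixation probabilities: linear solves on the absorbing chains, mutant
# initialization distributions, mean fixation probabilities, and the
# closed-form star expressions.

#' Solve for state-wise fixation probabilities
#'
#' Solves the recurrence `rho(x) = sum_y P[x -> y] rho(y)` with boundary
#' conditions `rho(all-C) = 1`, `rho(all-D) = 0` by a direct (sparse where
#' the kernel is sparse) factorization of the transient block. The residual
#' `max |rho - P rho|` must come out below `1e-10`, otherwise an error with
#' a conditioning diagnostic is raised.
#'
#' @param k a `transition_kernel` with exactly two absorbing states.
#' @return An object of class `fixation_result` with `rho_C` and `rho_D`
#'   (named by state labels, `rho_D = 1 - rho_C`), the achieved `residual`,
#'   and the kernel's `space` for downstream initialization averaging.
#' @export
solve_fixation <- function(k) {
  stopifnot(inherits(k, "transition_kernel"))
  nS <- length(k$labels)
  absb <- k$absorbing
  tr <- setdiff(seq_len(nS), absb)
  rho <- numeric(nS)
  rho[absb["C"]] <- 1
  if (length(tr)) {
    P <- k$P
    A <- if (inherits(P, "Matrix")) {
      Matrix::Diagonal(length(tr)) - P[tr, tr, drop = FALSE]
    } else {
      diag(length(tr)) - P[tr, tr, drop = FALSE]
    }
    rhs <- P[tr, absb["C"]]
    sol <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                    error = function(e) {
                      kap <- tryCatch(kappa(as.matrix(A)), error = function(e2) NA)
                      stop_socfix("fixation linear system could not be solved ",
                                  "(condition estimate ", format(kap), "): ",
                                  conditionMessage(e))
                    })
    rho[tr] <- sol
  }
  resid <- max(abs(rho - as.numeric(k$P %*% rho)))
  if (!is.finite(resid) || resid > 1e-10) {
    kap <- tryCatch(kappa(as.matrix(k$P)), error = function(e) NA)
    stop_socfix("fixation solve residual ", format(resid),
                " exceeds 1e-10 (kernel condition estimate ", format(kap), ")")
  }
  rho <- pmin(pmax(rho, 0), 1)
  names(rho) <- k$labels
  structure(list(rho_C = rho, rho_D = 1 - rho, residual = resid,
                 space = k$space, rule = k$rule),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat(sprintf("fixation_result: %d states (%s space), residual %.2e\n",
              length(x$rho_C), x$space$type, x$residual))
  invisible(x)
}

#' Per-node replacement (death) rates in a monomorphic state
#'
#' Probability that the individual at each node is replaced by another
#' individual's offspring in one step of the process, evaluated in the
#' monomorphic all-producer or all-non-producer state. These are the node
#' "temperatures" that drive temperature initialization.
#'
#' Under dB updating the dying individual is always uniform, so every node
#' has rate `1/N` regardless of structure or selection intensity. Under Bd
#' updating node `i` is replaced with probability
#' `sum_j E[F_j / sum_k F_k] p[j, i]`, with fecundities from the
#' monomorphic configuration (and the expectation over cf recipient
#' scenarios). The rates always sum to 1.
#'
#' @inheritParams simulate_fixation
#' @param monomorphic_type `"C"` or `"D"`: which monomorphic state the
#'   rates are evaluated in.
#' @return numeric vector of length `N` summing to 1.
#' @export
death_rates <- function(g, rule = c("dB", "Bd"), monomorphic_type = c("C", "D"),
                        s, m) {
  rule <- match.arg(rule)
  monomorphic_type <- match.arg(monomorphic_type)
  stopifnot(inherits(g, "graph_structure"))
  if (rule == "dB") return(rep(1 / g$N, g$N))
  require_reproduction(m)
  xc <- rep(monomorphic_type == "C", g$N)
  dist <- payoff_distribution(g, xc, s)
  sel <- expected_competition(dist, 0:(g$N - 1L), m)
  drop(crossprod(step_matrix(g), sel))
}

#' Mutant initialization distribution
#'
#' Where does the invading mutant appear? Under `"uniform"` initialization
#' each node carries probability `1/N` for either mutant type. Under
#' `"temperature"` initialization mutants arise during reproduction, so a
#' mutant producer appears at node `i` with probability proportional to the
#' node's replacement rate in the all-non-producer state (and a mutant
#' non-producer proportional to the rate in the all-producer state). Under
#' dB updating replacement is uniform, so the two modes coincide.
#'
#' @inheritParams death_rates
#' @param mode `"uniform"` or `"temperature"`.
#' @return An object of class `init_distribution` with node-level
#'   probability vectors `mu_C` and `mu_D` (each summing to 1).
#' @export
initialization <- function(g, rule = c("dB", "Bd"), s, m,
                           mode = c("uniform", "temperature")) {
  rule <- match.arg(rule)
  mode <- match.arg(mode)
  stopifnot(inherits(g, "graph_structure"))
  if (mode == "uniform") {
    mu_C <- mu_D <- rep(1 / g$N, g$N)
  } else {
    d_D <- death_rates(g, rule, "D", s, m)
    d_C <- death_rates(g, rule, "C", s, m)
    mu_C <- d_D / sum(d_D)
    mu_D <- d_C / sum(d_C)
  }
  structure(list(mode = mode, mu_C = mu_C, mu_D = mu_D),
            class = "init_distribution")
}

#' @export
print.init_distribution <- function(x, ...) {
  cat(sprintf("init_distribution: %s over %d nodes\n", x$mode, length(x$mu_C)))
  invisible(x)
}

# state index of the configuration with a single mutant of `type` at
# 0-based node `node`, in the state space of a fixation_result
single_mutant_state <- function(space, labels, node, type) {
  N <- space$N
  switch(space$type,
    "cycle-cluster" = if (type == "C") which(labels == "n=1")
                      else which(labels == paste0("n=", N - 1L)),
    "star-pair" = {
      lab <- if (type == "C") {
        if (node == 0L) "(1,0)" else "(0,1)"
      } else {
        if (node == 0L) paste0("(0,", N - 1L, ")") else paste0("(1,", N - 2L, ")")
      }
      which(labels == lab)
    },
    "full" = {
      tr <- rep(if (type == "C") "D" else "C", N)
      tr[node + 1L] <- type
      which(labels == paste(tr, collapse = ""))
    },
    stop_socfix("unknown state-space type: ", space$type)
  )
}

#' Mean fixation probabilities under an initialization distribution
#'
#' Averages the state-wise fixation probabilities over the single-mutant
#' starting states weighted by the mutant-appearance distribution:
#' `mean_rho_C = sum_i mu_C[i] rho_C(single C at i)` and likewise for
#' non-producers (whose fixation probability from a single-D state is
#' `1 - rho_C` of that state). On lumped state spaces, node masses
#' aggregate onto their orbit's state (e.g. all leaf starts of the star
#' onto `(0,1)`).
#'
#' @param fr a [solve_fixation()] result.
#' @param init an [initialization()] distribution over the same population.
#' @return named numeric vector `c(mean_rho_C = , mean_rho_D = )`.
#' @export
mean_fixation <- function(fr, init) {
  stopifnot(inherits(fr, "fixation_result"), inherits(init, "init_distribution"))
  N <- fr$space$N
  if (length(init$mu_C) != N)
    stop_socfix("initialization is over ", length(init$mu_C),
                " nodes but the chain describes ", N)
  nodes <- 0:(N - 1L)
  idx_C <- vapply(nodes, function(i)
    single_mutant_state(fr$space, names(fr$rho_C), i, "C"), 0L)
  idx_D <- vapply(nodes, function(i)
    single_mutant_state(fr$space, names(fr$rho_C), i, "D"), 0L)
  c(mean_rho_C = sum(init$mu_C * fr$rho_C[idx_C]),
    mean_rho_D = sum(init$mu_D * (1 - fr$rho_C[idx_D])))
}

#' Closed-form star fixation probabilities for ff-goods
#'
#' Evaluates the explicit expressions for the fixation probability of a
#' single producer of ff-goods on the star under Bd updating, starting from
#' the hub (state `(1,0)`) or from a leaf (state `(0,1)`). The expressions
#' are products and sums of transition probabilities conditioned on leaving
#' the current state; every term is accumulated in log space, so the
#' result is finite for population sizes of several thousand and selection
#' intensities of order 50 and beyond.
#'
#' This is the engine behind large-star sweeps (`N > 200`): each evaluation
#' is `O(N)` per selection intensity, against the `O(N^3)` worst case of a
#' dense linear solve. It agrees with [solve_fixation()] on
#' [kernel_star_bd()] to ~1e-12 wherever both run.
#'
#' @param N star size, `>= 3`.
#' @param b benefit; `c` cost (`>= 0`).
#' @param c cost paid by a producer.
#' @param delta selection intensity or vector thereof, `>= 0`.
#' @return matrix with one row per `delta` and columns `hub`, `leaf`.
#' @export
closed_form_star_ff <- function(N, b, c, delta) {
  N <- check_size(N)
  if (any(delta < 0)) stop_socfix("delta must be >= 0")
  be <- b / (N - 1)
  lN <- log(N - 1)
  one <- function(d) {
    lnA <- -logsumexp(c(0, lN + d * (be + c)))          # (1,0) -> (1,1)
    lnB <- -logsumexp(c(0, d * (b + c) - lN))           # (0,1) -> (1,1)
    i <- seq_len(N - 2L)
    lnQ <- -vapply(i, function(ii)
      logsumexp(c(0, d * ((ii - 1 / (N - 1)) * b - c) - lN)), 0)
    lnR <- vapply(i, function(jj)
      logsumexp(c(0, lN + d * (be + c - jj * b))) -
      logsumexp(c(0, lN - d * (jj * b + c))), 0)
    lnDen <- logsumexp(c(0, lnQ + cumsum(lnR)))
    c(hub = exp(lnA - lnDen), leaf = exp(lnB - lnDen))
  }
  out <- t(vapply(delta, one, c(hub = 0, leaf = 0)))
  rownames(out) <- NULL
  out
}
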