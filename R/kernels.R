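# Exact transition kernels for the evolutionary update rules.
#
# Every kernel is a row-stochastic matrix over a labelled state space with
# the two monomorphic configurations (all-D, all-C) as absorbing states.
# For stochastic (cf) payoffs, transition probabilities are expectations --
# taken per update step -- of the competition outcome over the joint
# distribution of recipient choices: the expectation of the softmax ratio,
# never the softmax of expected payoffs.

new_kernel <- function(P, labels, space, rule, absorbing) {
  P <- clip_probabilities(P)
  rs <- Matrix::rowSums(P)
  if (max(abs(rs - 1)) > 1e-10)
    stop_socfix("kernel rows do not sum to 1 (max deviation ",
                format(max(abs(rs - 1))), ")")
  for (a in absorbing) {
    row <- P[a, ]
    if (abs(row[a] - 1) > 1e-12 || sum(row) - row[a] > 1e-12)
      stop_socfix("absorbing state ", labels[a], " does not have an identity row")
  }
  structure(list(P = P, labels = labels, space = space, rule = rule,
                 absorbing = absorbing),
            class = "transition_kernel")
}

# entries outside [0,1] by more than numerical dust indicate a logic bug,
# not round-off; only dust is clipped
clip_probabilities <- function(P, slack = 1e-14) {
  mn <- min(P); mx <- max(P)
  if (mn < -slack || mx > 1 + slack)
    stop_socfix("kernel entries outside [0,1] beyond numerical slack: range [",
                format(mn), ", ", format(mx), "]")
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat(sprintf("transition_kernel: %s updating, %d states (%s space)\n",
              x$rule, length(x$labels), x$space$type))
  cat(sprintf("  absorbing: %s (all-D), %s (all-C)\n",
              x$labels[x$absorbing["D"]], x$labels[x$absorbing["C"]]))
  invisible(x)
}

require_reproduction <- function(m) {
  stopifnot(inherits(m, "fecundity_map"))
  if (m$mode != "reproduction")
    stop_socfix("update-rule kernels are defined for selection on ",
                "reproduction; survival-mode competition is available through ",
                "competition_probabilities()")
}

#' Reduced cycle chain under death-Birth updating
#'
#' On the cycle, a mutant lineage invading under dB updating stays a single
#' contiguous arc, so the chain can be lumped to the cluster size
#' `n = 0, ..., N`. A step picks the dying individual uniformly (probability
#' `1/N`); only deaths on a producer/non-producer boundary can change `n`,
#' and the vacancy is then contested by the two neighbors of the deceased
#' with probability proportional to fecundity. Payoffs are evaluated in the
#' full pre-death configuration (the dying individual still produces), and
#' for cf goods the competition outcome is averaged over the recipient
#' choices of every producer adjacent to a competitor. At `n = 1` and
#' `n = N - 1` the two boundaries share an individual; the construction
#' below handles that case by examining each dying node individually.
#'
#' The reduction is valid for trajectories started from a single mutant (or
#' any contiguous cluster); arbitrary configurations on the cycle go through
#' [kernel_full()].
#'
#' @param N cycle size, `>= 3`.
#' @param s a [goods_scheme()].
#' @param m a [fecundity_map()] with `mode = "reproduction"`.
#' @return A `transition_kernel` over states `n=0 .. n=N`.
#' @export
kernel_cycle_db <- function(N, s, m) {
  require_reproduction(m)
  g <- make_cycle(N)
  P <- matrix(0, N + 1L, N + 1L)
  P[1L, 1L] <- 1
  P[N + 1L, N + 1L] <- 1
  for (n in seq_len(N - 1L)) {
    xc <- c(rep(TRUE, n), rep(FALSE, N - n))
    row <- numeric(N + 1L)
    for (die in seq_len(N)) {
      cmp <- c((die - 2L) %% N + 1L, die %% N + 1L)
      tc <- xc[cmp]
      if (tc[1L] == tc[2L]) {
        p_c_wins <- as.numeric(tc[1L])
      } else {
        dist <- payoff_distribution(g, xc, s, relevant = cmp - 1L)
        p_c_wins <- sum(expected_competition(dist, cmp - 1L, m)[tc])
      }
      if (xc[die]) {                     # a producer dies
        row[n]      <- row[n]      + (1 - p_c_wins) / N
        row[n + 1L] <- row[n + 1L] + p_c_wins / N
      } else {                           # a non-producer dies
        row[n + 2L] <- row[n + 2L] + p_c_wins / N
        row[n + 1L] <- row[n + 1L] + (1 - p_c_wins) / N
      }
    }
    P[n + 1L, ] <- row
  }
  new_kernel(P, labels = paste0("n=", 0:N),
             space = list(type = "cycle-cluster", N = N),
             rule = "dB", absorbing = c(D = 1L, C = N + 1L))
}

#' Reduced star chain under Birth-death updating
#'
#' State `(m, n)`: `m` is 1 if the hub is a producer, `n` counts producers
#' among the `N - 1` leaves. A step selects the reproducing individual with
#' probability proportional to fecundity over the whole population
#' (expectation over cf recipient scenarios of that ratio); the hub's
#' offspring replaces a uniformly random leaf, a leaf's offspring replaces
#' the hub.
#'
#' For deterministic payoffs (pp, ff) the rows are assembled in closed,
#' vectorized form, which keeps the chain cheap even for populations of
#' several thousand; cf goods enumerate the hub's recipient choices
#' exactly.
#'
#' @param N star size, `>= 3`; the hub is node 0.
#' @inheritParams kernel_cycle_db
#' @return A `transition_kernel` over states `(m,n)`, ordered
#'   `(0,0), ..., (0,N-1), (1,0), ..., (1,N-1)`.
#' @export
kernel_star_bd <- function(N, s, m) {
  require_reproduction(m)
  N <- check_size(N)
  stopifnot(inherits(s, "goods_scheme"))
  nS <- 2L * N
  idx <- function(mm, nn) mm * N + nn + 1L
  labels <- paste0("(", rep(0:1, each = N), ",", rep(0:(N - 1L), 2L), ")")

  if (s$kind %in% c("pp", "ff")) {
    # payoffs per state depend only on (m, n); three payoff classes
    mm <- rep(0:1, each = N)
    nn <- rep(0:(N - 1L), 2L)
    if (s$kind == "ff") {
      uh <- nn * s$b - mm * s$c
      uC <- mm * s$b / (N - 1) - s$c
      uD <- mm * s$b / (N - 1)
    } else {
      uh <- nn * s$b - mm * s$c * (N - 1)
      uC <- mm * s$b - s$c
      uD <- mm * s$b
    }
    d <- m$delta
    lh <- d * uh
    lC <- ifelse(nn > 0, log(nn) + d * uC, -Inf)
    lD <- ifelse(N - 1L - nn > 0, log(N - 1L - nn) + d * uD, -Inf)
    mx <- pmax(lh, lC, lD)
    tot <- exp(lh - mx) + exp(lC - mx) + exp(lD - mx)
    sh <- exp(lh - mx) / tot          # hub reproduces
    sC <- exp(lC - mx) / tot          # some producer leaf reproduces
    sD <- exp(lD - mx) / tot          # some non-producer leaf reproduces

    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    add <- function(i, j, x) {
      keep <- x > 0
      ii <<- c(ii, i[keep]); jj <<- c(jj, j[keep]); xx <<- c(xx, x[keep])
    }
    st <- seq_len(nS)
    trans <- !(mm == 0L & nn == 0L) & !(mm == 1L & nn == N - 1L)
    up <- trans & mm == 1L
    add(st[up], idx(1L, nn[up] + 1L), (sh * (N - 1L - nn) / (N - 1L))[up])
    add(st[up], idx(0L, nn[up]), sD[up])
    dn <- trans & mm == 0L
    add(st[dn], idx(0L, nn[dn] - 1L), (sh * nn / (N - 1L))[dn])
    add(st[dn], idx(1L, nn[dn]), sC[dn])
    off <- rowsum(xx, ii)
    self <- rep(1, nS)
    self[as.integer(rownames(off))] <- 1 - off[, 1L]
    add(st, st, self)
    P <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nS, nS))
    if (N <= 64L) P <- as.matrix(P)
  } else {
    g <- make_star(N)
    P <- matrix(0, nS, nS)
    for (mm in 0:1) for (nn in 0:(N - 1L)) {
      sidx <- idx(mm, nn)
      if ((mm == 0L && nn == 0L) || (mm == 1L && nn == N - 1L)) {
        P[sidx, sidx] <- 1
        next
      }
      xc <- c(mm == 1L, seq_len(N - 1L) <= nn)
      dist <- payoff_distribution(g, xc, s)
      sel <- expected_competition(dist, 0:(N - 1L), m)
      sh <- sel[1L]
      sC <- if (nn > 0) sum(sel[1L + seq_len(nn)]) else 0
      sD <- 1 - sh - sC
      if (mm == 1L) {
        P[sidx, idx(1L, nn + 1L)] <- sh * (N - 1L - nn) / (N - 1L)
        P[sidx, idx(0L, nn)] <- sD
      } else {
        if (nn > 0) P[sidx, idx(0L, nn - 1L)] <- sh * nn / (N - 1L)
        P[sidx, idx(1L, nn)] <- sC
      }
      P[sidx, sidx] <- 1 - sum(P[sidx, -sidx])
    }
  }
  new_kernel(P, labels = labels,
             space = list(type = "star-pair", N = N),
             rule = "Bd", absorbing = c(D = idx(0L, 0L), C = idx(1L, N - 1L)))
}

#' Brute-force chain over all trait configurations
#'
#' Builds the exact transition kernel on the full space of `2^N` trait
#' vectors of a small graph, for either update rule. This is the oracle the
#' reduced cycle and star chains are checked against (lumping by symmetry),
#' and the only exact route for structures or rules without a reduced
#' chain.
#'
#' @param g a [graph_structure()] with at most `max_size` nodes.
#' @param rule `"dB"` (uniform death, neighbors compete by fecundity) or
#'   `"Bd"` (global fecundity-proportional birth, offspring to a random
#'   neighbor).
#' @inheritParams kernel_cycle_db
#' @param max_size cap on `N` (state count grows as `2^N`); default 12.
#' @return A `transition_kernel` whose labels are trait strings such as
#'   `"CCDD"` (node 0 first).
#' @export
kernel_full <- function(g, rule = c("dB", "Bd"), s, m, max_size = 12L) {
  rule <- match.arg(rule)
  require_reproduction(m)
  stopifnot(inherits(g, "graph_structure"))
  N <- g$N
  if (N > max_size)
    stop_socfix("full configuration space has 2^", N, " states; cap is 2^",
                max_size, " (raise max_size at your own risk)")
  nS <- 2L^N
  Pw <- step_matrix(g)
  nbr <- lapply(seq_len(N), function(i) which(g$W[i, ] > 0))
  bits <- function(state) as.logical(bitwAnd(state - 1L, bitwShiftL(1L, 0:(N - 1L))) > 0)
  state_of <- function(xc) sum(bitwShiftL(1L, which(xc) - 1L)) + 1L

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (st in seq_len(nS)) {
    xc <- bits(st)
    nC <- sum(xc)
    if (nC == 0L || nC == N) {
      ii <- c(ii, st); jj <- c(jj, st); xx <- c(xx, 1)
      next
    }
    if (rule == "dB") {
      for (die in seq_len(N)) {
        cmp <- nbr[[die]]
        tc <- xc[cmp]
        if (all(tc) || !any(tc)) {
          p_c_wins <- as.numeric(tc[1L])
        } else {
          dist <- payoff_distribution(g, xc, s, relevant = cmp - 1L)
          p_c_wins <- sum(expected_competition(dist, cmp - 1L, m)[tc])
        }
        for (type_c in c(TRUE, FALSE)) {
          p <- if (type_c) p_c_wins else 1 - p_c_wins
          if (p <= 0) next
          y <- xc; y[die] <- type_c
          ii <- c(ii, st); jj <- c(jj, state_of(y)); xx <- c(xx, p / N)
        }
      }
    } else {
      dist <- payoff_distribution(g, xc, s)
      sel <- expected_competition(dist, 0:(N - 1L), m)
      for (i in seq_len(N)) {
        if (sel[i] <= 0) next
        for (j in nbr[[i]]) {
          y <- xc; y[j] <- xc[i]
          ii <- c(ii, st); jj <- c(jj, state_of(y)); xx <- c(xx, sel[i] * Pw[i, j])
        }
      }
    }
  }
  P <- as.matrix(Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nS, nS)))
  labels <- vapply(seq_len(nS),
                   function(st) paste(ifelse(bits(st), "C", "D"), collapse = ""),
                   "")
  new_kernel(P, labels = labels,
             space = list(type = "full", N = N),
             rule = rule, absorbing = c(D = 1L, C = nS))
}

#' Export a kernel as CSV triples
#'
#' Writes the non-zero entries as `(from_state, to_state, probability)`
#' rows using the kernel's state labels.
#'
#' @param k a `transition_kernel`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_kernel_csv <- function(k, file) {
  stopifnot(inherits(k, "transition_kernel"))
  M <- as(as(k$P, "CsparseMatrix"), "TsparseMatrix")
  df <- data.frame(from_state = k$labels[M@i + 1L],
                   to_state = k$labels[M@j + 1L],
                   probability = M@x)
  df <- df[order(M@i, M@j), ]
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
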