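#' Social-goods scheme
#'
#' Describes how producers generate benefits and pay costs:
#'
#' * `"pp"` -- proportional goods: a producer donates `b` to *each* neighbor
#'   at a per-neighbor cost `c`, so total benefit and cost are proportional
#'   to its degree (the classical accumulated donation game).
#' * `"ff"` -- fixed-and-diffuse goods: a producer pays a total cost `c` and
#'   divides a total benefit `b` evenly among its neighbors (neighbor `j`
#'   receives `b * p[i, j]`); payoffs are deterministic.
#' * `"cf"` -- concentrated-and-fixed goods: a producer pays a total cost `c`
#'   and confers the entire benefit `b` on a single randomly chosen neighbor
#'   (drawn with the random-walk probabilities `p[i, j]`); payoffs are a
#'   stochastic function of the configuration.
#'
#' On unweighted graphs the `p[i, j]` rule reduces to "divided up evenly"
#' (ff) and "uniformly chosen neighbor" (cf). The weighted generalization is
#' a package choice; weighted graphs are accepted everywhere but are beyond
#' the setting in which the schemes were originally formulated.
#'
#' @param kind one of `"pp"`, `"ff"`, `"cf"`.
#' @param b benefit produced, `>= 0`.
#' @param c cost paid by a producer, `>= 0`.
#' @return An object of class `goods_scheme`.
#' @export
goods_scheme <- function(kind = c("pp", "ff", "cf"), b, c) {
  kind <- match.arg(kind)
  if (!is.finite(b) || b < 0 || !is.finite(c) || c < 0)
    stop_socfix("benefit b and cost c must be finite and non-negative")
  structure(list(kind = kind, b = b, c = c), class = "goods_scheme")
}

#' @export
print.goods_scheme <- function(x, ...) {
  cat(sprintf("goods_scheme: %s-goods, b = %g, c = %g\n", x$kind, x$b, x$c))
  invisible(x)
}

#' Exponential payoff-to-fecundity map
#'
#' The unique payoff-to-fecundity map satisfying positivity, monotonicity,
#' continuity, payoff scaling by the selection intensity, and invariance of
#' competition under a shared payoff shift: `F(u) = exp(delta * u)` when
#' selection acts on reproduction. When selection acts on survival the same
#' axioms (with monotonicity reversed) give the death-weight
#' `F(u) = exp(-delta * u)`.
#'
#' @param delta selection intensity, `>= 0`; `delta = 0` is neutral drift.
#' @param mode `"reproduction"` (fecundity weight `e^{delta u}`) or
#'   `"survival"` (death weight `e^{-delta u}`).
#' @return An object of class `fecundity_map`.
#' @export
fecundity_map <- function(delta, mode = c("reproduction", "survival")) {
  mode <- match.arg(mode)
  if (length(delta) != 1L || !is.finite(delta) || delta < 0)
    stop_socfix("selection intensity delta must be a single finite number >= 0")
  structure(list(delta = delta, mode = mode), class = "fecundity_map")
}

#' @export
print.fecundity_map <- function(x, ...) {
  cat(sprintf("fecundity_map: delta = %g, selection on %s\n", x$delta, x$mode))
  invisible(x)
}

# sign of the exponent: +delta*u for reproduction, -delta*u for survival
map_sign <- function(m) if (m$mode == "reproduction") 1 else -1

#' Fecundity of a payoff
#'
#' Evaluates the exponential map at one or more payoffs. Note that for
#' competition probabilities the package never uses raw fecundities (which
#' overflow for large `delta * u`); see [competition_probabilities()].
#'
#' @param u numeric payoff(s).
#' @param m a [fecundity_map()].
#' @return positive numeric vector `exp(+/- delta * u)`.
#' @export
fecundity <- function(u, m) {
  stopifnot(inherits(m, "fecundity_map"))
  exp(map_sign(m) * m$delta * u)
}

# ---- trait configurations -------------------------------------------------

# Accepts a character vector of "C"/"D" or a logical vector (TRUE = C);
# returns a logical is-producer vector of length N.
as_traits <- function(x, N) {
  if (is.character(x)) {
    if (!all(x %in% c("C", "D")))
      stop_socfix("trait configuration entries must be \"C\" or \"D\"")
    x <- x == "C"
  }
  if (!is.logical(x))
    stop_socfix("trait configuration must be a character (C/D) or logical vector")
  if (length(x) != N)
    stop_socfix("trait configuration length (", length(x),
                ") does not match graph size (", N, ")")
  x
}

#' Payoff distribution of a trait configuration
#'
#' Computes the (possibly stochastic) payoffs accruing to every individual
#' when the producers in `x` act under scheme `s`. For `pp` and `ff` goods
#' the result is a single deterministic scenario. For `cf` goods every
#' producer independently directs its benefit at one random neighbor, and
#' the scenarios enumerate the joint recipient assignment, with assignments
#' yielding identical payoff vectors merged.
#'
#' The optional `relevant` argument restricts exact enumeration to producers
#' adjacent to the given node set (the only producers whose choices can
#' affect those nodes' payoffs); the remaining producers contribute their
#' expected (diffuse) benefit instead. Payoff coordinates inside `relevant`
#' are then exactly distributed while coordinates outside it carry expected
#' values -- this is the device that keeps exact cf kernels tractable, since
#' a competition only ever reads the competitors' payoffs.
#'
#' @param g a [graph_structure()].
#' @param x trait configuration: character vector of `"C"`/`"D"` or logical
#'   (TRUE = producer) of length `N`.
#' @param s a [goods_scheme()].
#' @param relevant optional integer vector of 0-based node indices whose
#'   payoffs must be exactly distributed (cf goods only).
#' @param max_producers cf enumeration limit: maximum number of producers
#'   with more than one neighbor that may be enumerated exactly
#'   (default 20); beyond it, an error points to the Monte Carlo sampler.
#' @return An object of class `payoff_distribution`: a list with `prob`
#'   (scenario probabilities summing to 1) and `payoffs` (a scenarios-by-N
#'   matrix).
#' @export
payoff_distribution <- function(g, x, s, relevant = NULL, max_producers = 20L) {
  stopifnot(inherits(g, "graph_structure"), inherits(s, "goods_scheme"))
  xc <- as_traits(x, g$N)
  P <- step_matrix(g)
  cost <- switch(s$kind,
    pp = s$c * rowSums(g$W) * xc,
    s$c * xc)

  if (s$kind != "cf") {
    diffuse <- switch(s$kind,
      pp = s$b * drop(crossprod(g$W, xc)),
      ff = s$b * drop(crossprod(P, xc)))
    return(new_payoff_distribution(1, matrix(diffuse - cost, nrow = 1L), s$kind))
  }

  producers <- which(xc)
  if (!is.null(relevant)) {
    rel <- as.integer(relevant) + 1L
    if (any(rel < 1L | rel > g$N))
      stop_socfix("relevant node indices out of range")
    touches <- vapply(producers, function(j) any(g$W[j, rel] > 0), NA)
    enum <- producers[touches]
  } else {
    enum <- producers
  }
  nbrs <- lapply(enum, function(j) which(g$W[j, ] > 0))
  deg1 <- lengths(nbrs) == 1L
  # single-neighbor producers are deterministic: fold into the base payoff
  base <- -cost
  passive <- setdiff(producers, enum)
  if (length(passive))
    base <- base + s$b * drop(crossprod(P[passive, , drop = FALSE],
                                        rep(1, length(passive))))
  for (k in which(deg1)) base[nbrs[[k]][1L]] <- base[nbrs[[k]][1L]] + s$b
  enum <- enum[!deg1]
  nbrs <- nbrs[!deg1]

  if (length(enum) > max_producers)
    stop_socfix(length(enum), " producers with more than one neighbor exceed ",
                "the exact cf enumeration limit (", max_producers, "); use ",
                "simulate_fixation() / mc_fixation() for Monte Carlo estimates")
  if (!length(enum))
    return(new_payoff_distribution(1, matrix(base, nrow = 1L), "cf"))

  choice_idx <- expand.grid(lapply(nbrs, seq_along), KEEP.OUT.ATTRS = FALSE)
  S <- nrow(choice_idx)
  prob <- rep(1, S)
  pay <- matrix(rep(base, each = S), S, g$N)
  for (k in seq_along(enum)) {
    rec <- nbrs[[k]][choice_idx[[k]]]
    prob <- prob * P[enum[k], ][rec]
    pay[cbind(seq_len(S), rec)] <- pay[cbind(seq_len(S), rec)] + s$b
  }
  # merge scenarios with identical payoff vectors
  key <- apply(pay, 1L, paste, collapse = "\r")
  if (anyDuplicated(key)) {
    grp <- match(key, unique(key))
    prob <- as.vector(rowsum(prob, grp))
    pay <- pay[!duplicated(grp), , drop = FALSE]
  }
  new_payoff_distribution(prob, pay, "cf")
}

new_payoff_distribution <- function(prob, payoffs, kind) {
  tot <- sum(prob)
  if (abs(tot - 1) > 1e-12)
    stop_socfix("scenario probabilities sum to ", tot, ", not 1")
  structure(list(prob = prob / tot, payoffs = payoffs, kind = kind),
            class = "payoff_distribution")
}

#' @export
print.payoff_distribution <- function(x, ...) {
  cat(sprintf("payoff_distribution: %s-goods, %d scenario%s over %d individuals\n",
              x$kind, length(x$prob), if (length(x$prob) == 1L) "" else "s",
              ncol(x$payoffs)))
  invisible(x)
}

#' Expected payoffs of a distribution
#'
#' Probability-weighted mean payoff vector. For cf goods this equals,
#' exactly and for every configuration, the deterministic ff payoff vector
#' with the same `b` and `c` -- the diffuse scheme is the mean field of the
#' concentrated one.
#'
#' @param dist a [payoff_distribution()].
#' @return numeric vector of length `N`.
#' @export
expected_payoffs <- function(dist) {
  drop(crossprod(dist$payoffs, dist$prob))
}

#' Competition probabilities within a group
#'
#' Probability that each member of a competing group is the one chosen
#' (for reproduction, or for death under survival-mode selection), given
#' fixed payoffs: the softmax `F_i / sum_j F_j` with `F = e^{+/- delta u}`.
#' Computed in shifted-exponent (log-sum-exp) form, so the result is finite
#' for arbitrarily large `delta * |u|` and invariant (to machine precision)
#' under adding a constant to all payoffs.
#'
#' @param payoffs numeric payoffs of the competing group members.
#' @param m a [fecundity_map()].
#' @return probability vector of the same length, summing to 1.
#' @export
competition_probabilities <- function(payoffs, m) {
  stopifnot(inherits(m, "fecundity_map"))
  if (!length(payoffs)) stop_socfix("competition group must be non-empty")
  lw <- map_sign(m) * m$delta * payoffs
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Expected competition probabilities under stochastic payoffs
#'
#' Expectation over payoff scenarios of the within-group competition
#' probabilities: `sum_s prob(s) * softmax(payoffs_s[group])`. This is the
#' expectation of the ratio -- never the ratio of expected fecundities --
#' which is what distinguishes cf dynamics from their mean-field ff
#' analogue outside of weak selection.
#'
#' @param dist a [payoff_distribution()].
#' @param group integer vector of 0-based node indices competing.
#' @param m a [fecundity_map()].
#' @return probability vector over `group`, summing to 1.
#' @export
expected_competition <- function(dist, group, m) {
  stopifnot(inherits(dist, "payoff_distribution"), inherits(m, "fecundity_map"))
  if (!length(group)) stop_socfix("competition group must be non-empty")
  idx <- as.integer(group) + 1L
  if (any(idx < 1L | idx > ncol(dist$payoffs)))
    stop_socfix("group indices out of range")
  lw <- map_sign(m) * m$delta * dist$payoffs[, idx, drop = FALSE]
  drop(crossprod(softmax_rows(lw), dist$prob))
}
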