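# Selection-condition classification, delta sweeps, and peak detection.

#' Evaluate the four selection conditions at one intensity
#'
#' Classifies whether selection of intensity `delta` favors producers by
#' four strict criteria:
#'
#' * `A0`: `rho_C(delta) > rho_C(0)` -- absolutely, against neutral drift;
#' * `Aprime`: `rho_C'(delta) > 0` -- absolutely, against intensity `delta`;
#' * `R0`: `rho_C(delta) > rho_D(delta)` -- relative to non-producers,
#'   against neutral drift (equivalently, the rare-mutation process spends
#'   more than half its time in the all-producer state);
#' * `Rprime`: `rho_C'(delta) rho_D(delta) > rho_C(delta) rho_D'(delta)` --
#'   relative, against `delta` (equivalently,
#'   `(rho_C / (rho_C + rho_D))' > 0`).
#'
#' Derivatives are central finite differences with the recorded step
#' (one-sided forward at `delta = 0`). The strict comparisons use zero
#' tolerance; raw margins are returned so callers can apply their own.
#'
#' @param model a [social_model()].
#' @param delta selection intensity, `>= 0`.
#' @param fd_step finite-difference step; default
#'   `max(1e-4, 1e-3 * delta)`. Must be `< delta` when `delta > 0`.
#' @return one-row `data.frame`: `delta`, the four logical conditions,
#'   `rho_C`, `rho_D`, `drho_C`, `drho_D`, `fd_step`, and the raw margins
#'   `margin_A0`, `margin_R0`, `margin_Rprime`.
#' @export
evaluate_conditions <- function(model, delta, fd_step = NULL) {
  stopifnot(inherits(model, "social_model"), delta >= 0)
  if (is.null(fd_step)) fd_step <- max(1e-4, 1e-3 * delta)
  if (fd_step <= 0) stop_socfix("fd_step must be > 0")
  if (delta > 0 && fd_step >= delta)
    stop_socfix("fd_step = ", fd_step, " crosses zero at delta = ", delta,
                "; choose fd_step < delta")
  ctx <- build_context(model)
  f <- function(d) context_fixation(ctx, d, "kernel")
  r0 <- f(0)
  rd <- f(delta)
  rp <- f(delta + fd_step)
  if (delta > 0) {
    rm_ <- f(delta - fd_step)
    drho_C <- (rp$rho_C - rm_$rho_C) / (2 * fd_step)
    drho_D <- (rp$rho_D - rm_$rho_D) / (2 * fd_step)
  } else {
    drho_C <- (rp$rho_C - rd$rho_C) / fd_step
    drho_D <- (rp$rho_D - rd$rho_D) / fd_step
  }
  # at delta = 0 the two traits follow identical processes, so the strict
  # comparisons behind A0 and R0 are equalities by symmetry; forcing them
  # avoids reading round-off dust as a verdict
  data.frame(delta = delta,
             A0 = delta > 0 && rd$rho_C > r0$rho_C,
             Aprime = drho_C > 0,
             R0 = delta > 0 && rd$rho_C > rd$rho_D,
             Rprime = drho_C * rd$rho_D > rd$rho_C * drho_D,
             rho_C = rd$rho_C, rho_D = rd$rho_D,
             drho_C = drho_C, drho_D = drho_D, fd_step = fd_step,
             margin_A0 = rd$rho_C - r0$rho_C,
             margin_R0 = rd$rho_C - rd$rho_D,
             margin_Rprime = drho_C * rd$rho_D - rd$rho_C * drho_D)
}

#' Default selection-intensity grid
#'
#' Log-spaced grids resolving the features seen in practice: 200 points on
#' `[1e-3, 10]` for populations up to a few dozen; 400 points on
#' `[1e-4, 5]` for large stars, dense enough to separate the two fixation
#' peaks of big populations.
#'
#' @param model a [social_model()].
#' @return increasing numeric vector of `delta` values.
#' @export
default_delta_grid <- function(model) {
  if (model$N > 200) {
    exp(seq(log(1e-4), log(5), length.out = 400L))
  } else {
    exp(seq(log(1e-3), log(10), length.out = 200L))
  }
}

#' Sweep mean fixation probabilities over selection intensities
#'
#' Computes the mean producer and non-producer fixation probabilities of a
#' model on a grid of selection intensities, together with the ratio to the
#' neutral value and the fraction of time spent in the all-producer state,
#' and detects local maxima of `rho_C`.
#'
#' With the closed-form engine (large-star ff sweeps) only the producer
#' side is available: `rho_D` and `time_in_C` are `NA`, and refined maxima
#' are grid-independent because the refinement optimizes the closed form
#' directly.
#'
#' @param model a [social_model()].
#' @param deltas strictly increasing grid of intensities `>= 0`;
#'   default [default_delta_grid()].
#' @param refine refine detected maxima between their bracketing grid
#'   neighbors (golden-section search on the engine's value function).
#' @param engine passed to the fixation engine; `"auto"` picks the closed
#'   form for large star-ff models.
#' @return A `sweep_result`: a `data.frame` with columns `delta`, `rho_C`,
#'   `rho_D`, `ratio_to_neutral`, `time_in_C`, plus attributes
#'   `neutral_rho_C`, `maxima` (a `data.frame` from [find_local_maxima()])
#'   and `model`.
#' @export
delta_sweep <- function(model, deltas = NULL, refine = TRUE,
                        engine = c("auto", "kernel", "closed_form")) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "social_model"))
  if (is.null(deltas)) deltas <- default_delta_grid(model)
  if (length(deltas) < 1L || any(deltas < 0) || any(diff(deltas) <= 0))
    stop_socfix("deltas must be a strictly increasing grid of values >= 0")
  ctx <- build_context(model)
  if (engine == "auto")
    engine <- if (ctx$closed_form_default) "closed_form" else "kernel"

  if (engine == "closed_form") {
    if (!ctx$closed_form_available)
      stop_socfix("closed-form engine exists only for ff-goods on the star ",
                  "under Bd updating")
    rho_C <- closed_form_mean_rho_C(ctx$model, deltas)
    rho_D <- rep(NA_real_, length(deltas))
    neutral <- closed_form_mean_rho_C(ctx$model, 0)
    value_fun <- function(d) closed_form_mean_rho_C(ctx$model, d)
  } else {
    res <- lapply(deltas, function(d) context_fixation(ctx, d, "kernel"))
    rho_C <- vapply(res, `[[`, 0, "rho_C")
    rho_D <- vapply(res, `[[`, 0, "rho_D")
    neutral <- context_fixation(ctx, 0, "kernel")$rho_C
    value_fun <- function(d) context_fixation(ctx, d, "kernel")$rho_C
  }
  sr <- data.frame(delta = deltas, rho_C = rho_C, rho_D = rho_D,
                   ratio_to_neutral = rho_C / neutral,
                   time_in_C = rho_C / (rho_C + rho_D))
  attr(sr, "neutral_rho_C") <- neutral
  attr(sr, "value_fun") <- value_fun
  attr(sr, "model") <- model
  class(sr) <- c("sweep_result", "data.frame")
  attr(sr, "maxima") <- find_local_maxima(sr, refine = refine)
  sr
}

#' Local maxima of a swept quantity
#'
#' Interior grid points strictly greater than both neighbors; runs of
#' values equal within a plateau tolerance of `1e-14` are merged and count
#' as (at most) one maximum. Grid endpoints are never reported. With
#' `refine = TRUE` each maximum is polished by golden-section search
#' between its bracketing grid neighbors using the sweep's value function,
#' making the location grid-independent.
#'
#' @param x a `sweep_result` (maxima of `rho_C` over `delta`) or a numeric
#'   vector of values.
#' @param ... further arguments passed to methods.
#' @return `data.frame` with columns `delta`, `value`, `refined`.
#' @export
find_local_maxima <- function(x, ...) UseMethod("find_local_maxima")

#' @rdname find_local_maxima
#' @param refine polish maxima by golden-section search (needs `f` or a
#'   sweep value function).
#' @param grid x-coordinates of the values (defaults to indices).
#' @param f optional function evaluated during refinement.
#' @export
find_local_maxima.numeric <- function(x, grid = seq_along(x), refine = FALSE,
                                      f = NULL, ...) {
  stopifnot(length(x) == length(grid))
  if (length(x) < 3L)
    return(data.frame(delta = numeric(0), value = numeric(0),
                      refined = logical(0)))
  # merge plateau runs (ties within 1e-14) into single representatives
  run <- cumsum(c(TRUE, abs(diff(x)) > 1e-14))
  rep_idx <- vapply(split(seq_along(x), run), function(ix)
    ix[ceiling(length(ix) / 2)], 0L)
  v <- x[rep_idx]
  L <- length(v)
  peaks <- integer(0)
  if (L >= 3L)
    peaks <- which(v[2:(L - 1)] > v[1:(L - 2)] & v[2:(L - 1)] > v[3:L]) + 1L
  out <- data.frame(delta = grid[rep_idx[peaks]], value = v[peaks],
                    refined = rep(FALSE, length(peaks)))
  if (refine && !is.null(f) && nrow(out)) {
    for (r in seq_len(nrow(out))) {
      p <- rep_idx[peaks[r]]
      lo <- grid[max(1L, p - 1L)]
      hi <- grid[min(length(grid), p + 1L)]
      opt <- stats::optimize(function(d) as.numeric(f(d)),
                             interval = c(lo, hi), maximum = TRUE,
                             tol = .Machine$double.eps^0.5)
      if (opt$objective >= out$value[r]) {
        out$delta[r] <- opt$maximum
        out$value[r] <- opt$objective
      }
      out$refined[r] <- TRUE
    }
  }
  rownames(out) <- NULL
  out
}

#' @rdname find_local_maxima
#' @export
find_local_maxima.sweep_result <- function(x, refine = TRUE, ...) {
  find_local_maxima(x$rho_C, grid = x$delta, refine = refine,
                    f = attr(x, "value_fun"))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d deltas on [%g, %g], neutral rho_C = %g\n",
              nrow(x), min(x$delta), max(x$delta), attr(x, "neutral_rho_C")))
  mx <- attr(x, "maxima")
  if (!is.null(mx) && nrow(mx))
    cat(sprintf("  %d local maximum(a) of rho_C; global peak %g at delta = %g\n",
                nrow(mx), max(mx$value), mx$delta[which.max(mx$value)]))
  NextMethod()
}

# ---- result export --------------------------------------------------------

#' Export sweep and condition tables
#'
#' `write_sweep_csv()` writes the sweep table with its model descriptors;
#' `write_conditions_csv()` writes a table of condition reports;
#' `write_run_meta()` writes a JSON run-metadata record (parameters, seed,
#' package version).
#'
#' @param sr a `sweep_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sweep_csv <- function(sr, file) {
  model <- attr(sr, "model")
  df <- cbind(data.frame(structure = model$structure, N = model$N,
                         rule = model$rule, scheme = model$scheme$kind,
                         init = model$init),
              as.data.frame(sr))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_sweep_csv
#' @param conditions a `data.frame` of [evaluate_conditions()] rows.
#' @export
write_conditions_csv <- function(conditions, file) {
  utils::write.csv(conditions, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_sweep_csv
#' @param model the [social_model()] the run used.
#' @param seed RNG seed recorded for the run (may be `NA`).
#' @param extra named list of additional metadata fields.
#' @export
write_run_meta <- function(file, model, seed = NA, extra = list()) {
  meta <- c(list(
    package = "socfix",
    version = as.character(utils::packageVersion("socfix")),
    structure = model$structure, N = model$N, rule = model$rule,
    scheme = model$scheme$kind, b = model$scheme$b, c = model$scheme$c,
    init = model$init, seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(meta, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
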