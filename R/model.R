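#' Model specification
#'
#' Bundles a population structure, an update rule, a goods scheme, and a
#' mutant-initialization mode into one object that the sweep and condition
#' machinery evaluates across selection intensities.
#'
#' @param structure `"cycle"`, `"star"`, or `"general"` (supply `graph`).
#' @param rule update rule, `"dB"` or `"Bd"`.
#' @param scheme a [goods_scheme()].
#' @param N population size for the built-in structures.
#' @param graph a [graph_structure()] for `structure = "general"`.
#' @param init mutant initialization, `"uniform"` or `"temperature"`.
#' @param fecundity_mode `"reproduction"` (the update rules are defined for
#'   selection on reproduction; `"survival"` is available in the
#'   payoff-to-fecundity module only).
#' @return An object of class `social_model`.
#' @examples
#' mod <- social_model("cycle", "dB", goods_scheme("ff", b = 4, c = 1), N = 10)
#' fixation_probs(mod, delta = 0.5)
#' @export
social_model <- function(structure = c("cycle", "star", "general"),
                         rule = c("dB", "Bd"), scheme, N = NULL, graph = NULL,
                         init = c("uniform", "temperature"),
                         fecundity_mode = "reproduction") {
  structure_ <- match.arg(structure)
  rule <- match.arg(rule)
  init <- match.arg(init)
  stopifnot(inherits(scheme, "goods_scheme"))
  if (structure_ == "general") {
    if (is.null(graph)) stop_socfix("structure = \"general\" needs a graph")
    stopifnot(inherits(graph, "graph_structure"))
    N <- graph$N
  } else {
    if (is.null(N)) stop_socfix("built-in structures need a population size N")
    N <- check_size(N)
  }
  structure(list(structure = structure_, rule = rule, scheme = scheme,
                 N = N, graph = graph, init = init,
                 fecundity_mode = fecundity_mode),
            class = "social_model")
}

#' @export
print.social_model <- function(x, ...) {
  cat(sprintf("social_model: %s (N = %d), %s updating, %s-goods b = %g c = %g, %s init\n",
              x$structure, x$N, x$rule, x$scheme$kind, x$scheme$b, x$scheme$c,
              x$init))
  invisible(x)
}

model_graph <- function(model) {
  switch(model$structure,
         cycle = make_cycle(model$N),
         star = make_star(model$N),
         general = model$graph)
}

# Everything about a model that does not depend on delta, built once per
# sweep: the graph and, where initialization itself is delta-free, the
# node-level mutant-appearance masses.
build_context <- function(model) {
  ctx <- list(model = model)
  closed_ok <- model$structure == "star" && model$rule == "Bd" &&
    model$scheme$kind == "ff"
  ctx$closed_form_default <- closed_ok && model$N > 200
  ctx$closed_form_available <- closed_ok
  if (!ctx$closed_form_default) ctx$graph <- model_graph(model)
  ctx
}

# initialization for a given delta (temperature init depends on delta
# through the all-C death rates; the all-D rates, hence mu_C, do not when
# payoffs vanish in the all-D state, but we recompute generically)
context_init <- function(ctx, m) {
  model <- ctx$model
  initialization(ctx$graph, model$rule, model$scheme, m, model$init)
}

# closed-form engine: mean producer fixation probability on the large star.
# Under uniform init the hub start carries mass 1/N; under temperature init
# the all-D state has flat payoffs, so replacement rates are the neutral
# ones for every delta: hub (N-1)/N, each leaf 1/(N(N-1)).
closed_form_mean_rho_C <- function(model, delta) {
  N <- model$N
  v <- closed_form_star_ff(N, model$scheme$b, model$scheme$c, delta)
  w_hub <- if (model$init == "uniform") 1 / N else (N - 1) / N
  unname(w_hub * v[, "hub"] + (1 - w_hub) * v[, "leaf"])
}

#' Mean fixation probabilities of a model at one selection intensity
#'
#' Builds the appropriate exact chain (reduced cycle chain for cycle + dB,
#' reduced star chain for star + Bd, brute-force configuration chain
#' otherwise), solves it, and averages over the model's initialization
#' distribution. For ff-goods on large stars (`N > 200`) under Bd the
#' closed-form expressions are used by default; they return the producer
#' side only (`rho_D = NA`), since the explicit formulas cover single-C
#' starts -- force `engine = "kernel"` for both traits.
#'
#' @param model a [social_model()].
#' @param delta selection intensity, `>= 0`.
#' @param engine `"auto"`, `"kernel"`, or `"closed_form"`.
#' @return list with `rho_C`, `rho_D` (mean fixation probabilities),
#'   `engine`, and `delta`.
#' @export
fixation_probs <- function(model, delta, engine = c("auto", "kernel", "closed_form")) {
  engine <- match.arg(engine)
  ctx <- build_context(model)
  if (engine == "auto")
    engine <- if (ctx$closed_form_default) "closed_form" else "kernel"
  context_fixation(ctx, delta, engine)
}

context_fixation <- function(ctx, delta, engine) {
  model <- ctx$model
  if (engine == "closed_form") {
    if (!ctx$closed_form_available)
      stop_socfix("closed-form expressions exist only for ff-goods on the ",
                  "star under Bd updating")
    return(list(rho_C = unname(closed_form_mean_rho_C(model, delta)),
                rho_D = NA_real_, engine = "closed_form", delta = delta))
  }
  if (is.null(ctx$graph)) ctx$graph <- model_graph(model)
  m <- fecundity_map(delta, model$fecundity_mode)
  k <- if (model$structure == "cycle" && model$rule == "dB") {
    kernel_cycle_db(model$N, model$scheme, m)
  } else if (model$structure == "star" && model$rule == "Bd") {
    kernel_star_bd(model$N, model$scheme, m)
  } else {
    kernel_full(ctx$graph, model$rule, model$scheme, m)
  }
  fr <- solve_fixation(k)
  mf <- mean_fixation(fr, context_init(ctx, m))
  list(rho_C = unname(mf["mean_rho_C"]), rho_D = unname(mf["mean_rho_D"]),
       engine = "kernel", delta = delta)
}
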