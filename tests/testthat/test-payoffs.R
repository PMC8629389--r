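test_that("ff payoffs on the cycle match the boundary bookkeeping", {
  N <- 10
  g <- make_cycle(N)
  s <- goods_scheme("ff", b = 4, c = 1)
  # producers at nodes 0..4, non-producers at 5..9
  x <- c(rep(TRUE, 5), rep(FALSE, 5))
  u <- payoff_distribution(g, x, s)$payoffs[1, ]
  # a producer flanked by two producers earns b - c
  expect_equal(u[2], s$b - s$c)
  # a non-producer adjacent to exactly one producer earns b/2
  expect_equal(u[6], s$b / 2)
  # a non-producer with no producing neighbors earns 0
  expect_equal(u[8], 0)
})

test_that("the all-D configuration yields a single zero-payoff scenario", {
  g <- make_star(6)
  for (kind in c("pp", "ff", "cf")) {
    d <- payoff_distribution(g, rep(FALSE, 6), goods_scheme(kind, 3, 1))
    expect_length(d$prob, 1)
    expect_equal(d$payoffs[1, ], rep(0, 6))
  }
})

test_that("cf goods enumerate recipient scenarios exactly", {
  g <- make_star(4)
  d <- payoff_distribution(g, c(TRUE, FALSE, FALSE, FALSE),
                           goods_scheme("cf", b = 5, c = 1))
  expect_equal(d$prob, rep(1 / 3, 3))
  expect_equal(d$payoffs[, 1], rep(-1, 3))             # hub always pays c
  expect_equal(sort(colSums(d$payoffs[, -1])), c(5, 5, 5))  # each leaf hit once
  expect_true(all(apply(d$payoffs[, -1], 1, function(r) sum(r == 5)) == 1))
})

test_that("cf scenario probabilities sum to one and respect the degree bound", {
  set.seed(7)
  for (r in 1:8) {
    g <- random_connected_graph(sample(4:8, 1))
    x <- stats::runif(g$N) < 0.5
    d <- payoff_distribution(g, x, goods_scheme("cf", 3, 1))
    expect_lt(abs(sum(d$prob) - 1), 1e-12)
    bound <- prod(pmax(1, rowSums(g$W > 0)[x]))
    expect_lte(length(d$prob), bound)
  }
})

test_that("cf expected payoffs equal ff payoffs on every graph (mean-field identity)", {
  set.seed(11)
  for (r in 1:10) {
    g <- random_connected_graph(sample(4:8, 1))
    x <- stats::runif(g$N) < 0.5
    cf <- payoff_distribution(g, x, goods_scheme("cf", 3, 1))
    ff <- payoff_distribution(g, x, goods_scheme("ff", 3, 1))
    expect_equal(expected_payoffs(cf), ff$payoffs[1, ], tolerance = 1e-12)
  }
})

test_that("cf enumeration beyond the producer cap errors toward Monte Carlo", {
  g <- make_cycle(12)
  expect_error(
    payoff_distribution(g, rep(TRUE, 12) & c(rep(TRUE, 11), FALSE),
                        goods_scheme("cf", 1, 1), max_producers = 4),
    "Monte Carlo")
})

test_that("the exponential map behaves as specified", {
  expect_equal(fecundity(0, fecundity_map(3)), 1)
  expect_equal(fecundity(17, fecundity_map(0)), 1)
  expect_equal(fecundity(2, fecundity_map(0.5)), exp(1))
  # survival mode is a death weight with the opposite exponent sign
  expect_equal(fecundity(2, fecundity_map(0.5, "survival")), exp(-1))
  expect_error(fecundity_map(-1), "delta")
})

test_that("competition probabilities are a shifted softmax", {
  m <- fecundity_map(1)
  expect_equal(competition_probabilities(c(3, 3, 3, 3), m), rep(0.25, 4))
  # two competitors with delta * (u1 - u2) = log 3 split 3:1
  expect_equal(competition_probabilities(c(log(3), 0), m), c(0.75, 0.25))
  expect_error(competition_probabilities(numeric(0), m), "non-empty")
  # survival mode favors the lower payoff
  p <- competition_probabilities(c(1, 0), fecundity_map(2, "survival"))
  expect_lt(p[1], p[2])
})

test_that("competition is shift-invariant, stochastic, monotone, and overflow-free", {
  set.seed(23)
  for (r in 1:20) {
    n <- sample(2:6, 1)
    u <- stats::rnorm(n, sd = 5)
    m <- fecundity_map(stats::runif(1, 0, 5))
    p <- competition_probabilities(u, m)
    expect_lt(abs(sum(p) - 1), 1e-12)
    K <- stats::rnorm(1, sd = 100)
    expect_lt(max(abs(p - competition_probabilities(u + K, m))), 1e-12)
    # raising one payoff never lowers its own share
    i <- sample(n, 1)
    u2 <- u; u2[i] <- u2[i] + abs(stats::rnorm(1))
    expect_gte(competition_probabilities(u2, m)[i], p[i])
  }
  # log-domain contract: delta * |u| up to 1e4
  p <- competition_probabilities(c(5000, -5000), fecundity_map(2))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1)
})

test_that("expected competition is the expectation of the ratio", {
  g <- make_cycle(6)
  m <- fecundity_map(0.8)
  x <- single_C(6)
  ff <- payoff_distribution(g, x, goods_scheme("ff", 4, 1))
  expect_equal(expected_competition(ff, 0:5, m),
               competition_probabilities(ff$payoffs[1, ], m))
  # neutral drift: uniform regardless of scenarios
  cf <- payoff_distribution(g, c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                            goods_scheme("cf", 4, 1))
  expect_equal(expected_competition(cf, 0:5, fecundity_map(0)), rep(1 / 6, 6))
  # hand-built two-scenario distribution: mean of the two softmax vectors
  d2 <- structure(list(prob = c(0.5, 0.5),
                       payoffs = rbind(c(4, 3), c(0, 3)), kind = "cf"),
                  class = "payoff_distribution")
  expect_equal(expected_competition(d2, 0:1, m),
               0.5 * competition_probabilities(c(4, 3), m) +
               0.5 * competition_probabilities(c(0, 3), m))
  # and it differs from the softmax of the expected payoffs at delta > 0
  expect_gt(max(abs(expected_competition(d2, 0:1, m) -
                    competition_probabilities(c(2, 3), m))), 1e-3)
})
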