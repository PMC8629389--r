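test_that("neutral drift on the cycle is a symmetric gambler's ruin", {
  s <- goods_scheme("ff", 4, 1)
  for (N in c(5, 10, 17)) {
    fr <- solve_fixation(kernel_cycle_db(N, s, fecundity_map(0)))
    expect_equal(unname(fr$rho_C[paste0("n=", 1)]), 1 / N, tolerance = 1e-12)
    # from a cluster of n, the neutral fixation probability is n/N
    expect_equal(unname(fr$rho_C), (0:N) / N, tolerance = 1e-12)
  }
})

test_that("fixation results satisfy the boundary and complement identities", {
  set.seed(13)
  g <- random_connected_graph(5)
  for (rule in c("dB", "Bd")) {
    k <- kernel_full(g, rule, goods_scheme("cf", 3, 1), fecundity_map(1.2))
    fr <- solve_fixation(k)
    expect_equal(unname(fr$rho_C[k$absorbing["C"]]), 1)
    expect_equal(unname(fr$rho_C[k$absorbing["D"]]), 0)
    expect_equal(fr$rho_D, 1 - fr$rho_C)
    expect_true(all(fr$rho_C >= 0 & fr$rho_C <= 1))
    expect_lt(fr$residual, 1e-10)
  }
})

test_that("replacement rates follow the update rule", {
  g <- make_star(10)
  s <- goods_scheme("ff", 5, 1)
  # dB: uniform replacement regardless of structure or intensity
  expect_equal(death_rates(g, "dB", "D", s, fecundity_map(7)), rep(0.1, 10))
  # Bd, all-D state: flat payoffs, so the hub is replaced whenever a leaf
  # reproduces: 1 - 1/N, independent of delta
  for (d in c(0, 1, 12)) {
    dd <- death_rates(g, "Bd", "D", s, fecundity_map(d))
    expect_equal(dd[1], 1 - 1 / 10, tolerance = 1e-12)
    expect_equal(sum(dd), 1, tolerance = 1e-12)
  }
  # Bd, all-C state: under strong selection the hub all but monopolizes
  # reproduction, so total leaf replacement approaches 1
  expect_gt(sum(death_rates(g, "Bd", "C", s, fecundity_map(20))[-1]), 0.999)
})

test_that("initialization distributions place mutants as specified", {
  g <- make_star(10)
  s <- goods_scheme("ff", 5, 1)
  m <- fecundity_map(1)
  unif <- initialization(g, "Bd", s, m, "uniform")
  expect_equal(unif$mu_C, rep(0.1, 10))
  expect_equal(sum(unif$mu_C[-1]), 0.9)   # leaf starts aggregate to 9/10
  temp <- initialization(g, "Bd", s, m, "temperature")
  expect_equal(temp$mu_C[1], 0.9, tolerance = 1e-12)  # mutant C at the hub
  expect_lt(abs(sum(temp$mu_C) - 1), 1e-12)
  expect_lt(abs(sum(temp$mu_D) - 1), 1e-12)
  # under dB, temperature and uniform coincide on any structure
  g2 <- random_connected_graph(6)
  t2 <- initialization(g2, "dB", s, m, "temperature")
  expect_equal(t2$mu_C, rep(1 / 6, 6))
  expect_equal(t2$mu_D, rep(1 / 6, 6))
})

test_that("mean fixation averages over single-mutant states", {
  s <- goods_scheme("ff", 5, 1)
  m <- fecundity_map(0.8)
  N <- 12
  fr <- solve_fixation(kernel_star_bd(N, s, m))
  init <- initialization(make_star(N), "Bd", s, m, "temperature")
  mf <- mean_fixation(fr, init)
  manual <- (N - 1) / N * fr$rho_C[["(1,0)"]] + 1 / N * fr$rho_C[["(0,1)"]]
  expect_equal(unname(mf["mean_rho_C"]), manual, tolerance = 1e-12)
  expect_true(all(mf >= 0 & mf <= 1))
  # dimension mismatch is an error
  bad <- initialization(make_star(5), "Bd", s, m, "uniform")
  expect_error(mean_fixation(fr, bad), "nodes")
})

test_that("closed-form star expressions match the linear-solve oracle", {
  for (N in c(5, 10, 25)) for (d in c(0.1, 1, 3)) {
    fr <- solve_fixation(kernel_star_bd(N, goods_scheme("ff", 5, 1),
                                        fecundity_map(d)))
    v <- closed_form_star_ff(N, 5, 1, d)
    expect_equal(unname(v[1, "hub"]), unname(fr$rho_C[["(1,0)"]]), tolerance = 1e-9)
    expect_equal(unname(v[1, "leaf"]), unname(fr$rho_C[["(0,1)"]]), tolerance = 1e-9)
  }
  # neutral limit agrees with the solve at delta = 0
  fr0 <- solve_fixation(kernel_star_bd(10, goods_scheme("ff", 5, 1),
                                       fecundity_map(0)))
  v0 <- closed_form_star_ff(10, 5, 1, 0)
  expect_equal(unname(v0[1, "hub"]), unname(fr0$rho_C[["(1,0)"]]), tolerance = 1e-12)
  expect_equal(unname(v0[1, "leaf"]), unname(fr0$rho_C[["(0,1)"]]), tolerance = 1e-12)
})

test_that("closed form stays finite at extreme sizes and intensities", {
  v <- closed_form_star_ff(5000, 5, 1, c(0, 1e-3, 10, 50))
  expect_true(all(is.finite(v)))
  expect_true(all(v >= 0 & v <= 1))
  # producer fixation decays to zero as the benefit grows without bound
  bs <- c(20, 50, 100, 500, 1000)
  rho <- vapply(bs, function(b) {
    vv <- closed_form_star_ff(50, b, 1, 1)
    (49 * vv[1, "hub"] + vv[1, "leaf"]) / 50
  }, 0)
  expect_true(all(diff(rho) < 0))
  expect_lt(rho[length(rho)], 1e-10)
})

test_that("hub-start two-mutant transitions beat leaf-start ones (Bernoulli ordering)", {
  set.seed(41)
  for (r in 1:10) {
    N <- sample(4:30, 1)
    b <- stats::runif(1, 0.5, 8)
    d <- stats::runif(1, 0.05, 4)
    expect_gt(exp(d * b) - 1, (N - 1) * (exp(d * b / (N - 1)) - 1))
    # the same ordering read off the exact chain
    k <- kernel_star_bd(N, goods_scheme("ff", b, 1), fecundity_map(d))
    P <- as.matrix(k$P)
    hub <- P[which(k$labels == "(1,0)"), which(k$labels == "(1,1)")]
    leaf <- P[which(k$labels == "(0,1)"), which(k$labels == "(1,1)")]
    expect_lt(leaf, hub)
  }
})

test_that("stochastic and diffuse goods coincide to second order in weak selection", {
  for (struct in list(c("cycle", "dB"), c("star", "Bd"))) {
    deltas <- c(0.04, 0.02, 0.01, 0.005)
    mc_ <- social_model(struct[1], struct[2], goods_scheme("cf", 4, 1), N = 6)
    mf_ <- social_model(struct[1], struct[2], goods_scheme("ff", 4, 1), N = 6)
    ratio <- vapply(deltas, function(d)
      abs(fixation_probs(mc_, d)$rho_C - fixation_probs(mf_, d)$rho_C) / d^2, 0)
    # |rho_cf - rho_ff| = O(delta^2): the ratio must not blow up as delta -> 0
    expect_lt(max(ratio[-1]), 10 * (ratio[1] + 1e-6))
  }
})
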