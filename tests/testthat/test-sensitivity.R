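test_that("Beta fits from CIs use method-of-moments and keep the mean", {
  d <- beta_from_mean_ci(0.886, 0.806, 0.936)
  expect_equal(d$family, "beta")
  expect_equal(d$pars$alpha, 80.48, tolerance = 0.01)
  expect_equal(d$pars$beta, 10.355, tolerance = 0.01)
  expect_equal(d$pars$alpha / (d$pars$alpha + d$pars$beta), 0.886,
               tolerance = 1e-9)
  # degenerate interval collapses to a point mass
  expect_equal(beta_from_mean_ci(0.5, 0.5, 0.5)$family, "point_mass")
  # infeasible variance falls back with a warning
  expect_warning(w <- beta_from_mean_ci(0.02, 0.0001, 0.9), "point mass")
  expect_equal(w$family, "point_mass")
})

test_that("Beta fits from mean/SD handle the infeasible case both ways", {
  d <- beta_from_mean_sd(0.89, 0.11)
  expect_equal(d$pars$alpha + d$pars$beta, 0.89 * 0.11 / 0.11^2 - 1,
               tolerance = 1e-9)
  expect_equal(d$pars$alpha, 6.31, tolerance = 0.01)
  expect_equal(d$pars$beta, 0.78, tolerance = 0.01)
  # sd 0.49 at mean 0.64 exceeds the feasible max (~0.48)
  clamped <- beta_from_mean_sd(0.64, 0.49)
  expect_equal(clamped$family, "beta")
  expect_match(clamped$note, "clamped")
  fixed <- beta_from_mean_sd(0.64, 0.49, infeasible = "point_mass")
  expect_equal(fixed$family, "point_mass")
  expect_equal(beta_from_mean_sd(0.3, 0)$family, "point_mass")
  expect_error(beta_from_mean_sd(1.2, 0.1), "mean")
})

test_that("Gamma fits have the closed-form shape and scale", {
  d <- gamma_from_mean_cv(5644, 0.2)
  expect_equal(d$pars$shape, 25)
  expect_equal(d$pars$scale, 225.76)
  expect_error(gamma_from_mean_cv(-1, 0.2), "mean")
  expect_error(gamma_from_mean_cv(10, 0), "cv")
})

test_that("sampled moments match the fitted distributions", {
  set.seed(99)
  b <- beta_from_mean_ci(0.886, 0.806, 0.936)
  x <- sample_distribution(b, 1e5)
  expect_lt(abs(mean(x) - 0.886), 3 * sd(x) / sqrt(1e5))
  g <- gamma_from_mean_cv(5644, 0.2)
  y <- sample_distribution(g, 1e5)
  expect_lt(abs(mean(y) - 5644), 3 * 5644 * 0.2 / sqrt(1e5))
})

test_that("the tornado covers efficacy CIs, utilities and BSC costs", {
  pars <- owsa_parameters(base_cfg)
  expect_equal(nrow(pars), 2 * 8 + 2 + 4)
  expect_true(all(pars$low <= pars$base & pars$base <= pars$high))
  # controlled utility deliberately unclamped (mechanical +20% exceeds 1)
  expect_gt(pars$high[pars$parameter == "u_controlled"], 1)
  clamped <- owsa_parameters(base_cfg, clamp_utilities = TRUE)
  expect_equal(clamped$high[clamped$parameter == "u_controlled"], 1)
})

test_that("degenerate one-way bounds reproduce the base-case ICUR", {
  pars <- owsa_parameters(base_cfg)[1, ]
  pars$low <- pars$base
  pars$high <- pars$base
  ow <- run_owsa(base_cfg, parameters = pars)
  expect_equal(ow$tornado$icur_low, ow$tornado$icur_high)
  expect_equal(unname(ow$tornado$icur_low),
               unname(ow$base_icur[ow$tornado$strategy]))
})

test_that("degenerate PSA equals the base case exactly", {
  cfg <- base_cfg
  for (nm in names(cfg$drugs)) {
    cfg$drugs[[nm]]$p_induction_ci <- rep(cfg$drugs[[nm]]$p_induction, 2)
    cfg$drugs[[nm]]$p_maintenance_ci <- rep(cfg$drugs[[nm]]$p_maintenance, 2)
  }
  cfg$utilities$sd_uncontrolled <- 0
  cfg$utilities$sd_controlled <- 0
  psa <- run_psa(cfg, n_iterations = 5, seed = 3, bsc_cv = 0)
  arms <- evaluate_all_arms(cfg)
  for (i in seq_len(nrow(psa$means))) {
    a <- arms[[psa$means$strategy[i]]]
    expect_equal(psa$means$mean_cost[i], a$total_cost, tolerance = 1e-9)
    expect_equal(psa$means$mean_qaly[i], a$total_qaly, tolerance = 1e-12)
  }
})

test_that("the PSA is reproducible for a fixed seed and seeds matter", {
  p1 <- run_psa(base_cfg, n_iterations = 300, seed = 11)
  p2 <- run_psa(base_cfg, n_iterations = 300, seed = 11)
  expect_identical(p1$means, p2$means)
  expect_identical(p1$ceac, p2$ceac)
  p3 <- run_psa(base_cfg, n_iterations = 300, seed = 12)
  expect_false(identical(p1$means$mean_cost, p3$means$mean_cost))
  # different seeds agree within Monte-Carlo error (3 SE of the mean)
  for (arm in colnames(p1$draw_cost)) {
    se <- sd(p1$draw_cost[, arm]) / sqrt(300)
    expect_lt(abs(mean(p1$draw_cost[, arm]) - mean(p3$draw_cost[, arm])),
              5 * se + 1e-6)
  }
})

test_that("CEAC columns are winner fractions", {
  psa <- run_psa(base_cfg, n_iterations = 200, seed = 5,
                 wtp_grid = seq(0, 100000, by = 25000))
  shares <- as.matrix(psa$ceac[, -1])
  expect_true(all(abs(rowSums(shares) - 1) < 1e-9))
  expect_true(all(shares >= 0 & shares <= 1))
  # at WTP 0 the winner is simply the cheapest arm of the iteration
  cheapest <- colnames(psa$draw_cost)[max.col(-psa$draw_cost, ties.method = "first")]
  expect_equal(unname(shares[1, "tildrakizumab"]),
               mean(cheapest == "tildrakizumab"))
  one <- run_psa(base_cfg, n_iterations = 1, seed = 9,
                 wtp_grid = c(0, 50000))
  expect_true(all(as.matrix(one$ceac[, -1]) %in% c(0, 1)))
})
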