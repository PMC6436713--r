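sim_cache <- NULL
get_sim <- function() {
  if (is.null(sim_cache)) {
    sim_cache <<- small_sim(n = 500, M = 8, J = 20, seed = 31)
  }
  sim_cache
}

test_that("identical seed and config give bit-identical retained draws", {
  sim <- get_sim()
  cfg <- mcmc_config(n_draws = 60, burnin = 60, seed = 77)
  f1 <- run_mcmc(sim$dataset, sim$adjacency, model_spec("convolution"), cfg)
  f2 <- run_mcmc(sim$dataset, sim$adjacency, model_spec("convolution"), cfg)
  expect_identical(f1$chains, f2$chains)
  f3 <- run_mcmc(sim$dataset, sim$adjacency, model_spec("convolution"),
                 mcmc_config(n_draws = 60, burnin = 60, seed = 78))
  expect_false(identical(f1$chains[[1]]$beta, f3$chains[[1]]$beta))
})

test_that("structural draw invariants hold in every retained draw", {
  sim <- get_sim()
  fit <- run_mcmc(sim$dataset, sim$adjacency, model_spec("convolution"),
                  mcmc_config(n_draws = 150, burnin = 150, seed = 41))
  ch <- fit$chains[[1]]
  expect_equal(nrow(ch$beta), 150)            # retained draws = n_draws
  expect_true(all(ch$g2 > 0))
  expect_true(all(ch$kappa[, 2] > ch$kappa[, 1]))  # cutpoint ordering
  expect_true(all(ch$tau_h > 0 & ch$tau_v > 0 & ch$tau_c > 0))
  expect_equal(rowMeans(ch$phi), rep(0, 150), tolerance = 1e-12)
  acc <- unlist(fit$accept)
  expect_true(all(acc[!is.na(acc)] >= 0 & acc[!is.na(acc)] <= 1))
})

test_that("argument validation rejects inconsistent requests", {
  sim <- get_sim()
  expect_error(run_mcmc(sim$dataset, NULL, model_spec("convolution")),
               "adjacency is required")
  expect_error(run_mcmc(sim$dataset, NULL, model_spec("structured")),
               "adjacency is required")
  expect_warning(run_mcmc(sim$dataset, sim$adjacency, model_spec("none"),
                          mcmc_config(n_draws = 5, burnin = 0)),
                 "ignored")
  ds <- sim$dataset
  ds$X <- cbind(ds$X, flat = rep(1, ds$n))
  expect_error(
    run_mcmc(ds, sim$adjacency, model_spec("convolution")), "flat")
  expect_error(run_mcmc(sim$dataset, sim$adjacency,
                        model_spec("convolution", covariates = "nope")),
               "not in dataset")
})

test_that("posterior concentrates near truth without random effects", {
  set.seed(51)
  n <- 3000
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  beta_true <- c(0.8, -0.5)
  p <- category_probabilities(as.numeric(X %*% beta_true),
                              cutpoint_set(-0.5, 1.5))
  y <- spordinal:::sample_categorical(p)
  ds <- ordinal_dataset(y, X, rep(1:10, length.out = n),
                        rep(1:5, length.out = n), K = 3)
  fit <- run_mcmc(ds, NULL, model_spec("none", facility_effects = FALSE),
                  mcmc_config(n_draws = 600, burnin = 800, seed = 3))
  est <- colMeans(fit$chains[[1]]$beta)
  expect_lt(max(abs(est - beta_true)), 0.1)
  kap <- colMeans(fit$chains[[1]]$kappa)
  expect_lt(max(abs(kap - c(-0.5, 1.0))), 0.12)
})

test_that("prior-only moments are recovered when the likelihood is suppressed", {
  # 1-coefficient toy target with known normal form: N(0, 1/0.001)
  X <- matrix(numeric(0), 0, 1, dimnames = list(NULL, "a"))
  attr(X, "block") <- "b"
  ds <- ordinal_dataset(integer(0), X, integer(0), integer(0), K = 3)
  fit <- run_mcmc(ds, NULL, model_spec("none", facility_effects = FALSE),
                  mcmc_config(n_draws = 4000, burnin = 1000, thinning = 4,
                              seed = 19))
  b <- fit$chains[[1]]$beta[, 1]
  sd_theo <- 1 / sqrt(0.001)
  expect_lt(abs(mean(b)) / (sd_theo / sqrt(200)), 4)  # ESS-deflated z-score
  expect_equal(sd(b), sd_theo, tolerance = 0.12)
})

test_that("DIC components satisfy their defining identities", {
  sim <- get_sim()
  fit <- run_mcmc(sim$dataset, sim$adjacency, model_spec("convolution"),
                  mcmc_config(n_draws = 200, burnin = 300, seed = 61))
  dic <- compute_dic(fit, sim$dataset)
  dev <- fit$chains[[1]]$deviance
  expect_equal(dic$D_bar, mean(dev), tolerance = 1e-12)
  # independent plug-in evaluation at the posterior means
  st <- spordinal:::posterior_mean_state(fit)
  expect_equal(dic$D_at_mean,
               ordinal_deviance(sim$dataset, st, "convolution"),
               tolerance = 1e-12)
  expect_equal(dic$pD, dic$D_bar - dic$D_at_mean, tolerance = 1e-12)
  expect_equal(dic$DIC, dic$D_bar + dic$pD, tolerance = 1e-12)
  expect_gt(dic$D_bar, 0)
  expect_error(compute_dic(fake_draws(matrix(numeric(0), 0, 1,
                                             dimnames = list(NULL, "a"))),
                           sim$dataset), "empty")
})

test_that("stored deviance draws equal the deviance of the stored state", {
  sim <- small_sim(n = 120, M = 4, J = 8, seed = 71)
  fit <- run_mcmc(sim$dataset, sim$adjacency, model_spec("convolution"),
                  mcmc_config(n_draws = 20, burnin = 50, seed = 5))
  ch <- fit$chains[[1]]
  for (i in c(1, 10, 20)) {
    beta <- ch$beta[i, ]
    st <- parameter_state(beta,
                          cutpoint_set(ch$kappa[i, 1], diff(ch$kappa[i, ])),
                          u = ch$u[i, ], f = ch$f[i, ], phi = ch$phi[i, ],
                          tau_h = ch$tau_h[i], tau_v = ch$tau_v[i],
                          tau_c = ch$tau_c[i])
    expect_equal(ch$deviance[i],
                 ordinal_deviance(sim$dataset, st, "convolution"),
                 tolerance = 1e-8)
  }
})

test_that("odds-ratio summaries match draw-wise exponentiation", {
  bm <- cbind(b1 = c(0, 0.2, 0.4))
  s <- summarize_draws(fake_draws(bm), levels = 0.95)
  expect_equal(s$or_median, exp(0.2))
  expect_equal(s$or_mean, mean(exp(c(0, 0.2, 0.4))))
  expect_equal(s$or_sd, sd(exp(c(0, 0.2, 0.4))))
  expect_equal(s$mean_coef, 0.2)
  # symmetric draws around zero straddle OR = 1
  set.seed(9)
  bm2 <- cbind(b1 = rnorm(2000, 0, 0.5))
  s2 <- summarize_draws(fake_draws(bm2), levels = 0.95)
  expect_lt(s2$or_l95, 1)
  expect_gt(s2$or_u95, 1)
  # interval endpoints equal an independent sorting-based quantile
  or <- sort(exp(bm2[, 1]))
  expect_equal(s2$or_l95, quantile(or, 0.025, names = FALSE))
  expect_equal(s2$or_u95, quantile(or, 0.975, names = FALSE))
  expect_error(summarize_draws(fake_draws(bm), parameters = "zz"),
               "unknown parameter")
})

test_that("diagnostics flag unmixed chains and pass iid draws", {
  set.seed(13)
  mk <- function(shift) {
    list(beta = cbind(b1 = rnorm(1000) + shift), g1 = rnorm(1000),
         g2 = matrix(1, 1000, 1), kappa = cbind(rnorm(1000), rnorm(1000) + 2),
         u = matrix(numeric(0), 1000, 0), f = matrix(numeric(0), 1000, 0),
         phi = matrix(numeric(0), 1000, 0),
         tau_h = rgamma(1000, 2, 1), tau_v = rgamma(1000, 2, 1),
         tau_c = rgamma(1000, 2, 1), deviance = rnorm(1000, 100))
  }
  good <- fake_draws(cbind(b1 = rnorm(10)))
  good$chains <- list(mk(0), mk(0))
  good$accept <- list(c(beta_b = 0.3), c(beta_b = 0.3))
  d <- mcmc_diagnostics(good)
  expect_lt(abs(d$parameters$rhat[d$parameters$parameter == "b1"] - 1), 0.05)
  expect_true(all(d$parameters$converged[!is.na(d$parameters$converged)]))
  bad <- good
  bad$chains <- list(mk(0), mk(50))  # disjoint supports
  db <- mcmc_diagnostics(bad)
  expect_gt(db$parameters$rhat[db$parameters$parameter == "b1"], 2)
  expect_false(db$parameters$converged[db$parameters$parameter == "b1"])
  single <- good
  single$chains <- good$chains[1]
  single$accept <- good$accept[1]
  expect_warning(ds <- mcmc_diagnostics(single), "single chain")
  expect_true(all(is.na(ds$parameters$rhat)))
})

test_that("thinning lowers the lag-1 autocorrelation of retained draws", {
  sim <- small_sim(n = 250, M = 5, J = 10, seed = 81)
  f1 <- run_mcmc(sim$dataset, sim$adjacency, model_spec("convolution"),
                 mcmc_config(n_draws = 300, burnin = 300, thinning = 1,
                             seed = 7))
  f5 <- run_mcmc(sim$dataset, sim$adjacency, model_spec("convolution"),
                 mcmc_config(n_draws = 300, burnin = 300, thinning = 5,
                             seed = 7))
  ac <- function(x) cor(x[-1], x[-length(x)])
  a1 <- mean(sapply(1:3, function(j) ac(f1$chains[[1]]$beta[, j])))
  a5 <- mean(sapply(1:3, function(j) ac(f5$chains[[1]]$beta[, j])))
  expect_lt(a5, a1)
})

test_that("draws persist as CSV arrays with a JSON manifest", {
  sim <- small_sim(n = 120, M = 4, J = 8, seed = 91)
  fit <- run_mcmc(sim$dataset, sim$adjacency, model_spec("convolution"),
                  mcmc_config(n_draws = 25, burnin = 25, seed = 2))
  dir <- file.path(tempdir(), "drawstore")
  write_posterior_draws(fit, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_draws, 25)
  expect_equal(man$structure, "convolution")
  beta_back <- utils::read.csv(file.path(dir, "chain1_beta.csv"))
  expect_equal(as.matrix(beta_back), fit$chains[[1]]$beta,
               ignore_attr = TRUE, tolerance = 1e-12)
})
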