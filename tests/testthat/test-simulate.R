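test_that("null model generates the closed-form category mix", {
  plan <- list(list(name = "x", type = "continuous", level = "patient",
                    block = "b", beta = 0))
  sc <- simulation_config(n_counties = 5, n_facilities = 10,
                          n_patients = 100000, covariates = plan,
                          adjacency_kind = "lattice", seed = 2)
  adj <- generate_adjacency(5, "lattice")
  beta <- c(x = 0); attr(beta, "block") <- "b"
  tr <- truth_record(beta, cutpoint_set(0, log(3)), tau_h = 1, tau_v = 1,
                     tau_c = 1, u = rep(0, 5), f = rep(0, 10), phi = rep(0, 5))
  sim <- generate_dataset(sc, tr, adj)
  freq <- as.numeric(table(sim$dataset$y)) / 100000
  se <- sqrt(c(0.5, 0.25, 0.25) * c(0.5, 0.75, 0.75) / 100000)
  expect_true(all(abs(freq - c(0.5, 0.25, 0.25)) < 3 * se))
  # probabilities behind the draw normalize exactly
  p <- category_probabilities(sim$eta, tr$cutpoints)
  expect_equal(rowSums(p), rep(1, 100000), tolerance = 1e-12)
})

test_that("a very negative first cutpoint empties category 1", {
  plan <- list(list(name = "x", type = "continuous", level = "patient",
                    block = "b", beta = 0))
  sc <- simulation_config(5, 10, 5000, covariates = plan,
                          adjacency_kind = "lattice", seed = 3)
  adj <- generate_adjacency(5, "lattice")
  beta <- c(x = 0); attr(beta, "block") <- "b"
  tr <- truth_record(beta, cutpoint_set(-30, 30 + log(3)), tau_h = 1,
                     tau_v = 1, tau_c = 1, u = rep(0, 5), f = rep(0, 10),
                     phi = rep(0, 5))
  sim <- generate_dataset(sc, tr, adj)
  expect_equal(sum(sim$dataset$y == 1L), 0L)
})

test_that("the study's dimensions are reproduced exactly", {
  sc <- simulation_config()  # defaults are the study conditions
  expect_equal(sc$n_counties, 47L)
  expect_equal(sc$n_facilities, 281L)
  expect_equal(sc$n_patients, 2568L)
  adj <- generate_adjacency(sc$n_counties, sc$adjacency_kind, seed = 7)
  tr <- make_truth(sc, adj)
  sim <- generate_dataset(sc, tr, adj)
  expect_equal(sim$dataset$n, 2568L)
  expect_equal(sim$dataset$n_facilities, 281L)
  expect_equal(sim$dataset$n_counties, 47L)
  # nesting invariants: each facility maps to exactly one county
  expect_true(all(tapply(sim$dataset$county, sim$dataset$facility,
                         function(v) length(unique(v))) == 1L))
})

test_that("generation is a pure function of (config, truth, seed)", {
  sim1 <- small_sim(n = 200, M = 6, J = 12, seed = 9)
  sim2 <- small_sim(n = 200, M = 6, J = 12, seed = 9)
  expect_identical(sim1$dataset, sim2$dataset)
  expect_identical(sim1$eta, sim2$eta)
  sim3 <- small_sim(n = 200, M = 6, J = 12, seed = 10)
  expect_false(identical(sim1$dataset$y, sim3$dataset$y))
})

test_that("truth record enforces its invariants", {
  beta <- c(x = 0.1); attr(beta, "block") <- "b"
  expect_error(truth_record(beta, cutpoint_set(0, 1), tau_h = -1, tau_v = 1,
                            tau_c = 1), "precisions")
  expect_error(truth_record(beta, cutpoint_set(0, 1), 1, 1, 1,
                            phi = c(1, 1)), "sum to zero")
})

test_that("dataset CSV round-trips bit-identically", {
  sim <- small_sim(n = 150, M = 5, J = 10, seed = 13)
  path <- tempfile(fileext = ".csv")
  write_ordinal_csv(sim$dataset, path)
  back <- read_ordinal_csv(path, blocks = attr(sim$dataset$X, "block"))
  expect_identical(back$y, sim$dataset$y)
  expect_identical(back$facility, sim$dataset$facility)
  expect_identical(back$county, sim$dataset$county)
  expect_identical(unname(back$X), unname(sim$dataset$X))
  expect_identical(back$weight, sim$dataset$weight)
  expect_identical(colnames(back$X), colnames(sim$dataset$X))
})

test_that("truth JSON round-trips the generating parameters", {
  sim <- small_sim(n = 120, M = 5, J = 10, seed = 17)
  path <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  tr2 <- read_truth_json(path)
  expect_equal(as.numeric(tr2$beta), as.numeric(sim$truth$beta))
  expect_equal(attr(tr2$beta, "block"), attr(sim$truth$beta, "block"))
  expect_equal(tr2$cutpoints$kappa, sim$truth$cutpoints$kappa)
  expect_equal(tr2$phi, sim$truth$phi)
})

test_that("missing-as-category coding appears at the configured rate", {
  sim <- small_sim(n = 4000, M = 8, J = 24, seed = 19)
  miss_rate <- mean(sim$dataset$X[, "wanted_9"])
  expect_gt(miss_rate, 0.05)
  expect_lt(miss_rate, 0.16)
  # continuous covariates standardized at generation (facility-level values
  # standardized across facilities, then mapped to patients)
  expect_lt(abs(mean(sim$dataset$X[, "unmetneedfp"])), 0.5)
})

test_that("nested effects induce county-level clustering of the latent eta", {
  sim <- small_sim(n = 6000, M = 12, J = 48, seed = 23,
                   tau_h = 4, tau_c = 2)  # sizable county effects
  fit <- aov(sim$eta ~ factor(sim$dataset$county))
  pval <- summary(fit)[[1]][["Pr(>F)"]][1]
  expect_lt(pval, 1e-6)
})

test_that("config validation rejects impossible nesting sizes", {
  expect_error(simulation_config(n_counties = 1), "at least 2")
  expect_error(simulation_config(n_counties = 10, n_facilities = 5),
               "facility per county")
  expect_error(simulation_config(n_counties = 5, n_facilities = 10,
                                 n_patients = 5), "patient per facility")
  beta <- c(x = 0.1); attr(beta, "block") <- "b"
  tr <- truth_record(beta, cutpoint_set(0, 1), 1, 1, 1, u = rep(0, 3),
                     f = rep(0, 5), phi = rep(0, 3))
  sc <- simulation_config(n_counties = 4, n_facilities = 8, n_patients = 50,
                          adjacency_kind = "lattice")
  expect_error(generate_dataset(sc, tr), "inconsistent")
})
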