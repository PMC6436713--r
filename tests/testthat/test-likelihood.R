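test_that("category probabilities match logistic closed forms", {
  cp <- cutpoint_set(0, log(3))
  expect_equal(as.numeric(category_probabilities(0, cp)),
               c(0.5, 0.25, 0.25))
  # large eta pushes all mass to the top category
  expect_equal(as.numeric(category_probabilities(50, cp)), c(0, 0, 1),
               tolerance = 1e-12)
  # independent evaluation of the two logistic CDFs at eta = 1, kappa = (0, 1)
  p <- as.numeric(category_probabilities(1, cutpoint_set(0, 1)))
  expect_equal(p[1], 1 / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(p[2], 0.5 - 1 / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(p[3], 0.5, tolerance = 1e-12)
})

test_that("probability rows normalize and are monotone in eta", {
  set.seed(3)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    cp <- cutpoint_set(rnorm(1), if (K > 2) runif(K - 2, 0.1, 2) else numeric(0))
    eta <- sort(rnorm(50, 0, 3))
    p <- category_probabilities(eta, cp)
    expect_true(all(p > 0 & p < 1))
    expect_equal(rowSums(p), rep(1, 50), tolerance = 1e-12)
    # cumulative P(y > k) nondecreasing in eta for every k
    upper_tail <- 1 - t(apply(p, 1, cumsum))
    for (k in seq_len(K - 1)) {
      expect_true(all(diff(upper_tail[, k]) >= -1e-12))
    }
  }
  expect_error(category_probabilities(0, c(1, 0.5)), "increasing")
})

test_that("linear predictor assembles the active effect terms", {
  st <- parameter_state(c(0.5, -1), cutpoint_set(0, 1), u = 0.1, f = -0.1,
                        phi = 0)
  expect_equal(linear_predictor(c(1, 0), st, 1, 1, "convolution"), 0.5)
  st0 <- parameter_state(c(0, 0), cutpoint_set(0, 1), u = 0, f = 0, phi = 0)
  expect_equal(linear_predictor(c(1, 1), st0, 1, 1, "convolution"), 0)
  # with u = 0, structured and convolution coincide
  stu0 <- parameter_state(c(0.3, 0.2), cutpoint_set(0, 1), u = 0, f = 0.4,
                          phi = -0.7)
  expect_equal(linear_predictor(c(1, 2), stu0, 1, 1, "structured"),
               linear_predictor(c(1, 2), stu0, 1, 1, "convolution"))
  expect_error(linear_predictor(c(1, 0), st, 5, 1, "convolution"),
               "facility index")
  expect_error(linear_predictor(c(1, 0), st, 1, 9, "convolution"),
               "county index")
})

test_that("log-likelihood matches hand values and is additive", {
  ds1 <- ordinal_dataset(1L, matrix(c(1, -1), 1, 2), 1L, 1L, K = 3)
  st <- parameter_state(c(0, 0), cutpoint_set(0, 1), u = 0, f = 0, phi = 0)
  expect_equal(ordinal_log_likelihood(ds1, st, "convolution"), log(0.5),
               tolerance = 1e-9)
  expect_equal(ordinal_deviance(ds1, st, "convolution"), -2 * log(0.5),
               tolerance = 1e-9)
  ds2 <- ordinal_dataset(c(1L, 1L), matrix(c(1, 1, -1, -1), 2, 2),
                         c(1L, 1L), c(1L, 1L), K = 3)
  expect_equal(ordinal_log_likelihood(ds2, st, "convolution"),
               2 * ordinal_log_likelihood(ds1, st, "convolution"))
})

test_that("log-likelihood agrees with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:25) {
    case <- random_small_fit_case()
    for (structure in c("unstructured", "structured", "convolution")) {
      expect_equal(
        ordinal_log_likelihood(case$dataset, case$state, structure),
        oracle_loglik(case$dataset, case$state, structure),
        tolerance = 1e-10)
      expect_equal(ordinal_deviance(case$dataset, case$state, structure),
                   -2 * oracle_loglik(case$dataset, case$state, structure),
                   tolerance = 1e-10)
    }
  }
})

test_that("perfect prediction drives deviance to zero", {
  ds <- ordinal_dataset(3L, matrix(c(1, -1), 1, 2), 1L, 1L, K = 3)
  st <- parameter_state(c(40, 0), cutpoint_set(0, 1), u = 0, f = 0, phi = 0)
  expect_lt(ordinal_deviance(ds, st, "convolution"), 1e-10)
})

test_that("likelihood is invariant to a joint location shift", {
  set.seed(7)
  case <- random_small_fit_case(n = 30)
  base <- ordinal_log_likelihood(case$dataset, case$state, "convolution")
  for (c0 in c(-2.5, 1.3)) {
    st2 <- case$state
    st2$cutpoints <- cutpoint_set(st2$cutpoints$g1 + c0, st2$cutpoints$g2)
    st2$u <- st2$u + c0  # shifts every patient's eta by c0
    expect_equal(ordinal_log_likelihood(case$dataset, st2, "convolution"),
                 base, tolerance = 1e-10)
  }
})

test_that("underflowing probabilities stay finite in the log-likelihood", {
  ds <- ordinal_dataset(1L, matrix(c(1, 0), 1, 2), 1L, 1L, K = 3)
  st <- parameter_state(c(800, 0), cutpoint_set(0, 1), u = 0, f = 0, phi = 0)
  ll <- ordinal_log_likelihood(ds, st, "convolution")
  expect_true(is.finite(ll))
})

test_that("maximum of this likelihood matches an independent ML fit", {
  skip_if_not_installed("MASS")
  set.seed(21)
  n <- 4000
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  beta_true <- c(0.8, -0.5)
  kappa_true <- c(-0.5, 1.0)
  p <- category_probabilities(as.numeric(X %*% beta_true),
                              cutpoint_set(kappa_true[1], diff(kappa_true)))
  y <- spordinal:::sample_categorical(p)
  ds <- ordinal_dataset(y, X, rep(1L, n), rep(1L, n), K = 3)
  st0 <- parameter_state(c(0, 0), cutpoint_set(0, 1))
  negll <- function(par) {
    st <- parameter_state(par[1:2], cutpoint_set(par[3], exp(par[4])))
    -ordinal_log_likelihood(ds, st, "none")
  }
  opt <- optim(c(0, 0, 0, 0), negll, method = "BFGS")
  fit <- MASS::polr(factor(y) ~ x1 + x2, data = data.frame(y = y, X),
                    method = "logistic")
  expect_equal(unname(opt$par[1:2]), unname(coef(fit)), tolerance = 0.01)
  expect_equal(unname(opt$par[3]), unname(fit$zeta[1]), tolerance = 0.01)
  expect_equal(unname(opt$par[3] + exp(opt$par[4])), unname(fit$zeta[2]),
               tolerance = 0.01)
})

test_that("the loader rejects constant columns; containers validate inputs", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("outcome,a,b,facility_id,county_id,weight",
               "1,1,0,1,1,1", "2,1,1,1,1,1", "3,1,0,2,2,1"), path)
  expect_error(read_ordinal_csv(path), "constant")
  expect_error(ordinal_dataset(c(1L, 5L), cbind(a = c(0, 1)), c(1L, 1L),
                               c(1L, 1L), K = 3), "1..3")
  expect_error(cutpoint_set(0, -1), "positive")
})
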