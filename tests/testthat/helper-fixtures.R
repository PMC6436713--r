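# Shared fixtures and independent oracles.

# Brute-force log-likelihood oracle: evaluates each patient's full category
# probability vector from first principles (logistic CDF differences written
# out directly), independent of the package's vectorized path.
oracle_loglik <- function(dataset, state, structure) {
  kappa <- state$cutpoints$kappa
  K <- length(kappa) + 1L
  total <- 0
  for (i in seq_len(dataset$n)) {
    eta <- sum(dataset$X[i, ] * state$beta)
    if (length(state$f)) eta <- eta + state$f[dataset$facility[i]]
    if (structure %in% c("unstructured", "convolution") && length(state$u)) {
      eta <- eta + state$u[dataset$county[i]]
    }
    if (structure %in% c("structured", "convolution") && length(state$phi)) {
      eta <- eta + state$phi[dataset$county[i]]
    }
    probs <- numeric(K)
    for (k in seq_len(K)) {
      upper <- if (k == K) 1 else 1 / (1 + exp(-(kappa[k] - eta)))
      lower <- if (k == 1L) 0 else 1 / (1 + exp(-(kappa[k - 1L] - eta)))
      probs[k] <- upper - lower
    }
    total <- total + log(probs[dataset$y[i]])
  }
  total
}

# Dense-Laplacian CAR oracle: builds the full adjacency matrix W from the
# flattened representation and evaluates -(tau/2) * phi' (D - W) phi.
oracle_car_logdensity <- function(phi, adjacency, tau) {
  n <- adjacency$n
  W <- matrix(0, n, n)
  pos <- 0L
  for (j in seq_len(n)) {
    for (k in seq_len(adjacency$num[j])) {
      pos <- pos + 1L
      W[j, adjacency$adj[pos]] <- 1
    }
  }
  L <- diag(rowSums(W)) - W
  -(tau / 2) * as.numeric(t(phi) %*% L %*% phi)
}

# Random connected symmetric graph: random spanning tree plus extra edges.
random_connected_adjacency <- function(n, extra = n) {
  nb <- lapply(seq_len(n), function(i) integer(0))
  add_edge <- function(i, j) {
    if (i != j && !(j %in% nb[[i]])) {
      nb[[i]] <<- c(nb[[i]], j)
      nb[[j]] <<- c(nb[[j]], i)
    }
  }
  perm <- sample(n)
  for (k in 2:n) add_edge(perm[k], perm[sample(k - 1L, 1L)])
  for (e in seq_len(extra)) {
    ij <- sample(n, 2L)
    add_edge(ij[1L], ij[2L])
  }
  adjacency_structure(nb)
}

# Random small dataset with a matching random parameter state.
random_small_fit_case <- function(n = 20L, p = 2L, M = 3L, J = 4L, K = 3L) {
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  ds <- ordinal_dataset(sample.int(K, n, replace = TRUE), X,
                        sample.int(J, n, replace = TRUE),
                        sample.int(M, n, replace = TRUE), K = K)
  inc <- if (K > 2L) runif(K - 2L, 0.2, 1.5) else numeric(0)
  st <- parameter_state(
    stats::setNames(rnorm(p, 0, 0.7), colnames(X)),
    cutpoint_set(rnorm(1), inc),
    u = rnorm(M, 0, 0.5), f = rnorm(J, 0, 0.5), phi = {
      v <- rnorm(M); v - mean(v)
    },
    tau_h = 2, tau_v = 2, tau_c = 2)
  list(dataset = ds, state = st)
}

# Small simulated hierarchical dataset for sampler tests.
small_sim <- function(n = 600L, M = 10L, J = 30L, seed = 11L,
                      structure = "convolution", kind = "lattice", ...) {
  sc <- simulation_config(n_counties = M, n_facilities = J, n_patients = n,
                          structure = structure, adjacency_kind = kind,
                          seed = seed)
  adj <- generate_adjacency(M, kind, seed = seed)
  tr <- make_truth(sc, adj, ...)
  c(generate_dataset(sc, tr, adj), list(config = sc))
}

# Minimal posterior_draws skeleton for summary/surface unit tests.
fake_draws <- function(beta, blocks = rep("b", ncol(beta)), u = NULL,
                       phi = NULL, structure = "convolution") {
  nd <- nrow(beta)
  ch <- list(beta = beta, g1 = numeric(nd),
             g2 = matrix(1, nd, 1), kappa = cbind(numeric(nd), 1),
             u = u %||% matrix(numeric(0), nd, 0),
             f = matrix(numeric(0), nd, 0),
             phi = phi %||% matrix(numeric(0), nd, 0),
             tau_h = rep(1, nd), tau_v = rep(1, nd), tau_c = rep(1, nd),
             deviance = rep(1, nd))
  structure(list(chains = list(ch), accept = list(c(beta_b = 0.3)),
                 spec = model_spec(structure), config = mcmc_config(),
                 param_names = colnames(beta), blocks = blocks,
                 fingerprint = "fake", seed = 1L),
            class = "posterior_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
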