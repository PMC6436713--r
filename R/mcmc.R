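#' MCMC configuration
#'
#' `n_draws` is the number of retained draws per chain; the chain runs
#' `burnin + n_draws * thinning` iterations. Defaults mirror the study's
#' multivariable settings scaled for desk use. Proposal scales are adapted
#' toward a 20-45% acceptance rate during burn-in (Robbins-Monro) and frozen
#' afterward so the post-burn-in kernel is fixed.
#'
#' @param n_draws retained draws per chain (>= 1).
#' @param burnin burn-in iterations (>= 0).
#' @param thinning keep every `thinning`-th post-burn-in iteration (>= 1).
#' @param n_chains number of chains.
#' @param target_acceptance adaptation target (default 0.3).
#' @param adapt_window iterations between scale adjustments during burn-in.
#' @param init_scale initial random-walk proposal sd.
#' @param seed master seed; per-chain streams are derived deterministically.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_draws = 1000L, burnin = 1000L, thinning = 1L,
                        n_chains = 1L, target_acceptance = 0.3,
                        adapt_window = 50L, init_scale = 0.1, seed = 1L) {
  stopifnot(n_draws >= 1L, burnin >= 0L, thinning >= 1L, n_chains >= 1L,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(n_draws = as.integer(n_draws), burnin = as.integer(burnin),
                 thinning = as.integer(thinning),
                 n_chains = as.integer(n_chains),
                 target_acceptance = target_acceptance,
                 adapt_window = as.integer(adapt_window),
                 init_scale = init_scale, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Model specification
#'
#' Declares the random-effect structure, which design columns enter the
#' model, which covariates are forced into selection regardless of their
#' credible interval, whether facility effects are included (default on,
#' following the model code of the study design), and the prior.
#'
#' @param structure `"none"`, `"unstructured"`, `"structured"` or
#'   `"convolution"`.
#' @param covariates optional character vector of design columns to use
#'   (default: all columns of the dataset).
#' @param forced character vector of forced-in covariates (must be a subset
#'   of `covariates` when both are given).
#' @param facility_effects include facility random effects f.
#' @param prior a [prior_spec].
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(structure = c("convolution", "unstructured",
                                     "structured", "none"),
                       covariates = NULL, forced = character(0),
                       facility_effects = TRUE, prior = prior_spec()) {
  structure <- match.arg(structure)
  if (!is.null(covariates) && !all(forced %in% covariates)) {
    stop("forced covariates must be a subset of the model covariates")
  }
  base::structure(list(structure = structure, covariates = covariates,
                       forced = forced, facility_effects = facility_effects,
                       prior = prior),
                  class = "model_spec")
}

uses_u <- function(structure) structure %in% c("unstructured", "convolution")
uses_phi <- function(structure) structure %in% c("structured", "convolution")

#' Run the Metropolis-within-Gibbs sampler
#'
#' Samples the posterior of the hierarchical cumulative-logit model:
#' random-walk Metropolis block updates for each coefficient block and for
#' the cutpoints `(g1, log g2)`; coordinate-wise Metropolis updates for the
#' facility effects f and county unstructured effects u (valid as a product
#' kernel because their conditional target factorizes across units);
#' sequential single-site Metropolis for the CAR effects phi with
#' recentering to mean zero after every sweep (the standard intrinsic-CAR
#' identification); conjugate Gibbs draws for the precisions tau_h, tau_v,
#' tau_c. Deterministic given the seed.
#'
#' An empty dataset (0 rows) suppresses the likelihood, so the chain targets
#' the prior — useful for prior-recovery checks.
#'
#' @param dataset an [ordinal_dataset].
#' @param adjacency an [adjacency_structure]; required iff the structure uses
#'   the spatial effect.
#' @param spec a [model_spec].
#' @param config an [mcmc_config].
#' @return an object of class `posterior_draws`: per-chain draw matrices for
#'   beta, cutpoints, random effects, precisions and deviance, acceptance
#'   rates, and a config echo with a dataset fingerprint.
#' @export
run_mcmc <- function(dataset, adjacency = NULL, spec = model_spec(),
                     config = mcmc_config()) {
  if (uses_phi(spec$structure)) {
    if (is.null(adjacency)) {
      stop("adjacency is required for structure \"", spec$structure, "\"")
    }
  } else if (!is.null(adjacency) && spec$structure == "none") {
    warning("structure = \"none\": supplied adjacency is ignored")
  }
  if (!is.null(spec$covariates)) {
    missing_cols <- setdiff(spec$covariates, colnames(dataset$X))
    if (length(missing_cols)) {
      stop("covariates not in dataset: ", paste(missing_cols, collapse = ", "))
    }
    blocks <- (attr(dataset$X, "block") %||%
                 rep("b", ncol(dataset$X)))[match(spec$covariates,
                                                  colnames(dataset$X))]
    X <- dataset$X[, spec$covariates, drop = FALSE]
    attr(X, "block") <- blocks
    dataset <- ordinal_dataset(dataset$y, X, dataset$facility, dataset$county,
                               weight = dataset$weight, K = dataset$K,
                               blocks = blocks)
  }
  if (dataset$n > 1L) {
    sds <- apply(dataset$X, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variation covariate(s): ",
           paste(colnames(dataset$X)[sds == 0], collapse = ", "))
    }
  }
  M <- if (uses_phi(spec$structure) && !is.null(adjacency)) adjacency$n
       else dataset$n_counties
  M <- max(M, dataset$n_counties)
  J <- dataset$n_facilities
  chains <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    res <- run_one_chain(dataset, adjacency, spec, config,
                         chain_seed = derive_seed(config$seed, ch), M = M, J = J)
    chains[[ch]] <- res$draws
    accept[[ch]] <- res$accept
  }
  structure(list(chains = chains, accept = accept, spec = spec,
                 config = config, n_counties = M, n_facilities = J,
                 param_names = colnames(chains[[1]]$beta),
                 blocks = attr(dataset$X, "block") %||%
                   rep("b", ncol(dataset$X)),
                 fingerprint = dataset_fingerprint(dataset),
                 seed = config$seed),
            class = "posterior_draws")
}

dataset_fingerprint <- function(dataset) {
  paste(dataset$n, dataset$n_facilities, dataset$n_counties,
        ncol(dataset$X), sum(dataset$y),
        format(round(sum(dataset$X), 8), nsmall = 0), sep = ":")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", length(x$chains), "chain(s) x",
      nrow(x$chains[[1]]$beta), "retained draws; structure =",
      x$spec$structure, "\n")
  cat("Parameters:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

run_one_chain <- function(dataset, adjacency, spec, config, chain_seed, M, J) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(chain_seed)
  n <- dataset$n
  K <- dataset$K
  y <- dataset$y
  X <- dataset$X
  p <- ncol(X)
  blocks <- attr(X, "block") %||% rep("b", p)
  prior <- spec$prior
  beta_prec <- unname(prior$beta_precision[blocks])
  if (anyNA(beta_prec)) stop("unknown block label(s) in design matrix")
  struct <- spec$structure
  use_u <- uses_u(struct)
  use_phi <- uses_phi(struct)
  use_f <- isTRUE(spec$facility_effects)

  # initial values: cutpoints from empirical cumulative frequencies
  if (n > 0L) {
    cf <- cumsum(tabulate(y, K))[seq_len(K - 1L)] / n
    cf <- pmin(pmax(cf, 0.05), 0.95)
    kap0 <- stats::qlogis(cummax(cf + seq_len(K - 1L) * 1e-3))
  } else {
    kap0 <- seq_len(K - 1L) - 1
  }
  beta <- stats::setNames(numeric(p), colnames(X))
  g1 <- kap0[1L]
  g2 <- if (K > 2L) pmax(diff(kap0), 0.1) else numeric(0)
  u <- numeric(M); f <- numeric(J); phi <- numeric(M)
  tau_h <- 1; tau_v <- 1; tau_c <- 1

  kappa <- c(g1, g1 + cumsum(g2))
  xb <- as.numeric(X %*% beta)
  eta <- xb +
    (if (use_f && n) f[dataset$facility] else 0) +
    (if (use_u && n) u[dataset$county] else 0) +
    (if (use_phi && n) phi[dataset$county] else 0)
  lp_rows <- if (n) row_log_prob(eta, kappa, y) else numeric(0)

  # proposal scales and acceptance accounting
  block_names <- unique(blocks)
  sc_beta <- stats::setNames(rep(config$init_scale, length(block_names)),
                             block_names)
  sc_cut <- config$init_scale
  sc_u <- rep(config$init_scale, M)
  sc_f <- rep(config$init_scale, J)
  sc_phi <- rep(config$init_scale, M)
  acc <- list(beta = stats::setNames(numeric(length(block_names)), block_names),
              cutpoints = 0, u = 0, f = 0, phi = 0)
  att <- list(beta = stats::setNames(numeric(length(block_names)), block_names),
              cutpoints = 0, u = 0, f = 0, phi = 0)
  win <- list(beta = stats::setNames(numeric(length(block_names)), block_names),
              cutpoints = 0, u = numeric(M), f = numeric(J), phi = numeric(M))
  winn <- 0L

  fac_of <- dataset$facility
  cty_of <- dataset$county
  rows_by_county <- if (n) split(seq_len(n), factor(cty_of, levels = seq_len(M)))
                    else rep(list(integer(0)), M)
  county_has_rows <- lengths(rows_by_county) > 0L

  n_iter <- config$burnin + config$n_draws * config$thinning
  keep_every <- config$thinning
  draws <- list(
    beta = matrix(NA_real_, config$n_draws, p,
                  dimnames = list(NULL, colnames(X))),
    g1 = numeric(config$n_draws),
    g2 = matrix(NA_real_, config$n_draws, max(K - 2L, 0L)),
    kappa = matrix(NA_real_, config$n_draws, K - 1L),
    u = matrix(NA_real_, config$n_draws, if (use_u) M else 0L),
    f = matrix(NA_real_, config$n_draws, if (use_f) J else 0L),
    phi = matrix(NA_real_, config$n_draws, if (use_phi) M else 0L),
    tau_h = numeric(config$n_draws), tau_v = numeric(config$n_draws),
    tau_c = numeric(config$n_draws), deviance = numeric(config$n_draws))
  kept <- 0L

  for (iter in seq_len(n_iter)) {
    adapting <- iter <= config$burnin
    counting <- !adapting
    winn <- winn + 1L

    ## coefficient blocks: joint random-walk per block
    for (bl in block_names) {
      idx <- which(blocks == bl)
      delta <- stats::rnorm(length(idx), 0, sc_beta[[bl]])
      eta_new <- eta + as.numeric(X[, idx, drop = FALSE] %*% delta)
      lp_new <- if (n) row_log_prob(eta_new, kappa, y) else numeric(0)
      bn <- beta[idx] + delta
      logr <- sum(lp_new) - sum(lp_rows) +
        sum(stats::dnorm(bn, 0, 1 / sqrt(beta_prec[idx]), log = TRUE)) -
        sum(stats::dnorm(beta[idx], 0, 1 / sqrt(beta_prec[idx]), log = TRUE))
      ok <- is.finite(logr) && log(stats::runif(1)) < logr
      if (ok) {
        beta[idx] <- bn; eta <- eta_new; lp_rows <- lp_new
        xb <- xb + as.numeric(X[, idx, drop = FALSE] %*% delta)
        win$beta[[bl]] <- win$beta[[bl]] + 1
        if (counting) acc$beta[[bl]] <- acc$beta[[bl]] + 1
      }
      if (counting) att$beta[[bl]] <- att$beta[[bl]] + 1
    }

    ## cutpoints: joint RW on (g1, log g2), Jacobian for the log transform
    {
      g1_new <- g1 + stats::rnorm(1, 0, sc_cut)
      lg2_new <- if (K > 2L) log(g2) + stats::rnorm(K - 2L, 0, sc_cut)
                 else numeric(0)
      g2_new <- exp(lg2_new)
      kap_new <- c(g1_new, g1_new + cumsum(g2_new))
      lp_new <- if (n) row_log_prob(eta, kap_new, y) else numeric(0)
      logr <- sum(lp_new) - sum(lp_rows) +
        stats::dnorm(g1_new, 0, 1 / sqrt(prior$g1_precision), log = TRUE) -
        stats::dnorm(g1, 0, 1 / sqrt(prior$g1_precision), log = TRUE)
      if (K > 2L) {
        logr <- logr +
          sum(stats::dgamma(g2_new, prior$g2_shape, rate = prior$g2_rate,
                            log = TRUE)) + sum(lg2_new) -
          sum(stats::dgamma(g2, prior$g2_shape, rate = prior$g2_rate,
                            log = TRUE)) - sum(log(g2))
      }
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        g1 <- g1_new; g2 <- g2_new; kappa <- kap_new; lp_rows <- lp_new
        win$cutpoints <- win$cutpoints + 1
        if (counting) acc$cutpoints <- acc$cutpoints + 1
      }
      if (counting) att$cutpoints <- att$cutpoints + 1
    }

    ## facility effects: simultaneous coordinate-wise MH (iid prior,
    ## disjoint likelihood blocks => the conditional target factorizes)
    if (use_f) {
      f_new <- f + stats::rnorm(J, 0, sc_f)
      dlik <- numeric(J)
      if (n) {
        eta_new <- eta + (f_new - f)[fac_of]
        lp_new <- row_log_prob(eta_new, kappa, y)
        dlik <- group_sum(lp_new - lp_rows, fac_of, J)
      }
      logr <- dlik +
        stats::dnorm(f_new, 0, 1 / sqrt(tau_v), log = TRUE) -
        stats::dnorm(f, 0, 1 / sqrt(tau_v), log = TRUE)
      ok <- log(stats::runif(J)) < logr
      if (any(ok)) {
        delta_f <- ifelse(ok, f_new - f, 0)
        f[ok] <- f_new[ok]
        if (n) {
          eta <- eta + delta_f[fac_of]
          lp_rows <- row_log_prob(eta, kappa, y)
        }
      }
      win$f <- win$f + ok
      if (counting) acc$f <- acc$f + mean(ok)
      if (counting) att$f <- att$f + 1
      tau_v <- stats::rgamma(1, shape = prior$tau_v_shape + J / 2,
                             rate = prior$tau_v_rate + sum(f^2) / 2)
    }

    ## county unstructured effects: same factorized coordinate-wise MH
    if (use_u) {
      u_new <- u + stats::rnorm(M, 0, sc_u)
      dlik <- numeric(M)
      if (n) {
        eta_new <- eta + (u_new - u)[cty_of]
        lp_new <- row_log_prob(eta_new, kappa, y)
        dlik <- group_sum(lp_new - lp_rows, cty_of, M)
      }
      logr <- dlik +
        stats::dnorm(u_new, 0, 1 / sqrt(tau_h), log = TRUE) -
        stats::dnorm(u, 0, 1 / sqrt(tau_h), log = TRUE)
      ok <- log(stats::runif(M)) < logr
      if (any(ok)) {
        delta_u <- ifelse(ok, u_new - u, 0)
        u[ok] <- u_new[ok]
        if (n) {
          eta <- eta + delta_u[cty_of]
          lp_rows <- row_log_prob(eta, kappa, y)
        }
      }
      win$u <- win$u + ok
      if (counting) acc$u <- acc$u + mean(ok)
      if (counting) att$u <- att$u + 1
      tau_h <- stats::rgamma(1, shape = prior$tau_h_shape + M / 2,
                             rate = prior$tau_h_rate + sum(u^2) / 2)
    }

    ## CAR effects: sequential single-site MH with local prior term,
    ## then exact recentering (intrinsic-CAR identification)
    if (use_phi) {
      nb <- adjacency$neighbors
      acc_phi_sweep <- 0
      for (j in seq_len(M)) {
        pj <- phi[j] + stats::rnorm(1, 0, sc_phi[j])
        dprior <- -tau_c / 2 *
          (sum((pj - phi[nb[[j]]])^2) - sum((phi[j] - phi[nb[[j]]])^2))
        dlik <- 0
        rows <- rows_by_county[[j]]
        if (length(rows)) {
          lp_j <- row_log_prob(eta[rows] + (pj - phi[j]), kappa, y[rows])
          dlik <- sum(lp_j) - sum(lp_rows[rows])
        }
        if (log(stats::runif(1)) < dlik + dprior) {
          if (length(rows)) {
            eta[rows] <- eta[rows] + (pj - phi[j])
            lp_rows[rows] <- lp_j
          }
          phi[j] <- pj
          win$phi[j] <- win$phi[j] + 1
          acc_phi_sweep <- acc_phi_sweep + 1
        }
      }
      if (counting) acc$phi <- acc$phi + acc_phi_sweep / M
      if (counting) att$phi <- att$phi + 1
      mphi <- mean(phi)
      if (mphi != 0) {
        phi <- phi - mphi
        if (n) {
          eta <- eta - mphi
          lp_rows <- row_log_prob(eta, kappa, y)
        }
      }
      e <- edge_list(adjacency)
      ss <- sum((phi[e[, 1L]] - phi[e[, 2L]])^2)
      ncomp <- max(connected_components(adjacency))
      tau_c <- stats::rgamma(1, shape = prior$tau_c_shape + (M - ncomp) / 2,
                             rate = prior$tau_c_rate + ss / 2)
    }

    ## Robbins-Monro scale adaptation during burn-in
    if (adapting && winn >= config$adapt_window) {
      gain <- min(1, 5 / sqrt(iter / config$adapt_window))
      tgt <- config$target_acceptance
      for (bl in block_names) {
        sc_beta[[bl]] <- sc_beta[[bl]] *
          exp(gain * (win$beta[[bl]] / winn - tgt))
      }
      sc_cut <- sc_cut * exp(gain * (win$cutpoints / winn - tgt))
      sc_u <- sc_u * exp(gain * (win$u / winn - tgt))
      sc_f <- sc_f * exp(gain * (win$f / winn - tgt))
      sc_phi <- sc_phi * exp(gain * (win$phi / winn - tgt))
      win <- list(beta = win$beta * 0, cutpoints = 0, u = numeric(M),
                  f = numeric(J), phi = numeric(M))
      winn <- 0L
    }

    ## store retained draw
    if (iter > config$burnin &&
        (iter - config$burnin) %% keep_every == 0L) {
      kept <- kept + 1L
      draws$beta[kept, ] <- beta
      draws$g1[kept] <- g1
      if (K > 2L) draws$g2[kept, ] <- g2
      draws$kappa[kept, ] <- kappa
      if (use_u) draws$u[kept, ] <- u
      if (use_f) draws$f[kept, ] <- f
      if (use_phi) draws$phi[kept, ] <- phi
      draws$tau_h[kept] <- tau_h
      draws$tau_v[kept] <- tau_v
      draws$tau_c[kept] <- tau_c
      draws$deviance[kept] <- -2 * sum(lp_rows)
    }
  }

  denom <- max(att$cutpoints, 1)
  accept <- c(
    stats::setNames(as.numeric(acc$beta) / pmax(as.numeric(att$beta), 1),
                    paste0("beta_", block_names)),
    cutpoints = acc$cutpoints / denom,
    u = if (use_u) acc$u / max(att$u, 1) else NA_real_,
    f = if (use_f) acc$f / max(att$f, 1) else NA_real_,
    phi = if (use_phi) acc$phi / max(att$phi, 1) else NA_real_)
  list(draws = draws, accept = accept)
}

#' Deviance information criterion
#'
#' `D_bar` is the posterior mean deviance over retained draws; `D_at_mean`
#' the deviance at the posterior mean of every parameter (random effects
#' included — the plug-in used by the standard BUGS-style focused DIC);
#' `pD = D_bar - D_at_mean` and `DIC = D_bar + pD`.
#'
#' @param draws a [run_mcmc()] result.
#' @param dataset the dataset the draws were fitted to.
#' @param spec the [model_spec] used (default: the one stored in `draws`).
#' @return an object of class `dic_result` with `D_bar`, `D_at_mean`, `pD`,
#'   `DIC`.
#' @export
compute_dic <- function(draws, dataset, spec = draws$spec) {
  if (!length(draws$chains) || nrow(draws$chains[[1]]$beta) == 0L) {
    stop("empty draws")
  }
  dev <- unlist(lapply(draws$chains, `[[`, "deviance"))
  D_bar <- mean(dev)
  st <- posterior_mean_state(draws)
  D_hat <- ordinal_deviance(dataset, st, structure = effective_structure(spec))
  pD <- D_bar - D_hat
  structure(list(D_bar = D_bar, D_at_mean = D_hat, pD = pD, DIC = D_bar + pD),
            class = "dic_result")
}

effective_structure <- function(spec) {
  if (spec$structure == "none") "none" else spec$structure
}

posterior_mean_state <- function(draws) {
  pool <- function(name) {
    m <- do.call(rbind, lapply(draws$chains, `[[`, name))
    if (is.null(m) || (is.matrix(m) && ncol(m) == 0L)) numeric(0)
    else if (is.matrix(m)) colMeans(m) else mean(m)
  }
  beta <- pool("beta")
  attr(beta, "block") <- draws$blocks
  kap <- pool("kappa")
  cp <- cutpoint_set(kap[1], if (length(kap) > 1L) diff(kap) else numeric(0))
  parameter_state(beta, cp, u = pool("u"), f = pool("f"), phi = pool("phi"),
                  tau_h = max(pool("tau_h"), 1e-12),
                  tau_v = max(pool("tau_v"), 1e-12),
                  tau_c = max(pool("tau_c"), 1e-12))
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.1f  (D_bar = %.1f, D_at_mean = %.1f, pD = %.1f)\n",
              x$DIC, x$D_bar, x$D_at_mean, x$pD))
  invisible(x)
}

#' Summarize posterior draws as odds ratios with credible intervals
#'
#' Per coefficient: posterior mean and SD on the log-odds scale, posterior
#' mean/median and SD of the odds-ratio draws (exp applied draw-wise), and
#' equal-tailed quantile intervals of the OR at each requested credibility
#' level (default 85% and 95%).
#'
#' @param draws a [run_mcmc()] result.
#' @param levels credibility levels in (0, 1).
#' @param parameters optional subset of coefficient names.
#' @return a `fit_summary` data frame, one row per coefficient.
#' @export
summarize_draws <- function(draws, levels = c(0.85, 0.95), parameters = NULL) {
  stopifnot(all(levels > 0), all(levels < 1))
  bm <- do.call(rbind, lapply(draws$chains, `[[`, "beta"))
  parameters <- parameters %||% colnames(bm)
  unknown <- setdiff(parameters, colnames(bm))
  if (length(unknown)) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  }
  out <- do.call(rbind, lapply(parameters, function(pn) {
    b <- bm[, pn]
    or <- exp(b)
    row <- data.frame(parameter = pn,
                      block = draws$blocks[match(pn, colnames(bm))],
                      mean_coef = mean(b), sd_coef = stats::sd(b),
                      or_mean = mean(or), or_median = stats::median(or),
                      or_sd = stats::sd(or))
    for (lv in levels) {
      q <- stats::quantile(or, c((1 - lv) / 2, 1 - (1 - lv) / 2), names = FALSE)
      row[[sprintf("or_l%02.0f", 100 * lv)]] <- q[1]
      row[[sprintf("or_u%02.0f", 100 * lv)]] <- q[2]
    }
    row
  }))
  rownames(out) <- NULL
  class(out) <- c("fit_summary", "data.frame")
  out
}

#' Convergence and mixing diagnostics
#'
#' Split-chain potential-scale-reduction statistic (computed when at least
#' two chains are available; otherwise omitted with a warning), lag-1
#' autocorrelation of the retained draws, effective sample size, and the
#' sampler's block acceptance rates. Parameters with statistic above the
#' threshold are flagged.
#'
#' @param draws a [run_mcmc()] result.
#' @param rhat_threshold flag threshold (default 1.1).
#' @return list with `parameters` (data frame: rhat, lag1_autocorr, ess,
#'   converged) and `acceptance` (per-block rates).
#' @export
mcmc_diagnostics <- function(draws, rhat_threshold = 1.1) {
  scalar_mats <- function(ch) {
    kap <- ch$kappa
    colnames(kap) <- paste0("kappa", seq_len(ncol(kap)))
    cbind(ch$beta, g1 = ch$g1, kap,
          tau_h = ch$tau_h, tau_v = ch$tau_v, tau_c = ch$tau_c,
          deviance = ch$deviance)
  }
  mats <- lapply(draws$chains, scalar_mats)
  nm <- colnames(mats[[1]])
  multi <- length(mats) >= 2L
  if (!multi) {
    warning("single chain: split-chain convergence statistic omitted")
  }
  rows <- lapply(nm, function(pn) {
    xs <- lapply(mats, function(m) m[, pn])
    keep <- stats::sd(unlist(xs)) > 0
    r <- if (multi && keep) split_rhat(xs) else NA_real_
    ac <- if (keep) lag1_autocorr(xs[[1]]) else NA_real_
    ess <- if (keep) sum(vapply(xs, ess_one, numeric(1))) else NA_real_
    data.frame(parameter = pn, rhat = r, lag1_autocorr = ac, ess = ess,
               converged = if (multi && keep) r < rhat_threshold else NA)
  })
  acc <- do.call(rbind, draws$accept)
  list(parameters = do.call(rbind, rows),
       acceptance = colMeans(acc, na.rm = TRUE))
}

# split each chain in half and compute the between/within variance ratio
split_rhat <- function(xs) {
  halves <- unlist(lapply(xs, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

lag1_autocorr <- function(x) {
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  stats::cor(x[-1L], x[-length(x)])
}

ess_one <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(100L, n - 2L), plot = FALSE)$acf[-1L]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1L] - 1L else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}

#' Persist posterior draws as CSV arrays plus a JSON manifest
#'
#' @param draws a [run_mcmc()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_posterior_draws <- function(draws, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (ch in seq_along(draws$chains)) {
    for (nm in names(draws$chains[[ch]])) {
      v <- draws$chains[[ch]][[nm]]
      if ((is.matrix(v) && ncol(v) == 0L) || length(v) == 0L) next
      fn <- sprintf("chain%d_%s.csv", ch, nm)
      utils::write.csv(as.data.frame(v), file.path(dir, fn), row.names = FALSE)
      files[[fn]] <- if (is.matrix(v)) dim(v) else c(length(v), 1L)
    }
  }
  jsonlite::write_json(
    list(parameters = draws$param_names, blocks = draws$blocks,
         structure = draws$spec$structure, n_chains = length(draws$chains),
         n_draws = draws$config$n_draws, burnin = draws$config$burnin,
         thinning = draws$config$thinning, seed = draws$seed,
         fingerprint = draws$fingerprint,
         files = files),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
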