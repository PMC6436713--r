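#' Cutpoint set for a cumulative-logit model
#'
#' Cutpoints are stored as a free first cutpoint `g1` and strictly positive
#' increments `g2`, so that `kappa = c(g1, g1 + cumsum(g2))` is increasing by
#' construction. The implicit outer cutpoints are `kappa_0 = -Inf` and
#' `kappa_K = +Inf`. For the three-category model this is `kappa_1 = g1`,
#' `kappa_2 = g1 + g2`.
#'
#' @param g1 first cutpoint (real).
#' @param g2 numeric vector of positive increments (length K - 2; empty for
#'   K = 2).
#' @return an object of class `cutpoint_set` with elements `g1`, `g2` and the
#'   derived increasing vector `kappa`.
#' @examples
#' cp <- cutpoint_set(0, log(3))
#' cp$kappa  # 0, log(3)
#' @export
cutpoint_set <- function(g1, g2 = numeric(0)) {
  stopifnot(is.numeric(g1), length(g1) == 1L, is.finite(g1))
  if (length(g2)) {
    if (any(!is.finite(g2)) || any(g2 <= 0)) {
      stop("cutpoint increments `g2` must be strictly positive and finite")
    }
  }
  kappa <- c(g1, g1 + cumsum(g2))
  structure(list(g1 = g1, g2 = g2, kappa = kappa), class = "cutpoint_set")
}

#' @export
print.cutpoint_set <- function(x, ...) {
  cat("Cutpoints (kappa):", paste(signif(x$kappa, 5), collapse = " < "), "\n")
  invisible(x)
}

#' Ordinal category probabilities under the cumulative-logit model
#'
#' For linear predictor eta and cutpoints kappa the probability of category k
#' is the difference of two logistic CDFs,
#' `p_k = logistic(kappa_k - eta) - logistic(kappa_{k-1} - eta)`,
#' with kappa_0 = -Inf and kappa_K = +Inf. Larger eta shifts probability mass
#' toward higher categories.
#'
#' @param eta numeric vector of linear predictors.
#' @param cutpoints a [cutpoint_set] (or increasing numeric vector of interior
#'   cutpoints, length K - 1).
#' @return a length(eta) x K matrix of probabilities; rows sum to 1.
#' @examples
#' category_probabilities(0, cutpoint_set(0, log(3)))  # 0.5 0.25 0.25
#' @export
category_probabilities <- function(eta, cutpoints) {
  kappa <- if (inherits(cutpoints, "cutpoint_set")) cutpoints$kappa else cutpoints
  if (length(kappa) < 1L || is.unsorted(kappa, strictly = TRUE)) {
    stop("cutpoints must be a strictly increasing vector")
  }
  cum <- vapply(kappa, function(k) stats::plogis(k - eta), numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  p <- cbind(cum, 1)[, , drop = FALSE] - cbind(0, cum)
  colnames(p) <- paste0("p", seq_len(ncol(p)))
  p
}

# Log probability of the observed category for each row; vectorized hot path
# shared by the likelihood and the sampler. kappa is the interior cutpoints.
row_log_prob <- function(eta, kappa, y) {
  hi <- c(kappa, Inf)[y]
  lo <- c(-Inf, kappa)[y]
  p <- stats::plogis(hi - eta) - stats::plogis(lo - eta)
  log(pmax(p, .PROB_FLOOR))
}

#' Linear predictor of the hierarchical ordinal model
#'
#' Assembles `eta = x'beta + f_facility (+ u_county) (+ phi_county)` where the
#' unstructured county effect u enters under the `unstructured` and
#' `convolution` structures and the CAR spatial effect phi enters under
#' `structured` and `convolution`. The model carries no intercept: the
#' cutpoints absorb it.
#'
#' @param x_row numeric covariate vector (dummy-expanded, no constant).
#' @param state a [parameter_state].
#' @param facility facility index (1..J).
#' @param county county index (1..M).
#' @param structure one of `"none"`, `"unstructured"`, `"structured"`,
#'   `"convolution"`.
#' @return the scalar linear predictor.
#' @export
linear_predictor <- function(x_row, state, facility, county,
                             structure = c("convolution", "unstructured",
                                           "structured", "none")) {
  structure <- match.arg(structure)
  if (length(state$f) && (facility < 1L || facility > length(state$f))) {
    stop("facility index out of range: ", facility)
  }
  m <- max(length(state$u), length(state$phi))
  if (m > 0L && (county < 1L || county > m)) {
    stop("county index out of range: ", county)
  }
  eta <- sum(x_row * state$beta)
  if (length(state$f)) eta <- eta + state$f[facility]
  if (structure %in% c("unstructured", "convolution") && length(state$u)) {
    eta <- eta + state$u[county]
  }
  if (structure %in% c("structured", "convolution") && length(state$phi)) {
    eta <- eta + state$phi[county]
  }
  eta
}

# Vectorized eta for a whole dataset given a parameter state.
dataset_eta <- function(dataset, state, structure) {
  eta <- as.numeric(dataset$X %*% state$beta)
  if (length(state$f)) eta <- eta + state$f[dataset$facility]
  if (structure %in% c("unstructured", "convolution") && length(state$u)) {
    eta <- eta + state$u[dataset$county]
  }
  if (structure %in% c("structured", "convolution") && length(state$phi)) {
    eta <- eta + state$phi[dataset$county]
  }
  eta
}

#' Parameter state of the hierarchical ordinal model
#'
#' Bundles fixed-effect coefficients, cutpoints, facility effects, county
#' unstructured effects, county CAR effects, and the three precision
#' hyperparameters. Vectors for inactive components may be zero-length.
#'
#' @param beta named coefficient vector; names carry block labels via
#'   `attr(beta, "block")` when used with block priors.
#' @param cutpoints a [cutpoint_set].
#' @param u county unstructured effects (length M or 0).
#' @param f facility effects (length J or 0).
#' @param phi county CAR effects (length M or 0).
#' @param tau_h,tau_v,tau_c precisions (> 0) of u, f and phi.
#' @return an object of class `parameter_state`.
#' @export
parameter_state <- function(beta, cutpoints, u = numeric(0), f = numeric(0),
                            phi = numeric(0), tau_h = 1, tau_v = 1, tau_c = 1) {
  stopifnot(inherits(cutpoints, "cutpoint_set"))
  if (any(c(tau_h, tau_v, tau_c) <= 0)) stop("precisions must be > 0")
  if (length(u) && length(phi) && length(u) != length(phi)) {
    stop("u and phi must have equal length (number of counties)")
  }
  structure(list(beta = beta, cutpoints = cutpoints, u = u, f = f, phi = phi,
                 tau_h = tau_h, tau_v = tau_v, tau_c = tau_c),
            class = "parameter_state")
}

#' Log-likelihood of an ordinal dataset
#'
#' Sum over patients of the log probability of the realized category under the
#' cumulative-logit model with the chosen random-effect structure.
#' Probabilities are clamped at 1e-300 before the log so the result is finite
#' for all finite parameter values.
#'
#' @param dataset an [ordinal_dataset].
#' @param state a [parameter_state] with effect vectors sized to the dataset.
#' @param structure random-effect structure, see [linear_predictor].
#' @return scalar log-likelihood (<= 0).
#' @export
ordinal_log_likelihood <- function(dataset, state,
                                   structure = c("convolution", "unstructured",
                                                 "structured", "none")) {
  structure <- match.arg(structure)
  check_state_dims(dataset, state, structure)
  if (dataset$n == 0L) return(0)
  eta <- dataset_eta(dataset, state, structure)
  sum(row_log_prob(eta, state$cutpoints$kappa, dataset$y))
}

#' Deviance of an ordinal dataset
#'
#' `D = -2 * log-likelihood`; nonnegative, and the quantity averaged over
#' posterior draws in the DIC.
#' @inheritParams ordinal_log_likelihood
#' @return scalar deviance (>= 0).
#' @export
ordinal_deviance <- function(dataset, state,
                             structure = c("convolution", "unstructured",
                                           "structured", "none")) {
  -2 * ordinal_log_likelihood(dataset, state, structure = match.arg(structure))
}

check_state_dims <- function(dataset, state, structure) {
  if (length(state$beta) != ncol(dataset$X)) {
    stop("beta length ", length(state$beta), " does not match ",
         ncol(dataset$X), " covariate columns")
  }
  if (length(state$f) && dataset$n_facilities > length(state$f)) {
    stop("facility effect vector shorter than facility index range")
  }
  uses_u <- structure %in% c("unstructured", "convolution")
  uses_phi <- structure %in% c("structured", "convolution")
  if (uses_u && length(state$u) && dataset$n_counties > length(state$u)) {
    stop("county effect vector u shorter than county index range")
  }
  if (uses_phi && length(state$phi) && dataset$n_counties > length(state$phi)) {
    stop("spatial effect vector phi shorter than county index range")
  }
  invisible(TRUE)
}
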