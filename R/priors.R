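#' Prior specification
#'
#' Defaults follow the model files of the study design this package
#' implements: coefficient blocks get mean-zero normal priors with block
#' precision (`b` = patient characteristics, precision 0.001; `s` =
#' facility binaries, `q` = county continuous, `m` = mixed patient/facility,
#' precision 1e-6), the first cutpoint g1 a normal prior with precision 0.01,
#' the cutpoint increment g2 a Gamma(0.001, 0.001), and the precisions
#' tau_h (county unstructured) ~ Gamma(0.5, 5e-4), tau_c (CAR) ~
#' Gamma(0.5, 5e-4), tau_v (facility) ~ Gamma(0.001, 0.001). All Gamma
#' distributions are shape-rate.
#'
#' @param beta_precision named list/vector of per-block normal prior
#'   precisions.
#' @param g1_precision normal prior precision of the first cutpoint.
#' @param g2_shape,g2_rate Gamma prior of the cutpoint increment.
#' @param tau_h_shape,tau_h_rate Gamma prior of the county unstructured
#'   precision.
#' @param tau_c_shape,tau_c_rate Gamma prior of the CAR precision.
#' @param tau_v_shape,tau_v_rate Gamma prior of the facility precision.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(beta_precision = c(b = 0.001, s = 1e-6, q = 1e-6,
                                          m = 1e-6),
                       g1_precision = 0.01,
                       g2_shape = 0.001, g2_rate = 0.001,
                       tau_h_shape = 0.5, tau_h_rate = 0.0005,
                       tau_c_shape = 0.5, tau_c_rate = 0.0005,
                       tau_v_shape = 0.001, tau_v_rate = 0.001) {
  vals <- c(unlist(beta_precision), g1_precision, g2_shape, g2_rate,
            tau_h_shape, tau_h_rate, tau_c_shape, tau_c_rate,
            tau_v_shape, tau_v_rate)
  if (any(vals <= 0)) stop("all prior precisions, shapes and rates must be > 0")
  structure(list(beta_precision = unlist(beta_precision),
                 g1_precision = g1_precision,
                 g2_shape = g2_shape, g2_rate = g2_rate,
                 tau_h_shape = tau_h_shape, tau_h_rate = tau_h_rate,
                 tau_c_shape = tau_c_shape, tau_c_rate = tau_c_rate,
                 tau_v_shape = tau_v_shape, tau_v_rate = tau_v_rate),
            class = "prior_spec")
}

# per-coefficient prior precision from block labels (default block "b")
beta_prior_precisions <- function(beta, prior) {
  blocks <- attr(beta, "block") %||% rep("b", length(beta))
  prec <- prior$beta_precision[blocks]
  if (anyNA(prec)) stop("unknown coefficient block label(s): ",
                        paste(unique(blocks[is.na(prec)]), collapse = ", "))
  unname(prec)
}

#' Unnormalized intrinsic-CAR log density
#'
#' `log p(phi | tau_c) = -(tau_c/2) * sum over unordered neighbor pairs of
#' (phi_i - phi_j)^2`, i.e. `-(tau_c/2) phi' L phi` with L the graph
#' Laplacian. Translation-invariant: adding a constant to phi leaves it
#' unchanged (the intrinsic CAR's improper direction).
#'
#' @param phi effect vector, one entry per county.
#' @param adjacency an [adjacency_structure].
#' @param tau_c CAR precision (> 0).
#' @return unnormalized log density (scalar).
#' @examples
#' a <- generate_adjacency(2, "lattice")
#' car_log_density(c(1, -1), a, 1)  # -2
#' @export
car_log_density <- function(phi, adjacency, tau_c) {
  if (length(phi) != adjacency$n) {
    stop("phi has length ", length(phi), " but adjacency has ",
         adjacency$n, " counties")
  }
  if (tau_c <= 0) stop("tau_c must be > 0")
  e <- edge_list(adjacency)
  -tau_c / 2 * sum((phi[e[, 1L]] - phi[e[, 2L]])^2)
}

#' Total log prior of a parameter state
#'
#' Sum of the log prior terms active under the chosen random-effect
#' structure: normal log densities for each coefficient (block precisions)
#' and g1; Gamma log densities for g2 and each active precision; normal for
#' the unstructured county effects u (precision tau_h, when structure uses u)
#' and facility effects f (precision tau_v, when present); the unnormalized
#' CAR term for phi (when structure uses phi). Inactive components contribute
#' zero.
#'
#' @param state a [parameter_state].
#' @param prior a [prior_spec].
#' @param adjacency an [adjacency_structure]; required when `structure` uses
#'   the spatial effect.
#' @param structure one of `"none"`, `"unstructured"`, `"structured"`,
#'   `"convolution"`.
#' @return scalar log prior (CAR term unnormalized).
#' @export
log_prior_total <- function(state, prior, adjacency = NULL,
                            structure = c("convolution", "unstructured",
                                          "structured", "none")) {
  structure <- match.arg(structure)
  if (any(c(state$tau_h, state$tau_v, state$tau_c) <= 0)) {
    stop("precisions must be > 0")
  }
  lp <- 0
  if (length(state$beta)) {
    prec <- beta_prior_precisions(state$beta, prior)
    lp <- lp + sum(stats::dnorm(state$beta, 0, 1 / sqrt(prec), log = TRUE))
  }
  cp <- state$cutpoints
  lp <- lp + stats::dnorm(cp$g1, 0, 1 / sqrt(prior$g1_precision), log = TRUE)
  if (length(cp$g2)) {
    lp <- lp + sum(stats::dgamma(cp$g2, shape = prior$g2_shape,
                                 rate = prior$g2_rate, log = TRUE))
  }
  uses_u <- structure %in% c("unstructured", "convolution")
  uses_phi <- structure %in% c("structured", "convolution")
  if (uses_u && length(state$u)) {
    lp <- lp + sum(stats::dnorm(state$u, 0, 1 / sqrt(state$tau_h), log = TRUE)) +
      stats::dgamma(state$tau_h, shape = prior$tau_h_shape,
                    rate = prior$tau_h_rate, log = TRUE)
  }
  if (length(state$f)) {
    lp <- lp + sum(stats::dnorm(state$f, 0, 1 / sqrt(state$tau_v), log = TRUE)) +
      stats::dgamma(state$tau_v, shape = prior$tau_v_shape,
                    rate = prior$tau_v_rate, log = TRUE)
  }
  if (uses_phi && length(state$phi)) {
    if (is.null(adjacency)) stop("adjacency required for structure ", structure)
    lp <- lp + car_log_density(state$phi, adjacency, state$tau_c) +
      stats::dgamma(state$tau_c, shape = prior$tau_c_shape,
                    rate = prior$tau_c_rate, log = TRUE)
  }
  lp
}

#' Gibbs draw from a precision's conjugate Gamma full conditional
#'
#' For iid normal effects theta the conditional is
#' `Gamma(shape + m/2, rate + sum(theta^2)/2)`. For intrinsic-CAR effects it
#' is `Gamma(shape + (n - c)/2, rate + (1/2) sum over edges (phi_i - phi_j)^2)`
#' where `c` is the number of connected components (the CAR's rank
#' deficiency, one flat direction per component).
#'
#' @param effects realized effect vector.
#' @param prior_shape,prior_rate Gamma prior (shape-rate).
#' @param kind `"iid"` or `"car"`.
#' @param adjacency an [adjacency_structure]; required for `kind = "car"`.
#' @param n_draws number of draws.
#' @return one precision draw (or a vector of `n_draws`).
#' @export
sample_precision_conditional <- function(effects, prior_shape, prior_rate,
                                         kind = c("iid", "car"),
                                         adjacency = NULL, n_draws = 1L) {
  kind <- match.arg(kind)
  if (!length(effects)) stop("effects must be non-empty")
  par <- precision_conditional(effects, prior_shape, prior_rate, kind, adjacency)
  stats::rgamma(n_draws, shape = par$shape, rate = par$rate)
}

# conditional Gamma parameters, exposed separately for testing
precision_conditional <- function(effects, prior_shape, prior_rate,
                                  kind = c("iid", "car"), adjacency = NULL) {
  kind <- match.arg(kind)
  if (kind == "iid") {
    list(shape = prior_shape + length(effects) / 2,
         rate = prior_rate + sum(effects^2) / 2)
  } else {
    if (is.null(adjacency)) stop("adjacency required for kind = \"car\"")
    if (length(effects) != adjacency$n) stop("effects length must match adjacency")
    ncomp <- max(connected_components(adjacency))
    e <- edge_list(adjacency)
    ss <- sum((effects[e[, 1L]] - effects[e[, 2L]])^2)
    list(shape = prior_shape + (adjacency$n - ncomp) / 2,
         rate = prior_rate + ss / 2)
  }
}
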