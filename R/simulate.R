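#' Ground-truth parameter record for simulation
#'
#' Stores the generating values of the coefficients, cutpoints, precisions
#' and realized random effects of a simulated dataset, for later recovery
#' testing.
#'
#' @param beta named log-odds coefficient vector (with `block` attribute).
#' @param cutpoints a [cutpoint_set].
#' @param tau_h,tau_v,tau_c generating precisions (> 0).
#' @param u,f,phi realized county-unstructured, facility and CAR effect
#'   vectors (zero-length when inactive); `phi` must sum to zero.
#' @param seed integer seed used for the realization.
#' @return an object of class `truth_record`.
#' @export
truth_record <- function(beta, cutpoints, tau_h, tau_v, tau_c,
                         u = numeric(0), f = numeric(0), phi = numeric(0),
                         seed = NA_integer_) {
  stopifnot(inherits(cutpoints, "cutpoint_set"))
  if (any(c(tau_h, tau_v, tau_c) <= 0)) stop("precisions must be > 0")
  if (length(phi) && abs(sum(phi)) > 1e-8 * max(1, max(abs(phi)))) {
    stop("phi must sum to zero")
  }
  structure(list(beta = beta, cutpoints = cutpoints, tau_h = tau_h,
                 tau_v = tau_v, tau_c = tau_c, u = u, f = f, phi = phi,
                 seed = seed),
            class = "truth_record")
}

#' Default covariate plan of the synthetic generator
#'
#' A compact stand-in for the covariate structure of a facility-based
#' post-abortion-care survey: patient-level categoricals (one with a distinct
#' missing-as-category code 9), facility-level binaries and a continuous
#' facility measure, and one continuous county-level measure. Each entry
#' carries the prior block label (`b` patient, `s` facility-binary/continuous,
#' `q` county-continuous, `m` mixed) and the generating coefficients for the
#' non-reference levels.
#'
#' @return list of covariate descriptors.
#' @export
default_covariate_plan <- function() {
  list(
    list(name = "age", type = "categorical", level = "patient", block = "b",
         levels = c(1, 2, 3), beta = c(0.4, 0.7)),
    list(name = "wanted", type = "categorical", level = "patient", block = "b",
         levels = c(1, 2, 3), beta = c(0.3, 0.6, -0.2),
         missing_code = 9, missing_fraction = 0.10),
    list(name = "public", type = "categorical", level = "facility",
         block = "m", levels = c(1, 2), beta = -0.5),
    list(name = "maternity", type = "categorical", level = "facility",
         block = "s", levels = c(1, 2), beta = -0.8),
    list(name = "method_count", type = "continuous", level = "facility",
         block = "s", beta = 0.2),
    list(name = "unmetneedfp", type = "continuous", level = "county",
         block = "q", beta = -0.3)
  )
}

#' Simulation configuration
#'
#' Dimensions, covariate plan, adjacency kind and allocation rule of the
#' synthetic nested ordinal dataset. Defaults are the study conditions the
#' generator emulates: 47 counties, 281 facilities, 2,568 patients.
#'
#' @param n_counties,n_facilities,n_patients positive sizes;
#'   `n_counties >= 2`, every facility belongs to exactly one county and
#'   every patient to exactly one facility.
#' @param covariates covariate plan, see [default_covariate_plan()].
#' @param adjacency_kind `"random-planar"` (default; irregular county-map
#'   analogue) or `"lattice"`.
#' @param structure random-effect structure the data are generated under.
#' @param county_sizes optional relative county sizes for facility
#'   allocation (default uniform).
#' @param facility_sizes optional relative facility sizes for patient
#'   allocation (default uniform).
#' @param seed integer master seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_counties = 47L, n_facilities = 281L,
                              n_patients = 2568L,
                              covariates = default_covariate_plan(),
                              adjacency_kind = c("random-planar", "lattice"),
                              structure = c("convolution", "unstructured",
                                            "structured", "none"),
                              county_sizes = NULL, facility_sizes = NULL,
                              seed = 1L) {
  if (n_counties < 2L) stop("n_counties must be at least 2")
  if (n_facilities < n_counties) {
    stop("need at least one facility per county (n_facilities >= n_counties)")
  }
  if (n_patients < n_facilities) {
    stop("need at least one patient per facility (n_patients >= n_facilities)")
  }
  structure(list(n_counties = as.integer(n_counties),
                 n_facilities = as.integer(n_facilities),
                 n_patients = as.integer(n_patients),
                 covariates = covariates,
                 adjacency_kind = match.arg(adjacency_kind),
                 structure = match.arg(structure),
                 county_sizes = county_sizes,
                 facility_sizes = facility_sizes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw ground-truth parameters and random effects for a configuration
#'
#' Coefficients and cutpoints come from the covariate plan and `kappa`;
#' random effects are realized from their generating distributions:
#' u ~ N(0, 1/tau_h) per county, f ~ N(0, 1/tau_v) per facility, phi from the
#' sum-to-zero intrinsic CAR with precision tau_c. Effects not used by the
#' configured structure are zero vectors of full length.
#'
#' Default precisions give county-unstructured sd 0.25, facility sd ~0.3 and
#' CAR marginal sd ~0.3 — modest area-level heterogeneity on the logit scale.
#' Default cutpoints (-0.19, 2.30) reproduce a 45/46/9 percent marginal
#' outcome mix at eta = 0.
#'
#' @param config a [simulation_config].
#' @param adjacency the [adjacency_structure] to draw the CAR effect on.
#' @param kappa interior cutpoints (length K - 1, increasing).
#' @param tau_h,tau_v,tau_c generating precisions.
#' @param facility_effects draw facility effects f (default) or set them to
#'   zero.
#' @return a [truth_record].
#' @export
make_truth <- function(config, adjacency, kappa = c(-0.19, 2.30),
                       tau_h = 16, tau_v = 10, tau_c = 8,
                       facility_effects = TRUE) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(config$seed, 101L))
  beta <- plan_beta(config$covariates)
  uses_u <- config$structure %in% c("unstructured", "convolution")
  uses_phi <- config$structure %in% c("structured", "convolution")
  M <- config$n_counties; J <- config$n_facilities
  u <- if (uses_u) stats::rnorm(M, 0, 1 / sqrt(tau_h)) else numeric(M)
  f <- if (facility_effects) stats::rnorm(J, 0, 1 / sqrt(tau_v)) else numeric(J)
  phi <- if (uses_phi) sample_car_effects(adjacency, tau_c) else numeric(M)
  truth_record(beta, cutpoint_set(kappa[1], diff(kappa)),
               tau_h = tau_h, tau_v = tau_v, tau_c = tau_c,
               u = u, f = f, phi = phi, seed = config$seed)
}

# coefficient vector implied by a covariate plan, with block labels
plan_beta <- function(plan) {
  beta <- numeric(0); blocks <- character(0)
  for (p in plan) {
    if (identical(p$type, "continuous")) {
      b <- p$beta; names(b) <- p$name
    } else {
      levs <- setdiff(p$levels, p$levels[1])
      if (!is.null(p$missing_code)) levs <- c(levs, p$missing_code)
      b <- p$beta
      if (length(b) != length(levs)) {
        stop("covariate ", p$name, ": need ", length(levs),
             " coefficients, got ", length(b))
      }
      names(b) <- paste0(p$name, "_", levs)
    }
    beta <- c(beta, b)
    blocks <- c(blocks, rep(p$block, length(b)))
  }
  attr(beta, "block") <- blocks
  beta
}

#' Generate a nested ordinal dataset from a configuration and ground truth
#'
#' Facilities are allocated to counties (and patients to facilities) by a
#' multinomial draw proportional to the configured sizes, after seeding each
#' county with one facility and each facility with one patient so every unit
#' is populated. Covariates are drawn at their declared level (continuous
#' values standardized at generation; categoricals uniform over levels, with
#' the configured fraction recoded to the missing category), dummy-expanded
#' against reference level 1, and the outcome is drawn from the exact
#' cumulative-logit category probabilities at
#' `eta = X beta + u[county] + f[facility] + phi[county]`.
#'
#' Generation is a pure function of `(config, truth)`: the same seed yields
#' the same dataset.
#'
#' @param config a [simulation_config].
#' @param truth a [truth_record] (see [make_truth()]).
#' @param adjacency optional [adjacency_structure]; generated from the
#'   config when omitted.
#' @return list with elements `dataset` (an [ordinal_dataset]), `truth`,
#'   `adjacency`, and `eta` (the latent linear predictor per patient).
#' @export
generate_dataset <- function(config, truth, adjacency = NULL) {
  if (is.null(adjacency)) {
    adjacency <- generate_adjacency(config$n_counties, config$adjacency_kind,
                                    seed = derive_seed(config$seed, 7L))
  }
  M <- config$n_counties; J <- config$n_facilities; n <- config$n_patients
  if (length(truth$u) != M || length(truth$phi) != M || length(truth$f) != J) {
    stop("truth dimensions inconsistent with config: u/phi must have length ",
         M, " and f length ", J)
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(config$seed, 211L))

  csize <- config$county_sizes %||% rep(1, M)
  fsize <- config$facility_sizes %||% rep(1, J)
  fac_county <- c(seq_len(M),
                  sample.int(M, J - M, replace = TRUE, prob = csize))
  pat_fac <- c(seq_len(J),
               sample.int(J, n - J, replace = TRUE, prob = fsize))
  pat_county <- fac_county[pat_fac]

  cols <- list(); blocks <- character(0)
  for (p in config$covariates) {
    n_units <- switch(p$level, patient = n, facility = J, county = M)
    if (identical(p$type, "continuous")) {
      v <- stats::rnorm(n_units)
      v <- as.numeric(scale(v))  # standardized at generation
      vp <- switch(p$level, patient = v, facility = v[pat_fac],
                   county = v[pat_county])
      cols[[p$name]] <- vp
      blocks <- c(blocks, p$block)
    } else {
      v <- sample(p$levels, n_units, replace = TRUE)
      if (!is.null(p$missing_code) && (p$missing_fraction %||% 0) > 0) {
        miss <- stats::runif(n_units) < p$missing_fraction
        v[miss] <- p$missing_code
      }
      vp <- switch(p$level, patient = v, facility = v[pat_fac],
                   county = v[pat_county])
      levs <- setdiff(p$levels, p$levels[1])
      if (!is.null(p$missing_code)) levs <- c(levs, p$missing_code)
      for (lev in levs) {
        cols[[paste0(p$name, "_", lev)]] <- as.numeric(vp == lev)
        blocks <- c(blocks, p$block)
      }
    }
  }
  X <- do.call(cbind, cols)
  if (!identical(colnames(X), names(truth$beta))) {
    stop("design columns do not match truth coefficients: ",
         paste(setdiff(c(colnames(X), names(truth$beta)),
                       intersect(colnames(X), names(truth$beta))),
               collapse = ", "))
  }
  eta <- as.numeric(X %*% truth$beta) + truth$u[pat_county] +
    truth$f[pat_fac] + truth$phi[pat_county]
  prob <- category_probabilities(eta, truth$cutpoints)
  y <- sample_categorical(prob)
  dataset <- ordinal_dataset(y, X, pat_fac, pat_county, blocks = blocks,
                             K = length(truth$cutpoints$kappa) + 1L)
  list(dataset = dataset, truth = truth, adjacency = adjacency, eta = eta)
}

#' Write a ground-truth record as JSON
#' @param truth a [truth_record].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(beta = as.list(stats::setNames(as.numeric(truth$beta),
                                        names(truth$beta))),
         blocks = attr(truth$beta, "block"),
         g1 = truth$cutpoints$g1, g2 = truth$cutpoints$g2,
         kappa = truth$cutpoints$kappa,
         tau_h = truth$tau_h, tau_v = truth$tau_v, tau_c = truth$tau_c,
         u = truth$u, f = truth$f, phi = truth$phi, seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth record from JSON
#' @param path JSON path.
#' @return a [truth_record].
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(obj$beta)
  attr(beta, "block") <- obj$blocks
  truth_record(beta, cutpoint_set(obj$g1, obj$g2),
               tau_h = obj$tau_h, tau_v = obj$tau_v, tau_c = obj$tau_c,
               u = obj$u %||% numeric(0), f = obj$f %||% numeric(0),
               phi = obj$phi %||% numeric(0), seed = obj$seed)
}
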