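#' Screen candidate covariates by bivariate credible interval
#'
#' Fits one bivariate hierarchical model per candidate (county unstructured +
#' facility random effects, the Model-0 analogue of the workflow this package
#' implements) and retains candidates whose equal-tailed credible interval
#' for the odds ratio at the screening level excludes 1 for at least one of
#' the candidate's design columns. Forced-in covariates are always retained,
#' with reason `"forced"`.
#'
#' @param dataset an [ordinal_dataset].
#' @param candidates character vector of covariate base names or design
#'   column names; a base name `v` matches columns `v` and `v_<level>`.
#' @param adjacency unused by the unstructured screening model; accepted for
#'   interface symmetry.
#' @param level screening credibility level in (0, 1), default 0.85.
#' @param forced covariates retained regardless of their interval.
#' @param config an [mcmc_config] for the bivariate fits (default: the
#'   bivariate settings of the study design, 1000 retained / 1000 burn-in /
#'   thin 10).
#' @param facility_effects include facility effects in the screening model.
#' @return data frame with one row per candidate column: `candidate`,
#'   `column`, `or_median`, `or_lower`, `or_upper`, `retained`, `reason`;
#'   attribute `selected` holds the retained candidate names.
#' @export
screen_covariates <- function(dataset, candidates, adjacency = NULL,
                              level = 0.85, forced = character(0),
                              config = mcmc_config(n_draws = 1000L,
                                                   burnin = 1000L,
                                                   thinning = 10L),
                              facility_effects = TRUE) {
  stopifnot(level > 0, level < 1)
  cols_of <- function(cand) {
    cn <- colnames(dataset$X)
    hit <- cn[cn == cand | startsWith(cn, paste0(cand, "_"))]
    if (!length(hit)) stop("candidate not found in dataset: ", cand)
    hit
  }
  rows <- list()
  selected <- character(0)
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    cols <- cols_of(cand)
    spec <- model_spec("unstructured", covariates = cols,
                       facility_effects = facility_effects)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 1000L + k)
    fit <- run_mcmc(dataset, adjacency = NULL, spec = spec, config = cfg)
    sm <- summarize_draws(fit, levels = level)
    lo <- sm[[sprintf("or_l%02.0f", 100 * level)]]
    hi <- sm[[sprintf("or_u%02.0f", 100 * level)]]
    excludes <- lo > 1 | hi < 1
    retained <- any(excludes) || cand %in% forced
    reason <- if (any(excludes)) "credible"
              else if (cand %in% forced) "forced" else "not selected"
    if (retained) selected <- c(selected, cand)
    rows[[k]] <- data.frame(candidate = cand, column = sm$parameter,
                            or_median = sm$or_median, or_lower = lo,
                            or_upper = hi, retained = retained,
                            reason = reason)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selected") <- selected
  attr(out, "level") <- level
  out
}

#' Fit the unstructured / structured / convolution model sequence
#'
#' Fits the three multivariable random-effect structures on identical data
#' and seed, summarizes each as odds ratios with credible intervals, computes
#' each DIC, and flags the lowest-DIC structure.
#'
#' @param dataset an [ordinal_dataset] (already restricted to the screened
#'   covariates, or use `covariates`).
#' @param adjacency an [adjacency_structure] for the spatial structures.
#' @param spec_base a [model_spec] carrying covariates, the facility-effect
#'   switch and the prior; its `structure` field is overridden per fit.
#' @param config an [mcmc_config]; the same seed is used for every structure.
#' @param structures structures to fit, in order.
#' @return an object of class `model_sequence`: `fits` (named
#'   [run_mcmc()] results), `summaries`, `dic` (data frame), `best`
#'   (structure name), and `table` (one row per covariate, one OR/SD/CrI
#'   column block per model).
#' @export
fit_model_sequence <- function(dataset, adjacency, spec_base = model_spec(),
                               config = mcmc_config(),
                               structures = c("unstructured", "structured",
                                              "convolution")) {
  if (!is.null(spec_base$covariates)) {
    # restrict once so the fits and the DIC plug-in see the same columns
    blocks <- (attr(dataset$X, "block") %||%
                 rep("b", ncol(dataset$X)))[match(spec_base$covariates,
                                                  colnames(dataset$X))]
    dataset <- ordinal_dataset(
      dataset$y, dataset$X[, spec_base$covariates, drop = FALSE],
      dataset$facility, dataset$county, weight = dataset$weight,
      K = dataset$K, blocks = blocks)
    spec_base$covariates <- NULL
  }
  fits <- list(); summaries <- list(); dics <- list()
  for (st in structures) {
    spec <- spec_base
    spec$structure <- st
    fits[[st]] <- run_mcmc(dataset,
                           adjacency = if (uses_phi(st)) adjacency else NULL,
                           spec = spec, config = config)
    summaries[[st]] <- summarize_draws(fits[[st]])
    dics[[st]] <- compute_dic(fits[[st]], dataset)
  }
  dic <- data.frame(structure = structures,
                    D_bar = vapply(dics, `[[`, numeric(1), "D_bar"),
                    D_at_mean = vapply(dics, `[[`, numeric(1), "D_at_mean"),
                    pD = vapply(dics, `[[`, numeric(1), "pD"),
                    DIC = vapply(dics, `[[`, numeric(1), "DIC"))
  rownames(dic) <- NULL
  best <- structures[which.min(dic$DIC)]
  tab <- summaries[[1]][, "parameter", drop = FALSE]
  for (st in structures) {
    s <- summaries[[st]]
    tab[[paste0(st, "_or")]] <- s$or_mean
    tab[[paste0(st, "_sd")]] <- s$or_sd
    tab[[paste0(st, "_l95")]] <- s$or_l95
    tab[[paste0(st, "_u95")]] <- s$or_u95
  }
  structure(list(fits = fits, summaries = summaries, dic = dic,
                 best = best, table = tab),
            class = "model_sequence")
}

#' @export
print.model_sequence <- function(x, ...) {
  cat("Model sequence (lowest DIC flagged):\n")
  d <- x$dic
  d$best <- ifelse(d$structure == x$best, "<-- lowest DIC", "")
  print(d, row.names = FALSE)
  invisible(x)
}

#' Posterior county-effect surface for mapping
#'
#' Per county, the posterior mean and median of the odds multiplier
#' `exp(u + phi)` (the spatially structured plus unstructured county effect
#' on the odds of a more effective contraceptive category), with an
#' equal-tailed credible interval. Requires draws from a structured or
#' convolution fit.
#'
#' @param draws a [run_mcmc()] result with `structure` `"structured"` or
#'   `"convolution"`.
#' @param adjacency optional [adjacency_structure] supplying county labels.
#' @param geometry optional named list of polygons (two-column coordinate
#'   matrices keyed by county id); when supplied, a GeoJSON file with the
#'   multipliers as properties can be written via [write_county_geojson()].
#' @param level credibility level of the interval.
#' @return a `county_effect_surface` data frame: `county_id`,
#'   `mean_multiplier`, `median_multiplier`, `lower`, `upper`.
#' @export
export_county_effects <- function(draws, adjacency = NULL, geometry = NULL,
                                  level = 0.95) {
  if (!uses_phi(draws$spec$structure)) {
    stop("county-effect surfaces require a structured or convolution fit, ",
         "not structure \"", draws$spec$structure, "\"")
  }
  phim <- do.call(rbind, lapply(draws$chains, `[[`, "phi"))
  um <- do.call(rbind, lapply(draws$chains, `[[`, "u"))
  if (is.null(um) || ncol(um) == 0L) um <- matrix(0, nrow(phim), ncol(phim))
  mult <- exp(um + phim)
  ids <- if (!is.null(adjacency)) adjacency$county_ids
         else as.character(seq_len(ncol(mult)))
  q <- apply(mult, 2L, stats::quantile,
             probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  out <- data.frame(county_id = ids,
                    mean_multiplier = colMeans(mult),
                    median_multiplier = apply(mult, 2L, stats::median),
                    lower = q[1L, ], upper = q[2L, ])
  rownames(out) <- NULL
  class(out) <- c("county_effect_surface", "data.frame")
  attr(out, "level") <- level
  attr(out, "geometry") <- geometry
  out
}

#' Write a county-effect surface as GeoJSON
#'
#' One polygon feature per county with the posterior multiplier columns as
#' properties.
#'
#' @param surface a [export_county_effects()] result.
#' @param geometry named list of two-column polygon coordinate matrices,
#'   keyed by county id (defaults to the geometry attached to `surface`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_county_geojson <- function(surface, geometry = NULL, path) {
  geometry <- geometry %||% attr(surface, "geometry")
  if (is.null(geometry)) stop("no polygon geometry supplied")
  features <- lapply(seq_len(nrow(surface)), function(i) {
    id <- as.character(surface$county_id[i])
    poly <- geometry[[id]]
    if (is.null(poly)) stop("no polygon for county ", id)
    poly <- as.matrix(poly)
    if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
    list(type = "Feature",
         properties = list(county_id = id,
                           mean_multiplier = surface$mean_multiplier[i],
                           median_multiplier = surface$median_multiplier[i],
                           lower = surface$lower[i], upper = surface$upper[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(poly)),
                                                   function(r) poly[r, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis workflow from a configuration file
#'
#' Orchestrates the end-to-end workflow: load or simulate the dataset and
#' adjacency; compute and normalize survey weights; weighted descriptive
#' tabulation of the outcome; bivariate covariate screening; the
#' unstructured / structured / convolution model sequence with DIC
#' comparison; and the posterior county-effect surface from the best spatial
#' fit. All artifacts are written under one output directory with a
#' machine-readable manifest (file names and MD5 checksums), fully
#' reproducible from `(config, seed)`.
#'
#' @param config path to a YAML or JSON configuration file, or an equivalent
#'   named list. Recognized fields: `seed`; `output_dir`; `simulate` (a list
#'   of [simulation_config()] arguments) or `dataset`/`adjacency` paths;
#'   `survey` (list with `ps`, `pr` or frame/sample/respondent counts);
#'   `candidates`; `forced`; `screening` (list: `level`, `n_draws`, `burnin`,
#'   `thinning`); `mcmc` (list: `n_draws`, `burnin`, `thinning`, `n_chains`);
#'   `structures`.
#' @param output_dir overrides the config's output directory (default: a
#'   timestamped directory under the working directory).
#' @return list with the per-stage results and `manifest` (invisible files
#'   written under `output_dir`).
#' @export
run_full_analysis <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_analysis_config(config) else config
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- output_dir %||% cfg$output_dir %||%
    paste0("spordinal-run-", format(Sys.time(), "%Y%m%d-%H%M%S"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("analysis stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("data", {
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      args$seed <- args$seed %||% seed
      sc <- do.call(simulation_config, args)
      adjacency <- generate_adjacency(sc$n_counties, sc$adjacency_kind,
                                      seed = derive_seed(sc$seed, 7L))
      truth <- make_truth(sc, adjacency)
      sim <- generate_dataset(sc, truth, adjacency)
      write_ordinal_csv(sim$dataset, file.path(out_dir, "dataset.csv"))
      write_adjacency_json(adjacency, file.path(out_dir, "adjacency.json"))
      write_truth_json(truth, file.path(out_dir, "truth.json"))
      list(dataset = sim$dataset, adjacency = adjacency, truth = truth)
    } else {
      dataset <- read_ordinal_csv(cfg$dataset)
      adjacency <- if (!is.null(cfg$adjacency)) read_adjacency_json(cfg$adjacency)
      list(dataset = dataset, adjacency = adjacency, truth = NULL)
    }
  })
  dataset <- inputs$dataset
  adjacency <- inputs$adjacency

  weights <- stage("weights", {
    if (!is.null(cfg$survey)) {
      sv <- cfg$survey
      sw <- if (!is.null(sv$ps)) compute_sampling_weight(sv$ps, sv$pr)
            else survey_design(sv$n_frame, sv$n_sampled, sv$n_responded)$sw
      w <- normalize_weights(rep(sw, dataset$n))
      dataset$weight <- w
      w
    } else dataset$weight
  })

  descriptives <- stage("descriptives", {
    tab <- weighted_tabulate(dataset, "outcome")
    write_tabulation_csv(tab, file.path(out_dir, "descriptives_outcome.csv"))
    tab
  })

  candidates <- cfg$candidates %||% unique(sub("_[^_]+$", "",
                                               colnames(dataset$X)))
  forced <- as.character(cfg$forced %||% character(0))
  scr_cfg <- cfg$screening %||% list()
  screening <- stage("screening", {
    sc <- screen_covariates(
      dataset, candidates, level = scr_cfg$level %||% 0.85, forced = forced,
      config = mcmc_config(n_draws = scr_cfg$n_draws %||% 1000L,
                           burnin = scr_cfg$burnin %||% 1000L,
                           thinning = scr_cfg$thinning %||% 10L,
                           seed = derive_seed(seed, 2L)))
    utils::write.csv(sc, file.path(out_dir, "screening.csv"),
                     row.names = FALSE)
    sc
  })
  selected <- attr(screening, "selected")
  sel_cols <- colnames(dataset$X)[
    colnames(dataset$X) %in% selected |
      sub("_[^_]+$", "", colnames(dataset$X)) %in% selected]
  if (!length(sel_cols)) sel_cols <- colnames(dataset$X)

  mc <- cfg$mcmc %||% list()
  sequence <- stage("model_sequence", {
    fs <- fit_model_sequence(
      dataset, adjacency,
      spec_base = model_spec(covariates = sel_cols, forced = character(0)),
      config = mcmc_config(n_draws = mc$n_draws %||% 1000L,
                           burnin = mc$burnin %||% 1000L,
                           thinning = mc$thinning %||% 1L,
                           n_chains = mc$n_chains %||% 1L,
                           seed = derive_seed(seed, 3L)),
      structures = cfg$structures %||% c("unstructured", "structured",
                                         "convolution"))
    utils::write.csv(fs$table, file.path(out_dir, "model_table.csv"),
                     row.names = FALSE)
    utils::write.csv(fs$dic, file.path(out_dir, "dic.csv"), row.names = FALSE)
    fs
  })

  surface <- stage("county_surface", {
    spatial <- if (uses_phi(sequence$best)) sequence$best else "convolution"
    srf <- export_county_effects(sequence$fits[[spatial]], adjacency)
    utils::write.csv(srf, file.path(out_dir, "county_effects.csv"),
                     row.names = FALSE)
    srf
  })

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    seed = seed, created_from = if (is.character(config)) config else "list",
    selected = selected, best_structure = sequence$best,
    files = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(dataset = dataset, adjacency = adjacency,
                 truth = inputs$truth, weights = weights,
                 descriptives = descriptives, screening = screening,
                 sequence = sequence, surface = surface,
                 manifest = manifest, output_dir = out_dir))
}

#' Read an analysis configuration file (YAML or JSON)
#' @param path file path; format chosen by extension.
#' @return a named list.
#' @export
read_analysis_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
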