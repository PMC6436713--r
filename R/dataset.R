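#' Patient-level ordinal dataset
#'
#' The analysis container: one row per patient with an ordinal outcome in
#' 1..K (for the contraceptive-uptake study K = 3: 1 = no method,
#' 2 = less-effective method, 3 = highly effective method), a dummy-expanded
#' fixed-effect design matrix, facility and county membership indices, and an
#' optional positive survey weight per patient.
#'
#' The design matrix may not contain a constant column: the model has no
#' intercept because the cutpoints absorb it, so a constant column would be
#' unidentified.
#'
#' @param y integer outcome vector, values in 1..K.
#' @param X numeric design matrix, dummy-expanded, no constant column. Column
#'   block labels ("b", "s", "q", "m") may be supplied via `blocks`.
#' @param facility integer facility index per patient (1..J).
#' @param county integer county index per patient (1..M).
#' @param weight optional positive weight per patient (default 1).
#' @param K number of outcome categories (default `max(y)`, at least 2).
#' @param blocks optional character vector of per-column block labels.
#' @return an object of class `ordinal_dataset`.
#' @export
ordinal_dataset <- function(y, X, facility, county, weight = NULL, K = NULL,
                            blocks = NULL) {
  y <- as.integer(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  if (nrow(X) != n || length(facility) != n || length(county) != n) {
    stop("y, X, facility and county must have one entry per patient")
  }
  K <- K %||% max(y, 2L)
  if (n > 0L && (any(y < 1L) || any(y > K))) {
    stop("outcome values must lie in 1..", K)
  }
  if (any(is.na(X))) stop("X may not contain missing values")
  facility <- as.integer(facility)
  county <- as.integer(county)
  if (n > 0L && (any(facility < 1L) || any(county < 1L))) {
    stop("facility and county indices must be >= 1")
  }
  if (is.null(weight)) weight <- rep(1, n)
  if (any(weight <= 0)) stop("weights must be strictly positive")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(blocks)) {
    if (length(blocks) != ncol(X)) stop("one block label per design column")
    attr(X, "block") <- as.character(blocks)
  }
  structure(list(y = y, X = X, facility = facility, county = county,
                 weight = as.numeric(weight), K = as.integer(K), n = n,
                 n_facilities = if (n) max(facility) else 0L,
                 n_counties = if (n) max(county) else 0L),
            class = "ordinal_dataset")
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat("Ordinal dataset:", x$n, "patients,", x$n_facilities, "facilities,",
      x$n_counties, "counties,", x$K, "outcome categories\n")
  cat("Covariates:", paste(colnames(x$X), collapse = ", "), "\n")
  if (x$n) {
    tab <- table(factor(x$y, levels = seq_len(x$K)))
    cat("Outcome counts:", paste(sprintf("%d:%d", seq_len(x$K), tab),
                                 collapse = "  "), "\n")
  }
  invisible(x)
}

# full-precision numeric formatting so CSV round-trips are bit-identical
.fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15, sprintf("%.0f", x),
         sprintf("%.17g", x))
}

#' Write an ordinal dataset as delimited text
#'
#' Columns: `outcome`, one column per covariate, `facility_id`, `county_id`,
#' `weight`. Numerics are written at full precision so that
#' [read_ordinal_csv()] reproduces the dataset bit-identically.
#'
#' @param dataset an [ordinal_dataset].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ordinal_csv <- function(dataset, path) {
  df <- data.frame(outcome = dataset$y, check.names = FALSE)
  for (j in seq_len(ncol(dataset$X))) {
    df[[colnames(dataset$X)[j]]] <- .fmt_num(dataset$X[, j])
  }
  df$facility_id <- dataset$facility
  df$county_id <- dataset$county
  df$weight <- .fmt_num(dataset$weight)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ordinal dataset written by [write_ordinal_csv()]
#'
#' @param path CSV path.
#' @param blocks optional per-covariate block labels, or a schema list as
#'   produced by [read_covariate_schema()].
#' @param K number of outcome categories (default inferred).
#' @return an [ordinal_dataset].
#' @export
read_ordinal_csv <- function(path, blocks = NULL, K = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  fixed <- c("outcome", "facility_id", "county_id", "weight")
  covs <- setdiff(names(df), fixed)
  X <- as.matrix(df[, covs, drop = FALSE])
  # no intercept in this model (the cutpoints absorb it), so a constant
  # column can only be a data error
  if (nrow(X) > 1L) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant covariate column(s) in ", path, ": ",
           paste(covs[sds == 0], collapse = ", "))
    }
  }
  ordinal_dataset(df$outcome, X, df$facility_id, df$county_id,
                  weight = df$weight, K = K, blocks = blocks)
}

#' Read a covariate schema (JSON)
#'
#' The schema declares, per covariate, its prior block (`b`, `s`, `q` or
#' `m`), its level (`patient`, `facility`, `county`), its type
#' (`categorical` or `continuous`) and, for categoricals, the reference
#' category. Used to assign block-specific priors and to dummy-expand raw
#' (unexpanded) data files.
#'
#' @param path JSON file path.
#' @return a named list of covariate descriptors.
#' @export
read_covariate_schema <- function(path) {
  sch <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(sch)) sch <- split(sch, seq_len(nrow(sch)))
  sch
}

#' Dummy-expand a raw covariate data frame according to a schema
#'
#' Categorical covariates become one indicator column per non-reference level,
#' named `<var>_<level>` (the coding of the field's standard model files,
#' with a reference level of 1 and a distinct code for missing-as-category
#' levels). Continuous covariates pass through unchanged.
#'
#' @param df data frame of raw covariate columns.
#' @param schema list of descriptors: each with `name`, `type`, `block`, and
#'   for categoricals `reference` (default 1).
#' @return list with the expanded numeric `X` matrix and `blocks` labels.
#' @export
expand_covariates <- function(df, schema) {
  cols <- list(); blocks <- character(0)
  for (sc in schema) {
    v <- df[[sc$name]]
    if (is.null(v)) stop("covariate not found in data: ", sc$name)
    if (identical(sc$type, "continuous")) {
      cols[[sc$name]] <- as.numeric(v)
      blocks <- c(blocks, sc$block)
    } else {
      ref <- sc$reference %||% 1
      for (lev in setdiff(sort(unique(v)), ref)) {
        cols[[paste0(sc$name, "_", lev)]] <- as.numeric(v == lev)
        blocks <- c(blocks, sc$block)
      }
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, blocks = blocks)
}
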