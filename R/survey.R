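#' Facility survey design
#'
#' Records the sampling frame, the drawn sample and the responding sample of
#' facilities, together with the implied sampling fraction `ps`, response
#' rate `pr`, and raw design weight `sw = 1 / (ps * pr)`.
#'
#' @param n_frame facilities in the sampling frame.
#' @param n_sampled facilities drawn.
#' @param n_responded facilities that responded.
#' @param strata optional stratum label per responding facility.
#' @return an object of class `survey_design` with fields `ps`, `pr`, `sw`.
#' @examples
#' d <- survey_design(n_frame = 2838, n_sampled = 350, n_responded = 328)
#' d$sw
#' @export
survey_design <- function(n_frame, n_sampled, n_responded, strata = NULL) {
  stopifnot(n_frame >= n_sampled, n_sampled >= n_responded, n_responded > 0)
  ps <- n_sampled / n_frame
  pr <- n_responded / n_sampled
  structure(list(n_frame = n_frame, n_sampled = n_sampled,
                 n_responded = n_responded, ps = ps, pr = pr,
                 sw = compute_sampling_weight(ps, pr), strata = strata),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("Survey design: %d frame, %d sampled (ps = %.4f), %d responded (pr = %.4f)\n",
              x$n_frame, x$n_sampled, x$ps, x$n_responded, x$pr))
  cat(sprintf("Raw sampling weight sw = 1/(ps*pr) = %.4f\n", x$sw))
  invisible(x)
}

#' Facility sampling weight
#'
#' The raw design weight is the reciprocal of the product of the sampling
#' fraction and the response rate, `sw = 1 / (ps * pr)`.
#'
#' @param ps sampling fraction, in (0, 1].
#' @param pr response rate, in (0, 1].
#' @return the weight `1 / (ps * pr)`.
#' @examples
#' compute_sampling_weight(0.1233, 0.94)  # ~8.628
#' @export
compute_sampling_weight <- function(ps, pr) {
  if (!is.numeric(ps) || !is.numeric(pr) || any(ps <= 0) || any(ps > 1) ||
      any(pr <= 0) || any(pr > 1)) {
    stop("ps and pr must be fractions in (0, 1]")
  }
  1 / (ps * pr)
}

#' Normalize survey weights to mean one
#'
#' Rescales weights so they average 1 over the analysis sample (their sum
#' equals the number of rows), preserving all weight ratios — including
#' within-stratum ratios. Idempotent.
#'
#' @param weights positive weight vector.
#' @param strata optional stratum label per row (validated to cover all rows;
#'   normalization itself is a single global rescaling).
#' @return normalized weight vector, mean exactly 1.
#' @examples
#' normalize_weights(c(2, 2, 4, 4))  # 0.667 0.667 1.333 1.333
#' @export
normalize_weights <- function(weights, strata = NULL) {
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be strictly positive and finite")
  }
  if (!is.null(strata)) {
    if (length(strata) != length(weights)) {
      stop("strata labels must cover every row")
    }
    if (anyNA(strata)) stop("strata labels may not be missing")
  }
  weights * length(weights) / sum(weights)
}

#' Weighted percentage tabulation
#'
#' Percentage distribution of a variable, optionally within the cells of a
#' `by` variable, using the dataset's survey weights (percentages within each
#' `by` cell sum to 100). With unit weights this equals the raw frequency
#' table.
#'
#' @param dataset an [ordinal_dataset], or a data frame with a `weight`
#'   column (weights default to 1 when absent).
#' @param variable name of the column to tabulate (`"outcome"` tabulates the
#'   ordinal outcome of an [ordinal_dataset]).
#' @param by optional name of a grouping column.
#' @param levels optional vector of levels to report (default: observed
#'   levels; for the outcome, 1..K so empty categories report 0%).
#' @return data frame with columns `variable`, `level`, `by_level`,
#'   `weighted_pct`, `unweighted_n`.
#' @export
weighted_tabulate <- function(dataset, variable, by = NULL, levels = NULL) {
  if (inherits(dataset, "ordinal_dataset")) {
    df <- data.frame(outcome = dataset$y, facility_id = dataset$facility,
                     county_id = dataset$county, weight = dataset$weight)
    df <- cbind(df, as.data.frame(dataset$X))
    if (is.null(levels) && identical(variable, "outcome")) {
      levels <- seq_len(dataset$K)
    }
  } else {
    df <- as.data.frame(dataset)
    if (is.null(df$weight)) df$weight <- 1
  }
  if (!variable %in% names(df)) stop("unknown variable: ", variable)
  if (!is.null(by) && !by %in% names(df)) stop("unknown by-variable: ", by)
  v <- df[[variable]]
  lv <- levels %||% sort(unique(v))
  g <- if (is.null(by)) rep("all", nrow(df)) else df[[by]]
  out <- do.call(rbind, lapply(sort(unique(g)), function(cell) {
    sel <- g == cell
    wsum <- vapply(lv, function(l) sum(df$weight[sel & v == l]), numeric(1))
    data.frame(variable = variable, level = lv,
               by_level = if (is.null(by)) NA_character_ else as.character(cell),
               weighted_pct = 100 * wsum / sum(df$weight[sel]),
               unweighted_n = vapply(lv, function(l) sum(sel & v == l),
                                     numeric(1)))
  }))
  rownames(out) <- NULL
  out
}

#' Write a tabulation as CSV
#' @param table output of [weighted_tabulate()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_tabulation_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
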