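# Global sensitivity analysis: Latin hypercube sampling of the model
# parameters and partial rank correlation coefficients (PRCC) against the
# simulation outputs, with false-discovery-rate corrected significance.

#' Latin hypercube sample of the parameter space
#'
#' Stratified-uniform sample: each parameter's range is divided into `k`
#' equal strata and exactly one draw falls in each stratum, with independent
#' random permutations across parameters.
#'
#' @param ranges Tibble with `parameter`, `low`, `high` (and optionally
#'   `integer`) columns; defaults to the 17-parameter table of
#'   [param_ranges].
#' @param k Number of samples.
#' @param seed Seed for the design.
#' @return An `lhs_design`: a `k x j` tibble of sampled values, with the
#'   ranges stored in the `"ranges"` attribute.
#' @export
lhs_sample <- function(ranges = param_ranges(), k = 2000L, seed = 1L) {
  stopifnot(k >= 2L, all(ranges$low < ranges$high))
  set.seed(seed)
  u <- lhs::randomLHS(k, nrow(ranges))
  m <- sweep(u, 2L, ranges$high - ranges$low, "*")
  m <- sweep(m, 2L, ranges$low, "+")
  colnames(m) <- ranges$parameter
  out <- tibble::as_tibble(m)
  if ("integer" %in% names(ranges)) {
    for (p in ranges$parameter[ranges$integer])
      out[[p]] <- round(out[[p]])
  }
  attr(out, "ranges") <- ranges
  class(out) <- c("lhs_design", class(out))
  out
}

# rank-transform then residualize on the remaining columns; the PRCC is the
# correlation of the two residual vectors
prcc_one <- function(R, ry, j) {
  others <- R[, -j, drop = FALSE]
  X <- cbind(1, others)
  qx <- qr(X)
  res_t <- qr.resid(qx, R[, j])
  res_y <- qr.resid(qx, ry)
  if (stats::sd(res_t) == 0 || stats::sd(res_y) == 0) return(NA_real_)
  stats::cor(res_t, res_y)
}

#' Partial rank correlation coefficients
#'
#' PRCC between each design column and an output: all columns and the output
#' are rank-transformed, the target column and the output are each
#' residualized by least squares on the remaining columns, and the
#' coefficient is the correlation of the residuals.  The p-value comes from
#' the t statistic with `k - j - 1` degrees of freedom (`j` = number of
#' parameters).  Constant outputs yield `NA` coefficients with a warning.
#'
#' @param design A design matrix/tibble (`k x j`) of sampled parameters.
#' @param output Numeric vector of length `k` with one model output per
#'   design row.
#' @return A tibble with `parameter`, `estimate`, `statistic`, `p.value`.
#' @export
prcc <- function(design, output) {
  X <- as.matrix(design)
  k <- nrow(X); j <- ncol(X)
  stopifnot(length(output) == k, k > j + 2L)
  if (stats::sd(output) == 0) {
    warning("constant output: PRCC undefined")
    return(tibble::tibble(parameter = colnames(X), estimate = NA_real_,
                          statistic = NA_real_, p.value = NA_real_))
  }
  R <- apply(X, 2L, rank)
  ry <- rank(output)
  est <- vapply(seq_len(j), function(i) prcc_one(R, ry, i), numeric(1))
  df <- k - j - 1L
  tstat <- est * sqrt(df / pmax(1 - est^2, .Machine$double.eps))
  tibble::tibble(parameter = colnames(X), estimate = est, statistic = tstat,
                 p.value = 2 * stats::pt(-abs(tstat), df))
}

#' Global sensitivity study
#'
#' For each row of a Latin hypercube design, runs replicated simulations (or
#' any user-supplied simulator), averages the replicates, extracts the five
#' outputs of interest — lumen area, intima area and the intimal SMC, ECM
#' and MP contents — at each horizon, and computes the PRCC of every
#' (parameter, output, horizon) triple with Benjamini-Hochberg FDR-corrected
#' significance at level 0.05 per horizon.
#'
#' @param design An [lhs_sample] design over (a subset of) [param_ranges].
#' @param scenario_template Scenario run at every design point (default: the
#'   most general configuration — non-symmetric inputs with macrophage and
#'   chemoattractant events active).
#' @param tl A [timeline].
#' @param reps_per_sample Replicates averaged per design row.
#' @param horizons Hours at which outputs are extracted.
#' @param seed Base seed.
#' @param simulator Optional override: `function(params, seed)` returning a
#'   series tibble with the columns used above (for oracle tests and planted
#'   signals).
#' @param ... Geometry arguments passed to [run_simulation] (e.g. a reduced
#'   `spec`).
#' @return A `prcc_result` tibble: `parameter`, `output`, `horizon`,
#'   `estimate`, `statistic`, `p.value`, `p.adjusted`, `significant`; raw
#'   per-sample outputs in attribute `"outputs"`, failures in `"failures"`.
#' @export
sensitivity_study <- function(design,
                              scenario_template = build_scenario(14),
                              tl = timeline(), reps_per_sample = 3L,
                              horizons = c(168L, 672L), seed = 1L,
                              simulator = NULL, ...) {
  outputs_of <- function(series, h) {
    # after occlusion the series ends early; carry the last state forward
    row <- if (any(series$t == h)) which(series$t == h) else nrow(series)
    unlist(series[row, c("lumen_area", "intima_area", "intima_smc",
                         "intima_ecm", "intima_mp")])
  }
  if (is.null(simulator)) {
    simulator <- function(p, s)
      run_simulation(scenario_template, params = p, tl = tl, seed = s,
                     snapshot_times = integer(0), ...)$series
  }
  base <- param_midpoints()
  k <- nrow(design)
  out_names <- c("lumen_area", "intima_area", "intima_smc", "intima_ecm",
                 "intima_mp")
  res <- array(NA_real_, c(k, length(out_names), length(horizons)))
  failures <- integer(0)
  for (i in seq_len(k)) {
    p <- do.call(parameter_set,
                 utils::modifyList(unclass(base), as.list(design[i, ])))
    acc <- matrix(0, length(out_names), length(horizons))
    ok <- 0L
    for (r in seq_len(reps_per_sample)) {
      s <- tryCatch(simulator(p, seed + (i - 1L) * reps_per_sample + r),
                    error = function(e) NULL)
      if (is.null(s)) next
      for (hi in seq_along(horizons))
        acc[, hi] <- acc[, hi] + outputs_of(s, horizons[hi])
      ok <- ok + 1L
    }
    if (ok == 0L) { failures <- c(failures, i); next }
    res[i, , ] <- acc / ok
  }
  keep <- setdiff(seq_len(k), failures)
  tab <- purrr::map_dfr(seq_along(horizons), function(hi) {
    purrr::map_dfr(seq_along(out_names), function(oi) {
      dplyr::mutate(
        prcc(design[keep, , drop = FALSE], res[keep, oi, hi]),
        output = out_names[oi], horizon = horizons[hi], .after = "parameter")
    })
  })
  tab <- dplyr::group_by(tab, .data$horizon)
  tab <- dplyr::mutate(tab,
                       p.adjusted = stats::p.adjust(.data$p.value, "BH"),
                       significant = .data$p.adjusted < 0.05)
  tab <- dplyr::ungroup(tab)
  attr(tab, "outputs") <- res
  attr(tab, "failures") <- failures
  class(tab) <- c("prcc_result", class(tab))
  tab
}
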