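#' Fixed-effect inverse-variance pooling
#'
#' Pools per-cohort log-scale effects (log hazard ratios or log odds ratios)
#' with weights `w_k = 1/se_k^2`: the pooled estimate is
#' `sum(est_k * w_k) / sum(w_k)` with standard error `1/sqrt(sum(w_k))`, a
#' two-sided normal z-test for the overall effect, and Cochran's Q /
#' Higgins' I^2 for heterogeneity.
#'
#' @param effects a data frame of per-cohort effects with columns `estimate`
#'   and `se` (> 0), e.g. `rbind`-ed rows from [fit_cox_univariate()] or
#'   [fit_logistic_univariate()]; a `cohort_id` column names the weights.
#' @return Object of class `meta_result`: `pooled`, `se`, `z`, `p`, `tau2`,
#'   `Q`, `I2`, `K`, `weights` (normalized, summing to 1), `model`.
#' @export
pool_fixed <- function(effects) {
  eff <- as.data.frame(effects)
  stopifnot(all(c("estimate", "se") %in% names(eff)))
  est <- eff$estimate; se <- eff$se
  if (any(!is.finite(est)) || any(!is.finite(se)) || any(se <= 0))
    stop("all estimates finite and all se > 0 required", call. = FALSE)
  K <- length(est)
  w <- 1 / se^2
  pooled <- sum(est * w) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  Q <- sum(w * (est - pooled)^2)
  I2 <- if (Q > 0) max(0, (Q - (K - 1)) / Q) else 0
  wn <- w / sum(w)
  names(wn) <- eff$cohort_id %||% paste0("study", seq_len(K))
  structure(list(pooled = pooled, se = pooled_se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 tau2 = 0, Q = Q, I2 = I2, K = K,
                 weights = wn, model = "fixed"), class = "meta_result")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Estimates the between-study variance by the moment (DL) estimator
#' `tau2 = max(0, (Q - (K - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w_k = 1/se_k^2`, then pools with random-effects
#' weights `1/(se_k^2 + tau2)`. A single study has `tau2 = 0` and returns its
#' own estimate. The random-effects standard error is never smaller than the
#' fixed-effect one.
#'
#' @inheritParams pool_fixed
#' @return A `meta_result` with `model = "random"` and the DL `tau2`.
#' @export
pool_dersimonian_laird <- function(effects) {
  fx <- pool_fixed(effects)
  eff <- as.data.frame(effects)
  est <- eff$estimate; se <- eff$se
  K <- fx$K
  tau2 <- 0
  if (K >= 2) {
    w <- 1 / se^2
    C <- sum(w) - sum(w^2) / sum(w)
    if (C > 0) tau2 <- max(0, (fx$Q - (K - 1)) / C)
  }
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(est * wr) / sum(wr)
  pooled_se <- 1 / sqrt(sum(wr))
  z <- pooled / pooled_se
  wn <- wr / sum(wr)
  names(wn) <- names(fx$weights)
  structure(list(pooled = pooled, se = pooled_se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 tau2 = tau2, Q = fx$Q, I2 = fx$I2, K = K,
                 weights = wn, model = "random"), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %s-effect pooling of %d studies\n", x$model, x$K))
  cat(sprintf("  pooled = %.4f (se %.4f), z = %.2f, p = %.3g\n", x$pooled, x$se, x$z, x$p))
  cat(sprintf("  Q = %.3f, tau2 = %.4f, I2 = %.1f%%\n", x$Q, x$tau2, 100 * x$I2))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, with significance in
#' this package read at FDR <= 0.05. One family per (outcome x cohort-set)
#' analysis.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Subgroup meta-analysis
#'
#' Pools effects independently within each subgroup (e.g. the hot/cold
#' cancer-type stratification, see [hot_cold_types()]).
#'
#' @param effects per-cohort effect data frame (see [pool_fixed()]) with a
#'   `cohort_id` column.
#' @param groups named character vector mapping each `cohort_id` to a subgroup
#'   label; an unlabeled cohort is an error.
#' @param model `"random"` (default) or `"fixed"`.
#' @return Named list of `meta_result` objects, one per subgroup label.
#' @export
subgroup_meta <- function(effects, groups, model = c("random", "fixed")) {
  model <- match.arg(model)
  eff <- as.data.frame(effects)
  stopifnot("cohort_id" %in% names(eff))
  missing_lab <- setdiff(eff$cohort_id, names(groups))
  if (length(missing_lab) > 0)
    stop("unlabeled cohort(s): ", paste(missing_lab, collapse = ", "), call. = FALSE)
  lab <- groups[eff$cohort_id]
  pool <- if (model == "random") pool_dersimonian_laird else pool_fixed
  lapply(split(eff, lab), pool)
}

#' Hot/cold cancer-type configuration
#'
#' The bundled stratification of TCGA cancer types into immunologically "hot"
#' (high immune-cell infiltration, 18 types) and "cold" (immune-desert or
#' immune-excluded, 15 types) categories.
#'
#' @return List with character vectors `hot` and `cold`.
#' @export
hot_cold_types <- function() {
  jsonlite::read_json(system.file("extdata", "hot_cold_cancer_types.json",
                                  package = "tlsmeta"),
                      simplifyVector = TRUE)
}
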