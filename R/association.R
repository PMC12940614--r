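#' Classify ICB response from RECIST and PFS
#'
#' Responders (`"R"`) are complete response, partial response, or stable
#' disease without a PFS event within 6 months; non-responders (`"NR"`) are
#' progressive disease or stable disease with a PFS event by month 6. Stable
#' disease with missing PFS is `"non_assessable"`. When RECIST is missing, the
#' 6-month PFS status alone decides (event by month 6 = `"NR"`).
#'
#' @param recist character vector of RECIST categories (`CR`, `PR`, `SD`,
#'   `PD`) or `NA`.
#' @param pfs_time,pfs_event PFS follow-up in months and event indicator
#'   (`0`/`1`), possibly `NA`.
#' @return Character vector: `"R"`, `"NR"` or `"non_assessable"`. A row with
#'   every input missing is an error.
#' @export
classify_response <- function(recist, pfs_time = NULL, pfs_event = NULL) {
  n <- length(recist)
  pfs_time <- pfs_time %||% rep(NA_real_, n)
  pfs_event <- pfs_event %||% rep(NA_real_, n)
  stopifnot(length(pfs_time) == n, length(pfs_event) == n)
  all_missing <- is.na(recist) & is.na(pfs_time) & is.na(pfs_event)
  if (any(all_missing))
    stop("sample(s) ", paste(which(all_missing), collapse = ", "),
         ": neither RECIST nor PFS information present", call. = FALSE)
  early_event <- !is.na(pfs_event) & pfs_event == 1 & !is.na(pfs_time) & pfs_time <= 6
  out <- rep(NA_character_, n)
  out[recist %in% c("CR", "PR")] <- "R"
  out[recist %in% "PD"] <- "NR"
  sd_idx <- recist %in% "SD"
  out[sd_idx & early_event] <- "NR"
  out[sd_idx & !early_event & !is.na(pfs_event)] <- "R"
  out[sd_idx & is.na(pfs_event)] <- "non_assessable"
  miss <- is.na(recist)
  out[miss & early_event] <- "NR"
  out[miss & !early_event] <- "R"
  out
}

## one-row effect table shared by Cox and logistic fits
effect_estimate <- function(cohort_id, covariate, estimate, se, n, events,
                            converged, method) {
  z <- estimate / se
  structure(data.frame(
    cohort_id = cohort_id, covariate = covariate,
    estimate = estimate, se = se,
    p = 2 * stats::pnorm(-abs(z)),
    n = n, events = events, converged = converged, method = method,
    stringsAsFactors = FALSE
  ), class = c("effect_estimate", "data.frame"))
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ score` with Breslow tie handling (Efron available
#' via `ties`). The estimate is the log hazard ratio per unit of the score;
#' the p-value is the two-sided Wald test. Monotone-likelihood /
#' non-convergence is flagged in `converged` rather than silently returned.
#'
#' @param score per-sample numeric covariate (finite, variance > 0).
#' @param time,event survival follow-up (months, > 0) and event indicator.
#' @param cohort_id,covariate labels carried into the effect table.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return One-row `effect_estimate` data frame: `cohort_id`, `covariate`,
#'   `estimate`, `se`, `p`, `n`, `events`, `converged`, `method`.
#' @export
fit_cox_univariate <- function(score, time, event, cohort_id = "cohort",
                               covariate = "score", ties = "breslow") {
  stopifnot(length(score) == length(time), length(time) == length(event))
  keep <- stats::complete.cases(score, time, event)
  score <- score[keep]; time <- time[keep]; event <- event[keep]
  if (any(time <= 0)) stop("survival times must be strictly positive", call. = FALSE)
  if (sum(event) < 2) stop("need at least 2 events for a Cox fit", call. = FALSE)
  if (stats::sd(score) == 0) stop("constant score: Cox effect undefined", call. = FALSE)
  ok <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ score, ties = ties,
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 20) ok <- FALSE
  effect_estimate(cohort_id, covariate, beta, se, length(score), sum(event),
                  ok, paste0("cox_", ties))
}

## logistic IRLS core; returns list(beta, se, converged, iter)
logistic_irls <- function(X, y, firth = FALSE, max_iter = 50, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) break
    resid <- y - mu
    if (firth) { # Jeffreys-prior score correction via hat diagonal
      h <- rowSums((X %*% inv) * X) * w
      resid <- resid + h * (0.5 - mu)
    }
    step <- drop(inv %*% crossprod(X, resid))
    ## dampen huge steps to keep the Firth path stable
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  inv <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
  se <- if (is.null(inv)) rep(NA_real_, length(beta)) else sqrt(diag(inv))
  list(beta = beta, se = se, converged = converged, iter = it)
}

#' Univariate logistic regression of ICB response on a score
#'
#' Maximum likelihood via iteratively reweighted least squares. When the ML
#' path fails to converge or shows separation (diverging coefficient or
#' exploding standard error), the model is refit with Firth's Jeffreys-prior
#' penalization, which always yields a finite estimate; the result is then
#' flagged `converged = FALSE` with `method = "logistic_firth"`.
#'
#' @param score per-sample numeric covariate.
#' @param response `"R"`/`"NR"` labels (or a 0/1 vector); `non_assessable`
#'   samples must be excluded upstream and are rejected here.
#' @param cohort_id,covariate labels carried into the effect table.
#' @return One-row `effect_estimate` data frame; `estimate` is the log odds
#'   ratio of response per unit score.
#' @export
fit_logistic_univariate <- function(score, response, cohort_id = "cohort",
                                    covariate = "score") {
  stopifnot(length(score) == length(response))
  if (is.character(response) || is.factor(response)) {
    response <- as.character(response)
    if (any(response == "non_assessable"))
      stop("exclude non_assessable samples before fitting", call. = FALSE)
    y <- as.numeric(response == "R")
  } else y <- as.numeric(response)
  keep <- stats::complete.cases(score, y)
  score <- score[keep]; y <- y[keep]
  if (length(unique(y)) < 2) stop("both response classes must be present", call. = FALSE)
  if (stats::sd(score) == 0) stop("constant score: logistic effect undefined", call. = FALSE)
  X <- cbind(1, score)
  fit <- logistic_irls(X, y)
  separated <- !fit$converged || !all(is.finite(fit$se)) ||
    abs(fit$beta[2]) > 15 || (all(is.finite(fit$se)) && fit$se[2] > 50)
  if (separated) {
    fit <- logistic_irls(X, y, firth = TRUE, max_iter = 200)
    return(effect_estimate(cohort_id, covariate, fit$beta[2], fit$se[2],
                           length(y), sum(y), FALSE, "logistic_firth"))
  }
  effect_estimate(cohort_id, covariate, fit$beta[2], fit$se[2],
                  length(y), sum(y), TRUE, "logistic_ml")
}

#' Response AUC of a score
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney statistic:
#' the probability that a random responder outscores a random non-responder,
#' ties counted 1/2.
#'
#' @param score per-sample numeric score.
#' @param labels `"R"`/`"NR"` (or logical/0-1 with `TRUE`/1 = positive).
#' @param positive label treated as the positive class, default `"R"`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(score, labels, positive = "R") {
  pos <- if (is.logical(labels)) labels
         else if (is.numeric(labels)) labels == 1
         else as.character(labels) == positive
  keep <- !is.na(score) & !is.na(pos)
  score <- score[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for AUC", call. = FALSE)
  r <- rank(score) # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## DeLong placement values for one score
delong_placements <- function(score, pos) {
  x <- score[pos]; y <- score[!pos]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Tests `AUC(scoreA) - AUC(scoreB)` on the same samples using the DeLong
#' covariance of the paired placement values; two-sided normal p-value.
#' Identical scores return a difference of 0 with p = 1; a degenerate variance
#' with a nonzero difference is an error.
#'
#' @param score_a,score_b two per-sample scores over the same samples.
#' @param labels `"R"`/`"NR"` labels.
#' @param positive positive class label.
#' @return List: `auc_a`, `auc_b`, `delta_auc`, `z`, `p`.
#' @export
compare_auc <- function(score_a, score_b, labels, positive = "R") {
  stopifnot(length(score_a) == length(score_b), length(score_a) == length(labels))
  pos <- if (is.logical(labels)) labels
         else if (is.numeric(labels)) labels == 1
         else as.character(labels) == positive
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  pa <- delong_placements(score_a, pos)
  pb <- delong_placements(score_b, pos)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (var_diff < 1e-14) {
    if (abs(delta) < 1e-12)
      return(list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = 0, z = 0, p = 1))
    stop("degenerate DeLong variance with nonzero AUC difference", call. = FALSE)
  }
  z <- delta / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Kaplan-Meier curves and log-rank test at a median split
#'
#' Stratifies samples into high/low score groups at the median (ties to low),
#' fits product-limit curves per arm and runs the standard 1-df log-rank test.
#'
#' @param scores per-sample numeric score.
#' @param time,event survival follow-up and event indicator.
#' @return List: `fit` (a `survival::survfit` object), `groups`, `chisq`, `p`.
#'   Requires at least one event per arm.
#' @export
km_logrank <- function(scores, time, event) {
  grp <- median_stratify(scores)
  keep <- !is.na(grp) & !is.na(time) & !is.na(event)
  grp <- factor(grp[keep], levels = c("low", "high"))
  time <- time[keep]; event <- event[keep]
  if (nlevels(droplevels(grp)) < 2) stop("median split produced an empty arm", call. = FALSE)
  ev_by_arm <- tapply(event, grp, sum)
  if (any(ev_by_arm == 0)) stop("need >= 1 event per arm for the log-rank test", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(fit = fit, groups = grp, chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

## exact / Monte-Carlo permutation p for the rank-sum statistic
perm_ranksum_p <- function(x, y, n_perm = 10000, seed = 1L, enumerate_limit = 20000) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  ew <- nx * (nx + ny + 1) / 2
  t_obs <- abs(w_obs - ew)
  n_comb <- choose(nx + ny, nx)
  if (n_comb <= enumerate_limit) {
    idx <- utils::combn(nx + ny, nx)
    w_all <- colSums(matrix(r[idx], nrow = nx))
    p <- mean(abs(w_all - ew) >= t_obs - 1e-9)
    list(p = p, statistic = w_obs, exact = TRUE)
  } else {
    w_perm <- with_rng(seed, vapply(seq_len(n_perm), function(i)
      sum(r[sample.int(nx + ny, nx)]), 0))
    p <- (1 + sum(abs(w_perm - ew) >= t_obs - 1e-9)) / (n_perm + 1)
    list(p = p, statistic = w_obs, exact = FALSE)
  }
}

#' Two-group comparison with automatic method choice
#'
#' Continuous inputs: Wilcoxon rank-sum when both groups have >= 10
#' observations, otherwise a seeded (exact where enumerable) permutation test
#' of the rank-sum statistic. Categorical inputs (factor/character/logical):
#' Fisher's exact test on the 2 x k contingency table. All p-values two-sided.
#'
#' @param x,y the two groups (both nonempty).
#' @param method `"auto"` (default), `"wilcoxon"`, `"permutation"` or
#'   `"fisher"`.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed seed for the Monte-Carlo permutation path.
#' @return List: `statistic`, `p`, `method` (the path actually used).
#' @export
compare_groups <- function(x, y, method = c("auto", "wilcoxon", "permutation", "fisher"),
                           n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty", call. = FALSE)
  categorical <- is.factor(x) || is.character(x) || is.logical(x)
  if (method == "fisher" || (method == "auto" && categorical)) {
    tab <- table(factor(c(rep("x", length(x)), rep("y", length(y)))),
                 c(as.character(x), as.character(y)))
    ft <- stats::fisher.test(tab)
    return(list(statistic = unname(ft$estimate %||% NA_real_), p = ft$p.value,
                method = "fisher"))
  }
  small <- min(length(x), length(y)) < 10
  if (method == "permutation" || (method == "auto" && small)) {
    res <- perm_ranksum_p(x, y, n_perm = n_perm, seed = seed)
    return(list(statistic = res$statistic, p = res$p,
                method = if (res$exact) "permutation_exact" else "permutation_mc"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(wt$statistic), p = wt$p.value, method = "wilcoxon")
}

#' Median Spearman correlation between signatures across cohorts
#'
#' Computes the Spearman correlation matrix between signature scores within
#' each cohort and summarizes as the elementwise median across cohorts, with
#' the diagonal fixed at 1. A constant score vector yields `NA` correlations
#' for that cohort with a warning.
#'
#' @param score_matrices list (one per cohort) of signatures x samples score
#'   matrices sharing the same signature rownames.
#' @return Signatures x signatures matrix of median Spearman rho.
#' @export
correlate_signatures <- function(score_matrices) {
  stopifnot(length(score_matrices) >= 1)
  sig <- rownames(score_matrices[[1]])
  if (length(sig) < 2) stop("need >= 2 signatures", call. = FALSE)
  mats <- lapply(score_matrices, function(m) {
    stopifnot(identical(rownames(m), sig))
    if (ncol(m) < 3) stop("need >= 3 samples per cohort", call. = FALSE)
    const <- apply(m, 1, function(v) stats::sd(v) == 0)
    if (any(const))
      warning("constant score vector(s): ", paste(sig[const], collapse = ", "),
              "; correlations set to NA", call. = FALSE)
    cc <- suppressWarnings(stats::cor(t(m), method = "spearman"))
    cc[const, ] <- NA; cc[, const] <- NA
    cc
  })
  out <- apply(simplify2array(mats), c(1, 2), stats::median, na.rm = TRUE)
  diag(out) <- 1
  out
}
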