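#' Score spatial spots with a signature
#'
#' Z-scores genes across spots and computes the per-spot enrichment score of
#' the signature (see [gsva_like_score()]).
#'
#' @param sample a `spatial_sample` (see [simulate_spatial()]) or a genes x
#'   spots expression matrix.
#' @param sig a [gene_set]; at least one member must be present.
#' @param tau enrichment weight exponent.
#' @return Named numeric vector of per-spot scores.
#' @export
score_spots <- function(sample, sig, tau = 1) {
  expr <- if (inherits(sample, "spatial_sample")) sample$expression else sample
  if (ncol(expr) < 2) stop("need at least 2 spots", call. = FALSE)
  z <- zscore_expression(expr)
  gsva_like_score(z, sig, tau = tau)
}

#' Spot-level TLS detection AUC
#'
#' AUC of the spot scores against the pathologist-style annotation, positive
#' class = any annotated TLS spot (`mature_tls` or `immature_tls`). A
#' single-class sample (e.g. TLS-negative) yields a report with `auc = NA`
#' rather than an error.
#'
#' @param scores per-spot numeric scores.
#' @param annotation per-spot labels (`mature_tls` / `immature_tls` / `none`),
#'   or a `spatial_sample` whose annotation and metadata are used.
#' @param sample_id,maturity_label report labels (taken from the
#'   `spatial_sample` when one is given).
#' @return One-row data frame: `sample_id`, `maturity_label`, `n_spots`,
#'   `n_tls_spots`, `auc`.
#' @export
spot_auc <- function(scores, annotation, sample_id = "sample",
                     maturity_label = NA_character_) {
  if (inherits(annotation, "spatial_sample")) {
    sample_id <- annotation$sample_id
    maturity_label <- annotation$maturity_label
    annotation <- annotation$tls_annotation
  }
  stopifnot(length(scores) == length(annotation))
  pos <- annotation %in% c("mature_tls", "immature_tls")
  a <- if (any(pos) && any(!pos)) auc(scores, pos) else NA_real_
  data.frame(sample_id = sample_id, maturity_label = maturity_label,
             n_spots = length(scores), n_tls_spots = sum(pos), auc = a,
             stringsAsFactors = FALSE)
}

#' Summarize spot AUCs by sample maturity
#'
#' Min/median/max AUC per maturity group (`mature`, `immature`, `negative`);
#' the negative group has no defined AUC and is reported as `NA`.
#'
#' @param reports data frame of [spot_auc()] rows (rbind-ed).
#' @return Data frame: `maturity_label`, `n_samples`, `min_auc`, `median_auc`,
#'   `max_auc`.
#' @export
maturity_summary <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1)
  groups <- split(reports, reports$maturity_label)
  out <- lapply(names(groups), function(g) {
    a <- groups[[g]]$auc
    defined <- a[!is.na(a)]
    data.frame(maturity_label = g, n_samples = nrow(groups[[g]]),
               min_auc = if (length(defined)) min(defined) else NA_real_,
               median_auc = if (length(defined)) stats::median(defined) else NA_real_,
               max_auc = if (length(defined)) max(defined) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
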