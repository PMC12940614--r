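## R/NR labels for a cohort's assessable samples
cohort_response <- function(cohort) {
  cl <- cohort$clinical
  lab <- classify_response(cl$recist, cl$pfs_time, cl$pfs_event)
  stats::setNames(lab, cl$sample_id)
}

#' Drop candidate genes with majority-zero expression
#'
#' A candidate is excluded if, in *any* discovery cohort where it is measured,
#' more than 50% of samples have zero expression; exactly 50% is kept.
#'
#' @param cohorts list of `tls_cohort` objects (the discovery cohorts).
#' @param candidates a [gene_set] of candidate genes.
#' @return A filtered [gene_set]; an error if nothing survives.
#' @export
filter_zero_genes <- function(cohorts, candidates) {
  stopifnot(inherits(candidates, "gene_set"), length(cohorts) >= 1)
  drop <- vapply(candidates$members, function(g) {
    any(vapply(cohorts, function(co) {
      if (!g %in% rownames(co$expression)) return(FALSE)
      mean(co$expression[g, ] == 0) > 0.5
    }, FALSE))
  }, FALSE)
  kept <- candidates$members[!drop]
  if (length(kept) == 0L)
    stop("zero-expression filter removed every candidate gene", call. = FALSE)
  gene_set(candidates$name, kept)
}

#' Per-gene meta-analyzed log odds ratio of response
#'
#' For each candidate gene: z-score its expression within each discovery
#' cohort, fit a univariate logistic regression of R/NR response on the
#' z-scored expression, pool the per-cohort log odds ratios by
#' DerSimonian-Laird (or fixed-effect) meta-analysis, and adjust the pooled
#' p-values across genes by Benjamini-Hochberg. Cohorts lacking a gene are
#' skipped for that gene and counted in `n_cohorts_used`.
#'
#' @param cohorts list of `tls_cohort` discovery cohorts; each must contain
#'   both responders and non-responders after classification.
#' @param candidates a [gene_set] (apply [filter_zero_genes()] first).
#' @param model `"random"` (default) or `"fixed"` pooling.
#' @return Data frame with one row per gene: `gene`, `pooled_logor`,
#'   `pooled_se`, `p`, `fdr`, `n_cohorts_used`; the per-cohort effect tables
#'   are attached as attribute `"per_cohort"`.
#' @export
per_gene_meta_logor <- function(cohorts, candidates, model = c("random", "fixed")) {
  model <- match.arg(model)
  stopifnot(inherits(candidates, "gene_set"))
  pool <- if (model == "random") pool_dersimonian_laird else pool_fixed
  resp <- lapply(cohorts, cohort_response)
  zmats <- vector("list", length(cohorts))
  for (k in seq_along(cohorts)) {
    lab <- resp[[k]]
    lab <- lab[lab != "non_assessable"]
    if (length(unique(lab)) < 2)
      stop("cohort ", cohorts[[k]]$cohort_id,
           ": both responders and non-responders required", call. = FALSE)
    expr <- cohorts[[k]]$expression
    present <- intersect(candidates$members, rownames(expr))
    zmats[[k]] <- list(z = zscore_expression(expr[present, names(lab), drop = FALSE]),
                       y = as.numeric(lab == "R"),
                       id = cohorts[[k]]$cohort_id)
  }
  per_cohort <- list()
  rows <- lapply(candidates$members, function(g) {
    effs <- list()
    for (k in seq_along(zmats)) {
      zm <- zmats[[k]]
      if (!g %in% rownames(zm$z)) next
      zg <- zm$z[g, ]
      if (stats::sd(zg) == 0) next
      effs[[length(effs) + 1]] <-
        fit_logistic_univariate(zg, zm$y, cohort_id = zm$id, covariate = g)
    }
    if (length(effs) == 0)
      return(data.frame(gene = g, pooled_logor = NA_real_, pooled_se = NA_real_,
                        p = NA_real_, fdr = NA_real_, n_cohorts_used = 0L,
                        stringsAsFactors = FALSE))
    eff <- do.call(rbind, effs)
    per_cohort[[g]] <<- eff
    mr <- pool(eff)
    data.frame(gene = g, pooled_logor = mr$pooled, pooled_se = mr$se,
               p = mr$p, fdr = NA_real_, n_cohorts_used = nrow(eff),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  attr(out, "per_cohort") <- per_cohort
  out
}

## mean response AUC of one signature across prepared cohorts
mean_discovery_auc <- function(sig, prepared, tau = 1) {
  aucs <- vapply(prepared, function(pc) {
    present <- intersect(sig$members, rownames(pc$z))
    if (length(present) == 0) return(NA_real_)
    sc <- suppressWarnings(gsva_like_score(pc$z, gene_set(sig$name, present), tau = tau))
    auc(sc, pc$labels)
  }, 0)
  mean(aucs, na.rm = TRUE)
}

## z-matrices + labels reused across the cutoff grid
prepare_cohorts_for_scoring <- function(cohorts) {
  lapply(cohorts, function(co) {
    lab <- cohort_response(co)
    lab <- lab[lab != "non_assessable"]
    list(z = zscore_expression(co$expression[, names(lab), drop = FALSE]),
         labels = unname(lab), id = co$cohort_id)
  })
}

#' Log-odds cutoff sweep and signature selection
#'
#' Ranks genes by their signed pooled log odds ratio and, at every cutoff `c`
#' on the grid (default 0 to 0.5 in steps of 0.005, 101 cutoffs), forms the
#' signature of genes with pooled logOR >= c. Each nonempty signature is
#' scored by [gsva_like_score()] on every discovery cohort and its mean
#' response AUC recorded. The selected cutoff maximizes mean discovery AUC,
#' ties broken toward the *larger* cutoff (smaller signature). Negatively
#' associated genes are reported in the input table but never included.
#'
#' @param table per-gene table from [per_gene_meta_logor()].
#' @param discovery_cohorts list of `tls_cohort` objects.
#' @param cutoff_lo,cutoff_hi,step the cutoff grid.
#' @param tau enrichment weight exponent, see [gsva_like_score()].
#' @return Object of class `sweep_result`: `sweep` (data frame `cutoff`,
#'   `size`, `mean_auc`), `selected_cutoff`, `signature` (a [gene_set]),
#'   `table` (the input gene table).
#' @export
rank_and_sweep <- function(table, discovery_cohorts,
                           cutoff_lo = 0, cutoff_hi = 0.5, step = 0.005,
                           tau = 1) {
  stopifnot(step > 0, cutoff_lo <= cutoff_hi, nrow(table) > 0)
  tab <- table[!is.na(table$pooled_logor), , drop = FALSE]
  grid <- seq(cutoff_lo, cutoff_hi, by = step)
  prepared <- prepare_cohorts_for_scoring(discovery_cohorts)
  cache <- new.env(parent = emptyenv())
  sweep <- data.frame(cutoff = grid, size = NA_integer_, mean_auc = NA_real_)
  for (i in seq_along(grid)) {
    members <- tab$gene[tab$pooled_logor >= grid[i]]
    sweep$size[i] <- length(members)
    if (length(members) == 0) next
    key <- paste(sort(members), collapse = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- mean_discovery_auc(gene_set("sweep", members), prepared, tau = tau)
    sweep$mean_auc[i] <- cache[[key]]
  }
  eval_rows <- which(!is.na(sweep$mean_auc))
  if (length(eval_rows) == 0)
    stop("no cutoff on the grid yields a nonempty signature", call. = FALSE)
  best <- max(sweep$mean_auc[eval_rows])
  sel_i <- max(eval_rows[sweep$mean_auc[eval_rows] >= best - 1e-12])
  selected <- sweep$cutoff[sel_i]
  final <- gene_set("selected_signature",
                    tab$gene[tab$pooled_logor >= selected])
  structure(list(sweep = sweep, selected_cutoff = selected,
                 signature = final, table = table),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> selected cutoff", x$selected_cutoff,
      "->", length(x$signature$members), "genes\n")
  invisible(x)
}

#' Validate a signature on held-out cohorts
#'
#' Computes, per validation cohort, the response AUC of the signature's
#' enrichment score, a DeLong comparison against each competitor signature,
#' and the pooled Cox association of the score with overall survival, plus
#' Kaplan-Meier data at the median split. Evaluating on a discovery cohort is
#' data leakage and a hard error.
#'
#' @param sig a [gene_set].
#' @param validation_cohorts list of `tls_cohort` objects, disjoint from
#'   discovery.
#' @param competitors optional list of competitor [gene_set]s.
#' @param discovery_ids character vector of discovery cohort ids used to
#'   enforce the disjointness contract.
#' @param tau enrichment weight exponent.
#' @return List: `per_cohort` (data frame `cohort_id, n, auc`), `mean_auc`,
#'   `competitor_comparisons` (per competitor: per-cohort `delta_auc`, `p`),
#'   `os_meta` (`meta_result` pooling per-cohort logHR of OS on the score),
#'   `km` (per-cohort log-rank chisq/p).
#' @export
validate_signature <- function(sig, validation_cohorts, competitors = list(),
                               discovery_ids = character(), tau = 1) {
  stopifnot(inherits(sig, "gene_set"))
  ids <- vapply(validation_cohorts, `[[`, "", "cohort_id")
  leak <- intersect(ids, discovery_ids)
  if (length(leak) > 0)
    stop("validation on discovery cohort(s) ", paste(leak, collapse = ", "),
         ": data leakage", call. = FALSE)
  prepared <- prepare_cohorts_for_scoring(validation_cohorts)
  per_cohort <- data.frame(cohort_id = ids, n = NA_integer_, auc = NA_real_)
  comp_res <- stats::setNames(
    replicate(length(competitors),
              data.frame(cohort_id = ids, delta_auc = NA_real_, p = NA_real_),
              simplify = FALSE),
    vapply(competitors, `[[`, "", "name"))
  cox_effects <- list()
  km <- data.frame(cohort_id = ids, chisq = NA_real_, p = NA_real_)
  for (k in seq_along(validation_cohorts)) {
    co <- validation_cohorts[[k]]
    pc <- prepared[[k]]
    present <- intersect(sig$members, rownames(pc$z))
    if (length(present) < 1)
      stop("signature has no gene in cohort ", co$cohort_id, call. = FALSE)
    sc <- suppressWarnings(gsva_like_score(pc$z, gene_set(sig$name, present), tau = tau))
    per_cohort$n[k] <- length(sc)
    per_cohort$auc[k] <- auc(sc, pc$labels)
    for (ci in seq_along(competitors)) {
      csc <- tryCatch(
        suppressWarnings(gsva_like_score(pc$z, competitors[[ci]], tau = tau)),
        error = function(e) NULL)
      if (is.null(csc)) next
      cmp <- compare_auc(sc, csc, pc$labels)
      comp_res[[ci]]$delta_auc[k] <- cmp$delta_auc
      comp_res[[ci]]$p[k] <- cmp$p
    }
    ## survival association on the full cohort (response labels not needed)
    zfull <- zscore_expression(co$expression)
    sc_full <- suppressWarnings(
      gsva_like_score(zfull, gene_set(sig$name, present), tau = tau))
    cl <- co$clinical
    cox_effects[[k]] <- tryCatch(
      fit_cox_univariate(sc_full[cl$sample_id], cl$os_time, cl$os_event,
                         cohort_id = co$cohort_id, covariate = sig$name),
      error = function(e) NULL)
    kmres <- tryCatch(km_logrank(sc_full[cl$sample_id], cl$os_time, cl$os_event),
                      error = function(e) NULL)
    if (!is.null(kmres)) { km$chisq[k] <- kmres$chisq; km$p[k] <- kmres$p }
  }
  cox_effects <- Filter(Negate(is.null), cox_effects)
  os_meta <- if (length(cox_effects) > 0)
    pool_dersimonian_laird(do.call(rbind, cox_effects)) else NULL
  list(per_cohort = per_cohort,
       mean_auc = mean(per_cohort$auc, na.rm = TRUE),
       competitor_comparisons = comp_res,
       os_meta = os_meta,
       km = km)
}

#' Jaccard index between two gene sets
#'
#' @param a,b [gene_set]s or character vectors.
#' @return `|A intersect B| / |A union B|`.
#' @export
jaccard <- function(a, b) {
  a <- if (inherits(a, "gene_set")) a$members else as.character(a)
  b <- if (inherits(b, "gene_set")) b$members else as.character(b)
  length(intersect(a, b)) / length(union(a, b))
}
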