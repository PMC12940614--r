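#' Default benchmark configuration
#'
#' The end-to-end demonstration conditions: multi-cohort ICB simulation with a
#' 15-gene planted TLS program among 74 candidate genes, a discovery /
#' validation cohort split, the 0-0.5 (step 0.005) cutoff sweep, and a small
#' spatial evaluation panel. Sizes are chosen to make a single run complete in
#' well under a minute while leaving the planted-program recovery nontrivial.
#'
#' @param seed integer seed driving every stage.
#' @return Named list understood by [run_benchmark()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_discovery = 6L, n_validation = 3L,
    n_samples_discovery = 60L, n_samples_validation = 80L,
    n_planted = 15L, n_candidates = 74L, n_genes = 300L,
    gamma = 2, delta = -0.5, noise_sd = 1,
    cutoff_lo = 0, cutoff_hi = 0.5, cutoff_step = 0.005,
    spatial = list(width = 20L, height = 20L, n_tls = 2L, radius = 3L,
                   effect = 3, n_per_group = 2L)
  )
}

## planted truth + cohorts + candidate set for a benchmark config
benchmark_inputs <- function(config) {
  n_total <- config$n_discovery + config$n_validation
  sig_genes <- sprintf("TLS%02d", seq_len(config$n_planted))
  loadings <- with_rng(child_seed(config$seed, 1),
                       stats::setNames(stats::runif(config$n_planted, 0.8, 1.2), sig_genes))
  truth <- truth_set(sig_genes, gene_loadings = loadings,
                     activity_effect_response = config$gamma,
                     activity_effect_hazard = config$delta)
  cohorts <- simulate_cohorts(
    n_cohorts = n_total,
    n_samples = c(rep(config$n_samples_discovery, config$n_discovery),
                  rep(config$n_samples_validation, config$n_validation)),
    n_genes = config$n_genes, truth = truth, noise_sd = config$noise_sd,
    seed = child_seed(config$seed, 2))
  ## give 24 noise genes the COX-IS symbols so that score is computable here
  cox <- coxis_genes()
  cox_syms <- c(cox$cp$members, cox$ci$members)
  all_genes <- rownames(cohorts[[1]]$expression)
  renamed <- utils::tail(all_genes, length(cox_syms))
  for (k in seq_along(cohorts)) {
    rn <- rownames(cohorts[[k]]$expression)
    rn[match(renamed, rn)] <- cox_syms
    rownames(cohorts[[k]]$expression) <- rn
  }
  all_genes <- rownames(cohorts[[1]]$expression)
  filler <- setdiff(all_genes, sig_genes)[seq_len(config$n_candidates - config$n_planted)]
  candidates <- gene_set("candidates", c(sig_genes, filler))
  split <- list(discovery = names(cohorts)[seq_len(config$n_discovery)],
                validation = names(cohorts)[config$n_discovery + seq_len(config$n_validation)])
  list(truth = truth, cohorts = cohorts, candidates = candidates, split = split)
}

check_partition <- function(split, cohort_ids) {
  both <- c(split$discovery, split$validation)
  if (anyDuplicated(both) || !setequal(both, cohort_ids))
    stop("discovery/validation split must partition the cohort ids", call. = FALSE)
  invisible(TRUE)
}

#' Run the full synthetic benchmark pipeline
#'
#' Executes the complete analysis flow on simulated data with known ground
#' truth: simulate multi-cohort ICB data; score the registered signatures
#' (planted TLS program, COX-IS, TMB) per cohort; estimate per-cohort logistic
#' (response) and Cox (OS) effects; pool them by fixed- and random-effects
#' meta-analysis with hot/cold subgroup pooling and BH-FDR across signatures;
#' run the de novo discovery sweep on the discovery cohorts; validate the
#' selected signature (against a size-matched random competitor) on the
#' held-out cohorts; and evaluate spot-level TLS detection on simulated
#' spatial samples. When `out_dir` is given, every table is written as
#' fixed-precision text plus a manifest with the config and per-file MD5
#' hashes; identical config + seed reproduces identical files.
#'
#' @param config list from [default_config()] (possibly modified).
#' @param out_dir optional output directory for the artifact bundle.
#' @return List: `config`, `truth`, `signature_meta` (per registered signature:
#'   response and OS `meta_result`s + subgroup results + FDR table),
#'   `gene_table`, `sweep` (a `sweep_result`), `validation`, `spatial`
#'   (reports + summary), `recovery` (Jaccard vs planted truth), and
#'   `artifacts` (paths, when written).
#' @export
run_benchmark <- function(config = default_config(), out_dir = NULL) {
  stopifnot(config$cutoff_step > 0, config$cutoff_lo <= config$cutoff_hi)
  inputs <- benchmark_inputs(config)
  cohorts <- inputs$cohorts
  check_partition(inputs$split, names(cohorts))
  disc <- cohorts[inputs$split$discovery]
  val <- cohorts[inputs$split$validation]

  ## --- registered signature scoring + per-cohort effects -------------------
  planted <- gene_set("planted_program", inputs$truth$signature_genes)
  resp_eff <- list(); os_eff <- list()
  for (co in cohorts) {
    z <- zscore_expression(co$expression)
    scores <- list(
      planted_program = gsva_like_score(z, planted),
      coxis = tryCatch(suppressWarnings(coxis_score(co$expression)),
                       error = function(e) NULL),
      tmb = stats::setNames(co$clinical$tmb, co$clinical$sample_id)
    )
    lab <- cohort_response(co)
    lab <- lab[lab != "non_assessable"]
    for (nm in names(scores)) {
      s <- scores[[nm]]
      if (is.null(s) || stats::sd(s) == 0) next
      sz <- as.numeric(scale(s)) # z-scale scores for effect-size comparability
      names(sz) <- names(s)
      resp_eff[[length(resp_eff) + 1]] <- tryCatch(
        fit_logistic_univariate(sz[names(lab)], unname(lab),
                                cohort_id = co$cohort_id, covariate = nm),
        error = function(e) NULL)
      os_eff[[length(os_eff) + 1]] <- tryCatch(
        fit_cox_univariate(sz[co$clinical$sample_id], co$clinical$os_time,
                           co$clinical$os_event,
                           cohort_id = co$cohort_id, covariate = nm),
        error = function(e) NULL)
    }
  }
  resp_eff <- do.call(rbind, Filter(Negate(is.null), resp_eff))
  os_eff <- do.call(rbind, Filter(Negate(is.null), os_eff))
  context <- stats::setNames(vapply(cohorts, `[[`, "", "immune_context"),
                             names(cohorts))
  meta_one <- function(eff) {
    per_sig <- split(eff, eff$covariate)
    res <- lapply(per_sig, function(e) list(
      fixed = pool_fixed(e),
      random = pool_dersimonian_laird(e),
      subgroup = tryCatch(subgroup_meta(e, context), error = function(x) NULL)))
    fdr <- bh_fdr(vapply(res, function(r) r$random$p, 0))
    names(fdr) <- names(res)
    list(per_signature = res, fdr = fdr)
  }
  signature_meta <- list(response = meta_one(resp_eff), os = meta_one(os_eff))

  ## --- de novo discovery ---------------------------------------------------
  candidates <- filter_zero_genes(disc, inputs$candidates)
  gene_table <- per_gene_meta_logor(disc, candidates)
  sweep <- rank_and_sweep(gene_table, disc,
                          cutoff_lo = config$cutoff_lo,
                          cutoff_hi = config$cutoff_hi,
                          step = config$cutoff_step)
  competitor <- with_rng(child_seed(config$seed, 3), gene_set(
    "random_competitor",
    sample(setdiff(rownames(cohorts[[1]]$expression), sweep$signature$members),
           length(sweep$signature$members))))
  validation <- validate_signature(sweep$signature, val,
                                   competitors = list(competitor),
                                   discovery_ids = inputs$split$discovery)
  recovery <- jaccard(sweep$signature, planted)

  ## --- spatial evaluation --------------------------------------------------
  sp <- config$spatial
  reports <- list()
  for (g in c("mature", "immature", "negative")) {
    for (i in seq_len(sp$n_per_group)) {
      samp <- simulate_spatial(sp$width, sp$height, sp$n_tls, sp$radius,
                               signature = planted, effect = sp$effect,
                               maturity = g,
                               seed = child_seed(config$seed, 100 + 10 * i +
                                                   match(g, c("mature", "immature", "negative"))))
      sc <- suppressWarnings(score_spots(samp, sweep$signature))
      reports[[length(reports) + 1]] <- spot_auc(sc, samp)
    }
  }
  reports <- do.call(rbind, reports)
  spatial <- list(reports = reports, summary = maturity_summary(reports))

  result <- list(config = config, truth = inputs$truth,
                 signature_meta = signature_meta,
                 gene_table = gene_table, sweep = sweep,
                 validation = validation, spatial = spatial,
                 recovery = recovery)
  if (!is.null(out_dir)) result$artifacts <- write_benchmark(result, out_dir,
                                                             resp_eff, os_eff)
  result
}

## write the artifact bundle + manifest; fixed formatting keeps hashes stable
write_benchmark <- function(result, out_dir, resp_eff, os_eff) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable", call. = FALSE)
  p <- function(f) file.path(out_dir, f)
  num_cols <- function(df) {
    for (cn in names(df)) if (is.numeric(df[[cn]]) && !is.integer(df[[cn]]))
      df[[cn]] <- format_num(df[[cn]])
    df
  }
  write_effects_tsv(resp_eff, p("effects_response.tsv"))
  write_effects_tsv(os_eff, p("effects_os.tsv"))
  utils::write.table(num_cols(result$gene_table), p("gene_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(num_cols(result$sweep$sweep), p("sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(result$sweep$signature, p("signature.gmt"))
  jsonlite::write_json(list(
    per_cohort = num_cols(result$validation$per_cohort),
    mean_auc = signif(result$validation$mean_auc, 6),
    recovery_jaccard = signif(result$recovery, 6)
  ), p("validation.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(num_cols(result$spatial$reports), p("spatial_reports.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c("effects_response.tsv", "effects_os.tsv", "gene_meta.tsv",
             "sweep.tsv", "signature.gmt", "validation.json",
             "spatial_reports.tsv")
  manifest <- list(
    package = "tlsmeta",
    version = as.character(utils::packageVersion("tlsmeta")),
    seed = result$config$seed,
    config = result$config,
    files = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  file.path(out_dir, c(files, "manifest.json"))
}
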