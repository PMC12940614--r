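#' Define the ground truth of a simulated TLS program
#'
#' Fixes the planted signature genes, their loadings on the latent TLS
#' activity, and the strength with which activity drives ICB response
#' (log-odds per unit activity) and survival (log-hazard per unit activity),
#' plus per-cohort response intercepts.
#'
#' @param signature_genes character vector of planted signature gene symbols.
#' @param gene_loadings named numeric vector, loading of each signature gene on
#'   the latent activity; names must equal `signature_genes`. Default: all 1.
#' @param activity_effect_response gamma, log-odds of response per unit latent
#'   activity.
#' @param activity_effect_hazard delta, log-hazard per unit latent activity
#'   (positive = higher activity, higher hazard; use negative values for a
#'   protective program).
#' @param cohort_intercepts named numeric vector of per-cohort logistic
#'   intercepts alpha_k (controls response prevalence, which real ICB cohorts
#'   do not pin down).
#' @return Object of class `truth_set`.
#' @export
truth_set <- function(signature_genes,
                      gene_loadings = NULL,
                      activity_effect_response = 2,
                      activity_effect_hazard = -0.5,
                      cohort_intercepts = NULL) {
  signature_genes <- unique(as.character(signature_genes))
  if (length(signature_genes) == 0L) stop("signature_genes must be nonempty", call. = FALSE)
  if (is.null(gene_loadings))
    gene_loadings <- stats::setNames(rep(1, length(signature_genes)), signature_genes)
  if (!setequal(names(gene_loadings), signature_genes))
    stop("gene_loadings names must equal signature_genes", call. = FALSE)
  structure(list(
    signature_genes = signature_genes,
    gene_loadings = gene_loadings[signature_genes],
    activity_effect_response = activity_effect_response,
    activity_effect_hazard = activity_effect_hazard,
    cohort_intercepts = cohort_intercepts
  ), class = "truth_set")
}

#' Simulate multi-cohort ICB expression + clinical data with a planted program
#'
#' Each patient carries a latent TLS activity `a ~ N(0, 1)`. Signature-gene
#' expression is `baseline + loading * a + N(0, noise_sd)` on the log2(x+1)
#' scale (clipped at 0); the remaining genes are independent noise except for
#' one decoy module of mutually correlated genes that is *not* linked to
#' outcome (so that correlation alone cannot recover the planted program).
#' Response is Bernoulli with logit `alpha_k + gamma * a`; overall survival is
#' exponential with hazard `lambda * exp(delta * a)` under uniform censoring on
#' `[0.01, 2/lambda]` (roughly 30-50% censoring). RECIST categories and PFS are
#' drawn consistently with the responder rule (CR/PR/SD-without-early-event =
#' responder; PD or SD-with-event-by-6-months = non-responder), so
#' [classify_response()] inverts the generator exactly.
#'
#' @param n_cohorts number of cohorts (>= 1).
#' @param n_samples integer vector of per-cohort sizes (recycled), each >= 4.
#' @param n_genes total gene universe size (> number of signature genes).
#' @param truth a [truth_set()]; `cohort_intercepts` defaults to 0 for every
#'   cohort when unset.
#' @param noise_sd residual SD of expression around the program, default 1.
#' @param seed integer seed (mandatory; one private RNG stream per call).
#' @param decoy_size number of correlated decoy genes (first `decoy_size`
#'   non-signature genes), default 10.
#' @param cancer_types,immune_context optional per-cohort labels (recycled);
#'   defaults alternate hot/cold.
#' @param baseline_range range of per-gene baseline expression, default c(2, 6).
#' @param os_base_hazard,pfs_base_hazard baseline event rates per month.
#' @return List of `tls_cohort` objects (fields `cohort_id`, `cancer_type`,
#'   `immune_context`, `expression`, `clinical`), with the `truth_set` attached
#'   as attribute `"truth"`.
#' @export
simulate_cohorts <- function(n_cohorts, n_samples, n_genes, truth,
                             noise_sd = 1, seed,
                             decoy_size = 10,
                             cancer_types = NULL, immune_context = NULL,
                             baseline_range = c(2, 6),
                             os_base_hazard = 0.05, pfs_base_hazard = 0.08) {
  stopifnot(inherits(truth, "truth_set"), n_cohorts >= 1)
  n_samples <- rep_len(as.integer(n_samples), n_cohorts)
  if (any(n_samples < 4L)) stop("all cohort sizes must be >= 4", call. = FALSE)
  sig <- truth$signature_genes
  if (n_genes <= length(sig))
    stop("n_genes must exceed the number of signature genes", call. = FALSE)
  n_other <- n_genes - length(sig)
  decoy_size <- min(decoy_size, n_other)
  genes <- c(sig,
             sprintf("DECOY%03d", seq_len(decoy_size)),
             if (n_other > decoy_size) sprintf("NOISE%04d", seq_len(n_other - decoy_size)))
  cohort_ids <- sprintf("cohort%02d", seq_len(n_cohorts))
  alpha <- truth$cohort_intercepts %||%
    stats::setNames(rep(0, n_cohorts), cohort_ids)
  if (is.null(names(alpha))) names(alpha) <- cohort_ids
  cancer_types <- rep_len(cancer_types %||% c("SKCM", "KIRC", "LUAD", "GBM", "BLCA", "STAD"),
                          n_cohorts)
  immune_context <- rep_len(immune_context %||% rep(c("hot", "cold"), length.out = n_cohorts),
                            n_cohorts)
  gamma <- truth$activity_effect_response
  delta <- truth$activity_effect_hazard

  with_rng(seed, {
    baseline <- stats::runif(length(genes), baseline_range[1], baseline_range[2])
    names(baseline) <- genes
    cohorts <- vector("list", n_cohorts)
    for (k in seq_len(n_cohorts)) {
      n <- n_samples[k]
      ids <- sprintf("%s_S%03d", cohort_ids[k], seq_len(n))
      a <- stats::rnorm(n)                       # latent TLS activity
      d <- stats::rnorm(n)                       # decoy factor, outcome-free
      expr <- matrix(stats::rnorm(length(genes) * n, sd = noise_sd),
                     nrow = length(genes), dimnames = list(genes, ids))
      expr <- expr + baseline
      expr[sig, ] <- expr[sig, ] + outer(truth$gene_loadings, a)
      if (decoy_size > 0) {
        dg <- sprintf("DECOY%03d", seq_len(decoy_size))
        expr[dg, ] <- expr[dg, ] + outer(rep(1, decoy_size), d)
      }
      expr <- pmax(expr, 0)

      resp <- stats::rbinom(n, 1, stats::plogis(alpha[k] + gamma * a))
      os_rate <- os_base_hazard * exp(delta * a)
      os_raw <- stats::rexp(n, os_rate)
      os_cens <- stats::runif(n, 0.01, 2 / os_base_hazard)
      os_time <- pmin(os_raw, os_cens)
      os_event <- as.integer(os_raw <= os_cens)

      pfs_raw <- stats::rexp(n, pfs_base_hazard * exp(delta * a))
      pfs_cens <- stats::runif(n, 0.01, 2 / pfs_base_hazard)
      pfs_time <- pmin(pfs_raw, pfs_cens)
      pfs_event <- as.integer(pfs_raw <= pfs_cens)

      recist <- character(n)
      for (i in seq_len(n)) {
        if (resp[i] == 1L) {
          recist[i] <- sample(c("CR", "PR", "SD"), 1, prob = c(0.2, 0.5, 0.3))
          if (recist[i] == "SD" && pfs_event[i] == 1L && pfs_time[i] <= 6)
            pfs_time[i] <- pfs_time[i] + 6   # responder rule: no SD event by month 6
        } else {
          recist[i] <- sample(c("PD", "SD"), 1, prob = c(0.8, 0.2))
          if (recist[i] == "SD") {           # non-responder SD must progress early
            pfs_event[i] <- 1L
            pfs_time[i] <- stats::runif(1, 0.5, 6)
          }
        }
      }

      clinical <- data.frame(
        sample_id = ids,
        recist = recist,
        pfs_time = round(pfs_time, 4),
        pfs_event = pfs_event,
        os_time = round(os_time, 4),
        os_event = os_event,
        tmb = round(stats::rlnorm(n, log(2), 0.6), 4),
        stringsAsFactors = FALSE
      )
      cohorts[[k]] <- structure(list(
        cohort_id = cohort_ids[k],
        cancer_type = cancer_types[k],
        immune_context = immune_context[k],
        expression = expr,
        clinical = clinical,
        latent_activity = stats::setNames(a, ids)
      ), class = "tls_cohort")
    }
    names(cohorts) <- cohort_ids
    attr(cohorts, "truth") <- truth
    cohorts
  })
}

#' @export
print.tls_cohort <- function(x, ...) {
  cat("<tls_cohort>", x$cohort_id, sprintf("(%s, %s):", x$cancer_type, x$immune_context),
      nrow(x$expression), "genes x", ncol(x$expression), "samples\n")
  invisible(x)
}

#' Simulate a spatial transcriptomics sample with planted TLS regions
#'
#' Spots cover a full `width x height` grid. `n_tls` non-overlapping disks of
#' the given radius are placed uniformly at random (bounded rejection
#' sampling); inside the disks, signature-gene expression is raised by
#' `effect` (mature samples) or `effect / 3` (immature). Disk spots are
#' annotated `mature_tls` / `immature_tls`; a `negative` sample places no
#' disks and has no annotated spots.
#'
#' @param width,height grid dimensions in spots.
#' @param n_tls number of TLS disks.
#' @param radius disk radius in spot units.
#' @param signature a [gene_set]; its members form the elevated rows.
#' @param effect expression elevation inside mature TLS disks (log2 units),
#'   must be >= 0.
#' @param maturity `"mature"`, `"immature"` or `"negative"`.
#' @param seed integer seed.
#' @param n_background number of unrelated background genes, default 100.
#' @param baseline mean background expression, default 2.
#' @param noise_sd residual SD, default 1.
#' @param section_type `"frozen"` or `"FFPE"` label.
#' @param max_tries rejection-sampling budget for disk placement.
#' @return Object of class `spatial_sample`: `sample_id`, `section_type`,
#'   `spots` (data frame `spot_id, x, y`), `expression` (genes x spots),
#'   `tls_annotation` (per spot: `mature_tls`/`immature_tls`/`none`),
#'   `maturity_label`.
#' @export
simulate_spatial <- function(width, height, n_tls, radius, signature, effect,
                             maturity = c("mature", "immature", "negative"),
                             seed, n_background = 100, baseline = 2,
                             noise_sd = 1, section_type = "frozen",
                             max_tries = 500) {
  maturity <- match.arg(maturity)
  stopifnot(inherits(signature, "gene_set"), effect >= 0, width >= 1, height >= 1)
  if (maturity != "negative" && n_tls * pi * radius^2 >= width * height)
    stop("requested TLS disks cannot fit in the grid", call. = FALSE)

  with_rng(seed, {
    grid <- expand.grid(x = seq_len(width), y = seq_len(height))
    n_spots <- nrow(grid)
    spot_id <- sprintf("spot%04d", seq_len(n_spots))

    centers <- NULL
    if (maturity != "negative" && n_tls > 0) {
      centers <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(centers) < n_tls) {
        tries <- tries + 1
        if (tries > max_tries)
          stop("could not place ", n_tls, " non-overlapping disks in ",
               max_tries, " tries", call. = FALSE)
        cx <- stats::runif(1, radius + 0.5, width - radius + 0.5)
        cy <- stats::runif(1, radius + 0.5, height - radius + 0.5)
        if (nrow(centers) == 0 ||
            all((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 > (2 * radius)^2))
          centers <- rbind(centers, c(cx, cy))
      }
    }
    in_disk <- rep(FALSE, n_spots)
    if (!is.null(centers) && nrow(centers) > 0) {
      for (r in seq_len(nrow(centers)))
        in_disk <- in_disk |
          ((grid$x - centers[r, 1])^2 + (grid$y - centers[r, 2])^2 <= radius^2)
    }
    annotation <- rep("none", n_spots)
    if (maturity == "mature") annotation[in_disk] <- "mature_tls"
    if (maturity == "immature") annotation[in_disk] <- "immature_tls"

    genes <- c(signature$members, sprintf("BG%04d", seq_len(n_background)))
    expr <- matrix(stats::rnorm(length(genes) * n_spots, mean = baseline, sd = noise_sd),
                   nrow = length(genes), dimnames = list(genes, spot_id))
    bump <- switch(maturity, mature = effect, immature = effect / 3, negative = 0)
    if (bump > 0 && any(in_disk))
      expr[signature$members, in_disk] <- expr[signature$members, in_disk] + bump
    expr <- pmax(expr, 0)

    structure(list(
      sample_id = sprintf("spatial_%s_seed%d", maturity, as.integer(seed)),
      section_type = section_type,
      spots = data.frame(spot_id = spot_id, x = grid$x, y = grid$y,
                         stringsAsFactors = FALSE),
      expression = expr,
      tls_annotation = stats::setNames(annotation, spot_id),
      maturity_label = maturity,
      centers = centers, radius = radius
    ), class = "spatial_sample")
  })
}

#' Simulate per-sample mutation counts by consequence class
#'
#' Nonsynonymous totals are lognormal with median `mean_tmb * territory_mb`,
#' split multinomially into missense, frameshift indels and stop codons;
#' synonymous and other classes are drawn proportionally and do not count
#' toward TMB.
#'
#' @param n_samples number of samples (>= 1).
#' @param mean_tmb target median TMB in mutations/Mb (> 0).
#' @param seed integer seed.
#' @param territory_mb sequenced territory, default 38 Mb.
#' @param sdlog lognormal spread of the nonsynonymous total, default 0.5.
#' @return Data frame with `sample_id` and integer columns `missense`,
#'   `frameshift_indel`, `stop_codon`, `synonymous`, `other`.
#' @export
simulate_mutations <- function(n_samples, mean_tmb, seed, territory_mb = 38,
                               sdlog = 0.5) {
  stopifnot(n_samples >= 1, mean_tmb > 0)
  with_rng(seed, {
    nonsyn <- pmax(0L, round(stats::rlnorm(n_samples, log(mean_tmb * territory_mb), sdlog)))
    split <- t(vapply(nonsyn, function(tot) {
      if (tot == 0) return(c(0L, 0L, 0L))
      as.integer(stats::rmultinom(1, tot, prob = c(0.75, 0.12, 0.13)))
    }, integer(3)))
    data.frame(
      sample_id = sprintf("S%04d", seq_len(n_samples)),
      missense = split[, 1],
      frameshift_indel = split[, 2],
      stop_codon = split[, 3],
      synonymous = stats::rpois(n_samples, 0.4 * nonsyn),
      other = stats::rpois(n_samples, 0.1 * nonsyn),
      stringsAsFactors = FALSE
    )
  })
}
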