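#' Z-score expression gene-wise
#'
#' Centers and scales every gene row to mean 0 and (population) SD 1 across
#' samples. Constant rows cannot be scaled; they are mapped to all-zero rows
#' and flagged in the `"constant_genes"` attribute.
#'
#' The population SD convention (divisor n, not n-1) is used so that a row of
#' n equally spaced values has a fixed, convention-independent image.
#'
#' @param expr numeric matrix, genes x samples, log2(x+1) scale (rownames =
#'   genes, colnames = samples). At least two samples.
#' @return A genes x samples matrix on the z scale with attribute
#'   `constant_genes` (character vector, possibly empty).
#' @export
zscore_expression <- function(expr) {
  assert_expression(expr, allow_negative = TRUE)
  if (ncol(expr) < 2L)
    stop("z-scoring needs at least 2 samples", call. = FALSE)
  mu <- rowMeans(expr)
  centered <- expr - mu
  sdev <- sqrt(rowMeans(centered^2))
  constant <- sdev < 1e-12
  sdev[constant] <- 1
  z <- centered / sdev
  z[constant, ] <- 0
  attr(z, "constant_genes") <- rownames(expr)[constant]
  z
}

#' Single-sample gene-set enrichment score
#'
#' Deterministic rank/running-sum enrichment statistic of the ssGSEA family,
#' computed per sample on z-scored expression. For each sample, genes are
#' ranked by z descending (ties resolved by stable input gene order); the
#' running sum gains `|z|^tau` (normalized over in-set genes) at in-set
#' positions and loses `1/(G - m)` at out-of-set positions. The score is the
#' "maxdiff" combination: maximum positive deviation plus minimum negative
#' deviation of the running sum, bounded in `[-1, 1]`.
#'
#' Degenerate cases: a set covering every gene has an empty decrement pool and
#' scores +1 by definition; if all in-set weights are zero (all-zero z rows),
#' increments fall back to the uniform `1/m`.
#'
#' @param z_expr z-scored genes x samples matrix (see [zscore_expression()]).
#' @param set a [gene_set]. Members absent from the matrix are dropped with a
#'   warning; an error if none remain.
#' @param tau weight exponent on `|z|`; `tau = 1` (default) weights by
#'   magnitude, `tau = 0` is purely rank-based.
#' @return Named numeric vector of per-sample enrichment scores.
#' @export
gsva_like_score <- function(z_expr, set, tau = 1) {
  stopifnot(inherits(set, "gene_set"), is.matrix(z_expr))
  genes <- rownames(z_expr)
  members <- set$members
  absent <- setdiff(members, genes)
  if (length(absent) == length(members))
    stop("no member of gene set '", set$name, "' present in the matrix", call. = FALSE)
  if (length(absent) > 0L)
    warning("gene set '", set$name, "': ", length(absent),
            " member(s) absent from matrix, dropped", call. = FALSE)
  inset_gene <- genes %in% members
  G <- nrow(z_expr)
  m <- sum(inset_gene)
  n <- ncol(z_expr)
  if (m == G) { # decrement pool empty: defined as +1
    out <- rep(1, n)
    names(out) <- colnames(z_expr)
    return(out)
  }
  dec <- 1 / (G - m)
  es <- numeric(n)
  for (j in seq_len(n)) {
    z <- z_expr[, j]
    ord <- order(z, decreasing = TRUE, method = "radix") # stable in gene order
    inset <- inset_gene[ord]
    w <- abs(z[ord])^tau
    w_in <- w * inset
    tot <- sum(w_in)
    steps <- if (tot > 0) w_in / tot else inset / m
    steps[!inset] <- -dec
    rs <- cumsum(steps)
    es[j] <- max(rs, 0) + min(rs, 0)
  }
  names(es) <- colnames(z_expr)
  es
}

#' COX-IS inflammation balance score
#'
#' Ratio-style score of pro-tumor (CP) vs anti-tumor (CI) inflammatory gene
#' expression. Per sample, expression is mapped back to the linear scale
#' (`2^x - 1`), averaged over the present CP and CI genes, and the score is
#' `log2((mean CP + eps) / (mean CI + eps))`. Positive values indicate a
#' pro-tumor inflammatory balance.
#'
#' @param expr genes x samples matrix on log2(x+1) scale.
#' @param cp,ci [gene_set]s of pro- and anti-tumor genes; defaults to the
#'   bundled 9-gene CP and 15-gene CI lists ([coxis_genes()]). Missing genes
#'   are dropped with a warning; all-absent is an error.
#' @param eps pseudocount guarding the ratio, default 1e-6.
#' @return Named numeric vector of per-sample scores.
#' @export
coxis_score <- function(expr, cp = NULL, ci = NULL, eps = 1e-6) {
  assert_expression(expr)
  defaults <- if (is.null(cp) || is.null(ci)) coxis_genes()
  cp <- cp %||% defaults$cp
  ci <- ci %||% defaults$ci
  take <- function(set) {
    present <- intersect(set$members, rownames(expr))
    if (length(present) == 0L)
      stop("no ", set$name, " gene present in expression matrix", call. = FALSE)
    if (length(present) < length(set$members))
      warning(set$name, ": ", length(set$members) - length(present),
              " gene(s) absent, dropped", call. = FALSE)
    lin <- 2^expr[present, , drop = FALSE] - 1
    colMeans(lin)
  }
  pos <- take(cp)
  neg <- take(ci)
  out <- log2((pos + eps) / (neg + eps))
  names(out) <- colnames(expr)
  out
}

#' Tumor mutational burden
#'
#' Nonsynonymous mutations (missense + frameshift indels + stop codons) per
#' megabase of sequenced territory; synonymous and other consequence classes
#' are excluded.
#'
#' @param mutations a mutation table as produced by [simulate_mutations()]: a
#'   data frame with `sample_id` and integer count columns `missense`,
#'   `frameshift_indel`, `stop_codon`, `synonymous`, `other`.
#' @param territory_mb sequenced territory in Mb (38 for TCGA exomes).
#' @return Named numeric vector of mutations/Mb.
#' @export
tmb <- function(mutations, territory_mb = 38) {
  stopifnot(is.data.frame(mutations), territory_mb > 0)
  need <- c("sample_id", "missense", "frameshift_indel", "stop_codon")
  if (!all(need %in% names(mutations)))
    stop("mutation table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  counts <- mutations[, c("missense", "frameshift_indel", "stop_codon")]
  if (any(counts < 0)) stop("negative mutation counts", call. = FALSE)
  cnt <- counts$missense + counts$frameshift_indel + counts$stop_codon
  stats::setNames(cnt / territory_mb, mutations$sample_id)
}

#' Median stratification into high/low groups
#'
#' Values strictly above the median are `"high"`; values at or below it are
#' `"low"` (ties go to `"low"`, a fixed deterministic rule). A fully constant
#' input yields all-`"low"` with a degeneracy warning.
#'
#' @param values named numeric vector; `NA`s propagate.
#' @return Character vector (`"high"`/`"low"`) with the input's names.
#' @export
median_stratify <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("median stratification needs >= 2 non-missing values", call. = FALSE)
  med <- stats::median(v)
  if (max(v) == min(v))
    warning("all values identical: median split is degenerate (all 'low')", call. = FALSE)
  out <- ifelse(values > med, "high", "low")
  out[is.na(values)] <- NA_character_
  names(out) <- names(values)
  out
}
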