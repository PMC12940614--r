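#' Read/write an expression matrix as TSV
#'
#' Genes as rows (first column `gene`), header row of sample ids, tab
#' separated. Duplicate gene symbols or ragged rows are rejected with a
#' line-numbered message.
#'
#' @param path file path.
#' @return [read_expression_tsv()]: numeric genes x samples matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >= 1 sample", call. = FALSE)
  genes <- df[[1]]
  dup <- which(duplicated(genes))
  if (length(dup) > 0)
    stop("duplicate gene symbol at data row(s) ", paste(dup, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(df[, -1, drop = FALSE], 1, function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric expression value at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  rownames(m) <- genes
  assert_expression(m, allow_negative = TRUE)
  m
}

#' @rdname read_expression_tsv
#' @param expr genes x samples matrix.
#' @param digits significant digits written (fixed formatting keeps file
#'   hashes portable).
#' @export
write_expression_tsv <- function(expr, path, digits = 6L) {
  assert_expression(expr, allow_negative = TRUE)
  df <- data.frame(gene = rownames(expr),
                   apply(expr, 2, format_num, digits = digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a clinical table as TSV
#'
#' Columns: `sample_id`, `recist`, `pfs_time`, `pfs_event`, `os_time`,
#' `os_event`, `tmb`. Validation is strict: times must be strictly positive
#' when present, events binary, RECIST in {CR, PR, SD, PD, NA}; violations
#' report the offending row numbers.
#'
#' @param path file path.
#' @return [read_clinical_tsv()]: validated data frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "recist", "pfs_time", "pfs_event", "os_time", "os_event", "tmb")
  if (!all(need %in% names(df)))
    stop("clinical TSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  check_rows <- function(bad, what) {
    if (any(bad))
      stop("clinical row(s) ", paste(which(bad), collapse = ", "), ": ", what, call. = FALSE)
  }
  check_rows(duplicated(df$sample_id), "duplicate sample_id")
  check_rows(!is.na(df$recist) & !df$recist %in% c("CR", "PR", "SD", "PD"),
             "unknown RECIST category")
  check_rows(!is.na(df$pfs_time) & df$pfs_time <= 0, "pfs_time must be > 0")
  check_rows(!is.na(df$os_time) & df$os_time <= 0, "os_time must be > 0")
  check_rows(!is.na(df$pfs_event) & !df$pfs_event %in% c(0, 1), "pfs_event must be 0/1")
  check_rows(!is.na(df$os_event) & !df$os_event %in% c(0, 1), "os_event must be 0/1")
  check_rows(!is.na(df$tmb) & df$tmb < 0, "tmb must be >= 0")
  df
}

#' @rdname read_clinical_tsv
#' @param clinical clinical data frame.
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a spatial spot table as CSV
#'
#' Columns `spot_id`, `x`, `y`, `annotation` (the expression matrix travels
#' separately as a genes x spots TSV).
#'
#' @param path file path.
#' @export
read_spot_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "x", "y", "annotation")
  if (!all(need %in% names(df)))
    stop("spot CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  bad <- !df$annotation %in% c("mature_tls", "immature_tls", "none")
  if (any(bad))
    stop("spot row(s) ", paste(which(bad), collapse = ", "),
         ": unknown annotation value", call. = FALSE)
  df
}

#' @rdname read_spot_csv
#' @param sample a `spatial_sample`.
#' @export
write_spot_csv <- function(sample, path) {
  stopifnot(inherits(sample, "spatial_sample"))
  df <- cbind(sample$spots,
              annotation = unname(sample$tls_annotation[sample$spots$spot_id]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a truth set as JSON
#'
#' @param truth a [truth_set()].
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  x <- unclass(truth)
  x$gene_loadings <- as.list(x$gene_loadings)           # keep names in JSON
  if (!is.null(x$cohort_intercepts))
    x$cohort_intercepts <- as.list(x$cohort_intercepts)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth_set(x$signature_genes,
            gene_loadings = unlist(x$gene_loadings),
            activity_effect_response = x$activity_effect_response,
            activity_effect_hazard = x$activity_effect_hazard,
            cohort_intercepts = if (length(x$cohort_intercepts)) unlist(x$cohort_intercepts))
}

#' Write a per-cohort effect table as TSV
#'
#' Forest-plot-ready layout: one row per study plus a pooled row.
#'
#' @param effects effect data frame (rows from the fit functions).
#' @param meta optional `meta_result` appended as the pooled row.
#' @param path output path.
#' @export
write_effects_tsv <- function(effects, path, meta = NULL) {
  eff <- as.data.frame(effects)
  out <- data.frame(study = eff$cohort_id, estimate = format_num(eff$estimate),
                    se = format_num(eff$se), p = format_num(eff$p),
                    n = eff$n, events = eff$events,
                    weight = if (!is.null(meta)) format_num(unname(meta$weights[eff$cohort_id])) else NA,
                    stringsAsFactors = FALSE)
  if (!is.null(meta))
    out <- rbind(out, data.frame(study = paste0("POOLED_", meta$model),
                                 estimate = format_num(meta$pooled),
                                 se = format_num(meta$se), p = format_num(meta$p),
                                 n = sum(eff$n), events = sum(eff$events),
                                 weight = "1", stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
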