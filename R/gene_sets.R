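#' Construct a gene set
#'
#' A gene set is a named, ordered collection of unique gene symbols, the unit
#' handled by every scoring and discovery function in the package.
#'
#' @param name character scalar, the set's name.
#' @param members character vector of gene symbols. Duplicates are removed with
#'   a warning; an empty set is an error.
#' @return An object of class `gene_set`: a list with `name` and `members`.
#' @examples
#' gene_set("demo", c("CXCL13", "CCL19", "CCL21"))
#' @export
gene_set <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- as.character(members)
  members <- members[!is.na(members) & nzchar(members)]
  if (length(members) == 0L) stop("gene set '", name, "' is empty", call. = FALSE)
  if (anyDuplicated(members)) {
    warning("gene set '", name, "': duplicate members removed", call. = FALSE)
    members <- unique(members)
  }
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set>", x$name, "-", length(x$members), "genes\n")
  cat(" ", paste(utils::head(x$members, 10), collapse = ", "),
      if (length(x$members) > 10) "...", "\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT dialect: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members within
#' a set are dropped with a warning; malformed lines (fewer than three fields)
#' raise a line-numbered error.
#'
#' @param path file path.
#' @return Named list of [gene_set] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, ": expected name, description and >= 1 member", call. = FALSE)
    gene_set(f[1], f[-c(1, 2)])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in GMT file", call. = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set] or list of them.
#' @param path output path.
#' @param description description field written for each set (recycled).
#' @export
write_gmt <- function(sets, path, description = "tlsmeta") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    paste(c(s$name, description[i], s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' The 17-gene PredictTLS signature
#'
#' The de novo TLS signature selected by the log-odds-ratio cutoff sweep
#' (cutoff 0.145): chemokines and receptors mediating lymphocyte recruitment
#' (CCL8, CXCL9/10/11, CXCR3, CCR3, CCR5, ICAM1), B-cell follicle and plasma
#' cell markers (CXCL13, CD40, CD38, DERL3, SSR4), T-cell checkpoint molecules
#' (PDCD1, TIGIT, CD274) and the lymphocyte pro-survival kinase PIM2.
#'
#' @return A [gene_set] of 17 symbols.
#' @export
predict_tls_signature <- function() {
  read_gmt(system.file("extdata", "predict_tls.gmt", package = "tlsmeta"))[["PredictTLS"]]
}

#' COX-IS component gene lists
#'
#' Pro-tumor (CP) and anti-tumor (CI) inflammatory gene lists used by
#' [coxis_score()].
#'
#' @return List with `gene_set` elements `cp` (9 genes) and `ci` (15 genes).
#' @export
coxis_genes <- function() {
  sets <- read_gmt(system.file("extdata", "coxis.gmt", package = "tlsmeta"))
  list(cp = sets[["COXIS_CP"]], ci = sets[["COXIS_CI"]])
}

#' Normalize gene symbols to HGNC style
#'
#' Uppercases, strips hyphens (`ICAM-1` -> `ICAM1`) and maps a small table of
#' legacy aliases (`IL8` -> `CXCL8`) when `apply_aliases = TRUE`. COX-IS lists
#' keep `IL8` as given, so aliasing is off by default.
#'
#' @param x character vector of symbols.
#' @param apply_aliases map known legacy aliases to current symbols.
#' @return Character vector of normalized symbols.
#' @export
normalize_symbols <- function(x, apply_aliases = FALSE) {
  out <- gsub("-", "", toupper(trimws(x)), fixed = TRUE)
  if (apply_aliases) {
    al <- symbol_aliases()
    hit <- out %in% names(al)
    out[hit] <- al[out[hit]]
  }
  out
}

#' @rdname normalize_symbols
#' @export
symbol_aliases <- function() {
  c(IL8 = "CXCL8", MS4A1 = "MS4A1", PDL1 = "CD274", PD1 = "PDCD1", B7H1 = "CD274")
}
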