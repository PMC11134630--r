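#' Gene-set over-representation tests
#'
#' Fisher's exact test of the overlap between a hit list and each
#' annotation set within a declared universe. The 2x2 table per set is
#' `(hits & anno, hits & !anno, !hits & anno, !hits & !anno)`; the
#' sample odds ratio `ad/bc` is reported (with an optional
#' Haldane-Anscombe 0.5 correction when a cell is zero) along with the
#' exact hypergeometric p-value and BH q-values across the tested sets.
#'
#' @param hits Character vector of significant gene ids (subset of
#'   `universe`).
#' @param annotations Named list of annotation gene sets (each a subset
#'   of `universe`), or a single character vector.
#' @param universe Character vector of all testable gene ids (nonempty).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @param haldane Add 0.5 to every cell of the odds ratio when any cell
#'   is zero.
#' @return Data frame with one row per set: `set`, the four cell counts
#'   `n_hit_anno`, `n_hit_only`, `n_anno_only`, `n_rest`, `odds_ratio`,
#'   `p`, `q`.
#' @export
#' @examples
#' u <- paste0("g", 1:100)
#' overrep_test(u[1:20], list(s = u[15:24]), u)
overrep_test <- function(hits, annotations, universe,
                         alternative = c("greater", "two.sided"),
                         haldane = TRUE) {
  alternative <- match.arg(alternative)
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (!all(hits %in% universe))
    stop("hits contain ids outside the universe")
  if (!is.list(annotations)) annotations <- list(set = annotations)
  if (is.null(names(annotations)))
    names(annotations) <- paste0("set", seq_along(annotations))

  rows <- lapply(names(annotations), function(nm) {
    anno <- unique(annotations[[nm]])
    if (!all(anno %in% universe))
      stop("annotation set '", nm, "' contains ids outside the universe")
    a <- length(intersect(hits, anno))
    b <- length(hits) - a
    c_ <- length(anno) - a
    d <- length(universe) - a - b - c_
    or <- if ((b * c_) == 0 || a * d == 0) {
      if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
      else (a * d) / (b * c_)
    } else (a * d) / (b * c_)
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = alternative)$p.value
    data.frame(set = nm, n_hit_anno = a, n_hit_only = b,
               n_anno_only = c_, n_rest = d, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Tissue-specific gene sets from an expression atlas table
#'
#' A gene belongs to a tissue's set iff its expression in that tissue is
#' strictly more than `fold` times its whole-body expression.
#'
#' @param tissue_expr Data frame or matrix, genes in rows (rownames or a
#'   `gene_id` column), tissues in columns, including a whole-body
#'   column.
#' @param whole_body Name of the whole-body column.
#' @param fold Fold-change cutoff (strict `>`), default 2.
#' @return Named list of per-tissue gene-id vectors.
#' @export
tissue_specific_genes <- function(tissue_expr, whole_body = "whole_body",
                                  fold = 2) {
  d <- as.data.frame(tissue_expr)
  if ("gene_id" %in% names(d)) {
    rownames(d) <- d$gene_id
    d$gene_id <- NULL
  }
  if (!whole_body %in% names(d))
    stop("missing whole-body column '", whole_body, "'")
  wb <- d[[whole_body]]
  tissues <- setdiff(names(d), whole_body)
  sets <- lapply(tissues, function(tt)
    rownames(d)[d[[tt]] > fold * wb])
  stats::setNames(sets, tissues)
}

#' Read gene sets from a GMT-like file
#'
#' Each line: set name, a description field (may be empty), then gene
#' ids, all tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >= 1 gene): ", l)
    f[-(1:2)]
  })
  stats::setNames(sets, vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], ""))
}

#' Write gene sets to a GMT-like file
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param description Description field written for each set.
#' @export
write_gmt <- function(sets, path, description = "") {
  if (is.null(names(sets))) stop("sets must be named")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
}
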