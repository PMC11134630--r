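#' Heterogeneity of expression evolution across replicates
#'
#' For a gene set, let `x_i` be the vector of expression changes of the
#' set's genes in replicate `i`. The heterogeneity statistic is the mean
#' pairwise correlation distance over the `N = choose(R, 2)` unordered
#' replicate pairs:
#' \deqn{H = \sum_{i<j} (1 - cor(x_i, x_j)) / N \in [0, 2].}
#' `H = 0` when all replicates changed identically (up to affine
#' rescaling) and approaches 2 for perfectly anti-correlated changes.
#' A replicate whose vector has zero variance makes its pairs'
#' correlations undefined; those pairs are dropped with a warning and
#' `N` reduced.
#'
#' @param changes Genes-by-replicates numeric matrix of expression
#'   changes (e.g. `per_replicate_change(m)$lfc`).
#' @param gene_set Character vector of gene ids (rownames of `changes`);
#'   `NULL` uses all genes. At least 3 set genes must be present.
#' @param method Correlation type, `"pearson"` (default) or
#'   `"spearman"`.
#' @param name Label stored in the result.
#' @return List of class `heterogeneity_result`: `name`, `H`,
#'   `pair_cors` (named vector over pairs), `N`, `n_genes`.
#' @export
#' @examples
#' ch <- cbind(R1 = c(1, 2, 3), R2 = c(1, 2, 3), R3 = c(3, 2, 1))
#' rownames(ch) <- paste0("g", 1:3)
#' heterogeneity(ch)$H  # (0 + 2 + 2) / 3
heterogeneity <- function(changes, gene_set = NULL,
                          method = c("pearson", "spearman"),
                          name = "set") {
  method <- match.arg(method)
  changes <- as.matrix(changes)
  if (ncol(changes) < 2L) stop("need >= 2 replicates")
  if (!is.null(gene_set)) {
    hit <- intersect(gene_set, rownames(changes))
    if (length(hit) < 3L)
      stop("gene set overlaps fewer than 3 genes of the change matrix")
    changes <- changes[hit, , drop = FALSE]
  }
  R <- ncol(changes)
  cm <- suppressWarnings(stats::cor(changes, method = method))
  pairs <- utils::combn(R, 2L)
  cors <- cm[cbind(pairs[1, ], pairs[2, ])]
  labels <- paste(colnames(changes)[pairs[1, ]],
                  colnames(changes)[pairs[2, ]], sep = ":")
  ok <- !is.na(cors)
  if (!all(ok)) {
    warning(sum(!ok), " replicate pair(s) with undefined correlation dropped")
    cors <- cors[ok]; labels <- labels[ok]
  }
  if (!length(cors)) stop("no replicate pair has a defined correlation")
  structure(list(name = name,
                 H = sum(1 - cors) / length(cors),
                 pair_cors = stats::setNames(cors, labels),
                 N = length(cors),
                 n_genes = nrow(changes)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("heterogeneity '%s': H = %.4f over %d pairs (%d genes)\n",
              x$name, x$H, x$N, x$n_genes))
  invisible(x)
}

#' Compare the heterogeneity of a focal gene set with backgrounds
#'
#' Three complementary views of whether a focal set (e.g.
#' reproduction-associated genes) evolved more heterogeneously than
#' background genes: (1) bootstrap distributions of `H` obtained by
#' resampling genes within each set with replacement; (2) the empirical
#' quantile of the focal `H` among `n_random` size-matched random sets
#' drawn from the background; (3) a Mann-Whitney test between the focal
#' and background bootstrap distributions.
#'
#' @param changes Genes-by-replicates change matrix.
#' @param focal_set Character vector of focal gene ids (>= 3 present).
#' @param background_sets Named list of additional gene sets to profile
#'   alongside; the all-genes background is always included.
#' @param n_boot Bootstrap resamples per set (> 1).
#' @param n_random Number of size-matched random sets.
#' @param seed Optional seed.
#' @param method Correlation type.
#' @return List with `H` (named vector of point estimates), `boot`
#'   (named list of bootstrap `H` vectors), `random_H`, `focal_quantile`
#'   (fraction of random sets with `H` below the focal `H`),
#'   `mw_p_vs_background`.
#' @export
compare_gene_sets <- function(changes, focal_set,
                              background_sets = list(),
                              n_boot = 1000L, n_random = 1000L,
                              seed = NULL, method = "pearson") {
  if (n_boot <= 1L)
    stop("n_boot must exceed 1: a single resample gives a degenerate ",
         "bootstrap distribution")
  if (!is.null(seed)) set.seed(seed)
  changes <- as.matrix(changes)
  all_genes <- rownames(changes)
  focal <- intersect(focal_set, all_genes)
  if (length(focal) < 3L) stop("focal set smaller than 3 genes")

  sets <- c(list(focal = focal, background = all_genes), background_sets)
  boot_H <- lapply(names(sets), function(nm) {
    g <- intersect(sets[[nm]], all_genes)
    sub <- changes[g, , drop = FALSE]
    replicate(n_boot, {
      res <- sub[sample.int(nrow(sub), replace = TRUE), , drop = FALSE]
      H_or_na(res, method)
    })
  })
  names(boot_H) <- names(sets)

  k <- length(focal)
  random_H <- replicate(n_random, {
    g <- sample(all_genes, k)
    H_or_na(changes[g, , drop = FALSE], method)
  })
  Hs <- vapply(names(sets), function(nm)
    heterogeneity(changes, intersect(sets[[nm]], all_genes),
                  method = method, name = nm)$H, 1)
  mw <- suppressWarnings(
    stats::wilcox.test(boot_H$focal, boot_H$background,
                       alternative = "greater", exact = FALSE))
  list(H = Hs,
       boot = boot_H,
       random_H = random_H,
       focal_quantile = mean(random_H < Hs[["focal"]], na.rm = TRUE),
       mw_p_vs_background = mw$p.value)
}

H_or_na <- function(sub, method) {
  tryCatch(suppressWarnings(heterogeneity(sub, method = method)$H),
           error = function(e) NA_real_)
}

#' PCA of a gene-subset expression (or change) matrix
#'
#' Restricts a genes-by-samples matrix to a gene set and runs
#' [pca_fixed()] on its transpose, so that samples (or replicates) get
#' scores. Used to visualise replicate-specific evolution of, e.g.,
#' reproduction-associated genes.
#'
#' @param mat Genes-by-samples numeric matrix.
#' @param gene_set Character vector of gene ids; `NULL` keeps all.
#' @return An `evoiso_pca` (samples are rows of `scores`).
#' @export
subset_pca <- function(mat, gene_set = NULL) {
  mat <- as.matrix(mat)
  if (!is.null(gene_set)) {
    hit <- intersect(gene_set, rownames(mat))
    if (length(hit) < 2L) stop("gene set overlaps fewer than 2 genes")
    mat <- mat[hit, , drop = FALSE]
  }
  pca_fixed(t(mat))
}

#' Direction bias of expression changes in a gene set
#'
#' Among the "changed" gene-replicate calls of a set, the fraction that
#' are up-regulations, with an exact binomial test against 0.5. If a
#' background set is supplied, a Fisher 2x2 test (up/down by
#' focal/background) asks whether the up-bias is specific to the focal
#' set.
#'
#' @param direction Genes-by-replicates character matrix of calls
#'   (`"up"`, `"down"`, `"none"`), e.g.
#'   `per_replicate_change(m)$direction`.
#' @param focal_set Gene ids of the focal set.
#' @param background_set Optional gene ids of a comparison set (calls in
#'   the focal set are excluded from it).
#' @return List with `n_up`, `n_down`, `fraction_up`, `binom_p`, and —
#'   with a background — `background_fraction_up`, `fisher_p`,
#'   `odds_ratio`.
#' @export
direction_bias <- function(direction, focal_set, background_set = NULL) {
  direction <- as.matrix(direction)
  focal <- intersect(focal_set, rownames(direction))
  if (!length(focal)) stop("focal set absent from the call matrix")
  dd <- direction[focal, , drop = FALSE]
  n_up <- sum(dd == "up"); n_down <- sum(dd == "down")
  n <- n_up + n_down
  out <- list(n_up = n_up, n_down = n_down,
              fraction_up = if (n > 0) n_up / n else NA_real_,
              binom_p = if (n > 0)
                stats::binom.test(n_up, n, 0.5)$p.value else NA_real_)
  if (!is.null(background_set)) {
    bg <- setdiff(intersect(background_set, rownames(direction)), focal)
    db <- direction[bg, , drop = FALSE]
    b_up <- sum(db == "up"); b_down <- sum(db == "down")
    tab <- matrix(c(n_up, n_down, b_up, b_down), 2,
                  dimnames = list(c("up", "down"), c("focal", "background")))
    ft <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      stats::fisher.test(tab) else NULL
    out$background_fraction_up <-
      if (b_up + b_down > 0) b_up / (b_up + b_down) else NA_real_
    out$fisher_p <- if (is.null(ft)) NA_real_ else ft$p.value
    out$odds_ratio <- if (is.null(ft)) NA_real_ else unname(ft$estimate)
  }
  out
}
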