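#' Construct a replicate-labelled count matrix
#'
#' @param counts Genes-by-samples matrix of nonnegative integers.
#' @param meta Data frame with one row per sample: `sample_id`,
#'   `replicate` (ancestral samples labelled `"anc"`), `group`
#'   (`"ancestral"` / `"evolved"`).
#' @param lib_sizes Optional per-sample library sizes (> 0); defaults to
#'   column sums.
#' @return List of class `count_matrix` with `counts`, `meta`,
#'   `lib_sizes`.
#' @export
count_matrix <- function(counts, meta, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (nrow(meta) != ncol(counts))
    stop("meta rows must match count columns")
  need <- c("sample_id", "replicate", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  if (!all(meta$group %in% c("ancestral", "evolved")))
    stop("group must be 'ancestral' or 'evolved'")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  colnames(counts) <- meta$sample_id
  structure(list(counts = counts, meta = meta,
                 lib_sizes = as.numeric(lib_sizes)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", sum(x$meta$group == "evolved"), "evolved )\n")
  invisible(x)
}

#' Counts per million
#'
#' @param m A [count_matrix()].
#' @return Genes-by-samples matrix of `count / lib_size * 1e6`.
#' @export
cpm <- function(m) {
  sweep(m$counts, 2L, m$lib_sizes, `/`) * 1e6
}

#' Expression filter on counts per million
#'
#' Keeps a gene only if its CPM exceeds `threshold` in every sample,
#' the usual low-expression filter before dispersion estimation.
#'
#' @param m A [count_matrix()].
#' @param threshold CPM cutoff (>= 0); the comparison is strict.
#' @return The filtered `count_matrix`.
#' @export
cpm_filter <- function(m, threshold = 0.1) {
  if (threshold < 0) stop("threshold must be >= 0")
  keep <- apply(cpm(m) > threshold, 1L, all)
  m$counts <- m$counts[keep, , drop = FALSE]
  m
}

# ---- NB group-mean fitting ------------------------------------------------
# Log-link NB GLM with a group factor and log library-size offsets has a
# per-group intercept as its only parameter; the score equation
#   sum_j (y_j - mu_j) / (1 + phi * mu_j) = 0,  mu_j = exp(beta + o_j)
# is solved per gene by Newton iterations vectorised over genes.

nb_fit_beta <- function(Y, log_off, phi, max_iter = 60L, tol = 1e-10) {
  G <- nrow(Y)
  phi <- rep_len(pmax(phi, 1e-10), G)
  rs <- rowSums(Y)
  beta <- log(pmax(rs, 0.5) / sum(exp(log_off)))
  converged <- rep(FALSE, G)
  for (it in seq_len(max_iter)) {
    Mu <- exp(outer(beta, rep(1, length(log_off))) +
                matrix(log_off, G, length(log_off), byrow = TRUE))
    denom <- 1 + phi * Mu
    score <- rowSums((Y - Mu) / denom)
    info <- rowSums(Mu * (1 + phi * Y) / denom^2)
    step <- score / pmax(info, 1e-12)
    step <- pmax(pmin(step, 5), -5)
    beta <- beta + step
    converged <- abs(step) < tol
    if (all(converged)) break
  }
  beta[rs == 0] <- -30        # empty group: mean pinned near zero
  converged[rs == 0] <- TRUE
  list(beta = beta, converged = converged)
}

nb_loglik_rows <- function(Y, Mu, phi) {
  phi <- rep_len(pmax(phi, 1e-10), nrow(Y))
  rowSums(stats::dnbinom(Y, mu = Mu, size = 1 / phi, log = TRUE))
}

# Fit the group-factor model for all genes: returns per-gene log-lik,
# fitted betas (genes x groups) and a convergence flag. With
# cox_reid = TRUE the log-likelihood is the Cox-Reid adjusted profile
# likelihood used for dispersion estimation: for this one-parameter-
# per-group model the adjustment is half the log Fisher information of
# each fitted intercept, sum_j mu_j / (1 + phi * mu_j).
nb_fit_groups <- function(Y, log_off, groups, phi, cox_reid = FALSE) {
  groups <- factor(groups)
  G <- nrow(Y)
  phi <- rep_len(pmax(phi, 1e-10), G)
  betas <- matrix(NA_real_, G, nlevels(groups),
                  dimnames = list(rownames(Y), levels(groups)))
  ll <- numeric(G)
  conv <- rep(TRUE, G)
  for (lev in levels(groups)) {
    j <- which(groups == lev)
    fit <- nb_fit_beta(Y[, j, drop = FALSE], log_off[j], phi)
    betas[, lev] <- fit$beta
    conv <- conv & fit$converged
    Mu <- exp(outer(fit$beta, rep(1, length(j))) +
                matrix(log_off[j], G, length(j), byrow = TRUE))
    ll <- ll + nb_loglik_rows(Y[, j, drop = FALSE], Mu, phi)
    if (cox_reid) {
      info <- rowSums(Mu / (1 + phi * Mu))
      ll <- ll - 0.5 * log(pmax(info, 1e-12))
    }
  }
  list(loglik = ll, betas = betas, converged = conv)
}

#' Estimate negative-binomial dispersions
#'
#' Two-stage estimate for a group-structured count matrix: a common
#' dispersion `phi0` maximising the pooled Cox-Reid adjusted profile
#' likelihood (APL; group means are refitted at each candidate `phi`
#' and the adjustment compensates for the estimated means), and
#' per-gene dispersions from empirical-Bayes weighted-likelihood
#' shrinkage: on a grid of dispersions around `phi0`, each gene
#' maximises its own APL plus `prior_df / df_resid` times the average
#' APL over all genes, pulling noisy per-gene estimates towards the
#' common value with `prior_df` prior degrees of freedom. Genes with
#' fewer than 2 residual degrees of freedom fall back to `phi0`.
#'
#' @param m A [count_matrix()].
#' @param groups Grouping factor defining the fitted means; default the
#'   replicate label of evolved samples (ancestral samples are ignored).
#' @param prior_df Prior degrees of freedom of the shrinkage (default
#'   10).
#' @return List with `common` (`phi0`), `per_gene` (unshrunk per-gene
#'   APL maximisers), `shrunk` (the EB-shrunk per-gene dispersions).
#' @export
estimate_dispersion <- function(m, groups = NULL, prior_df = 10) {
  if (is.null(groups)) {
    use <- m$meta$group == "evolved"
    Y <- m$counts[, use, drop = FALSE]
    off <- log(m$lib_sizes[use])
    groups <- factor(m$meta$replicate[use])
  } else {
    Y <- m$counts
    off <- log(m$lib_sizes)
    groups <- factor(groups)
  }
  G <- nrow(Y)
  df_resid <- ncol(Y) - nlevels(groups)
  if (df_resid < 1L) stop("no residual degrees of freedom")

  prof <- function(log_phi)
    -sum(nb_fit_groups(Y, off, groups, exp(log_phi),
                       cox_reid = TRUE)$loglik)
  opt <- stats::optimize(prof, interval = log(c(1e-6, 5)))
  phi0 <- exp(opt$minimum)
  # boundary: effectively Poisson data
  if (phi0 < 2e-6) phi0 <- 0

  # weighted-likelihood empirical Bayes on a dispersion grid
  grid <- if (phi0 > 0) phi0 * 2^seq(-8, 8, length.out = 25)
          else 10^seq(-6, 0.5, length.out = 25)
  apl <- vapply(grid, function(ph)
    nb_fit_groups(Y, off, groups, ph, cox_reid = TRUE)$loglik,
    numeric(G))
  if (G == 1L) apl <- matrix(apl, nrow = 1L)
  per_gene <- grid[max.col(apl, ties.method = "first")]
  if (df_resid < 2L) {
    shrunk <- rep(phi0, G)
  } else {
    prior_n <- prior_df / df_resid
    score <- apl + matrix(prior_n * colMeans(apl), G, length(grid),
                          byrow = TRUE)
    shrunk <- grid[max.col(score, ties.method = "first")]
  }
  list(common = phi0,
       per_gene = stats::setNames(per_gene, rownames(Y)),
       shrunk = stats::setNames(shrunk, rownames(Y)))
}

#' Likelihood-ratio test for among-replicate expression divergence
#'
#' Per gene, a negative-binomial GLM with log link and log-library-size
#' offsets is fitted to the evolved samples under the full model
#' (expression = replicate factor) and the null model (intercept only);
#' the statistic `2 * (ll_full - ll_null)` is referred to a chi-square
#' distribution with `n_replicates - 1` degrees of freedom, and
#' Benjamini-Hochberg adjusted q-values are computed across converged
#' genes. Only evolved samples enter this test.
#'
#' @param m A filtered [count_matrix()].
#' @param dispersion Per-gene dispersions or a scalar; `NULL` uses the
#'   estimated common dispersion (`estimate_dispersion(m)$common`),
#'   which is exactly calibrated when genes share one dispersion;
#'   pass `estimate_dispersion(m)$shrunk` for dispersion-heterogeneous
#'   data.
#' @param fdr FDR threshold recorded in the `divergent` call column.
#' @return Data frame of class `divergence_result`: `gene`, `stat`,
#'   `df`, `p`, `q`, `divergent`, `converged`.
#' @export
divergence_lrt <- function(m, dispersion = NULL, fdr = 0.05) {
  use <- m$meta$group == "evolved"
  if (!any(use)) stop("no evolved samples")
  Y <- m$counts[, use, drop = FALSE]
  off <- log(m$lib_sizes[use])
  repl <- factor(m$meta$replicate[use])
  if (nlevels(repl) < 2L) stop("need >= 2 replicates")
  if (min(table(repl)) < 2L)
    stop("need >= 2 samples per replicate for the divergence test")
  if (is.null(dispersion)) dispersion <- estimate_dispersion(m)$common
  phi <- rep_len(dispersion, nrow(Y))

  full <- nb_fit_groups(Y, off, repl, phi)
  null <- nb_fit_groups(Y, off, rep("all", ncol(Y)), phi)
  stat <- pmax(2 * (full$loglik - null$loglik), 0)
  df <- nlevels(repl) - 1L
  conv <- full$converged & null$converged
  p <- ifelse(conv, stats::pchisq(stat, df, lower.tail = FALSE), NA_real_)
  q <- rep(NA_real_, length(p))
  q[conv] <- stats::p.adjust(p[conv], "BH")
  out <- data.frame(gene = rownames(Y), stat = stat, df = df, p = p, q = q,
                    divergent = !is.na(q) & q < fdr, converged = conv,
                    stringsAsFactors = FALSE)
  class(out) <- c("divergence_result", class(out))
  out
}

#' Per-replicate expression change versus the ancestral mean
#'
#' For each gene and evolved replicate, the log2 fold-change of the
#' replicate's mean CPM over the ancestral mean CPM (both offset by a
#' pseudo-count, default 0.5 CPM). A gene is called "changed" in a
#' replicate when `|log2FC|` exceeds `lfc_threshold` and the
#' replicate-vs-rest contrast (NB GLM LRT on the evolved samples, 1 df)
#' is significant after BH correction over all gene-by-replicate tests.
#'
#' @param m A filtered [count_matrix()] containing ancestral samples.
#' @param dispersion Per-gene dispersions or scalar; `NULL` estimates
#'   them.
#' @param lfc_threshold Absolute log2 fold-change needed for a call.
#' @param pseudo_cpm Pseudo-count on the CPM scale.
#' @param fdr BH threshold for the contrast test.
#' @return List with matrices `lfc`, `p`, `q` (genes x replicates) and
#'   `direction` (`"up"`, `"down"`, `"none"`).
#' @export
per_replicate_change <- function(m, dispersion = NULL, lfc_threshold = 1,
                                 pseudo_cpm = 0.5, fdr = 0.05) {
  anc <- m$meta$group == "ancestral"
  if (!any(anc)) stop("no ancestral samples")
  evo <- !anc
  cp <- cpm(m)
  repls <- unique(m$meta$replicate[evo])
  anc_mean <- rowMeans(cp[, anc, drop = FALSE])

  if (is.null(dispersion)) dispersion <- estimate_dispersion(m)$common
  phi <- rep_len(dispersion, nrow(m$counts))
  Y <- m$counts[, evo, drop = FALSE]
  off <- log(m$lib_sizes[evo])
  evo_repl <- m$meta$replicate[evo]

  G <- nrow(Y)
  lfc <- p <- matrix(NA_real_, G, length(repls),
                     dimnames = list(rownames(Y), repls))
  null <- nb_fit_groups(Y, off, rep("all", ncol(Y)), phi)
  for (r in repls) {
    lab <- ifelse(evo_repl == r, "this", "rest")
    if (length(unique(lab)) < 2L)
      stop("replicate-vs-rest contrast needs >= 2 replicates")
    two <- nb_fit_groups(Y, off, lab, phi)
    stat <- pmax(2 * (two$loglik - null$loglik), 0)
    p[, r] <- stats::pchisq(stat, 1L, lower.tail = FALSE)
    rmean <- rowMeans(cp[, evo, drop = FALSE][, evo_repl == r, drop = FALSE])
    lfc[, r] <- log2((rmean + pseudo_cpm) / (anc_mean + pseudo_cpm))
  }
  q <- matrix(stats::p.adjust(p, "BH"), G, length(repls),
              dimnames = dimnames(p))
  direction <- matrix("none", G, length(repls), dimnames = dimnames(p))
  changed <- abs(lfc) > lfc_threshold & q < fdr
  direction[changed & lfc > 0] <- "up"
  direction[changed & lfc < 0] <- "down"
  list(lfc = lfc, p = p, q = q, direction = direction)
}

#' Read a count matrix and its sample metadata
#'
#' @param counts_path TSV of integer counts; first column `gene_id`,
#'   remaining columns one per sample.
#' @param meta_path TSV with `sample_id`, `replicate`, `group` (and
#'   optionally `lib_size`).
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(counts_path, meta_path) {
  d <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (names(d)[1] != "gene_id")
    stop("first column of the count table must be gene_id")
  counts <- as.matrix(d[, -1, drop = FALSE])
  rownames(counts) <- d$gene_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(colnames(counts) == meta$sample_id))
    stop("count columns and metadata sample_id disagree")
  lib <- if ("lib_size" %in% names(meta)) meta$lib_size else NULL
  count_matrix(counts, meta, lib)
}
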