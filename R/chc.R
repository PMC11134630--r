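#' Close a nonnegative vector to a composition
#'
#' @param v Nonnegative numeric vector with positive sum.
#' @return `v / sum(v)`, summing to 1.
#' @export
#' @examples
#' closure(c(2, 2, 4))  # 0.25 0.25 0.50
closure <- function(v) {
  if (any(v < 0)) stop("composition parts must be nonnegative")
  s <- sum(v)
  if (s == 0) stop("cannot close the zero vector")
  v / s
}

#' Centred log-ratio transform
#'
#' `clr_i = ln(c_i) - mean(ln(c))`; the output sums to zero and is
#' invariant to rescaling of the input (`clr(lambda * v) = clr(v)`).
#' Zeros are either an error or replaced multiplicatively: each zero
#' becomes `delta = 0.65 * min positive fraction` of that sample, and the
#' vector is re-closed.
#'
#' @param c Composition vector, or a samples-by-compounds matrix / data
#'   frame transformed row-wise.
#' @param zero_strategy `"multiplicative"` (default) or `"error"`.
#' @return Numeric vector or matrix of CLR values.
#' @export
#' @examples
#' clr(closure(c(2, 2, 8)))  # -0.4621 -0.4621 0.9242
clr <- function(c, zero_strategy = c("multiplicative", "error")) {
  zero_strategy <- match.arg(zero_strategy)
  if (is.matrix(c) || is.data.frame(c)) {
    m <- as.matrix(c)
    out <- t(apply(m, 1L, clr, zero_strategy = zero_strategy))
    dimnames(out) <- dimnames(m)
    return(out)
  }
  v <- closure(as.numeric(c))
  if (any(v == 0)) {
    if (zero_strategy == "error")
      stop("composition contains zeros (zero_strategy = \"error\")")
    delta <- 0.65 * min(v[v > 0])
    v[v == 0] <- delta
    v <- closure(v)
  }
  lv <- log(v)
  lv - mean(lv)
}

#' Keep compounds detected in every sample
#'
#' Completeness filter used before PCA: a compound is retained only if
#' its relative abundance is strictly positive in all samples (e.g.,
#' keeping 12 of 18 detected compounds).
#'
#' @param m Samples-by-compounds abundance matrix or data frame.
#' @return The matrix restricted to complete compounds.
#' @export
complete_compounds <- function(m) {
  m <- as.matrix(m)
  keep <- apply(m > 0, 2L, all)
  if (!any(keep)) stop("no compound is detected in every sample")
  m[, keep, drop = FALSE]
}

#' Principal component analysis with a fixed sign convention
#'
#' Column-centred (not rescaled) eigendecomposition of the covariance
#' matrix, as used for CLR-transformed CHC profiles and for expression
#' matrices restricted to a gene set. The sign of each component is fixed
#' so that its largest-magnitude loading is positive; variance-explained
#' fractions sum to 1 for full-rank data. A constant matrix is flagged
#' degenerate (all variances zero) instead of erroring.
#'
#' @param x Samples-by-variables numeric matrix (>= 2 samples).
#' @return List of class `evoiso_pca` with `scores` (samples x PCs),
#'   `loadings` (variables x PCs), `var_explained`, `degenerate`.
#' @export
pca_fixed <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  total <- sum(xc^2)
  if (total < .Machine$double.eps * length(xc)) {
    k <- min(dim(x))
    return(structure(list(
      scores = matrix(0, nrow(x), k),
      loadings = matrix(0, ncol(x), k),
      var_explained = rep(0, k),
      degenerate = TRUE), class = "evoiso_pca"))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = ve, degenerate = FALSE),
            class = "evoiso_pca")
}

#' @export
print.evoiso_pca <- function(x, ...) {
  if (x$degenerate) {
    cat("degenerate PCA (constant input)\n")
  } else {
    ve <- round(100 * x$var_explained[seq_len(min(3, length(x$var_explained)))], 2)
    cat("PCA:", paste0("PC", seq_along(ve), " = ", ve, "%", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Two-way ANOVA for one response
#'
#' Type-II sums-of-squares F-tests for `sex`, `evolution` and their
#' interaction on a single response (one compound's CLR value or raw
#' fraction). A factor with a single level makes the corresponding
#' effect undefined (`NA`, flagged).
#'
#' @param values Numeric response per sample.
#' @param sex,evolution Factors (or coercible) of the two crossed
#'   effects.
#' @return List with `p_sex`, `p_evolution`, `p_interaction`, `table`
#'   (the type-II ANOVA table) and `degenerate`.
#' @export
two_way_anova <- function(values, sex, evolution) {
  sex <- factor(sex); evolution <- factor(evolution)
  if (nlevels(sex) < 2L || nlevels(evolution) < 2L) {
    return(list(p_sex = if (nlevels(sex) < 2L) NA_real_ else NA_real_,
                p_evolution = NA_real_, p_interaction = NA_real_,
                table = NULL, degenerate = TRUE))
  }
  d <- data.frame(y = as.numeric(values), sex = sex, evolution = evolution)
  fit <- stats::lm(y ~ sex * evolution, data = d)
  a2 <- car::Anova(fit, type = 2)
  p <- a2[["Pr(>F)"]]
  rn <- rownames(a2)
  list(p_sex = p[rn == "sex"],
       p_evolution = p[rn == "evolution"],
       p_interaction = p[rn == "sex:evolution"],
       table = a2, degenerate = FALSE)
}

#' Compound-wise CHC analysis table
#'
#' Runs [two_way_anova()] on every compound of a profile table, either on
#' CLR-transformed values (default, compositionally coherent) or on raw
#' relative abundances, and optionally BH-adjusts each effect's p-values
#' across compounds.
#'
#' @param profiles Data frame as produced by [simulate_chc()] /
#'   [read_chc_tsv()]: metadata columns `sample_id`, `sex`, `group`,
#'   `replicate` plus one numeric column per compound.
#' @param on `"clr"` or `"raw"`.
#' @param adjust Apply BH correction across compounds (adds `q_*`
#'   columns).
#' @param zero_strategy Passed to [clr()].
#' @return Data frame with one row per compound: mean percentage in each
#'   sex-by-group cell and the three ANOVA p-values.
#' @export
chc_anova_table <- function(profiles, on = c("clr", "raw"), adjust = FALSE,
                            zero_strategy = "multiplicative") {
  on <- match.arg(on)
  ab <- chc_abundance_matrix(profiles)
  vals <- if (on == "clr") clr(ab, zero_strategy = zero_strategy) else ab
  cell <- interaction(profiles$group, profiles$sex, sep = ".")
  out <- lapply(colnames(ab), function(cp) {
    av <- two_way_anova(vals[, cp], profiles$sex, profiles$group)
    pct <- tapply(100 * ab[, cp], cell, mean)
    data.frame(compound = cp,
               pct_anc_female = pct[["ancestral.female"]],
               pct_anc_male = pct[["ancestral.male"]],
               pct_evo_female = pct[["evolved.female"]],
               pct_evo_male = pct[["evolved.male"]],
               p_sex = av$p_sex, p_evolution = av$p_evolution,
               p_interaction = av$p_interaction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (adjust) {
    out$q_sex <- stats::p.adjust(out$p_sex, "BH")
    out$q_evolution <- stats::p.adjust(out$p_evolution, "BH")
    out$q_interaction <- stats::p.adjust(out$p_interaction, "BH")
  }
  rownames(out) <- NULL
  out
}

#' CLR-PCA of CHC profiles
#'
#' The standard compositional ordination: restrict to compounds detected
#' in every sample, CLR-transform, and run [pca_fixed()].
#'
#' @inheritParams chc_anova_table
#' @return An `evoiso_pca` with the sample metadata attached as
#'   `$meta`.
#' @export
chc_pca <- function(profiles, zero_strategy = "multiplicative") {
  ab <- complete_compounds(chc_abundance_matrix(profiles))
  p <- pca_fixed(clr(ab, zero_strategy = zero_strategy))
  p$meta <- profiles[, intersect(c("sample_id", "sex", "group", "replicate"),
                                 names(profiles)), drop = FALSE]
  p
}

chc_abundance_matrix <- function(profiles) {
  meta_cols <- c("sample_id", "sex", "group", "replicate")
  num <- setdiff(names(profiles), meta_cols)
  ab <- as.matrix(profiles[, num, drop = FALSE])
  if (!is.numeric(ab)) stop("compound columns must be numeric")
  rownames(ab) <- profiles$sample_id
  ab
}

#' Read a CHC profile table
#'
#' TSV with metadata columns `sample_id`, `sex`, `group`, `replicate`
#' and one numeric relative-abundance column per compound. Rows are
#' re-closed to sum exactly 1.
#'
#' @param path TSV file path.
#' @return Data frame in the layout of [simulate_chc()].
#' @export
read_chc_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "group", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("CHC table missing column(s): ", paste(miss, collapse = ", "))
  ab <- chc_abundance_matrix(d)
  if (any(ab < 0)) stop("negative abundance in CHC table")
  ab <- ab / rowSums(ab)
  d[, colnames(ab)] <- ab
  d
}
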