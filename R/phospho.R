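#' Preprocess a phosphopeptide intensity table
#'
#' Log2-transforms linear intensities, median-centres each sample, and imputes
#' missing values from a down-shifted Gaussian: per sample, imputed values are
#' drawn from N(mean - shift * sd, (width * sd)^2) of that sample's observed
#' log2 values. This is the standard missing-not-at-random style imputation
#' for label-free proteomics, reflecting that absent peptides tend to sit
#' below the detection limit. No missing values remain afterwards.
#'
#' @param table A [phospho_table()] with positive linear intensities (or
#'   already log2 values, in which case the transform is skipped).
#' @param seed Integer seed for the imputation draws.
#' @param shift Down-shift in sample standard deviations (default 1.8).
#' @param width Width of the imputation distribution in sample standard
#'   deviations (default 0.3).
#' @return A `phospho_table` on the log2 scale with no missing values.
#' @export
preprocess <- function(table, seed = 1, shift = 1.8, width = 0.3) {
  stopifnot(inherits(table, "phospho_table"))
  m <- table$intensity
  all_na <- colSums(!is.na(m)) == 0
  if (any(all_na))
    stop("sample(s) with all-missing values: ",
         paste(colnames(m)[all_na], collapse = ", "), call. = FALSE)
  if (!table$log2) m <- log2(m)
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  m <- sweep(m, 2, med)
  set.seed(seed)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (!any(miss)) next
    mu <- mean(m[, j], na.rm = TRUE)
    sdv <- stats::sd(m[, j], na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    m[miss, j] <- stats::rnorm(sum(miss), mu - shift * sdv, width * sdv)
  }
  out <- table
  out$intensity <- m
  out$log2 <- TRUE
  out
}

#' Welch's two-tailed heteroscedastic t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom, as
#' used for per-phosphosite group comparisons. Wraps [stats::t.test()] with an
#' explicit convention for degenerate inputs: if both groups have zero
#' variance and equal means the result is t = 0, p = 1; zero variance with
#' unequal means gives p = 0.
#'
#' @param a,b Numeric vectors (>= 2 non-missing values each).
#' @return A list with `t`, `df` and `p`.
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone in rank order, capped at 1), via
#' [stats::p.adjust()]. Values outside [0, 1] are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Detect an anti-conservative p-value distribution
#'
#' Deterministic surrogate for visual histogram inspection: returns `TRUE`
#' when the observed fraction of p-values below `alpha` exceeds
#' `factor` times the uniform expectation `alpha`. Used to gate the
#' fold-change fallback when FDR correction yields no hits despite apparent
#' signal near zero.
#'
#' @param p Numeric vector of at least 50 p-values.
#' @param alpha Significance threshold (default 0.05).
#' @param factor Multiple of the uniform expectation required (default 1.5).
#' @return Logical scalar.
#' @export
detect_anticonservative <- function(p, alpha = 0.05, factor = 1.5) {
  if (length(p) < 50)
    stop("too few p-values to assess the distribution; use BH only",
         call. = FALSE)
  mean(p < alpha) > factor * alpha
}

#' Per-site differential testing between two groups
#'
#' Runs [welch_test()] per site on a preprocessed (log2, no missing values)
#' table, comparing a treatment group against the control group. The log2
#' fold change is the treatment minus control mean of log2 intensities.
#'
#' @param table A preprocessed [phospho_table()].
#' @param control,treatment Group labels in `levels(table$design)`.
#' @return A data frame with columns `site_id`, `protein_id`, `log2fc`, `t`,
#'   `p` (one row per site).
#' @export
differential_sites <- function(table, control = levels(table$design)[1],
                               treatment = levels(table$design)[2]) {
  stopifnot(inherits(table, "phospho_table"))
  if (!all(c(control, treatment) %in% levels(table$design)))
    stop("control/treatment must be design groups", call. = FALSE)
  m <- table$intensity
  ia <- which(table$design == treatment)
  ib <- which(table$design == control)
  res <- lapply(seq_len(nrow(m)), function(i)
    welch_test(m[i, ia], m[i, ib]))
  data.frame(site_id = table$site_id, protein_id = table$protein_id,
             log2fc = rowMeans(m[, ia, drop = FALSE]) -
                      rowMeans(m[, ib, drop = FALSE]),
             t = vapply(res, `[[`, numeric(1), "t"),
             p = vapply(res, `[[`, numeric(1), "p"),
             row.names = NULL)
}

#' Call site significance with BH and an anti-conservative fallback
#'
#' BH-adjusted p-values are computed and sites with `p_adj < alpha` are
#' called significant. If BH yields zero hits *and* the raw p-value
#' distribution is anti-conservative ([detect_anticonservative()]), an
#' alternative FDR control is applied instead: significant iff `p < alpha`
#' and |fold change| > `fc_cutoff` (i.e. |log2fc| > log2(fc_cutoff),
#' two-sided). The `procedure` column records which rule fired.
#'
#' @param results Data frame with columns `p` and `log2fc` (e.g. from
#'   [differential_sites()]).
#' @param alpha Significance threshold (default 0.05).
#' @param fc_cutoff Linear-scale fold-change cut-off for the fallback
#'   (default 1.5).
#' @param factor Anti-conservativeness factor passed to
#'   [detect_anticonservative()].
#' @return `results` with added columns `p_adj`, `significant`, `procedure`.
#' @export
call_significance <- function(results, alpha = 0.05, fc_cutoff = 1.5,
                              factor = 1.5) {
  stopifnot(all(c("p", "log2fc") %in% names(results)))
  results$p_adj <- bh_adjust(results$p)
  bh_sig <- results$p_adj < alpha
  use_fallback <- !any(bh_sig) && length(results$p) >= 50 &&
    detect_anticonservative(results$p, alpha = alpha, factor = factor)
  if (use_fallback) {
    results$significant <- results$p < alpha &
      abs(results$log2fc) > log2(fc_cutoff)
    results$procedure <- "fallback"
  } else {
    results$significant <- bh_sig
    results$procedure <- "BH"
  }
  results
}

#' Cumulative phosphorylation-state score per protein
#'
#' For each protein, the score is the sum of log2 fold changes over all its
#' phosphopeptides with raw `p < alpha`; if no peptide passes, the score is
#' exactly zero. Proteins are classified hyperphosphorylated when the score
#' exceeds +2 sigma and hypophosphorylated below -2 sigma, where sigma is the
#' population standard deviation of the scores across proteins (including
#' zeros by default; set `sigma_mode = "nonzero"` to compute it over proteins
#' with a nonzero score only).
#'
#' @param results Data frame with columns `protein_id`, `log2fc`, `p`.
#' @param alpha Raw p-value threshold for a peptide to contribute
#'   (default 0.05).
#' @param sigma_mode `"all"` (default) or `"nonzero"`.
#' @return A data frame with columns `protein_id`, `delta_ps`, `n_sig`,
#'   `klass` (factor hyper/none/hypo), plus attribute `sigma`.
#' @export
delta_ps <- function(results, alpha = 0.05,
                     sigma_mode = c("all", "nonzero")) {
  sigma_mode <- match.arg(sigma_mode)
  stopifnot(all(c("protein_id", "log2fc", "p") %in% names(results)))
  if (nrow(results) == 0) {
    out <- data.frame(protein_id = character(), delta_ps = numeric(),
                      n_sig = integer(),
                      klass = factor(character(),
                                     levels = c("hypo", "none", "hyper")))
    attr(out, "sigma") <- NA_real_
    return(out)
  }
  proteins <- unique(results$protein_id)
  sig <- results$p < alpha
  contrib <- results$log2fc * sig
  dps <- vapply(proteins, function(pr) {
    k <- results$protein_id == pr
    sum(contrib[k])
  }, numeric(1))
  n_sig <- vapply(proteins, function(pr)
    sum(sig[results$protein_id == pr]), integer(1))
  pool <- if (sigma_mode == "all") dps else dps[dps != 0]
  sigma <- if (length(pool)) sqrt(mean((pool - mean(pool))^2)) else NA_real_
  klass <- factor(ifelse(dps > 2 * sigma, "hyper",
                         ifelse(dps < -2 * sigma, "hypo", "none")),
                  levels = c("hypo", "none", "hyper"))
  out <- data.frame(protein_id = proteins, delta_ps = unname(dps),
                    n_sig = unname(n_sig), klass = klass, row.names = NULL)
  attr(out, "sigma") <- sigma
  out
}

#' Row-wise z-score normalization of a site-by-sample matrix
#'
#' Each site (row) is transformed to mean 0 and unit population (divide-by-n)
#' standard deviation across samples. Zero-variance rows become all-zero with
#' a warning.
#'
#' @param m Numeric matrix with no missing values (run after [preprocess()]).
#' @return Matrix of the same shape.
#' @export
zscore_sites <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix must not contain missing values", call. = FALSE)
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))
  zero <- sdp == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance row(s) set to zero")
    sdp[zero] <- 1
  }
  (m - mu) / sdp
}

#' Hierarchical clustering of z-scored phosphosites
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage via
#' [stats::hclust()] `"ward.D2"`) cut at `k` clusters, with per-cluster
#' per-group mean z-scores when a design is supplied. Deterministic given the
#' input row order (ties broken by first index, the hclust convention).
#'
#' @param zmatrix Z-scored site-by-sample matrix (see [zscore_sites()]).
#' @param k Number of clusters (1 <= k <= number of sites).
#' @param design Optional factor of group labels per sample.
#' @return A list with `assignments` (named integer vector),
#'   `cluster_group_mean` (k x groups matrix, or `NULL`), and `tree`
#'   (the hclust object).
#' @export
cluster_sites <- function(zmatrix, k, design = NULL) {
  zmatrix <- as.matrix(zmatrix)
  if (k > nrow(zmatrix)) stop("k exceeds the number of sites", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  tree <- stats::hclust(stats::dist(zmatrix, method = "euclidean"),
                        method = "ward.D2")
  assignments <- stats::cutree(tree, k = k)
  cgm <- NULL
  if (!is.null(design)) {
    design <- as.factor(design)
    stopifnot(length(design) == ncol(zmatrix))
    cgm <- t(vapply(seq_len(k), function(cl) {
      rows <- zmatrix[assignments == cl, , drop = FALSE]
      tapply(colMeans(rows), design, mean)
    }, numeric(nlevels(design))))
    dimnames(cgm) <- list(paste0("cluster", seq_len(k)), levels(design))
  }
  list(assignments = assignments, cluster_group_mean = cgm, tree = tree)
}

#' Non-parametric group comparison of cluster abundance
#'
#' Convenience wrapper around [stats::kruskal.test()] comparing the per-site
#' mean z-score of one cluster across design groups (the routine statistic
#' used to compare normalized cluster abundance between conditions).
#'
#' @param zmatrix Z-scored matrix.
#' @param assignments Cluster assignments from [cluster_sites()].
#' @param cluster Cluster id to test.
#' @param design Factor of group labels per sample.
#' @return The `htest` object from [stats::kruskal.test()].
#' @export
cluster_group_test <- function(zmatrix, assignments, cluster, design) {
  rows <- zmatrix[assignments == cluster, , drop = FALSE]
  design <- as.factor(design)
  values <- as.vector(rows)
  groups <- factor(rep(design, each = nrow(rows)), levels = levels(design))
  stats::kruskal.test(values, groups)
}

#' Percentage of significant sites
#'
#' `100 * n_sig / n_total`, rounded to 2 decimals — the convention used to
#' report the fraction of significantly modulated phosphosites or
#' phosphoproteins.
#'
#' @param n_sig,n_total Counts with `0 <= n_sig <= n_total`, `n_total > 0`.
#' @return Percentage rounded to 2 decimals.
#' @export
report_fractions <- function(n_sig, n_total) {
  if (n_total <= 0) stop("n_total must be > 0", call. = FALSE)
  if (n_sig < 0 || n_sig > n_total)
    stop("require 0 <= n_sig <= n_total", call. = FALSE)
  round(100 * n_sig / n_total, 2)
}
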