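#' Detect cis-CNA genes
#'
#' A gene is called cis when its expression is significantly positively
#' associated with its own copy number: per-gene Spearman correlation of
#' `expression[g, ]` against `cna[g, ]`, a one-sided p-value for positive
#' association (t approximation on the rank correlation), and
#' Benjamini-Hochberg adjustment across genes. Spearman is used because
#' copy-number log-ratios have heavy, non-Gaussian tails; the test is
#' one-sided because copy gain is expected to raise expression.
#'
#' @param expression gene x sample expression matrix.
#' @param cna gene x sample copy-number matrix with the same dimnames.
#' @param fdr_threshold FDR level for the cis call, in (0, 1).
#' @return data.frame with columns `gene`, `correlation`, `p`, `q`, `is_cis`,
#'   one row per gene in matrix order.
#' @export
detect_cis_cna <- function(expression, cna, fdr_threshold = 0.05) {
  check_matrix(expression, "expression")
  check_matrix(cna, "cna")
  if (!identical(dimnames(expression), dimnames(cna))) {
    stop("`expression` and `cna` must share gene and sample axes", call. = FALSE)
  }
  check_scalar(fdr_threshold, "fdr_threshold")
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("`fdr_threshold` must be in (0, 1)", call. = FALSE)
  }
  n <- ncol(expression)
  if (n < 5L) stop("need at least 5 samples for the rank test", call. = FALSE)

  rho <- vapply(seq_len(nrow(expression)), function(i) {
    if (sd(expression[i, ]) == 0 || sd(cna[i, ]) == 0) return(0)
    cor(expression[i, ], cna[i, ], method = "spearman")
  }, numeric(1))
  # one-sided upper-tail p via the t approximation; exact at |rho| = 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- pt(tstat, df = n - 2, lower.tail = FALSE)
  p[rho >= 1] <- 0
  q <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(expression),
             correlation = rho, p = p, q = q,
             is_cis = q < fdr_threshold & rho > 0,
             stringsAsFactors = FALSE)
}

#' Select informative genes for network learning
#'
#' Returns the union of (a) the `top_frac` fraction of genes ranked by
#' expression variance and (b) all cis-CNA genes, in the stable order of the
#' expression matrix. Anchoring every cis gene keeps the genetics-informed
#' nodes in the network even when their variance is modest. The `clinical`
#' argument is accepted for interface stability but not used by the default
#' rule.
#'
#' @param expression gene x sample expression matrix.
#' @param cis optional data.frame from [detect_cis_cna()].
#' @param top_frac fraction of genes kept by variance, in (0, 1].
#' @param clinical optional survival table; reserved, ignored by the default
#'   selection rule.
#' @return character vector of selected genes (no duplicates).
#' @export
select_informative_genes <- function(expression, cis = NULL, top_frac = 0.5,
                                     clinical = NULL) {
  check_matrix(expression, "expression")
  if (nrow(expression) == 0L) stop("`expression` is empty", call. = FALSE)
  check_scalar(top_frac, "top_frac")
  if (top_frac <= 0 || top_frac > 1) stop("`top_frac` must be in (0, 1]", call. = FALSE)

  genes <- rownames(expression)
  v <- apply(expression, 1L, var)
  k <- round(top_frac * length(genes))
  top <- genes[order(-v)][seq_len(k)]
  cis_genes <- if (!is.null(cis)) cis$gene[cis$is_cis] else character(0)
  genes[genes %in% union(top, cis_genes)]
}

#' Discretize expression into three states
#'
#' Per-gene one-dimensional k-means with k = 3, deterministically initialized
#' at the 1/6, 3/6 and 5/6 quantiles (Lloyd iterations), with states
#' relabeled 0/1/2 by ascending cluster mean, the three-state convention of
#' discretized Bayesian-network learning. Genes with fewer than three
#' distinct values map every sample to the middle state 1.
#'
#' @param expression gene x sample matrix of finite values.
#' @return integer gene x sample matrix with entries in \{0, 1, 2\}.
#' @export
discretize_expression <- function(expression) {
  check_matrix(expression, "expression")
  out <- matrix(1L, nrow = nrow(expression), ncol = ncol(expression),
                dimnames = dimnames(expression))
  for (i in seq_len(nrow(expression))) {
    out[i, ] <- discretize_vector(expression[i, ])
  }
  out
}

# 3-state 1-D k-means for one gene; returns integer states 0..2
discretize_vector <- function(x) {
  ux <- unique(x)
  if (length(ux) < 3L) return(rep(1L, length(x)))
  centers <- unique(unname(quantile(x, c(1, 3, 5) / 6)))
  if (length(centers) < 3L) {
    # collapse at quantile centers (heavily tied data): spread over the
    # distinct observed values instead
    sux <- sort(ux)
    m <- length(sux)
    centers <- sux[unique(round(c(1, (m + 1) / 2, m)))]
    if (length(centers) < 3L) return(rep(1L, length(x)))
  }
  fit <- tryCatch(
    kmeans(x, centers = matrix(sort(centers)), algorithm = "Lloyd", iter.max = 200L),
    error = function(e) NULL,
    warning = function(w) suppressWarnings(
      kmeans(x, centers = matrix(sort(centers)), algorithm = "Lloyd", iter.max = 200L))
  )
  if (is.null(fit)) {
    # degenerate clustering (empty cluster): single nearest-center assignment
    cl <- apply(outer(x, sort(centers), function(a, b) abs(a - b)), 1L, which.min)
    means <- tapply(x, cl, mean)
    lev <- as.integer(names(sort(means)))
    return(match(cl, lev) - 1L)
  }
  relabel <- order(fit$centers[, 1L])   # ascending cluster mean -> 0,1,2
  match(fit$cluster, relabel) - 1L
}
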