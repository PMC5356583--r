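#' Gene-wise Cox screen against a recurrence endpoint
#'
#' Fits a univariate Cox proportional-hazards model per gene on z-scored
#' expression (so coefficients are log hazard ratios per standard deviation
#' and comparable across genes), with Efron tie handling, Wald p-values and
#' Benjamini-Hochberg adjustment across genes. A gene is significant when
#' `q < alpha`; significant genes are partitioned by coefficient sign into
#' positively and negatively associated sets. Zero-variance genes are
#' skipped with a warning; non-converging fits are flagged and excluded.
#'
#' @param expression gene x sample matrix whose columns cover the survival
#'   samples.
#' @param survival data.frame with columns `sample`, `time`, `event`
#'   (at least 10 events).
#' @param alpha significance level on the adjusted p-value.
#' @param method multiple-testing correction passed to [stats::p.adjust()].
#' @return data.frame with `gene`, `coefficient`, `hr`, `p`, `q`,
#'   `direction`, `significant`, `converged`.
#' @export
cox_screen <- function(expression, survival, alpha = 0.01, method = "BH") {
  check_matrix(expression, "expression")
  validate_survival(survival)
  if (sum(survival$event) < 10L) stop("need at least 10 events", call. = FALSE)
  if (!all(survival$sample %in% colnames(expression))) {
    stop("expression must cover all survival samples", call. = FALSE)
  }
  expr <- expression[, survival$sample, drop = FALSE]
  surv_obj <- survival::Surv(survival$time, survival$event)

  fit_one <- function(x) {
    if (sd(x) == 0) return(c(NA_real_, NA_real_, 0))
    z <- as.numeric(scale(x))
    fit <- tryCatch(survival::coxph(surv_obj ~ z), error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(fit)) return(c(NA_real_, NA_real_, 0))
    s <- summary(fit)
    c(unname(coef(fit)), s$coefficients[1L, "Pr(>|z|)"], 1)
  }
  res <- t(apply(expr, 1L, fit_one))
  converged <- res[, 3L] == 1
  if (any(!converged)) {
    warning(sprintf("%d gene(s) skipped (zero variance or non-convergence)",
                    sum(!converged)))
  }
  p <- res[, 2L]
  q <- rep(NA_real_, length(p))
  q[converged] <- p.adjust(p[converged], method = method)
  out <- data.frame(gene = rownames(expr),
                    coefficient = res[, 1L],
                    hr = exp(res[, 1L]),
                    p = p, q = q,
                    direction = ifelse(res[, 1L] >= 0, "positive", "negative"),
                    significant = !is.na(q) & q < alpha,
                    converged = converged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

validate_survival <- function(survival) {
  stopifnot(is.data.frame(survival),
            all(c("sample", "time", "event") %in% names(survival)))
  if (anyDuplicated(survival$sample)) stop("duplicated samples", call. = FALSE)
  if (any(survival$time <= 0)) stop("times must be > 0", call. = FALSE)
  if (!all(survival$event %in% c(0L, 1L))) stop("event must be 0/1", call. = FALSE)
  invisible(survival)
}

#' Residual association of a gene with recurrence given clinical covariates
#'
#' Multivariable Cox model of the endpoint on the z-scored expression of one
#' gene plus the named clinical covariates (columns of the survival table);
#' returns the Wald p-value of every term so the gene's residual prognostic
#' value can be read off next to the covariates.
#'
#' @param expression gene x sample matrix.
#' @param survival data.frame with `sample`, `time`, `event` and the
#'   covariate columns.
#' @param gene gene to test.
#' @param covariates character vector of covariate column names.
#' @return named numeric vector of Wald p-values (gene term first).
#' @export
multivariable_residual_test <- function(expression, survival, gene, covariates) {
  check_matrix(expression, "expression")
  validate_survival(survival)
  if (!gene %in% rownames(expression)) stop("unknown gene", call. = FALSE)
  if (!all(covariates %in% names(survival))) {
    stop("covariates missing from survival table", call. = FALSE)
  }
  df <- survival[, c("time", "event", covariates), drop = FALSE]
  df$gene_z <- as.numeric(scale(expression[gene, survival$sample]))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~ gene_z +",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("collinear terms in the Cox fit: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  s <- summary(fit)$coefficients
  setNames(s[, "Pr(>|z|)"], rownames(s))
}

#' Call gene-low tumours against a normal-tissue reference
#'
#' Fits `Normal(mu, sigma)` to the reference expression by moments; a tumour
#' sample is "low" when its lower-tail probability under that normal is
#' below `p_cut`. This reproduces the gene-low stratification in which a
#' tumour must fall significantly below the normal-tissue distribution to be
#' flagged.
#'
#' @param tumor_expr named numeric vector of tumour expression values.
#' @param reference_expr numeric vector of reference (normal tissue) values,
#'   length >= 5, non-degenerate.
#' @param p_cut lower-tail probability cut-off.
#' @return list with `groups` (factor `low`/`high` named by sample),
#'   `tail_prob`, `n_low`, `frac_low`, `mu`, `sigma`.
#' @export
gene_low_groups <- function(tumor_expr, reference_expr, p_cut = 0.01) {
  if (length(reference_expr) < 5L) stop("need >= 5 reference samples", call. = FALSE)
  mu <- mean(reference_expr)
  sigma <- sd(reference_expr)
  if (sigma == 0) stop("reference has zero variance", call. = FALSE)
  tail_prob <- pnorm(tumor_expr, mean = mu, sd = sigma)
  low <- tail_prob < p_cut
  list(groups = factor(ifelse(low, "low", "high"), levels = c("high", "low")),
       tail_prob = tail_prob,
       n_low = sum(low),
       frac_low = mean(low),
       mu = mu, sigma = sigma)
}

#' Split tumours into low/high groups at an expression quantile
#'
#' The `ceiling(frac_low * n)` lowest-expressing samples are labelled low;
#' samples tied with the boundary value are all included in the low group
#' (so a constant vector is entirely low).
#'
#' @param tumor_expr numeric vector of tumour expression values.
#' @param frac_low target fraction labelled low, in (0, 1).
#' @return list with `groups` (factor `low`/`high`), `n_low`, `frac_low`,
#'   `cutoff`.
#' @export
quantile_split_groups <- function(tumor_expr, frac_low) {
  check_scalar(frac_low, "frac_low")
  if (frac_low <= 0 || frac_low >= 1) stop("`frac_low` must be in (0, 1)", call. = FALSE)
  n <- length(tumor_expr)
  k <- ceiling(frac_low * n)
  cutoff <- sort(tumor_expr)[k]
  low <- tumor_expr <= cutoff
  list(groups = factor(ifelse(low, "low", "high"), levels = c("high", "low")),
       n_low = sum(low), frac_low = mean(low), cutoff = cutoff)
}

#' Compare survival between low and high expression groups
#'
#' Log-rank test p-value plus the Cox hazard ratio of the low group relative
#' to the high group (binary covariate, Efron ties).
#'
#' @param groups factor with levels `high`/`low` (e.g. from
#'   [gene_low_groups()] or [quantile_split_groups()]), aligned with the
#'   rows of `survival`.
#' @param survival data.frame with `sample`, `time`, `event`.
#' @return list with `hr` (low vs high), `logrank_p`, `n_low`, `frac_low`.
#' @export
compare_groups <- function(groups, survival) {
  validate_survival(survival)
  groups <- as.factor(groups)
  if (length(groups) != nrow(survival)) {
    stop("`groups` must align with `survival` rows", call. = FALSE)
  }
  if (length(unique(groups[!is.na(groups)])) < 2L) {
    stop("need two non-empty groups", call. = FALSE)
  }
  if (sum(survival$event) < 1L) stop("need at least one event", call. = FALSE)
  surv_obj <- survival::Surv(survival$time, survival$event)
  sd_fit <- survival::survdiff(surv_obj ~ groups)
  logrank_p <- stats::pchisq(sd_fit$chisq, df = length(sd_fit$n) - 1L,
                             lower.tail = FALSE)
  is_low <- as.integer(groups == "low")
  cox <- survival::coxph(surv_obj ~ is_low)
  list(hr = unname(exp(coef(cox))),
       logrank_p = logrank_p,
       n_low = sum(is_low),
       frac_low = mean(is_low))
}
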