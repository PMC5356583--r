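#' Generate a ground-truth causal gene network
#'
#' Samples a sparse directed acyclic graph over `n_genes` genes by drawing a
#' random topological order and attaching parents with hub-biased preferential
#' attachment: a designated set of `n_hubs` early-order genes is upweighted
#' when parents are sampled, which concentrates out-degree on a few regulators
#' as observed in regulatory networks. A fraction `frac_cis` of genes is
#' flagged cis: their expression is driven by their own copy number in
#' [simulate_expression()], mirroring genes whose transcript level tracks a
#' somatic copy-number alteration.
#'
#' @param n_genes number of genes (>= 5).
#' @param n_hubs number of hub regulators (< `n_genes`).
#' @param mean_out_degree expected number of regulations per gene; total edge
#'   count is approximately `n_genes * mean_out_degree`.
#' @param frac_cis fraction of genes flagged as cis-CNA genes, in (0, 1).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments, so the same call reproduces identical edges and weights.
#' @param hub_boost sampling weight multiplier for hub parents.
#' @return An object of class `causal_network`: a list with `genes`,
#'   `edges` (data.frame `regulator`, `target`, `weight`), `cis_genes`,
#'   `cis_effect` (named vector over `cis_genes`), `topo_order`, and `seed`.
#' @examples
#' net <- generate_ground_truth_dag(20, n_hubs = 2, mean_out_degree = 1,
#'                                  frac_cis = 0.2, seed = 1)
#' nrow(net$edges)
#' @export
generate_ground_truth_dag <- function(n_genes, n_hubs, mean_out_degree,
                                      frac_cis, seed, hub_boost = 8) {
  n_genes <- check_count(n_genes, "n_genes", min = 5L)
  n_hubs <- check_count(n_hubs, "n_hubs", min = 0L)
  if (n_hubs >= n_genes) stop("`n_hubs` must be smaller than `n_genes`", call. = FALSE)
  check_scalar(mean_out_degree, "mean_out_degree")
  if (mean_out_degree < 0) stop("`mean_out_degree` must be >= 0", call. = FALSE)
  check_scalar(frac_cis, "frac_cis")
  if (frac_cis <= 0 || frac_cis >= 1) stop("`frac_cis` must be in (0, 1)", call. = FALSE)
  check_scalar(hub_boost, "hub_boost")

  genes <- sprintf("g%03d", seq_len(n_genes))
  with_seed(seed, {
    topo <- sample(genes)                       # topo[1] is the most upstream
    hubs <- topo[seq_len(n_hubs)]               # hubs sit early so they can regulate

    # expected parents per node so that E[#edges] = n_genes * mean_out_degree
    lambda <- mean_out_degree * n_genes / max(1L, n_genes - 1L)
    reg <- character(0); tgt <- character(0)
    for (i in seq(2L, n_genes)) {
      preds <- topo[seq_len(i - 1L)]
      k <- min(rpois(1L, lambda), length(preds))
      if (k == 0L) next
      w <- ifelse(preds %in% hubs, hub_boost, 1)
      parents <- if (length(preds) == 1L) preds else sample(preds, k, prob = w)
      reg <- c(reg, parents)
      tgt <- c(tgt, rep(topo[i], k))
    }
    weight <- if (length(reg)) {
      runif(length(reg), 0.5, 1.5) * sample(c(-1, 1), length(reg), replace = TRUE)
    } else numeric(0)

    n_cis <- round(frac_cis * n_genes)
    cis_genes <- sort(sample(genes, n_cis))
    cis_effect <- setNames(runif(n_cis, 0.8, 1.2), cis_genes)

    structure(list(
      genes = genes,
      edges = data.frame(regulator = reg, target = tgt, weight = weight,
                         stringsAsFactors = FALSE),
      cis_genes = cis_genes,
      cis_effect = cis_effect,
      topo_order = topo,
      seed = as.integer(seed)
    ), class = "causal_network")
  })
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("causal_network: %d genes, %d edges, %d cis genes (seed %d)\n",
              length(x$genes), nrow(x$edges), length(x$cis_genes), x$seed))
  invisible(x)
}

#' Simulate segmental copy-number log-ratios
#'
#' Genes are partitioned into contiguous blocks along their list order (a
#' stand-in for genomic coordinates) and every block takes a single
#' `Normal(0, segment_sd)` value per sample. Genes sharing a block therefore
#' have identical copy-number values within a sample, reproducing the
#' co-localization confound in which neighbouring genes co-vary through shared
#' segmental alterations rather than regulation.
#'
#' @param truth a `causal_network` from [generate_ground_truth_dag()].
#' @param n_samples number of samples (>= 2).
#' @param segment_sd standard deviation of the per-block log-ratio; 0 yields
#'   an all-zero matrix, negative values are rejected.
#' @param seed integer seed.
#' @param mean_block_len expected number of genes per contiguous block.
#' @return gene x sample numeric matrix of copy-number log-ratios, with a
#'   `"blocks"` attribute giving each gene's block index.
#' @export
simulate_cna <- function(truth, n_samples, segment_sd, seed, mean_block_len = 5) {
  stopifnot(inherits(truth, "causal_network"))
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  check_scalar(segment_sd, "segment_sd")
  if (segment_sd < 0) stop("`segment_sd` must be >= 0", call. = FALSE)
  check_scalar(mean_block_len, "mean_block_len")
  if (mean_block_len < 1) stop("`mean_block_len` must be >= 1", call. = FALSE)

  genes <- truth$genes
  n <- length(genes)
  with_seed(seed, {
    # contiguous blocks with mean length mean_block_len
    lens <- integer(0)
    while (sum(lens) < n) lens <- c(lens, 1L + rpois(1L, mean_block_len - 1))
    blocks <- rep(seq_along(lens), lens)[seq_len(n)]
    n_blocks <- max(blocks)
    bvals <- matrix(rnorm(n_blocks * n_samples, 0, segment_sd),
                    nrow = n_blocks, ncol = n_samples)
    cna <- bvals[blocks, , drop = FALSE]
    dimnames(cna) <- list(genes, sprintf("s%03d", seq_len(n_samples)))
    attr(cna, "blocks") <- setNames(blocks, genes)
    cna
  })
}

#' Simulate expression from the causal network and copy number
#'
#' Evaluates linear-Gaussian structural equations in topological order:
#' `expr(g) = sum_parents weight * expr(parent) + cis_effect(g) * cna(g) +
#' Normal(0, noise_sd)`, with the copy-number term present only for genes
#' flagged cis in `truth`. Because parents are evaluated before children,
#' every parent value exists when needed.
#'
#' @param truth a `causal_network`.
#' @param cna gene x sample copy-number matrix covering `truth$genes`
#'   (e.g. from [simulate_cna()]).
#' @param noise_sd standard deviation of the independent Gaussian noise
#'   added to every gene (> 0).
#' @param seed integer seed.
#' @return gene x sample expression matrix aligned with `cna`.
#' @export
simulate_expression <- function(truth, cna, noise_sd, seed) {
  stopifnot(inherits(truth, "causal_network"))
  check_matrix(cna, "cna")
  if (!all(truth$genes %in% rownames(cna))) {
    stop("`cna` must cover all genes of `truth`", call. = FALSE)
  }
  check_scalar(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)

  genes <- truth$genes
  samples <- colnames(cna)
  n_s <- length(samples)
  parents_of <- split(seq_len(nrow(truth$edges)), truth$edges$target)

  with_seed(seed, {
    expr <- matrix(NA_real_, nrow = length(genes), ncol = n_s,
                   dimnames = list(genes, samples))
    for (g in truth$topo_order) {
      val <- rnorm(n_s, 0, noise_sd)
      idx <- parents_of[[g]]
      if (!is.null(idx)) {
        for (i in idx) {
          p <- truth$edges$regulator[i]
          if (anyNA(expr[p, ])) stop("internal error: parent evaluated after child")
          val <- val + truth$edges$weight[i] * expr[p, ]
        }
      }
      if (g %in% truth$cis_genes) {
        val <- val + truth$cis_effect[[g]] * cna[g, ]
      }
      expr[g, ] <- val
    }
    expr
  })
}

#' Simulate a recurrence endpoint under proportional hazards
#'
#' Draws exponential event times with hazard
#' `baseline_rate * exp(sum(log_hr * z))` where `z` is the z-scored
#' expression of each driver gene, plus independent exponential censoring at
#' rate `censor_rate`. The observed time is the earlier of failure and
#' censoring; `event = 1` when failure came first.
#'
#' @param expression gene x sample expression matrix.
#' @param driver_genes genes carrying a survival effect (may be empty for a
#'   pure baseline cohort).
#' @param log_hr log hazard ratio per unit z-scored expression; recycled to
#'   the length of `driver_genes`.
#' @param baseline_rate baseline exponential hazard (> 0), per month.
#' @param censor_rate exponential censoring rate (>= 0; 0 means no censoring).
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `time` (months, > 0) and
#'   `event` (0/1).
#' @export
simulate_bcr <- function(expression, driver_genes, log_hr, baseline_rate,
                         censor_rate, seed) {
  check_matrix(expression, "expression")
  if (!all(driver_genes %in% rownames(expression))) {
    stop("`driver_genes` must be rows of `expression`", call. = FALSE)
  }
  check_scalar(baseline_rate, "baseline_rate")
  if (baseline_rate <= 0) stop("`baseline_rate` must be > 0", call. = FALSE)
  check_scalar(censor_rate, "censor_rate")
  if (censor_rate < 0) stop("`censor_rate` must be >= 0", call. = FALSE)

  n <- ncol(expression)
  lp <- rep(0, n)
  if (length(driver_genes)) {
    log_hr <- rep_len(log_hr, length(driver_genes))
    z <- zscore_rows(expression[driver_genes, , drop = FALSE])
    lp <- as.numeric(crossprod(z, log_hr))
  }
  with_seed(seed, {
    t_fail <- rexp(n, rate = baseline_rate * exp(lp))
    t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
    data.frame(sample = colnames(expression),
               time = pmin(t_fail, t_cens),
               event = as.integer(t_fail <= t_cens),
               stringsAsFactors = FALSE)
  })
}

#' Build a synthetic tissue-expression atlas
#'
#' Baseline expression is 1.0 for every gene in every tissue; each designated
#' tissue-specific gene instead has expression `fold` in its home tissue.
#' The planted assignment is stored in the `"truth"` attribute so recovery by
#' [preferential_tissues()] can be checked exactly.
#'
#' @param n_genes total genes in the atlas.
#' @param tissues character vector of tissue names (>= 2).
#' @param n_specific_per_tissue planted specific genes per tissue;
#'   `n_specific_per_tissue * length(tissues)` must not exceed `n_genes`.
#' @param fold expression of a specific gene in its tissue (> 1).
#' @param seed integer seed used to pick which genes are planted.
#' @return gene x tissue matrix with a `"truth"` attribute (named character
#'   vector: planted gene -> tissue).
#' @export
make_tissue_fixture <- function(n_genes, tissues, n_specific_per_tissue, fold, seed) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  stopifnot(is.character(tissues), length(tissues) >= 2L, !anyDuplicated(tissues))
  n_specific_per_tissue <- check_count(n_specific_per_tissue, "n_specific_per_tissue")
  if (n_specific_per_tissue * length(tissues) > n_genes) {
    stop("too many planted genes for `n_genes`", call. = FALSE)
  }
  check_scalar(fold, "fold")
  if (fold <= 1) stop("`fold` must be > 1", call. = FALSE)

  genes <- sprintf("g%03d", seq_len(n_genes))
  with_seed(seed, {
    atlas <- matrix(1, nrow = n_genes, ncol = length(tissues),
                    dimnames = list(genes, tissues))
    planted <- sample(genes, n_specific_per_tissue * length(tissues))
    assign_tissue <- rep(tissues, each = n_specific_per_tissue)
    for (i in seq_along(planted)) atlas[planted[i], assign_tissue[i]] <- fold
    attr(atlas, "truth") <- setNames(assign_tissue, planted)
    atlas
  })
}
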