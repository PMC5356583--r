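#' Tissue preferential-expression calls
#'
#' For each gene, z-scores its expression in every tissue against that
#' gene's across-tissue mean and standard deviation; a (gene, tissue) pair
#' is preferential when the z-score is at least `z_threshold`. A gene may be
#' preferential in several tissues; genes with zero across-tissue spread
#' yield no calls.
#'
#' @param atlas gene x tissue matrix of non-negative expression values
#'   (at least 3 tissues).
#' @param z_threshold z-score threshold for a preferential call.
#' @return data.frame with `gene`, `tissue`, `zscore`, `is_preferential`
#'   (one row per gene x tissue for genes with non-zero spread).
#' @export
preferential_tissues <- function(atlas, z_threshold = 2) {
  check_matrix(atlas, "atlas")
  if (ncol(atlas) < 3L) stop("need at least 3 tissues", call. = FALSE)
  mu <- rowMeans(atlas)
  s <- apply(atlas, 1L, sd)
  keep <- s > 0
  if (!any(keep)) {
    return(data.frame(gene = character(0), tissue = character(0),
                      zscore = numeric(0), is_preferential = logical(0)))
  }
  z <- (atlas[keep, , drop = FALSE] - mu[keep]) / s[keep]
  data.frame(gene = rep(rownames(z), times = ncol(z)),
             tissue = rep(colnames(z), each = nrow(z)),
             zscore = as.numeric(z),
             is_preferential = as.numeric(z) >= z_threshold,
             stringsAsFactors = FALSE)
}

#' Tally preferential tissues over a gene list
#'
#' Counts, per tissue, how many genes of interest are preferentially
#' expressed there, in descending order.
#'
#' @param calls data.frame from [preferential_tissues()].
#' @param genes_of_interest character vector of genes to tally.
#' @return data.frame with `tissue`, `count`, sorted by descending count
#'   (ties alphabetical); every tissue present in `calls` appears.
#' @export
tally_by_tissue <- function(calls, genes_of_interest) {
  tissues <- sort(unique(calls$tissue))
  sel <- calls$is_preferential & calls$gene %in% genes_of_interest
  tab <- table(factor(calls$tissue[sel], levels = tissues))
  out <- data.frame(tissue = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$tissue), , drop = FALSE]
}
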