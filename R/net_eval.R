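#' Reference interaction or pathway collections
#'
#' Constructors for the two kinds of reference used to score network
#' accuracy: an edge set (unordered interacting gene pairs, as in
#' protein-interaction databases) or a gene-set collection (named pathways,
#' as in GMT files).
#'
#' @param pairs two-column matrix or data.frame of gene pairs (order within
#'   a pair is ignored; self-pairs are rejected).
#' @param sets named list of non-empty character vectors.
#' @param name label for the collection.
#' @return an object of class `reference_collection` with fields `name`,
#'   `kind` (`"edge_set"` or `"gene_set"`), `content` and `universe`.
#' @export
reference_edge_set <- function(pairs, name = "edges") {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  if (any(pairs[, 1L] == pairs[, 2L])) stop("self-pairs are not allowed", call. = FALSE)
  key <- unique(paste(pmin(pairs[, 1L], pairs[, 2L]),
                      pmax(pairs[, 1L], pairs[, 2L]), sep = "\r"))
  structure(list(name = name, kind = "edge_set", content = key,
                 universe = unique(as.character(pairs))),
            class = "reference_collection")
}

#' @rdname reference_edge_set
#' @export
reference_gene_set <- function(sets, name = "gene_sets") {
  stopifnot(is.list(sets), length(sets) > 0L)
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty", call. = FALSE)
  structure(list(name = name, kind = "gene_set", content = sets,
                 universe = unique(unlist(sets, use.names = FALSE))),
            class = "reference_collection")
}

#' Read a GMT file as a reference collection
#'
#' @param path path to a tab-delimited GMT file (set name, description,
#'   member genes).
#' @param name label for the collection; defaults to the file name.
#' @return a `reference_collection` of kind `"gene_set"`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  reference_gene_set(fgsea::gmtPathways(path), name = name)
}

#' Fraction of network edges supported by a reference collection
#'
#' For an edge-set reference, the fraction of consensus edges whose unordered
#' gene pair is present in the reference; for a gene-set reference, the
#' fraction of edges whose two endpoints are co-members of at least one set.
#' Edges with either endpoint absent from the reference universe are excluded
#' from the denominator, so networks are only judged where the reference has
#' coverage.
#'
#' @param network a `consensus_network` with at least one edge.
#' @param reference a `reference_collection`.
#' @return accuracy in [0, 1] (`NA` if no edge is covered by the reference).
#' @export
edge_accuracy <- function(network, reference) {
  stopifnot(inherits(network, "consensus_network"),
            inherits(reference, "reference_collection"))
  if (nrow(network$edges) == 0L) stop("network has no edges", call. = FALSE)
  a <- network$edges$regulator
  b <- network$edges$target
  covered <- a %in% reference$universe & b %in% reference$universe
  if (!any(covered)) return(NA_real_)
  a <- a[covered]; b <- b[covered]
  if (reference$kind == "edge_set") {
    hit <- paste(pmin(a, b), pmax(a, b), sep = "\r") %in% reference$content
  } else {
    gene2sets <- membership_index(reference$content)
    hit <- mapply(function(x, y) {
      length(intersect(gene2sets[[x]], gene2sets[[y]])) > 0L
    }, a, b, USE.NAMES = FALSE)
  }
  mean(hit)
}

membership_index <- function(sets) {
  long <- data.frame(gene = unlist(sets, use.names = FALSE),
                     set = rep(seq_along(sets), lengths(sets)))
  split(long$set, long$gene)
}

#' Permutation null for network accuracy
#'
#' Permutes gene labels on the network nodes uniformly and recomputes
#' [edge_accuracy()] for each permutation; the empirical p-value uses the
#' add-one estimator `(1 + #\{null >= observed\}) / (n_perm + 1)` so it is
#' never exactly zero.
#'
#' @param network a `consensus_network`.
#' @param reference a `reference_collection`.
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed.
#' @return list with `observed`, `null_mean`, `null_sd`, `p`.
#' @export
permutation_null <- function(network, reference, n_perm = 1000, seed = 1) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  observed <- edge_accuracy(network, reference)
  nodes <- network$nodes
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      relab <- setNames(sample(nodes), nodes)
      pn <- network
      pn$edges$regulator <- unname(relab[network$edges$regulator])
      pn$edges$target <- unname(relab[network$edges$target])
      edge_accuracy(pn, reference)
    }, numeric(1))
  })
  ok <- !is.na(null)
  list(observed = observed,
       null_mean = mean(null[ok]),
       null_sd = sd(null[ok]),
       p = (1 + sum(null[ok] >= observed)) / (sum(ok) + 1))
}

#' ROC curve of nested seed subnetworks against a gene signature
#'
#' For radius `h = 1..max_radius` the subnetwork `S_h` is the set of genes
#' within `h` undirected steps of `seed_gene` (excluding the seed itself).
#' Each radius contributes the point
#' `(|S_h| / N, |S_h intersect signature| / |S_h|)` where `N` is the network
#' node count: the x-axis is 1 - specificity as the fraction of the network
#' pulled into the subnetwork, and the y-axis is the fraction of subnetwork
#' genes that carry the signature. The curve is anchored at (0, 0). With
#' `sensitivity = "signature"` the y-axis is instead
#' `|S_h intersect signature| / |signature|`, the conventional recall; the
#' subnetwork-denominator definition is the default.
#'
#' @param network a `consensus_network`.
#' @param seed_gene network gene at the centre of the subnetworks.
#' @param signature non-empty character vector of signature genes.
#' @param max_radius largest neighbourhood radius.
#' @param spec_floor specificity floor passed to [partial_auc()].
#' @param sensitivity denominator convention for the y-axis.
#' @return an object of class `roc_curve`: list with `points` (data.frame
#'   `one_minus_specificity`, `sensitivity`), `pauc`, `permutation_p` (`NA`
#'   until [signature_roc_permutation_p()] is run).
#' @export
signature_roc <- function(network, seed_gene, signature, max_radius = 5,
                          spec_floor = 0.9,
                          sensitivity = c("subnetwork", "signature")) {
  stopifnot(inherits(network, "consensus_network"))
  sensitivity <- match.arg(sensitivity)
  if (!seed_gene %in% network$nodes) stop("`seed_gene` not in network", call. = FALSE)
  if (length(signature) == 0L) stop("`signature` is empty", call. = FALSE)
  max_radius <- check_count(max_radius, "max_radius", min = 1L)

  g <- as_igraph(network)
  d <- igraph::distances(g, v = seed_gene, mode = "all")[1L, ]
  N <- length(network$nodes)
  pts <- data.frame(one_minus_specificity = 0, sensitivity = 0)
  for (h in seq_len(max_radius)) {
    s_h <- names(d)[d > 0 & d <= h]
    if (length(s_h) == 0L) next
    ov <- length(intersect(s_h, signature))
    y <- if (sensitivity == "subnetwork") ov / length(s_h) else ov / length(unique(signature))
    pts <- rbind(pts, data.frame(one_minus_specificity = length(s_h) / N,
                                 sensitivity = y))
  }
  pts <- unique(pts)
  curve <- structure(list(points = pts, pauc = NA_real_, permutation_p = NA_real_),
                     class = "roc_curve")
  curve$pauc <- partial_auc(curve, spec_floor = spec_floor)
  curve
}

#' Partial area under a subnetwork ROC curve
#'
#' Trapezoidal area over `one_minus_specificity` in `[0, 1 - spec_floor]`,
#' linearly interpolating between curve points, truncating at the window
#' boundary, and carrying the last sensitivity forward when the curve ends
#' inside the window. The area is normalized by the window width
#' `1 - spec_floor` so a curve at sensitivity 1 throughout scores exactly 1.
#'
#' @param curve a `roc_curve` (or any list with a `points` data.frame).
#' @param spec_floor specificity floor in [0, 1); default restricts to
#'   specificity above 90 percent.
#' @return normalized partial AUC in [0, 1].
#' @export
partial_auc <- function(curve, spec_floor = 0.9) {
  check_scalar(spec_floor, "spec_floor")
  if (spec_floor < 0 || spec_floor >= 1) stop("`spec_floor` must be in [0, 1)", call. = FALSE)
  w <- 1 - spec_floor
  pts <- unique(curve$points)
  pts <- pts[order(pts$one_minus_specificity, pts$sensitivity), , drop = FALSE]
  x <- pts$one_minus_specificity
  y <- pts$sensitivity
  if (length(x) == 0L || all(x == 0)) return(0)
  if (x[1L] > 0) { x <- c(0, x); y <- c(0, y) }
  area <- 0
  for (i in seq_len(length(x) - 1L)) {
    x0 <- x[i]; x1 <- x[i + 1L]
    if (x0 >= w) break
    y0 <- y[i]; y1 <- y[i + 1L]
    if (x1 > w) {            # truncate the segment at the window edge
      y1 <- y0 + (y1 - y0) * (w - x0) / (x1 - x0)
      x1 <- w
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  if (max(x) < w) area <- area + (w - max(x)) * y[length(y)]   # constant extension
  area / w
}

#' Permutation p-value for a signature ROC partial AUC
#'
#' Node labels are permuted uniformly (equivalently, the seed gene and the
#' signature genes are re-assigned to random network positions) and the
#' partial AUC is recomputed; the empirical p-value uses add-one smoothing.
#'
#' @inheritParams signature_roc
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return empirical p-value in (0, 1].
#' @export
signature_roc_permutation_p <- function(network, seed_gene, signature,
                                        n_perm = 1000, seed = 1,
                                        max_radius = 5, spec_floor = 0.9) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  observed <- signature_roc(network, seed_gene, signature, max_radius,
                            spec_floor)$pauc
  nodes <- network$nodes
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      inv <- setNames(nodes, sample(nodes))   # new label -> original node
      seed0 <- unname(inv[seed_gene])
      sig0 <- unname(inv[intersect(signature, nodes)])
      sig0 <- c(sig0, setdiff(signature, nodes))
      if (length(sig0) == 0L) return(0)
      signature_roc(network, seed0, sig0, max_radius, spec_floor)$pauc
    }, numeric(1))
  })
  (1 + sum(null >= observed)) / (n_perm + 1)
}
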