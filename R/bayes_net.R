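#' BDeu local score of one family
#'
#' Log marginal likelihood of `target` given a parent set under the BDeu
#' (Bayesian Dirichlet equivalent uniform) prior on a three-state discrete
#' matrix: `log prod_j Gamma(a_j)/Gamma(a_j + N_j) prod_k
#' Gamma(a_jk + N_jk)/Gamma(a_jk)` with `a_jk = ess / (q r)`, `q = 3^|parents|`
#' parent configurations and `r = 3` states. When `cis_flags` is supplied the
#' log structure-prior increments of [edge_prior()] for each parent edge are
#' added, so the returned value is the quantity the structure search optimizes.
#'
#' @param target gene name.
#' @param parents character vector of parent gene names (excluding `target`).
#' @param data integer gene x sample matrix with values in \{0, 1, 2\}
#'   (from [discretize_expression()]).
#' @param ess equivalent sample size of the Dirichlet prior.
#' @param cis_flags optional named logical vector over genes; when given, the
#'   cis-CNA structure prior is included.
#' @param kappa_penalty,kappa_bonus prior strengths passed to [edge_prior()].
#' @return the local log score (a single real).
#' @export
local_score <- function(target, parents, data, ess = 1, cis_flags = NULL,
                        kappa_penalty = 0.1, kappa_bonus = 10) {
  genes <- rownames(data)
  ti <- match(target, genes)
  pi <- match(parents, genes)
  if (is.na(ti) || anyNA(pi)) {
    stop("unknown gene in `target` or `parents`", call. = FALSE)
  }
  if (target %in% parents) stop("`parents` must exclude `target`", call. = FALSE)
  sc <- bdeu_family_score_cpp(data, ti, as.integer(pi), ess)
  if (!is.null(cis_flags)) {
    for (p in parents) {
      sc <- sc + edge_prior(p, target, cis_flags, kappa_penalty, kappa_bonus)
    }
  }
  sc
}

#' Log structure-prior increment for a candidate edge
#'
#' Encodes the copy-number anchoring used during structure search: a cis-CNA
#' gene's expression is already explained by its own DNA dosage, so *any*
#' expression edge into a cis-flagged target is penalized
#' (`log(kappa_penalty)`, `kappa_penalty < 1`) — including edges from other
#' cis genes, which is exactly where co-localization in a shared CNA block
#' mimics regulation — while an edge from a cis regulator to a non-cis
#' target is favoured (`log(kappa_bonus)`, `kappa_bonus > 1`) because the
#' genetic anchor gives the dependency a causal direction. Edges between two
#' non-cis genes are neutral. Because the BDeu score is likelihood
#' equivalent, these increments are what orients edges inside a Markov
#' equivalence class.
#'
#' @param regulator,target gene names.
#' @param cis_flags named logical vector over genes (TRUE = cis-CNA gene).
#' @param kappa_penalty prior odds multiplier (< 1) for any edge into a cis
#'   target.
#' @param kappa_bonus prior odds multiplier (> 1) for a cis regulator
#'   explaining a non-cis target.
#' @return log prior increment (0 when neither rule applies).
#' @export
edge_prior <- function(regulator, target, cis_flags,
                       kappa_penalty = 0.1, kappa_bonus = 10) {
  if (is.na(cis_flags[regulator]) || is.na(cis_flags[target])) {
    stop("both genes must be present in `cis_flags`", call. = FALSE)
  }
  if (cis_flags[[target]]) return(log(kappa_penalty))
  if (cis_flags[[regulator]]) return(log(kappa_bonus))
  0
}

# n x n matrix of log prior increments for all ordered pairs
edge_prior_matrix <- function(genes, cis_flags = NULL,
                              kappa_penalty = 0.1, kappa_bonus = 10) {
  n <- length(genes)
  pm <- matrix(0, n, n, dimnames = list(genes, genes))
  if (is.null(cis_flags)) return(pm)
  cis <- as.logical(cis_flags[genes])
  cis[is.na(cis)] <- FALSE
  pm[, cis] <- log(kappa_penalty)       # any regulator -> cis target
  pm[cis, !cis] <- log(kappa_bonus)     # cis regulator -> non-cis target
  diag(pm) <- 0
  pm
}

#' Search for a high-scoring network structure
#'
#' Simulated annealing over single-edge add/delete/reverse moves on the space
#' of directed acyclic graphs with bounded in-degree, scored by the sum of
#' BDeu family scores plus the cis-CNA structure prior. Moves that would
#' create a cycle or exceed `max_parents` are rejected outright; otherwise a
#' move is accepted with Metropolis probability `exp(delta / T)` under a
#' geometric temperature schedule from `t0` down to `t_end`. The best-scoring
#' structure visited is returned, so the reported score trace is
#' non-decreasing.
#'
#' @param data integer gene x sample matrix with values in \{0, 1, 2\}.
#' @param cis_flags optional named logical vector over genes enabling the
#'   copy-number structure prior.
#' @param max_parents maximum in-degree (>= 1; 0 is accepted and yields the
#'   empty graph).
#' @param n_steps number of proposal steps; defaults to `300 * n_genes`.
#' @param t0,t_end initial and final temperatures of the geometric schedule.
#' @param ess BDeu equivalent sample size.
#' @param kappa_penalty,kappa_bonus prior strengths, see [edge_prior()].
#' @param seed integer seed; the search is deterministic given the seed.
#' @return An object of class `structure_sample`: list with `edges`
#'   (data.frame `regulator`, `target`), `score`, `seed`, `nodes` and `trace`
#'   (best score over the run).
#' @export
search_structure <- function(data, cis_flags = NULL, max_parents = 3,
                             n_steps = NULL, t0 = 1.5, t_end = 0.01, ess = 1,
                             kappa_penalty = 0.1, kappa_bonus = 10, seed = 1) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  storage.mode(data) <- "integer"
  if (any(data < 0L | data > 2L)) stop("`data` must contain states 0, 1, 2", call. = FALSE)
  max_parents <- check_count(max_parents, "max_parents")
  genes <- rownames(data)
  if (is.null(n_steps)) n_steps <- 1500L * length(genes)
  n_steps <- check_count(n_steps, "n_steps", min = 1L)

  pm <- edge_prior_matrix(genes, cis_flags, kappa_penalty, kappa_bonus)
  res <- anneal_search_cpp(data, pm, max_parents, n_steps, t0, t_end, ess,
                           as.integer(seed), trace_every = 10L)
  em <- res$edges
  structure(list(
    edges = data.frame(regulator = genes[em[, 1L]], target = genes[em[, 2L]],
                       stringsAsFactors = FALSE),
    score = res$score,
    seed = as.integer(seed),
    nodes = genes,
    trace = as.numeric(res$trace)
  ), class = "structure_sample")
}

#' Per-edge occurrence frequencies over structure samples
#'
#' @param samples list of `structure_sample` objects.
#' @return data.frame `regulator`, `target`, `frequency` (fraction of samples
#'   containing the directed edge), sorted by decreasing frequency.
#' @export
edge_frequencies <- function(samples) {
  stopifnot(length(samples) >= 1L)
  all_edges <- do.call(rbind, lapply(samples, function(s) s$edges))
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    return(data.frame(regulator = character(0), target = character(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  }
  key <- paste(all_edges$regulator, all_edges$target, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(regulator = vapply(parts, `[`, "", 1L),
                    target = vapply(parts, `[`, "", 2L),
                    frequency = as.numeric(tab) / length(samples),
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$regulator, out$target), , drop = FALSE]
}

#' Build the consensus network from structure samples
#'
#' A directed edge is retained when it appears in at least
#' `consensus_threshold` of the structure samples; its consensus frequency is
#' recorded as the edge weight. Because a frequency-thresholded union of DAGs
#' need not be acyclic, [resolve_cycles()] is applied before returning.
#'
#' @param samples list of `structure_sample` objects (>= 1).
#' @param consensus_threshold minimum edge frequency in (0, 1].
#' @param cis_flags optional named logical vector over genes, stored on the
#'   network for downstream annotation.
#' @return A `consensus_network`: list with `nodes`, `edges` (data.frame
#'   `regulator`, `target`, `frequency`), `cis`, and `removed` (edges deleted
#'   during cycle resolution).
#' @export
build_consensus <- function(samples, consensus_threshold = 0.3, cis_flags = NULL) {
  stopifnot(length(samples) >= 1L)
  check_scalar(consensus_threshold, "consensus_threshold")
  if (consensus_threshold <= 0 || consensus_threshold > 1) {
    stop("`consensus_threshold` must be in (0, 1]", call. = FALSE)
  }
  nodes <- samples[[1L]]$nodes
  freq <- edge_frequencies(samples)
  keep <- freq[freq$frequency >= consensus_threshold, , drop = FALSE]
  net <- new_consensus_network(nodes, keep, cis_flags)
  resolve_cycles(net)
}

new_consensus_network <- function(nodes, edges, cis_flags = NULL,
                                  removed = NULL) {
  cis <- setNames(rep(FALSE, length(nodes)), nodes)
  if (!is.null(cis_flags)) {
    common <- intersect(names(cis_flags), nodes)
    cis[common] <- as.logical(cis_flags[common])
  }
  if (is.null(removed)) {
    removed <- data.frame(regulator = character(0), target = character(0),
                          frequency = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, cis = cis, removed = removed),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("consensus_network: %d nodes, %d edges (%d cis genes; %d edges removed to break cycles)\n",
              length(x$nodes), nrow(x$edges), sum(x$cis), nrow(x$removed)))
  invisible(x)
}

#' Convert a consensus network to an igraph object
#'
#' @param network a `consensus_network`.
#' @return directed [igraph::igraph] graph with a `frequency` edge attribute
#'   and a `cis` vertex attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "consensus_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("regulator", "target", "frequency"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = network$nodes,
                          cis = unname(network$cis[network$nodes])))
  g
}

#' Break directed cycles by deleting the weakest edge on a cycle
#'
#' While a directed cycle exists, the minimum-frequency edge lying on some
#' cycle (an edge inside a non-trivial strongly connected component) is
#' deleted, with ties broken by the lexicographically smallest
#' `(regulator, target)` pair. High-confidence consensus edges are therefore
#' preserved whenever possible. Deletions are recorded in `$removed`.
#'
#' @param network a `consensus_network`, or a data.frame of weighted edges
#'   (`regulator`, `target`, `frequency`).
#' @return an acyclic `consensus_network`.
#' @export
resolve_cycles <- function(network) {
  if (is.data.frame(network)) {
    nodes <- sort(unique(c(network$regulator, network$target)))
    network <- new_consensus_network(nodes, network)
  }
  stopifnot(inherits(network, "consensus_network"))
  edges <- network$edges
  removed <- network$removed
  repeat {
    g <- igraph::graph_from_data_frame(
      edges[, c("regulator", "target"), drop = FALSE],
      directed = TRUE, vertices = network$nodes)
    if (igraph::is_dag(g)) break
    comp <- igraph::components(g, mode = "strong")
    memb <- comp$membership[edges$regulator]
    in_cycle <- memb == comp$membership[edges$target] &
      comp$csize[memb] > 1L
    cand <- edges[in_cycle, , drop = FALSE]
    cand <- cand[order(cand$frequency, cand$regulator, cand$target), , drop = FALSE]
    victim <- cand[1L, , drop = FALSE]
    removed <- rbind(removed, victim)
    drop <- edges$regulator == victim$regulator & edges$target == victim$target
    edges <- edges[!drop, , drop = FALSE]
  }
  new_consensus_network(network$nodes, edges, network$cis, removed)
}

#' Skeleton precision and recall against a ground-truth network
#'
#' Compares the undirected skeleton (deduplicated unordered gene pairs) of a
#' learned consensus network with the skeleton of the simulation truth.
#'
#' @param network a `consensus_network`.
#' @param truth a `causal_network`.
#' @return list with `precision`, `recall`, `tp`, `n_learned`, `n_true`.
#' @export
skeleton_metrics <- function(network, truth) {
  stopifnot(inherits(network, "consensus_network"), inherits(truth, "causal_network"))
  skel <- function(a, b) {
    unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
  }
  learned <- skel(network$edges$regulator, network$edges$target)
  true <- skel(truth$edges$regulator, truth$edges$target)
  tp <- length(intersect(learned, true))
  list(precision = if (length(learned)) tp / length(learned) else NA_real_,
       recall = if (length(true)) tp / length(true) else NA_real_,
       tp = tp, n_learned = length(learned), n_true = length(true))
}

#' Area under the precision-recall curve for directed edge recovery
#'
#' Ranks all ordered gene pairs by consensus frequency (pairs never observed
#' score 0) against the directed edges of the simulation truth, and computes
#' the area under the precision-recall curve by trapezoidal integration over
#' the distinct frequency thresholds, treating tied scores as a single block.
#'
#' @param freq data.frame from [edge_frequencies()].
#' @param truth a `causal_network`.
#' @return AUPRC in [0, 1].
#' @export
edge_recovery_auprc <- function(freq, truth) {
  stopifnot(inherits(truth, "causal_network"))
  genes <- truth$genes
  n_pairs <- length(genes) * (length(genes) - 1L)
  true_key <- paste(truth$edges$regulator, truth$edges$target, sep = "\r")
  n_pos <- length(unique(true_key))
  if (n_pos == 0L) return(NA_real_)

  freq <- freq[freq$regulator %in% genes & freq$target %in% genes, , drop = FALSE]
  key <- paste(freq$regulator, freq$target, sep = "\r")
  is_pos <- key %in% true_key

  thresholds <- sort(unique(freq$frequency), decreasing = TRUE)
  rec <- 0; prec <- 1
  auc <- 0
  for (th in thresholds) {
    sel <- freq$frequency >= th
    tp <- sum(is_pos & sel)
    npred <- sum(sel)
    r <- tp / n_pos
    p <- tp / npred
    auc <- auc + (r - rec) * (p + prec) / 2
    rec <- r; prec <- p
  }
  # remaining mass: every unscored pair at frequency 0 in one tie block
  p_final <- n_pos / n_pairs
  auc <- auc + (1 - rec) * (p_final + prec) / 2
  auc
}
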