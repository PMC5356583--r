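#' Number of close neighbours of a gene
#'
#' Counts the distinct genes within `hops` undirected steps of `gene`,
#' excluding the gene itself.
#'
#' @param network a `consensus_network`.
#' @param gene gene name (must be a network node).
#' @param hops neighbourhood radius.
#' @return integer neighbour count.
#' @export
node_degree <- function(network, gene, hops = 1) {
  stopifnot(inherits(network, "consensus_network"))
  if (!gene %in% network$nodes) stop(sprintf("gene '%s' not in network", gene), call. = FALSE)
  hops <- check_count(hops, "hops", min = 1L)
  unname(node_degree_all(network, hops)[gene])
}

# degree of every node at once (named integer vector)
node_degree_all <- function(network, hops = 1) {
  g <- as_igraph(network)
  nb <- igraph::ego_size(g, order = hops, mode = "all", mindist = 1)
  setNames(as.integer(nb), network$nodes)
}

#' Spearman correlation of node degrees between two networks
#'
#' @param network1,network2 `consensus_network` objects sharing at least 10
#'   genes.
#' @param hops neighbourhood radius for the degree definition.
#' @return list with `rho` and `p` (two-sided, t approximation).
#' @export
degree_correlation <- function(network1, network2, hops = 1) {
  common <- intersect(network1$nodes, network2$nodes)
  if (length(common) < 10L) stop("need at least 10 common genes", call. = FALSE)
  d1 <- node_degree_all(network1, hops)[common]
  d2 <- node_degree_all(network2, hops)[common]
  ct <- suppressWarnings(stats::cor.test(d1, d2, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Fisher-style overlap test of a gene's neighbourhoods in two networks
#'
#' One-sided hypergeometric upper-tail probability for the observed overlap
#' of the two neighbour sets within a stated gene universe.
#'
#' @param network1,network2 `consensus_network` objects containing `gene`.
#' @param gene gene whose neighbourhoods are compared.
#' @param hops neighbourhood radius.
#' @param universe gene universe containing both neighbourhoods.
#' @return list with `overlap` and `p`.
#' @export
neighborhood_overlap_test <- function(network1, network2, gene, hops = 1,
                                      universe) {
  if (length(universe) == 0L) stop("`universe` is empty", call. = FALSE)
  if (!gene %in% network1$nodes || !gene %in% network2$nodes) {
    stop("`gene` must be in both networks", call. = FALSE)
  }
  nb <- function(net) {
    g <- as_igraph(net)
    setdiff(names(igraph::ego(g, order = hops, nodes = gene, mode = "all")[[1L]]), gene)
  }
  a <- nb(network1); b <- nb(network2)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    stop("`universe` must contain both neighbourhoods", call. = FALSE)
  }
  ov <- length(intersect(a, b))
  n_u <- length(unique(universe))
  p <- phyper(ov - 1, length(a), n_u - length(a), length(b), lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Call key regulators by directed downstream reach
#'
#' A gene's downstream count is the number of distinct directed descendants
#' within `hops` steps. A gene is a key regulator when its downstream count
#' exceeds `mean + sd_mult * sd` of the counts over all nodes; when the
#' counts have zero spread (e.g. an empty network) no gene is called.
#'
#' @param network an acyclic `consensus_network`.
#' @param hops downstream reach radius.
#' @param sd_mult threshold multiplier on the standard deviation.
#' @return data.frame with `gene`, `downstream_count`, `degree` (undirected
#'   close-neighbour count), `threshold`, `is_key`.
#' @export
call_key_regulators <- function(network, hops = 3, sd_mult = 2) {
  stopifnot(inherits(network, "consensus_network"))
  hops <- check_count(hops, "hops", min = 1L)
  g <- as_igraph(network)
  ds <- igraph::ego_size(g, order = hops, mode = "out", mindist = 1)
  ds <- setNames(as.integer(ds), network$nodes)
  s <- sd(ds)
  thr <- mean(ds) + sd_mult * s
  data.frame(gene = network$nodes,
             downstream_count = unname(ds),
             degree = unname(node_degree_all(network, 1L)),
             threshold = thr,
             is_key = if (is.na(s) || s == 0) rep(FALSE, length(ds)) else unname(ds > thr),
             stringsAsFactors = FALSE)
}

#' Reduce key regulators to distinct key drivers
#'
#' Removes any key regulator that is directly regulated by another key
#' regulator of strictly higher degree; among the survivors, pairs with equal
#' degree and mutual edges lose the lexicographically later gene. The result
#' is ordered by descending degree (ties alphabetical).
#'
#' @param network a `consensus_network`.
#' @param key_regulators data.frame from [call_key_regulators()] (only rows
#'   with `is_key = TRUE` are used), or a character vector of genes.
#' @return character vector of distinct key drivers.
#' @export
distinct_key_drivers <- function(network, key_regulators) {
  stopifnot(inherits(network, "consensus_network"))
  if (is.data.frame(key_regulators)) {
    kr <- key_regulators$gene[key_regulators$is_key]
  } else {
    kr <- as.character(key_regulators)
  }
  if (!all(kr %in% network$nodes)) stop("key regulators must be network nodes", call. = FALSE)
  if (length(kr) == 0L) return(character(0))
  deg <- node_degree_all(network, 1L)
  ekey <- paste(network$edges$regulator, network$edges$target, sep = "\r")
  has_edge <- function(a, b) paste(a, b, sep = "\r") %in% ekey

  drop <- vapply(kr, function(k) {
    any(vapply(kr, function(k2) {
      k2 != k && deg[k2] > deg[k] && has_edge(k2, k)
    }, logical(1)))
  }, logical(1))
  surv <- kr[!drop]
  # equal-degree mutual edges: lexicographically later gene is removed
  drop2 <- rep(FALSE, length(surv))
  for (i in seq_along(surv)) {
    for (j in seq_along(surv)) {
      if (i == j) next
      a <- surv[i]; b <- surv[j]
      if (deg[a] == deg[b] && has_edge(a, b) && has_edge(b, a) && a < b) {
        drop2[j] <- TRUE
      }
    }
  }
  surv <- surv[!drop2]
  surv[order(-deg[surv], surv)]
}

#' Project seed genes onto a network and keep seed-rich components
#'
#' Takes the induced subgraph on the seeds present in the network plus their
#' first undirected neighbours, then keeps the connected components
#' containing at least `min_component_seeds` seeds.
#'
#' @param network a `consensus_network`.
#' @param seeds character vector of seed genes (at least one must be a
#'   network node).
#' @param min_component_seeds minimum seeds per retained component.
#' @return An object of class `subnetwork_result`: list with `members`,
#'   `seeds_in_network`, `component` (named membership for members), and
#'   `n_components_kept`. Empty (with a warning) when no component
#'   qualifies.
#' @export
project_seed_subnetwork <- function(network, seeds, min_component_seeds = 3) {
  stopifnot(inherits(network, "consensus_network"))
  seeds <- unique(as.character(seeds))
  seeds_in <- intersect(seeds, network$nodes)
  if (length(seeds_in) == 0L) stop("no seed is a network node", call. = FALSE)
  g <- as_igraph(network)
  nb <- unique(unlist(lapply(igraph::ego(g, order = 1, nodes = seeds_in, mode = "all"),
                             names)))
  sub <- igraph::induced_subgraph(g, vids = nb)
  comp <- igraph::components(sub, mode = "weak")
  memb <- comp$membership
  keep <- which(vapply(seq_len(comp$no), function(k) {
    sum(names(memb)[memb == k] %in% seeds_in) >= min_component_seeds
  }, logical(1)))
  if (length(keep) == 0L) {
    warning("no component contains enough seeds; returning empty subnetwork")
    members <- character(0); memb_out <- integer(0)
  } else {
    members <- names(memb)[memb %in% keep]
    memb_out <- memb[members]
  }
  structure(list(members = members,
                 seeds_in_network = seeds_in,
                 component = memb_out,
                 n_components_kept = length(keep)),
            class = "subnetwork_result")
}

#' Mean directed shortest distance from a driver set to every gene
#'
#' Breadth-first shortest-path length from each driver to each gene
#' (direction driver to gene); a driver is at distance 0 from itself. The
#' mean over drivers is finite only for genes reachable from all drivers;
#' other genes get `Inf` and are excluded from the top-decile flag, which
#' marks the `ceiling(frac * n)` fully-reachable genes of smallest mean
#' distance (boundary ties included).
#'
#' @param network a `consensus_network`.
#' @param drivers non-empty set of driver genes (network nodes).
#' @param frac top fraction flagged as common downstream genes.
#' @param mode `"out"` follows edge direction (default); `"all"` ignores it.
#' @return data.frame with `gene`, `mean_distance`, `reachable_from`,
#'   `is_common_downstream`, sorted by ascending mean distance; the number of
#'   drivers is stored in the `"n_drivers"` attribute.
#' @export
mean_distance_to_drivers <- function(network, drivers, frac = 0.1,
                                     mode = c("out", "all")) {
  stopifnot(inherits(network, "consensus_network"))
  mode <- match.arg(mode)
  drivers <- unique(as.character(drivers))
  if (length(drivers) == 0L) stop("`drivers` is empty", call. = FALSE)
  if (!all(drivers %in% network$nodes)) stop("drivers must be network nodes", call. = FALSE)
  g <- as_igraph(network)
  d <- igraph::distances(g, v = drivers, to = network$nodes, mode = mode)
  ranking <- data.frame(gene = network$nodes,
                        mean_distance = colMeans(d),
                        reachable_from = colSums(is.finite(d)),
                        stringsAsFactors = FALSE)
  ranking$is_common_downstream <- FALSE
  full <- is.finite(ranking$mean_distance)
  if (any(full)) {
    md <- ranking$mean_distance[full]
    k <- ceiling(frac * sum(full))
    cutoff <- sort(md)[k]
    ranking$is_common_downstream[full] <- md <= cutoff
  }
  ranking <- ranking[order(ranking$mean_distance, ranking$gene), , drop = FALSE]
  rownames(ranking) <- NULL
  attr(ranking, "n_drivers") <- length(drivers)
  ranking
}

#' Common downstream genes of a driver set
#'
#' Among genes reachable from all drivers, the `ceiling(frac * n)` genes with
#' the smallest mean shortest distance; genes tied with the cutoff value are
#' all included.
#'
#' @param ranking data.frame from [mean_distance_to_drivers()].
#' @param frac top fraction in (0, 1].
#' @return character vector of gene names (empty, with a warning, when no
#'   gene is reachable from all drivers).
#' @export
common_downstream_genes <- function(ranking, frac = 0.1) {
  check_scalar(frac, "frac")
  if (frac <= 0 || frac > 1) stop("`frac` must be in (0, 1]", call. = FALSE)
  full <- is.finite(ranking$mean_distance)
  if (!any(full)) {
    warning("no gene is reachable from all drivers")
    return(character(0))
  }
  md <- ranking$mean_distance[full]
  k <- ceiling(frac * sum(full))
  cutoff <- sort(md)[k]
  sel <- full & ranking$mean_distance <= cutoff
  ranking$gene[sel]
}
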