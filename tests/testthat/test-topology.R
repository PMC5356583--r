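path_net <- function() {
  make_net(c("A", "B", "C", "D", "E"),
           data.frame(regulator = c("A", "B", "C", "D"),
                      target = c("B", "C", "D", "E"), frequency = 1))
}

test_that("node degree counts close neighbours at the requested radius", {
  net <- path_net()
  expect_equal(node_degree(net, "A", hops = 1), 1)
  expect_equal(node_degree(net, "A", hops = 2), 2)   # path A-B-C
  expect_equal(node_degree(net, "C", hops = 1), 2)
  iso <- make_net(c("A", "B", "C"),
                  data.frame(regulator = "A", target = "B", frequency = 1))
  expect_equal(node_degree(iso, "C"), 0)
  star <- make_net(c("h", paste0("L", 1:7)),
                   data.frame(regulator = "h", target = paste0("L", 1:7),
                              frequency = 1))
  expect_equal(node_degree(star, "h"), 7)
  expect_error(node_degree(net, "ZZ"), "not in network")
})

test_that("degree correlation is 1 on itself and near 0 for independent graphs", {
  g1 <- random_dag_edges(200, 0.02, seed = 1)
  net1 <- make_net(g1$nodes, g1$edges)
  self <- degree_correlation(net1, net1)
  expect_equal(self$rho, 1)
  g2 <- random_dag_edges(200, 0.02, seed = 99)
  net2 <- make_net(g2$nodes, g2$edges)
  indep <- degree_correlation(net1, net2)
  expect_lt(abs(indep$rho), 0.2)
  small <- make_net(c("A", "B"), data.frame(regulator = "A", target = "B",
                                            frequency = 1))
  expect_error(degree_correlation(small, small), "10 common genes")
})

test_that("neighbourhood overlap test matches exhaustive hypergeometric tails", {
  net <- path_net()
  # disjoint neighbourhoods -> P(X >= 0) = 1
  net_b <- make_net(net$nodes, data.frame(regulator = "A", target = "E",
                                          frequency = 1))
  r <- neighborhood_overlap_test(net, net_b, "A", universe = net$nodes)
  expect_equal(r$p, 1)

  # direct check against the summed tail for many configurations
  for (cfg in list(c(20, 5, 6, 4), c(30, 10, 8, 5), c(60, 20, 15, 10),
                   c(15, 5, 5, 5), c(40, 12, 9, 3))) {
    u <- cfg[1]; na <- cfg[2]; nb <- cfg[3]; k <- cfg[4]
    expect_equal(phyper(k - 1, na, u - na, nb, lower.tail = FALSE),
                 oracle_hyper_tail(k, na, nb, u), tolerance = 1e-12)
  }

  # maximal overlap gives the smallest achievable p
  u <- 20; na <- 5; nb <- 6
  pmax_ov <- phyper(min(na, nb) - 1, na, u - na, nb, lower.tail = FALSE)
  expect_equal(pmax_ov, oracle_hyper_tail(min(na, nb), na, nb, u),
               tolerance = 1e-12)
  expect_error(neighborhood_overlap_test(net, net_b, "A", universe = character(0)),
               "empty")
})

test_that("key regulators are genes with extreme directed downstream reach", {
  # hub with 20 direct targets in a sparse 100-node graph
  nodes <- sprintf("n%03d", 1:100)
  hub_edges <- data.frame(regulator = "n001", target = nodes[2:21])
  sparse <- data.frame(regulator = nodes[22:40], target = nodes[23:41])
  sparse <- sparse[sparse$regulator != sparse$target, ]
  net <- make_net(nodes, rbind(hub_edges, sparse)[, 1:2] |>
                    transform(frequency = 1))
  kr <- call_key_regulators(net, hops = 3, sd_mult = 2)
  expect_true(kr$is_key[kr$gene == "n001"])
  expect_equal(kr$downstream_count[kr$gene == "n001"], 20)

  # empty graph: zero spread, no calls
  empty <- make_net(nodes[1:10], data.frame(regulator = character(0),
                                            target = character(0),
                                            frequency = numeric(0)))
  expect_false(any(call_key_regulators(empty)$is_key))

  # descendant counts agree with matrix-power reachability on random DAGs
  for (s in 1:10) {
    g <- random_dag_edges(25, 0.08, seed = s)
    netr <- make_net(g$nodes, g$edges)
    krr <- call_key_regulators(netr, hops = 3)
    for (u in sample(g$nodes, 5)) {
      expect_equal(krr$downstream_count[krr$gene == u],
                   length(oracle_descendants(g$edges, g$nodes, u, 3)),
                   info = sprintf("seed %d node %s", s, u))
    }
  }
})

test_that("distinct key drivers drop regulators dominated by stronger neighbours", {
  nodes <- c("A", "B", "C", "D", "E", "F")
  # A (high degree) directly regulates B (lower degree): B is filtered
  edges <- data.frame(regulator = c("A", "A", "A", "A", "B", "B", "C"),
                      target = c("B", "C", "D", "E", "E", "F", "F"),
                      frequency = 1)
  net <- make_net(nodes, edges)
  out <- distinct_key_drivers(net, c("A", "B"))
  expect_identical(out, "A")

  # key regulators with no edges among them are all retained
  out2 <- distinct_key_drivers(net, c("D", "E", "F"))
  expect_setequal(out2, c("D", "E", "F"))

  # antichain property on random graphs: no survivor regulated by a
  # higher-degree survivor
  for (s in 1:5) {
    g <- random_dag_edges(30, 0.1, seed = s)
    netr <- make_net(g$nodes, g$edges)
    kr <- call_key_regulators(netr, hops = 2, sd_mult = 1)
    dk <- distinct_key_drivers(netr, kr)
    deg <- sapply(dk, function(x) node_degree(netr, x))
    ek <- paste(g$edges$regulator, g$edges$target)
    for (a in dk) for (b in dk) {
      if (a != b && deg[a] > deg[b]) {
        expect_false(paste(a, b) %in% ek)
      }
    }
  }
})

test_that("seed projection keeps seed-rich components and their neighbours", {
  # path A-B-C-D-E with seeds {A, C}: members A,B,C,D at min 2 seeds
  net <- path_net()
  r <- project_seed_subnetwork(net, c("A", "C"), min_component_seeds = 2)
  expect_setequal(r$members, c("A", "B", "C", "D"))
  expect_true(all(r$seeds_in_network %in% r$members))

  # all nodes as seeds recovers the whole connected graph
  r2 <- project_seed_subnetwork(net, net$nodes, min_component_seeds = 3)
  expect_setequal(r2$members, net$nodes)

  # monotone in min_component_seeds
  expect_warning(
    r3 <- project_seed_subnetwork(net, c("A", "C"), min_component_seeds = 3),
    "enough seeds")
  expect_warning(r4 <- project_seed_subnetwork(net, "A", min_component_seeds = 3),
                 "enough seeds")
  expect_lte(length(r3$members), length(r$members))
  expect_length(r4$members, 0)
  expect_error(project_seed_subnetwork(net, "ZZ"), "no seed")
})

test_that("mean driver distances match brute-force shortest paths", {
  # chain with drivers {A}: C sits at distance 2
  net <- path_net()
  rk <- mean_distance_to_drivers(net, "A")
  expect_equal(rk$mean_distance[rk$gene == "A"], 0)
  expect_equal(rk$mean_distance[rk$gene == "C"], 2)

  # random DAGs vs Floyd-Warshall, including unreachable = Inf
  for (s in 1:10) {
    g <- random_dag_edges(30, 0.07, seed = s + 50)
    netr <- make_net(g$nodes, g$edges)
    drivers <- g$nodes[1:3]
    rk <- mean_distance_to_drivers(netr, drivers)
    d <- oracle_shortest_paths(g$edges, g$nodes, directed = TRUE)
    want <- colMeans(d[drivers, , drop = FALSE])
    expect_equal(setNames(rk$mean_distance, rk$gene)[g$nodes], want)
  }
  expect_error(mean_distance_to_drivers(net, character(0)), "empty")
})

test_that("common downstream genes are the closest decile with inclusive ties", {
  nodes <- c("D", sprintf("m%02d", 1:20))
  edges <- data.frame(regulator = c("D", sprintf("m%02d", 1:19)),
                      target = sprintf("m%02d", 1:20), frequency = 1)
  net <- make_net(nodes, edges)
  rk <- mean_distance_to_drivers(net, "D")
  cdg <- common_downstream_genes(rk, frac = 0.1)
  # 21 reachable genes -> ceiling(2.1) = 3 closest: D itself, m01, m02
  expect_setequal(cdg, c("D", "m01", "m02"))
  expect_setequal(common_downstream_genes(rk, frac = 1), nodes)

  # tie at the cutoff includes every tied gene
  star <- make_net(c("D", "x", "y", "z"),
                   data.frame(regulator = "D", target = c("x", "y", "z"),
                              frequency = 1))
  rks <- mean_distance_to_drivers(star, "D")
  expect_setequal(common_downstream_genes(rks, frac = 0.5),
                  c("D", "x", "y", "z"))   # x,y,z all tied at distance 1
  # unreachable genes never enter the decile
  iso <- make_net(c("D", "a", "b"),
                  data.frame(regulator = "D", target = "a", frequency = 1))
  rki <- mean_distance_to_drivers(iso, "D")
  expect_false("b" %in% common_downstream_genes(rki, frac = 1))
})
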