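disc_fixture <- function(n_genes = 4, n = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(0:2, n_genes * n, replace = TRUE), n_genes, n,
              dimnames = list(sprintf("g%02d", 1:n_genes), sprintf("s%02d", 1:n)))
  storage.mode(m) <- "integer"
  m
}

test_that("BDeu local score matches the independent log-gamma oracle", {
  # frozen closed-form value for empty-parent counts (3, 3, 3), ess = 1:
  # lgamma(1) - lgamma(10) + 3 * (lgamma(1/3 + 3) - lgamma(1/3))
  m <- matrix(rep(0:2, each = 3), 1, 9, dimnames = list("g", paste0("s", 1:9)))
  storage.mode(m) <- "integer"
  want <- lgamma(1) - lgamma(10) + 3 * (lgamma(1 / 3 + 3) - lgamma(1 / 3))
  expect_equal(local_score("g", character(0), m, ess = 1), want, tolerance = 1e-12)

  # random 4-node families vs the oracle tabulation
  d <- disc_fixture(4, 40, seed = 3)
  for (target in rownames(d)) {
    for (parents in list(character(0), setdiff(rownames(d), target)[1],
                         setdiff(rownames(d), target)[1:2])) {
      expect_equal(local_score(target, parents, d, ess = 1),
                   oracle_bdeu_from_data(d, target, parents, ess = 1),
                   tolerance = 1e-10)
    }
  }
  # sample order invariance
  d2 <- d[, sample(ncol(d))]
  expect_equal(local_score("g01", "g02", d, 1), local_score("g01", "g02", d2, 1))
  expect_error(local_score("nope", character(0), d, 1), "unknown gene")
})

test_that("an informative parent raises the local score", {
  set.seed(5)
  x <- sample(0:2, 30, replace = TRUE)
  d <- rbind(X = x, Y = x)
  colnames(d) <- paste0("s", 1:30)
  storage.mode(d) <- "integer"
  expect_gt(local_score("Y", "X", d, ess = 1),
            local_score("Y", character(0), d, ess = 1))
})

test_that("edge prior encodes the cis anchoring rules", {
  cf <- c(a = FALSE, b = FALSE, c = TRUE, d = TRUE)
  expect_equal(edge_prior("a", "b", cf), 0)
  expect_equal(edge_prior("a", "c", cf, kappa_penalty = 0.1), log(0.1))
  expect_equal(edge_prior("c", "a", cf, kappa_bonus = 10), log(10))
  # a genetics-anchored target resists parents even from another cis gene
  # (a cis-cis edge is the co-localization confound, not regulation)
  expect_equal(edge_prior("c", "d", cf, kappa_penalty = 0.1), log(0.1))
  expect_error(edge_prior("zz", "a", cf), "cis_flags")
})

test_that("total score decomposes into local scores (whole-graph oracle)", {
  d <- disc_fixture(4, 50, seed = 7)
  # whole-graph oracle: independent evaluation over all families of a DAG
  graph <- list(g01 = character(0), g02 = "g01", g03 = c("g01", "g02"), g04 = "g03")
  total_oracle <- sum(vapply(names(graph), function(t) {
    oracle_bdeu_from_data(d, t, graph[[t]], ess = 1)
  }, numeric(1)))
  total_local <- sum(vapply(names(graph), function(t) {
    local_score(t, graph[[t]], d, ess = 1)
  }, numeric(1)))
  expect_equal(total_local, total_oracle, tolerance = 1e-10)
})

test_that("annealing returns acyclic structures with a monotone best-score trace", {
  d <- disc_fixture(8, 60, seed = 9)
  for (s in 1:20) {
    res <- search_structure(d, n_steps = 2000, seed = s)
    expect_true(oracle_is_acyclic(res$edges, res$nodes))
    expect_true(all(diff(res$trace) >= 0))
    expect_true(all(table(res$edges$target) <= 3))
  }
  # determinism
  expect_identical(search_structure(d, n_steps = 2000, seed = 4)$edges,
                   search_structure(d, n_steps = 2000, seed = 4)$edges)
  # max_parents = 0 leaves no legal add move
  expect_equal(nrow(search_structure(d, max_parents = 0, n_steps = 500, seed = 1)$edges), 0)
})

test_that("a three-gene chain is recovered in most restarts", {
  truth <- structure(list(
    genes = c("A", "B", "C"),
    edges = data.frame(regulator = c("A", "B"), target = c("B", "C"),
                       weight = c(1, 1)),
    cis_genes = character(0), cis_effect = numeric(0),
    topo_order = c("A", "B", "C"), seed = 1L), class = "causal_network")
  cna <- matrix(0, 3, 500, dimnames = list(truth$genes, sprintf("s%03d", 1:500)))
  expr <- simulate_expression(truth, cna, noise_sd = 0.2, seed = 2)
  d <- discretize_expression(expr)
  hits <- vapply(1:20, function(s) {
    res <- search_structure(d, n_steps = 3000, seed = s)
    skel <- sort(paste(pmin(res$edges$regulator, res$edges$target),
                       pmax(res$edges$regulator, res$edges$target)))
    identical(skel, c("A B", "B C"))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("consensus keeps edges at the frequency threshold and counts exactly", {
  mk <- function(edges) structure(list(edges = edges, score = 0, seed = 1,
                                       nodes = c("A", "B", "C"), trace = 0),
                                  class = "structure_sample")
  e_ab <- data.frame(regulator = "A", target = "B")
  e_ac <- data.frame(regulator = "A", target = "C")
  samples <- c(lapply(1:3, function(i) mk(rbind(e_ab, e_ac))),
               lapply(1:7, function(i) mk(e_ac)))
  # A->B in 3/10 kept at threshold 0.3; in 2/10 dropped
  cons <- build_consensus(samples, consensus_threshold = 0.3)
  expect_setequal(paste(cons$edges$regulator, cons$edges$target),
                  c("A B", "A C"))
  expect_equal(cons$edges$frequency[cons$edges$target == "B"], 0.3)
  cons2 <- build_consensus(c(samples[1:2], samples[4:11]), 0.3)
  expect_false("B" %in% cons2$edges$target)

  # identical samples: consensus equals the structure, frequency 1
  cons3 <- build_consensus(lapply(1:5, function(i) mk(e_ab)), 0.3)
  expect_equal(cons3$edges$frequency, 1)
  expect_equal(nrow(cons3$edges), 1)
})

test_that("cycle resolution deletes the weakest edge on each cycle", {
  # DAG input unchanged
  dag <- data.frame(regulator = c("A", "B"), target = c("B", "C"),
                    frequency = c(0.5, 0.9))
  r <- resolve_cycles(dag)
  expect_equal(nrow(r$edges), 2)
  expect_equal(nrow(r$removed), 0)

  # 2-cycle: keep the stronger direction
  two <- data.frame(regulator = c("A", "B"), target = c("B", "A"),
                    frequency = c(0.6, 0.4))
  r2 <- resolve_cycles(two)
  expect_equal(paste(r2$edges$regulator, r2$edges$target), "A B")
  expect_equal(paste(r2$removed$regulator, r2$removed$target), "B A")

  # 3-cycle 0.5 / 0.4 / 0.35: only the 0.35 edge goes
  three <- data.frame(regulator = c("A", "B", "C"), target = c("B", "C", "A"),
                      frequency = c(0.5, 0.4, 0.35))
  r3 <- resolve_cycles(three)
  expect_equal(nrow(r3$edges), 2)
  expect_equal(r3$removed$frequency, 0.35)

  # tie broken by lexicographically smallest (regulator, target)
  tie <- data.frame(regulator = c("B", "A"), target = c("A", "B"),
                    frequency = c(0.5, 0.5))
  rt <- resolve_cycles(tie)
  expect_equal(paste(rt$removed$regulator, rt$removed$target), "A B")
})
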