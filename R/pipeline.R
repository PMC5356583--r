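#' Default pipeline configuration
#'
#' Returns the full nested parameter list driving [run_pipeline()], at the
#' demo scale used throughout the package: a 50-gene / 200-sample synthetic
#' cohort, 20 annealing restarts, consensus threshold 0.3 and the default
#' cis-CNA prior strengths. Any subset of these fields may be overridden by
#' the user config; unknown keys are rejected.
#'
#' @param seed global seed; per-stage seeds are derived from it with a
#'   stage-name-keyed splitting rule so stages are independently
#'   reproducible.
#' @param outdir output directory.
#' @return nested named list.
#' @export
default_config <- function(seed = 1, outdir = tempfile("imbnet_run_")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = list(simulate = TRUE, preprocess = TRUE, learn = TRUE,
                  evaluate = TRUE, survival = TRUE, subnet = TRUE,
                  drivers = TRUE, mediators = TRUE, tissue = TRUE),
    simulate = list(n_genes = 50L, n_hubs = 3L, mean_out_degree = 1.5,
                    frac_cis = 0.3, hub_boost = 8,
                    n_samples = 200L, segment_sd = 1, mean_block_len = 5,
                    noise_sd = 0.5,
                    n_drivers = 2L, log_hr = 1, baseline_rate = 0.02,
                    censor_rate = 0.01),
    preprocess = list(fdr_threshold = 0.05, top_frac = 1),
    learn = list(n_restarts = 20L, max_parents = 3L, n_steps = NULL,
                 ess = 1, use_prior = TRUE, kappa_penalty = 0.1,
                 kappa_bonus = 10, consensus_threshold = 0.3,
                 t0 = 1.5, t_end = 0.01),
    evaluate = list(n_perm = 200L, max_radius = 5L, spec_floor = 0.9,
                    signature_hops = 2L),
    survival = list(alpha = 0.01, fallback_top = 20L),
    subnet = list(min_component_seeds = 3L),
    drivers = list(hops = 3L, sd_mult = 2),
    mediators = list(frac = 0.1, n_drivers_used = 5L),
    tissue = list(tissues = c("prostate", "prefrontal_cortex", "cardiac_muscle",
                              "skeletal_muscle", "adipocyte", "uterus",
                              "ovary", "caudate_nucleus", "conjunctiva",
                              "liver", "kidney", "lung"),
                  n_specific_per_tissue = 3L, fold = 10, z_threshold = 2)
  )
}

# merge a partial user config into defaults, rejecting unknown keys
merge_config <- function(user, defaults) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Resolve a run configuration
#'
#' @param config `NULL` (defaults), a partial nested list, or the path of a
#'   YAML file with the same structure; unknown keys are rejected.
#' @param seed,outdir optional overrides applied after merging.
#' @return the fully resolved config list.
#' @export
resolve_config <- function(config = NULL, seed = NULL, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  base <- default_config(seed = if (is.null(seed)) 1 else seed)
  cfg <- merge_config(config, base)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  cfg
}

# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 10007L + sum(utf8ToInt(stage)) * 131L) %% 2147480000L
}

md5_of <- function(paths) unname(tools::md5sum(paths))

param_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(params), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-to-analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate (ground truth,
#' copy number, expression, survival endpoint), preprocess (cis-CNA
#' detection, informative genes, discretization), learn (annealing restarts
#' + consensus), evaluate (accuracy vs the truth-derived reference with a
#' permutation null, signature ROC), survival screen, seed-subnetwork
#' projection, key-driver calling, mediator ranking, and the tissue tally.
#' Every stage writes its outputs as TSV/GraphML under `outdir`, records
#' them in the returned manifest with md5 checksums, and uses a seed derived
#' from the global seed and the stage name, so identical configs reproduce
#' identical artefacts.
#'
#' @param config see [resolve_config()].
#' @param seed,outdir optional overrides.
#' @return An object of class `run_manifest`: per-stage list of `params_hash`,
#'   `outputs`, `checksums`, `elapsed`, `warnings`, plus the resolved config
#'   (also written to `outdir/config.yaml`).
#' @export
run_pipeline <- function(config = NULL, seed = NULL, outdir = NULL) {
  cfg <- resolve_config(config, seed = seed, outdir = outdir)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "config.yaml"))
  manifest <- list()
  state <- new.env(parent = emptyenv())

  record <- function(stage, params, outputs, t0, warn = character(0)) {
    manifest[[stage]] <<- list(
      params_hash = param_hash(params),
      outputs = outputs,
      checksums = md5_of(outputs),
      elapsed = as.numeric(Sys.time()) - t0,
      warnings = warn)
  }
  need <- function(stage, what) {
    if (is.null(state[[what]])) {
      stop(sprintf("stage '%s' needs missing upstream output '%s'", stage, what),
           call. = FALSE)
    }
    state[[what]]
  }
  path <- function(...) file.path(cfg$outdir, ...)

  if (isTRUE(cfg$stages$simulate)) {
    t0 <- as.numeric(Sys.time()); p <- cfg$simulate
    s <- stage_seed(cfg$seed, "simulate")
    truth <- generate_ground_truth_dag(p$n_genes, p$n_hubs, p$mean_out_degree,
                                       p$frac_cis, seed = s,
                                       hub_boost = p$hub_boost)
    cna <- simulate_cna(truth, p$n_samples, p$segment_sd, seed = s + 1L,
                        mean_block_len = p$mean_block_len)
    expr <- simulate_expression(truth, cna, p$noise_sd, seed = s + 2L)
    out_deg <- table(factor(truth$edges$regulator, levels = truth$genes))
    drivers <- names(sort(out_deg, decreasing = TRUE))[seq_len(p$n_drivers)]
    surv <- simulate_bcr(expr, drivers, p$log_hr, p$baseline_rate,
                         p$censor_rate, seed = s + 3L)
    state$truth <- truth; state$cna <- cna; state$expr <- expr
    state$surv <- surv; state$drivers <- drivers
    outs <- c(path("truth_edges.tsv"), path("truth_edges.tsv.cis.tsv"),
              path("cna.tsv"), path("expression.tsv"), path("survival.tsv"),
              path("planted_drivers.tsv"))
    write_network_tsv(truth, outs[1L])
    write_matrix_tsv(cna, outs[3L])
    write_matrix_tsv(expr, outs[4L])
    write_survival_tsv(surv, outs[5L])
    write.table(data.frame(gene = drivers), outs[6L], sep = "\t",
                quote = FALSE, row.names = FALSE)
    record("simulate", p, outs, t0)
  }

  if (isTRUE(cfg$stages$preprocess)) {
    t0 <- as.numeric(Sys.time()); p <- cfg$preprocess
    expr <- need("preprocess", "expr"); cna <- need("preprocess", "cna")
    cis <- detect_cis_cna(expr, cna, fdr_threshold = p$fdr_threshold)
    informative <- select_informative_genes(expr, cis, top_frac = p$top_frac)
    disc <- discretize_expression(expr[informative, , drop = FALSE])
    state$cis <- cis; state$disc <- disc
    state$cis_flags <- setNames(cis$is_cis, cis$gene)
    outs <- c(path("cis_genes.tsv"), path("informative_genes.tsv"),
              path("discrete.tsv"))
    write.table(cis, outs[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = informative), outs[2L], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_matrix_tsv(disc, outs[3L])
    record("preprocess", p, outs, t0)
  }

  if (isTRUE(cfg$stages$learn)) {
    t0 <- as.numeric(Sys.time()); p <- cfg$learn
    disc <- need("learn", "disc")
    cis_flags <- if (isTRUE(p$use_prior)) need("learn", "cis_flags") else NULL
    s <- stage_seed(cfg$seed, "learn")
    samples <- lapply(seq_len(p$n_restarts), function(i) {
      search_structure(disc, cis_flags = cis_flags, max_parents = p$max_parents,
                       n_steps = p$n_steps, t0 = p$t0, t_end = p$t_end,
                       ess = p$ess, kappa_penalty = p$kappa_penalty,
                       kappa_bonus = p$kappa_bonus, seed = s + i)
    })
    consensus <- build_consensus(samples, p$consensus_threshold,
                                 cis_flags = state$cis_flags)
    state$samples <- samples; state$consensus <- consensus
    outs <- c(path("consensus_edges.tsv"), path("consensus.graphml"),
              path("restart_scores.tsv"))
    write_network_tsv(consensus, outs[1L])
    write_graphml(consensus, outs[2L])
    write.table(data.frame(seed = vapply(samples, `[[`, 1L, "seed"),
                           score = vapply(samples, `[[`, 1, "score"),
                           n_edges = vapply(samples, function(x) nrow(x$edges), 1L)),
                outs[3L], sep = "\t", quote = FALSE, row.names = FALSE)
    record("learn", p, outs, t0)
  }

  if (isTRUE(cfg$stages$evaluate)) {
    t0 <- as.numeric(Sys.time()); p <- cfg$evaluate
    consensus <- need("evaluate", "consensus")
    truth <- need("evaluate", "truth")
    s <- stage_seed(cfg$seed, "evaluate")
    ref <- reference_edge_set(truth$edges[, c("regulator", "target")],
                              name = "simulation_truth")
    nullres <- permutation_null(consensus, ref, n_perm = p$n_perm, seed = s)
    metrics <- skeleton_metrics(consensus, truth)
    # planted signature: true downstream genes of the strongest hub
    hub <- state$drivers[1L]
    tg <- igraph::graph_from_data_frame(truth$edges[, 1:2], directed = TRUE,
                                        vertices = truth$genes)
    sig <- setdiff(names(igraph::ego(tg, order = p$signature_hops, nodes = hub,
                                     mode = "out")[[1L]]), hub)
    roc <- if (hub %in% consensus$nodes && length(sig)) {
      signature_roc(consensus, hub, sig, max_radius = p$max_radius,
                    spec_floor = p$spec_floor)
    } else NULL
    outs <- c(path("accuracy_report.tsv"), path("roc_points.tsv"))
    write.table(data.frame(reference = ref$name,
                           observed = nullres$observed,
                           null_mean = nullres$null_mean,
                           null_sd = nullres$null_sd,
                           p = nullres$p,
                           skeleton_precision = metrics$precision,
                           skeleton_recall = metrics$recall),
                outs[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    roc_pts <- if (is.null(roc)) {
      data.frame(one_minus_specificity = numeric(0), sensitivity = numeric(0))
    } else roc$points
    write.table(roc_pts, outs[2L], sep = "\t", quote = FALSE, row.names = FALSE)
    state$accuracy <- nullres; state$skeleton <- metrics; state$roc <- roc
    record("evaluate", p, outs, t0)
  }

  if (isTRUE(cfg$stages$survival)) {
    t0 <- as.numeric(Sys.time()); p <- cfg$survival
    expr <- need("survival", "expr"); surv <- need("survival", "surv")
    warn <- character(0)
    screen <- withCallingHandlers(
      cox_screen(expr, surv, alpha = p$alpha),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    sig <- screen[screen$significant, , drop = FALSE]
    if (nrow(sig) == 0L) {
      warn <- c(warn, "no gene passed the corrected threshold; using top genes by p")
      ord <- screen[order(screen$p), , drop = FALSE]
      sig <- head(ord, p$fallback_top)
    }
    state$screen <- screen
    state$bcr_pos <- sig$gene[sig$direction == "positive"]
    state$bcr_neg <- sig$gene[sig$direction == "negative"]
    outs <- path("cox_screen.tsv")
    write.table(screen, outs, sep = "\t", quote = FALSE, row.names = FALSE)
    record("survival", p, outs, t0, warn)
  }

  if (isTRUE(cfg$stages$subnet)) {
    t0 <- as.numeric(Sys.time()); p <- cfg$subnet
    consensus <- need("subnet", "consensus")
    warn <- character(0)
    proj <- function(seeds) {
      if (length(intersect(seeds, consensus$nodes)) == 0L) return(NULL)
      withCallingHandlers(
        project_seed_subnetwork(consensus, seeds, p$min_component_seeds),
        warning = function(w) {
          warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
        })
    }
    sub_pos <- proj(need("subnet", "bcr_pos"))
    sub_neg <- proj(need("subnet", "bcr_neg"))
    state$sub_pos <- sub_pos; state$sub_neg <- sub_neg
    members <- rbind(
      if (!is.null(sub_pos) && length(sub_pos$members))
        data.frame(gene = sub_pos$members, direction = "positive"),
      if (!is.null(sub_neg) && length(sub_neg$members))
        data.frame(gene = sub_neg$members, direction = "negative"))
    if (is.null(members)) members <- data.frame(gene = character(0),
                                                direction = character(0))
    outs <- path("bcr_subnetworks.tsv")
    write.table(members, outs, sep = "\t", quote = FALSE, row.names = FALSE)
    record("subnet", p, outs, t0, warn)
  }

  if (isTRUE(cfg$stages$drivers)) {
    t0 <- as.numeric(Sys.time()); p <- cfg$drivers
    consensus <- need("drivers", "consensus")
    kr <- call_key_regulators(consensus, hops = p$hops, sd_mult = p$sd_mult)
    dkd <- distinct_key_drivers(consensus, kr)
    state$key_regulators <- kr; state$distinct_drivers <- dkd
    outs <- c(path("key_regulators.tsv"), path("distinct_key_drivers.tsv"))
    write.table(kr, outs[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = dkd), outs[2L], sep = "\t", quote = FALSE,
                row.names = FALSE)
    record("drivers", p, outs, t0)
  }

  if (isTRUE(cfg$stages$mediators)) {
    t0 <- as.numeric(Sys.time()); p <- cfg$mediators
    consensus <- need("mediators", "consensus")
    dkd <- need("mediators", "distinct_drivers")
    warn <- character(0)
    if (length(dkd) == 0L) {
      warn <- "no distinct key drivers; falling back to planted drivers"
      dkd <- intersect(need("mediators", "drivers"), consensus$nodes)
    }
    use <- head(dkd, p$n_drivers_used)
    ranking <- mean_distance_to_drivers(consensus, use, frac = p$frac)
    cdg <- withCallingHandlers(
      common_downstream_genes(ranking, frac = p$frac),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    state$ranking <- ranking; state$common_downstream <- cdg
    rk <- ranking
    rk$mean_distance[!is.finite(rk$mean_distance)] <- NA
    outs <- c(path("mediator_ranking.tsv"), path("common_downstream.tsv"))
    write.table(rk, outs[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = cdg), outs[2L], sep = "\t", quote = FALSE,
                row.names = FALSE)
    record("mediators", p, outs, t0, warn)
  }

  if (isTRUE(cfg$stages$tissue)) {
    t0 <- as.numeric(Sys.time()); p <- cfg$tissue
    truth <- need("tissue", "truth")
    s <- stage_seed(cfg$seed, "tissue")
    # atlas covers the network genes (shared g### names) plus enough filler
    # genes to host every planted tissue-specific gene
    n_atlas <- max(length(truth$genes),
                   2L * p$n_specific_per_tissue * length(p$tissues))
    atlas <- make_tissue_fixture(n_atlas, p$tissues,
                                 p$n_specific_per_tissue, p$fold, seed = s)
    calls <- preferential_tissues(atlas, z_threshold = p$z_threshold)
    goi <- if (!is.null(state$common_downstream)) state$common_downstream else truth$genes
    tally <- tally_by_tissue(calls, goi)
    state$tissue_tally <- tally
    outs <- c(path("tissue_atlas.tsv"), path("tissue_tally.tsv"))
    write_matrix_tsv(atlas, outs[1L])
    write.table(tally, outs[2L], sep = "\t", quote = FALSE, row.names = FALSE)
    record("tissue", p, outs, t0)
  }

  structure(list(stages = manifest, config = cfg,
                 results = as.list(state)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  if (length(x$stages) == 0L) {
    cat("run_manifest: no stages executed\n")
    return(invisible(x))
  }
  cat(sprintf("run_manifest: %d stage(s) in %s\n",
              length(x$stages), x$config$outdir))
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-10s %5.1fs  %d output(s)%s\n", s, st$elapsed,
                length(st$outputs),
                if (length(st$warnings)) sprintf("  [%d warning(s)]", length(st$warnings)) else ""))
  }
  invisible(x)
}
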