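# End-to-end orchestration: from per-group activity tables to the full set
# of per-group and cross-group results as tab-delimited files plus a JSON
# manifest. Every stage draws from a sub-seed derived deterministically
# from the master seed and the stage name, so adding a stage never
# perturbs another stage's randomness and a fixed master seed gives
# byte-identical outputs.

#' Pipeline configuration
#'
#' Defaults follow the standard analysis settings: one-tailed alpha tiers
#' 0.01 / 0.005 / 0.0025 (low / primary / high), Pearson correlations, 1000
#' degree-matched null networks, 1000 bootstrap replicates for network
#' metrics, 500 PLS permutations and bootstraps, MCL inflation 2.6, hub
#' cutoff at the 80th percentile and FDR control at the 5% level.
#'
#' @param tables Named list of [activity_table()] (one per group), or
#'   `NULL` when `table_paths` is given.
#' @param table_paths Named character vector of activity-table files.
#' @param metadata A [region_metadata()] table, or a path to one.
#' @param out_dir Output directory.
#' @param alphas Named numeric vector of one-tailed tier levels.
#' @param method Correlation method.
#' @param ensemble_size Null ensemble size.
#' @param n_boot_network Bootstrap replicates for network metrics.
#' @param n_boot_pls,n_perm_pls PLS bootstrap / permutation sizes.
#' @param n_perm_compare Permutations for matrix comparison.
#' @param inflation MCL inflation.
#' @param hub_percentile Hub cutoff percentile.
#' @param fdr_q FDR level.
#' @param metrics Network metrics to evaluate against null ensembles.
#' @param compare_groups Length-2 character vector of group labels for the
#'   cross-group matrix comparison (default: first two groups).
#' @param pls_groups Character vector of group labels entering task PLS
#'   (default: all groups).
#' @param master_seed Master seed; all stage seeds derive from it.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(tables = NULL, table_paths = NULL,
                            metadata = NULL, out_dir = tempfile("fosnet_"),
                            alphas = c(low = 0.01, primary = 0.005,
                                       high = 0.0025),
                            method = "pearson",
                            ensemble_size = 1000,
                            n_boot_network = 1000,
                            n_boot_pls = 500, n_perm_pls = 500,
                            n_perm_compare = 1000,
                            inflation = 2.6, hub_percentile = 80,
                            fdr_q = 0.05,
                            metrics = c("clustering", "global_efficiency"),
                            compare_groups = NULL, pls_groups = NULL,
                            master_seed = 1L) {
  if (is.null(tables) && is.null(table_paths))
    stop("provide 'tables' or 'table_paths'")
  if (any(alphas <= 0) || any(alphas >= 0.5))
    stop("alpha tiers must be one-tailed levels in (0, 0.5)")
  if (is.null(names(alphas)) || !"primary" %in% names(alphas))
    stop("'alphas' must be named and include a 'primary' tier")
  if (inflation <= 1) stop("'inflation' must be > 1")
  if (fdr_q <= 0 || fdr_q >= 1) stop("'fdr_q' must be in (0, 1)")
  if (hub_percentile <= 0 || hub_percentile >= 100)
    stop("'hub_percentile' must be in (0, 100)")
  structure(
    list(tables = tables, table_paths = table_paths, metadata = metadata,
         out_dir = out_dir, alphas = alphas, method = method,
         ensemble_size = ensemble_size,
         n_boot_network = n_boot_network,
         n_boot_pls = n_boot_pls, n_perm_pls = n_perm_pls,
         n_perm_compare = n_perm_compare,
         inflation = inflation, hub_percentile = hub_percentile,
         fdr_q = fdr_q, metrics = metrics,
         compare_groups = compare_groups, pls_groups = pls_groups,
         master_seed = as.integer(master_seed)),
    class = "pipeline_config")
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full co-activation analysis pipeline
#'
#' Per group: correlation matrix, networks at every tier, metric estimates
#' with null-ensemble intervals, MCL partition (plus composition when
#' metadata is available), hub report across tiers, and targeted/random
#' attack curves. Cross-group: permutation matrix comparison of the first
#' configured pair and task PLS over the configured groups. All
#' quantitative results are written as TSV under `out_dir` together with a
#' JSON manifest of the configuration and stage seeds.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`correlations`,
#'   `networks`, `metrics`, `partitions`, `hubs`, `attacks`, `comparison`,
#'   `pls`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  meta <- config$metadata
  if (is.character(meta)) meta <- read_region_metadata(meta)
  tables <- config$tables
  if (is.null(tables)) {
    tables <- lapply(config$table_paths, read_activity_table,
                     metadata = meta)
    names(tables) <- names(config$table_paths) %||%
      vapply(tables, `[[`, character(1), "group_label")
  }
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, `[[`, character(1), "group_label")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[fosnet] ", sprintf(...))
  ms <- config$master_seed
  res <- list(correlations = list(), networks = list(), metrics = list(),
              partitions = list(), hubs = list(), attacks = list())
  stage_seeds <- list()
  run_stage <- function(stage, fun) {
    log_stage("stage %s", stage)
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  for (gl in names(tables)) {
    tb <- tables[[gl]]
    n <- length(tb$subjects)
    tiers <- lapply(names(config$alphas), function(tier)
      threshold_spec(config$alphas[[tier]], n,
                     if (tier %in% c("low", "primary", "high")) tier
                     else "primary"))
    names(tiers) <- names(config$alphas)
    corr <- run_stage(paste0("correlate:", gl), function()
      pairwise_correlations(tb, config$method))
    res$correlations[[gl]] <- corr
    write_correlation_matrix(corr, file.path(
      config$out_dir, sprintf("corr_%s.tsv", gl)))
    nets <- run_stage(paste0("network:", gl), function()
      lapply(tiers, function(th) build_network(corr, th)))
    res$networks[[gl]] <- nets
    for (tier in names(nets))
      export_network(nets[[tier]],
                     file.path(config$out_dir,
                               sprintf("net_%s_%s.graphml", gl, tier)),
                     format = "graphml", metadata = meta)
    prim <- nets[["primary"]]
    res$metrics[[gl]] <- run_stage(paste0("metrics:", gl), function() {
      out <- lapply(config$metrics, function(metric) {
        sseed <- stage_seed(ms, paste0("null:", gl, ":", metric))
        stage_seeds[[paste0("null:", gl, ":", metric)]] <<- sseed
        nd <- null_distribution(prim, metric,
                                ensemble_size = config$ensemble_size,
                                seed = sseed)
        bseed <- stage_seed(ms, paste0("boot:", gl, ":", metric))
        stage_seeds[[paste0("boot:", gl, ":", metric)]] <<- bseed
        be <- bootstrap_network_metric(tb, tiers[["primary"]], metric,
                                       n_boot = config$n_boot_network,
                                       seed = bseed,
                                       method = config$method)
        data.frame(metric = metric, observed = be$value,
                   boot_lo = be$ci95[1L], boot_hi = be$ci95[2L],
                   null_mean = nd$ensemble_mean,
                   null_lo = nd$interval95[1L],
                   null_hi = nd$interval95[2L])
      })
      df <- do.call(rbind, out)
      .write_tsv(df, config$out_dir, sprintf("metrics_%s.tsv", gl))
      df
    })
    res$partitions[[gl]] <- run_stage(paste0("cluster:", gl), function() {
      part <- mcl_cluster(prim, inflation = config$inflation)
      .write_tsv(data.frame(region = names(part$assignment),
                            cluster = unname(part$assignment)),
                 config$out_dir, sprintf("clusters_%s.tsv", gl))
      if (!is.null(meta))
        .write_tsv(cluster_composition(part, meta), config$out_dir,
                   sprintf("cluster_composition_%s.tsv", gl))
      part
    })
    res$hubs[[gl]] <- run_stage(paste0("hubs:", gl), function() {
      hr <- identify_hubs(nets, cutoff_percentile = config$hub_percentile)
      .write_tsv(data.frame(hub = hr$hub_set %||% character(0)),
                 config$out_dir, sprintf("hubs_%s.tsv", gl))
      hr
    })
    res$attacks[[gl]] <- run_stage(paste0("attack:", gl), function() {
      aseed <- stage_seed(ms, paste0("attack:", gl))
      stage_seeds[[paste0("attack:", gl)]] <<- aseed
      targ <- attack_simulation(prim, "targeted")
      rand <- attack_simulation(prim, "random", n_reps = 100,
                                seed = aseed)
      .write_tsv(cbind(mode = "targeted", targ$points), config$out_dir,
                 sprintf("attack_targeted_%s.tsv", gl))
      .write_tsv(cbind(mode = "random", rand$points), config$out_dir,
                 sprintf("attack_random_%s.tsv", gl))
      list(targeted = targ, random = rand)
    })
  }
  cg <- config$compare_groups %||% names(tables)[1:2]
  res$comparison <- if (length(tables) >= 2L)
    run_stage("compare", function() {
      cseed <- stage_seed(ms, "compare")
      stage_seeds[["compare"]] <<- cseed
      cmp <- compare_matrices_permutation(
        tables[[cg[1L]]], tables[[cg[2L]]],
        n_perm = config$n_perm_compare, fdr_q = config$fdr_q,
        seed = cseed, method = config$method)
      .write_tsv(cmp$pairs, config$out_dir, "matrix_comparison.tsv")
      cmp
    })
  pg <- config$pls_groups %||% names(tables)
  res$pls <- if (length(pg) >= 2L)
    run_stage("pls", function() {
      pls_tabs <- tables[pg]
      fit <- task_pls(pls_tabs)
      pseed <- stage_seed(ms, "pls_perm")
      bseed <- stage_seed(ms, "pls_boot")
      stage_seeds[["pls_perm"]] <<- pseed
      stage_seeds[["pls_boot"]] <<- bseed
      pvals <- permutation_test_lvs(pls_tabs, n_perm = config$n_perm_pls,
                                    seed = pseed)
      bsr <- bootstrap_salience_ratios(pls_tabs,
                                       n_boot = config$n_boot_pls,
                                       seed = bseed)
      .write_tsv(data.frame(lv = seq_along(fit$singular_values),
                            singular_value = fit$singular_values,
                            perm_p = pvals),
                 config$out_dir, "pls_lvs.tsv")
      .write_tsv(data.frame(region = fit$regions,
                            salience_lv1 = fit$region_saliences[, 1L],
                            bsr_lv1 = bsr$bsr[, 1L],
                            reliable_lv1 = bsr$reliable[, 1L]),
                 config$out_dir, "pls_saliences.tsv")
      list(fit = fit, perm_p = pvals, bsr = bsr)
    })
  manifest <- list(
    package = "fosnet",
    version = as.character(utils::packageVersion("fosnet")),
    master_seed = ms,
    stage_seeds = stage_seeds,
    groups = names(tables),
    alphas = as.list(config$alphas),
    method = config$method,
    settings = list(ensemble_size = config$ensemble_size,
                    n_boot_network = config$n_boot_network,
                    n_boot_pls = config$n_boot_pls,
                    n_perm_pls = config$n_perm_pls,
                    n_perm_compare = config$n_perm_compare,
                    inflation = config$inflation,
                    hub_percentile = config$hub_percentile,
                    fdr_q = config$fdr_q))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  log_stage("done; outputs in %s", config$out_dir)
  invisible(res)
}
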