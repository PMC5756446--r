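#' Define a scenario grid for the full experiment
#'
#' The study grid crosses QTL-effect distributions with FST-selection
#' quantiles for the proposed method and prior-exclusion probabilities for
#' BayesB/BayesC, evaluated on shared simulated data within each replicate
#' so method comparisons are paired.
#'
#' @param effect_dists subset of `c("gamma", "predefined")`.
#' @param quantiles FST quantiles for the proposed method.
#' @param models methods to run; `"all_snp"` is the no-filtering reference
#'   (the preselection model fitted to every marker).
#' @param pi_zero_grid prior exclusion probabilities for BayesB/BayesC.
#' @param n_replicates independent simulation replicates per scenario.
#' @param n_train,n_valid animals sampled from genotyped G3 / G4.
#' @param tail_fraction phenotype-tail fraction per side for the FST scan.
#' @param chain_length,burn_in,thin Gibbs chain settings for every fit.
#' @param master_seed seed from which every replicate seed derives.
#' @return list of class `scenario_grid`.
#' @export
scenario_grid <- function(effect_dists = c("gamma", "predefined"),
                          quantiles = c(0.975, 0.99, 0.995),
                          models = c("all_snp", "fst_preselect", "bayesB",
                                     "bayesC"),
                          pi_zero_grid = c(0.90, 0.95, 0.98, 0.99),
                          n_replicates = 5, n_train = 10000, n_valid = 5000,
                          tail_fraction = 0.05,
                          chain_length = 11000, burn_in = 1000, thin = 10,
                          master_seed = 1) {
  effect_dists <- match.arg(effect_dists, several.ok = TRUE)
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(n_replicates >= 1, length(quantiles) >= 1 || !("fst_preselect" %in% models),
            all(quantiles > 0 & quantiles < 1),
            all(pi_zero_grid > 0 & pi_zero_grid < 1))
  structure(list(effect_dists = effect_dists, quantiles = quantiles,
                 models = models, pi_zero_grid = pi_zero_grid,
                 n_replicates = as.integer(n_replicates),
                 n_train = as.integer(n_train),
                 n_valid = as.integer(n_valid),
                 tail_fraction = tail_fraction,
                 chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 master_seed = as.integer(master_seed)),
            class = "scenario_grid")
}

# fit one method on prepared training/validation data and evaluate it
evaluate_method <- function(label, design_ids, spec, train_geno, train_phen,
                            valid_geno, valid_tbv, valid_phen,
                            qtl_train, qtl_effects, selected_ids) {
  fit <- gwr_fit(train_geno[, design_ids, drop = FALSE], train_phen, spec)
  gebv <- predict_gebv(fit, valid_geno)
  if (is.null(selected_ids)) {
    n_model <- max(1L, round((1 - spec$pi_zero) * length(design_ids)))
    selected_ids <- names(sort(fit$include_prob, decreasing = TRUE))[seq_len(n_model)]
  }
  tg <- tag_qtl(qtl_train, train_geno[, selected_ids, drop = FALSE],
                qtl_effects)
  data.frame(
    model = label, n_selected = length(selected_ids),
    n_tagged_qtl = tg$n_tagged, gv_explained_pct = tg$gv_explained_pct,
    acc_g = genomic_accuracy(valid_tbv, gebv),
    acc_p = phenotype_accuracy(gebv, valid_phen, fit$mu_hat),
    stringsAsFactors = FALSE)
}

#' Run the full simulate-score-select-fit-evaluate experiment
#'
#' For every effect distribution and replicate: simulate a fresh population
#' (child seed), scan the genotyped G3 animals' phenotype tails for FST,
#' select SNPs at each quantile, fit each requested model on the training
#' sample, predict GEBVs for the validation sample (G4), and evaluate
#' accuracy and QTL tagging. All methods within a replicate share the same
#' simulated data. A failing scenario cell is recorded and the grid
#' continues.
#'
#' @param grid a [scenario_grid()].
#' @param config a [sim_config()]; its effect distribution and seed are
#'   overridden per cell.
#' @return list of class `experiment_result`: `results` (one row per method
#'   x replicate), `summary` (means and SEs via [aggregate_accuracy()]),
#'   `comparison` (percentage accuracy differences of BayesB/BayesC at
#'   their best settings relative to the proposed method at its best
#'   quantile), and `errors`.
#' @export
run_experiment <- function(grid, config) {
  stopifnot(inherits(grid, "scenario_grid"), inherits(config, "sim_config"))
  rep_seeds <- matrix(derive_seeds(grid$master_seed,
                                   paste0("cell", seq_len(grid$n_replicates *
                                                            length(grid$effect_dists)))),
                      nrow = grid$n_replicates)
  rows <- list()
  errors <- list()
  for (d in seq_along(grid$effect_dists)) {
    dist <- grid$effect_dists[d]
    for (r in seq_len(grid$n_replicates)) {
      res <- tryCatch(
        run_experiment_cell(grid, config, dist, rep_seeds[r, d]),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <-
          list(effect_dist = dist, replicate = r,
               message = conditionMessage(res))
        next
      }
      res$effect_dist <- dist
      res$replicate <- r
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame()
  out <- list(results = results,
              summary = if (nrow(results) > 0L)
                aggregate_accuracy(results[, setdiff(names(results), "seed")])
              else NULL,
              comparison = if (nrow(results) > 0L)
                comparison_table(results) else NULL,
              errors = errors, grid = grid)
  class(out) <- "experiment_result"
  out
}

run_experiment_cell <- function(grid, config, dist, seed) {
  cfg <- config
  cfg$qtl_effect_dist <- dist
  cfg$seed <- as.integer(seed)
  sim <- run_simulation(cfg)
  ped <- sim$pop$pedigree
  set.seed(seed)

  g3 <- ped$id[ped$generation == 3L & ped$genotyped]
  g4 <- ped$id[ped$generation == 4L & ped$genotyped]
  if (length(g3) < grid$n_train || length(g4) < grid$n_valid)
    stop("genotyped generations smaller than requested training/validation sets")
  train_ids <- sort(sample(g3, grid$n_train))
  valid_ids <- sort(sample(g4, grid$n_valid))

  g3_geno <- dosages(sim$pop, g3, "markers")
  scan_qs <- sort(unique(grid$quantiles), decreasing = TRUE)
  group_size <- 2L * round(grid$tail_fraction * length(g3))
  scans <- lapply(scan_qs, function(q)
    fst_scan(g3_geno, sim$trait$phenotype[g3], quantile = q,
             group_size = group_size))
  names(scans) <- sprintf("%.4g", scan_qs)

  train_geno <- g3_geno[as.character(train_ids), , drop = FALSE]
  rm(g3_geno)
  valid_geno <- dosages(sim$pop, valid_ids, "markers")
  qtl_train <- dosages(sim$pop, train_ids, "qtl")
  train_phen <- sim$trait$phenotype[train_ids]
  valid_tbv <- sim$trait$tbv[valid_ids]
  valid_phen <- sim$trait$phenotype[valid_ids]
  marker_ids <- colnames(train_geno)

  base_spec <- function(model, pi_zero = 0)
    gwr_spec(model, pi_zero = pi_zero,
             prior_scale_g = cfg$sigma2_g, prior_scale_e = sim$trait$sigma2_e,
             chain_length = grid$chain_length, burn_in = grid$burn_in,
             thin = grid$thin, seed = seed + 1L)

  out <- list()
  eval1 <- function(label, design_ids, spec, selected_ids = NULL) {
    row <- evaluate_method(label, design_ids, spec, train_geno, train_phen,
                           valid_geno, valid_tbv, valid_phen, qtl_train,
                           sim$trait$qtl_effects, selected_ids)
    out[[length(out) + 1L]] <<- row
  }
  if ("all_snp" %in% grid$models)
    eval1("all_snp", marker_ids, base_spec("fst_preselect"), marker_ids)
  if ("fst_preselect" %in% grid$models)
    for (q in names(scans)) {
      sel <- scans[[q]]$selected_ids
      eval1(paste0("fst_preselect@", q), sel, base_spec("fst_preselect"),
            sel)
    }
  for (model in intersect(c("bayesB", "bayesC"), grid$models))
    for (pi0 in grid$pi_zero_grid)
      eval1(paste0(model, "@pi", pi0), marker_ids, base_spec(model, pi0))
  res <- do.call(rbind, out)
  res$seed <- seed
  res
}

# Percentage accuracy differences (best setting per method) relative to the
# proposed preselection method; negative = worse than proposed.
comparison_table <- function(results) {
  method_of <- sub("@.*$", "", results$model)
  out <- list()
  for (dist in unique(results$effect_dist)) {
    rd <- results[results$effect_dist == dist, ]
    md <- method_of[results$effect_dist == dist]
    best <- function(m, col) {
      rows <- rd[md == m, ]
      if (nrow(rows) == 0L) return(NA_real_)
      by_model <- tapply(rows[[col]], rows$model, mean)
      max(by_model)
    }
    prop_g <- best("fst_preselect", "acc_g")
    prop_p <- best("fst_preselect", "acc_p")
    for (m in intersect(c("bayesB", "bayesC"), unique(md))) {
      out[[length(out) + 1L]] <- data.frame(
        effect_dist = dist, method = m,
        diff_acc_g_pct = 100 * (best(m, "acc_g") - prop_g) / prop_g,
        diff_acc_p_pct = 100 * (best(m, "acc_p") - prop_p) / prop_p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Write experiment tables as TSV
#'
#' Emits `results.tsv` (one row per method x replicate), `summary.tsv`
#' (means and standard errors) and `comparison.tsv` (percentage accuracy
#' differences relative to the proposed method) under `dir`.
#'
#' @param x an `experiment_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "experiment_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(x$results, file.path(dir, "results.tsv"), sep = "\t")
  if (!is.null(x$summary))
    data.table::fwrite(x$summary, file.path(dir, "summary.tsv"), sep = "\t")
  if (!is.null(x$comparison))
    data.table::fwrite(x$comparison, file.path(dir, "comparison.tsv"),
                       sep = "\t")
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d rows (%d failed cells)\n",
              nrow(x$results), length(x$errors)))
  if (!is.null(x$summary)) {
    cols <- intersect(c("effect_dist", "model", "n_selected", "n_tagged_qtl",
                        "gv_explained_pct", "acc_g", "acc_g_se", "acc_p"),
                      names(x$summary))
    print(x$summary[, cols], digits = 3)
  }
  invisible(x)
}
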