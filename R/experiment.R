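#' Build a factorial scenario grid
#'
#' Crosses strategy, genetic-effects model, family-mean heritability and
#' parental population size into a deterministic, fully ordered grid. The
#' case-study factors (2 strategies x 3 models x 3 heritabilities x 3
#' sizes) give 54 scenarios.
#'
#' Per-scenario, per-run seeds are derived from the base seed with a
#' counter-based scheme keyed on the genotype-environment configuration
#' (model x heritability x size) and the run index -- deliberately *not* on
#' the strategy -- so the two strategies of a configuration run under
#' common random numbers (same map, same QTL effect draw, same founders),
#' which sharpens paired AHS/AWHS comparisons.
#'
#' @param strategies,models,heritabilities,sizes Non-empty factor levels.
#' @param runs Replicate runs per scenario.
#' @param base_seed Integer base seed.
#' @return A `scenario_grid`: a data frame with one row per scenario
#'   (`scenario`, `strategy`, `model`, `h2`, `n_parents`, `ges_config`)
#'   and attributes `runs` and `base_seed`.
#' @examples
#' g <- build_scenario_grid()
#' nrow(g)   # 54
#' @export
build_scenario_grid <- function(strategies = c("AHS", "AWHS"),
                                models = c("additive", "additive_dominance",
                                           "dominance"),
                                heritabilities = c(0.1, 0.5, 0.9),
                                sizes = c(10, 50, 100),
                                runs = 100L,
                                base_seed = 1L) {
  if (!length(strategies) || !length(models) || !length(heritabilities) ||
      !length(sizes))
    stop("every factor needs at least one level")
  grid <- expand.grid(strategy = strategies, model = models,
                      h2 = heritabilities, n_parents = sizes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cfg <- expand.grid(model = models, h2 = heritabilities, n_parents = sizes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cfg$ges_config <- seq_len(nrow(cfg))
  grid <- merge(grid, cfg, by = c("model", "h2", "n_parents"), sort = FALSE)
  grid <- grid[order(grid$ges_config, grid$strategy), ]
  grid$scenario <- seq_len(nrow(grid))
  grid <- grid[, c("scenario", "strategy", "model", "h2", "n_parents",
                   "ges_config")]
  rownames(grid) <- NULL
  attr(grid, "runs") <- as.integer(runs)
  attr(grid, "base_seed") <- as.integer(base_seed)
  class(grid) <- c("scenario_grid", "data.frame")
  grid
}

# Counter-based seed: reproducible, order-insensitive, < 2^31.
derive_seed <- function(base_seed, ges_config, run) {
  as.integer((as.numeric(base_seed) * 1000003 + ges_config * 20011 +
                run * 101 + 7) %% 2147483629) + 1L
}

#' Run a scenario grid
#'
#' Executes every scenario of the grid for the requested number of
#' replicate runs. For each run the QTL effects and the founder population
#' are drawn afresh under the run's derived seed; the synthetic linkage map
#' is either fixed per genotype-environment configuration (default, lower
#' between-run variance) or redrawn per run.
#'
#' @param grid A `scenario_grid`.
#' @param design A `trial_design` shared by all scenarios.
#' @param runs Override of the grid's run count (e.g. for a scaled-down
#'   rehearsal of a large grid).
#' @param map_args Arguments passed to [build_synthetic_map()].
#' @param map_mode `"fixed"` (one map per genotype-environment
#'   configuration) or `"per_run"`.
#' @param out_dir Optional directory; when given, per-scenario
#'   `fit/ham/fre` files and a `summary.tsv` are written there.
#' @param verbose Print per-scenario progress to stderr.
#' @return An `hs_experiment` list: `summary` (one row per scenario with
#'   replicate means and standard errors), `runs` (per-scenario list of
#'   run summaries), `design`, `grid`.
#' @export
run_experiment <- function(grid, design, runs = NULL,
                           map_args = list(),
                           map_mode = c("fixed", "per_run"),
                           out_dir = NULL, verbose = FALSE) {
  map_mode <- match.arg(map_mode)
  stopifnot(inherits(grid, "scenario_grid"))
  runs <- as.integer(runs %||% attr(grid, "runs"))
  base_seed <- attr(grid, "base_seed")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  summary_rows <- vector("list", nrow(grid))
  run_store <- vector("list", nrow(grid))
  for (s in seq_len(nrow(grid))) {
    sc <- grid[s, ]
    if (verbose)
      message(sprintf("scenario %d/%d: %s %s h2=%g N=%d", sc$scenario,
                      nrow(grid), sc$strategy, sc$model, sc$h2, sc$n_parents))
    cfg <- strategy_config(sc$strategy, n_parents = sc$n_parents)
    if (map_mode == "fixed") {
      set.seed(derive_seed(base_seed, sc$ges_config, 0L))
      fixed_map <- do.call(build_synthetic_map, map_args)
    }
    run_res <- vector("list", runs)
    failures <- 0L
    for (r in seq_len(runs)) {
      set.seed(derive_seed(base_seed, sc$ges_config, r))
      map <- if (map_mode == "fixed") fixed_map else
        do.call(build_synthetic_map, map_args)
      eff <- sample_qtl_effects(sc$model, sum(map$kind == "qtl"),
                                qtl_ids = map$id[map$kind == "qtl"])
      ges <- genetic_system(map, eff, model = sc$model)
      res <- tryCatch(run_strategy(cfg, ges, design, target_h2_fm = sc$h2),
                      error = function(e) {
                        warning(sprintf("scenario %d run %d failed: %s",
                                        sc$scenario, r, conditionMessage(e)))
                        NULL
                      })
      if (is.null(res)) { failures <- failures + 1L; next }
      last <- nrow(res$stats)
      run_res[[r]] <- list(
        run = r,
        stats = res$stats,
        dg90_value = res$summary$value,
        dg90_cycle = res$summary$cycle,
        dg90_per_cycle = res$summary$per_cycle,
        total_gain_pct = sum(res$stats$delta_g_pct),
        final_hamming = res$stats$hamming_pct[last],
        final_fixed_favorable = res$stats$fixed_favorable_pct[last],
        final_fixed_nonfavorable = res$stats$fixed_nonfavorable_pct[last])
    }
    run_res <- Filter(Negate(is.null), run_res)
    run_store[[s]] <- run_res
    num <- function(field) vapply(run_res, `[[`, numeric(1), field)
    se <- function(x) stats::sd(x) / sqrt(length(x))
    summary_rows[[s]] <- data.frame(
      scenario = sc$scenario, strategy = sc$strategy, model = sc$model,
      h2 = sc$h2, n_parents = sc$n_parents, ges_config = sc$ges_config,
      runs = length(run_res), failed = failures,
      mean_dg90_cycle = mean(num("dg90_cycle")),
      se_dg90_cycle = se(num("dg90_cycle")),
      mean_dg90 = mean(num("dg90_value")),
      se_dg90 = se(num("dg90_value")),
      mean_dg90_per_cycle = mean(num("dg90_per_cycle")),
      mean_total_gain_pct = mean(num("total_gain_pct")),
      mean_final_hamming = mean(num("final_hamming")),
      mean_final_fixed_favorable = mean(num("final_fixed_favorable")),
      mean_final_fixed_nonfavorable = mean(num("final_fixed_nonfavorable")))
    if (!is.null(out_dir)) {
      sdir <- file.path(out_dir, sprintf("scenario_%03d", sc$scenario))
      write_outputs(lapply(run_res, function(x) {
        structure(list(stats = x$stats), class = "hs_run")
      }), sdir)
    }
  }
  summary <- do.call(rbind, summary_rows)
  if (!is.null(out_dir))
    write_tsv_full(summary, file.path(out_dir, "summary.tsv"))
  structure(list(summary = summary, runs = run_store, design = design,
                 grid = grid),
            class = "hs_experiment")
}

#' Recompute an experiment summary from raw output files
#'
#' Reads the per-scenario `fit/ham/fre` files written by
#' [run_experiment()] and recomputes the per-scenario aggregates, as an
#' audit of `summary.tsv`.
#'
#' @param out_dir The experiment output directory.
#' @return A data frame with one row per scenario directory.
#' @export
summarize_output_dir <- function(out_dir) {
  dirs <- sort(list.dirs(out_dir, recursive = FALSE))
  dirs <- dirs[grepl("scenario_\\d+$", dirs)]
  if (!length(dirs)) stop("no scenario_* directories under ", out_dir)
  rows <- lapply(dirs, function(d) {
    fit <- utils::read.delim(file.path(d, "fit.tsv"))
    ham <- utils::read.delim(file.path(d, "ham.tsv"))
    fre <- utils::read.delim(file.path(d, "fre.tsv"))
    per_run <- lapply(split(fit, fit$run), function(f) {
      dg <- delta_g90(f$mean_g)
      c(cycle = dg$cycle,
        total_gain_pct = sum(f$delta_g_pct))
    })
    last_ham <- vapply(split(ham, ham$run),
                       function(h) h$hamming_pct[nrow(h)], numeric(1))
    last_fav <- vapply(split(fre, fre$run),
                       function(h) h$favorable_pct[nrow(h)], numeric(1))
    data.frame(scenario = basename(d),
               runs = length(per_run),
               mean_dg90_cycle = mean(vapply(per_run, `[[`, numeric(1),
                                             "cycle")),
               mean_total_gain_pct = mean(vapply(per_run, `[[`, numeric(1),
                                                 "total_gain_pct")),
               mean_final_hamming = mean(last_ham),
               mean_final_fixed_favorable = mean(last_fav))
  })
  do.call(rbind, rows)
}

#' Read a full simulation configuration file
#'
#' A YAML (or JSON) file with up to three blocks: `strategy` (keys of
#' [strategy_config()] plus `target_h2_fm`), `design` (keys of
#' [trial_design()]) and `grid` (keys of [build_scenario_grid()]). Unknown
#' blocks or keys are errors; missing blocks fall back to defaults.
#'
#' @param path Configuration file path.
#' @return A list with elements `strategy`, `design`, `grid`.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), c("strategy", "design", "grid"))
  if (length(unknown))
    stop("unknown configuration blocks: ", paste(unknown, collapse = ", "))
  check <- function(block, fn_args, what) {
    bad <- setdiff(names(block), fn_args)
    if (length(bad))
      stop(sprintf("unknown %s keys: %s", what, paste(bad, collapse = ", ")))
    block
  }
  strat <- NULL
  if (!is.null(vals$strategy)) {
    block <- check(vals$strategy,
                   c(names(formals(strategy_config)), "target_h2_fm"),
                   "strategy")
    h2 <- block$target_h2_fm
    block$target_h2_fm <- NULL
    strat <- do.call(strategy_config, block)
    attr(strat, "target_h2_fm") <- h2
  }
  design <- do.call(trial_design,
                    check(vals$design %||% list(),
                          names(formals(trial_design)), "design"))
  grid <- do.call(build_scenario_grid,
                  check(vals$grid %||% list(),
                        names(formals(build_scenario_grid)), "grid"))
  list(strategy = strat, design = design, grid = grid)
}
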