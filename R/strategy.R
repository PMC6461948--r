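#' Configuration of a half-sib recurrent-selection strategy
#'
#' The two supported strategies differ only in the within-family step:
#' \describe{
#'   \item{AHS}{among half-sib family selection; a *random* set of plants
#'     is taken from each advanced family.}
#'   \item{AWHS}{among and within half-sib family selection; the *best*
#'     plants by individual phenotype are taken from each advanced family.}
#' }
#'
#' @param kind `"AHS"` or `"AWHS"`.
#' @param n_parents Initial parental population size (also the number of
#'   half-sib families per cycle, since every parent is female once).
#' @param family_selection_proportion Proportion of families advanced each
#'   cycle (default 0.2).
#' @param within_family_count Plants kept per advanced family (default 5).
#' @param within_family_mode `"random"` or `"best_phenotype"`; defaults to
#'   the mode implied by `kind`, and conflicting combinations are rejected.
#' @param cycles Number of selection cycles (default 50).
#' @param crossing_block_replace_proportion Proportion of the crossing
#'   block replaced by the newly selected parents (default 1, full
#'   replacement).
#' @param progeny_test_update Flag for updating the crossing block from
#'   progeny-test results. Among-family selection on family phenotypic
#'   means already constitutes a progeny test of the female parents, so
#'   this flag adds no further behavior in the default pipeline.
#' @return A `strategy_config` list.
#' @export
strategy_config <- function(kind,
                            n_parents = 10L,
                            family_selection_proportion = 0.2,
                            within_family_count = 5L,
                            within_family_mode = NULL,
                            cycles = 50L,
                            crossing_block_replace_proportion = 1,
                            progeny_test_update = FALSE) {
  kind <- match.arg(kind, c("AHS", "AWHS"))
  default_mode <- if (kind == "AHS") "random" else "best_phenotype"
  within_family_mode <- within_family_mode %||% default_mode
  within_family_mode <- match.arg(within_family_mode,
                                  c("random", "best_phenotype"))
  if (within_family_mode != default_mode)
    stop(sprintf("%s requires within_family_mode = \"%s\"", kind, default_mode))
  if (family_selection_proportion <= 0 || family_selection_proportion > 1)
    stop("family_selection_proportion must lie in (0, 1]")
  if (crossing_block_replace_proportion <= 0 ||
      crossing_block_replace_proportion > 1)
    stop("crossing_block_replace_proportion must lie in (0, 1]")
  if (within_family_count < 1) stop("within_family_count must be >= 1")
  if (n_parents < 2) stop("n_parents must be >= 2 (selfing is excluded)")
  if (cycles < 1) stop("cycles must be >= 1")
  structure(list(kind = kind, n_parents = as.integer(n_parents),
                 family_selection_proportion = family_selection_proportion,
                 within_family_count = as.integer(within_family_count),
                 within_family_mode = within_family_mode,
                 cycles = as.integer(cycles),
                 crossing_block_replace_proportion =
                   crossing_block_replace_proportion,
                 progeny_test_update = isTRUE(progeny_test_update)),
            class = "strategy_config")
}

#' Select the best families by phenotypic mean
#'
#' Advances the top `round(k * proportion)` families (round half up,
#' minimum 1) by family phenotypic mean, in descending order; ties are
#' broken in favor of the lower family index.
#'
#' @param family_means Numeric vector of family phenotypic means, indexed
#'   by family.
#' @param proportion Selected proportion in (0, 1].
#' @return Integer indices of the selected families.
#' @export
select_among_families <- function(family_means, proportion) {
  k <- length(family_means)
  if (k < 1) stop("no families to select from")
  if (proportion <= 0 || proportion > 1)
    stop("proportion must lie in (0, 1]")
  n_sel <- max(1L, round_half_up(k * proportion))
  ord <- order(-family_means, seq_len(k))
  ord[seq_len(min(n_sel, k))]
}

#' Select plants within a half-sib family
#'
#' In `random` mode (AHS) `k` distinct plants are drawn uniformly; in
#' `best_phenotype` mode (AWHS) the `k` plants with the highest individual
#' phenotypic values are taken (ties broken by plant id). If `k` is at
#' least the family size the whole family is returned.
#'
#' @param family A `halfsib_family`.
#' @param phenotypes Individual phenotypic values aligned with the family
#'   members (required for `best_phenotype` mode).
#' @param k Number of plants to keep.
#' @param mode `"random"` or `"best_phenotype"`.
#' @return A `population` with the selected members.
#' @export
select_within_family <- function(family, phenotypes, k,
                                 mode = c("random", "best_phenotype")) {
  mode <- match.arg(mode)
  members <- family$members
  n <- pop_size(members)
  if (n < 1) stop("family is empty")
  if (k >= n) return(members)
  sel <- if (mode == "random") {
    sample.int(n, k)
  } else {
    if (length(phenotypes) != n)
      stop("phenotypes must align with the family members")
    order(-phenotypes, members$id)[seq_len(k)]
  }
  subset_population(members, sel)
}

#' Update the crossing block with newly selected parents
#'
#' Replaces `round(size * replace_proportion)` (round half up, minimum 1)
#' randomly chosen members of the old block with new parents; a proportion
#' of 1 replaces the whole block. The block size is preserved.
#'
#' @param old_block The current crossing block (`population`).
#' @param new_parents A `population` of candidate replacements.
#' @param replace_proportion Proportion in (0, 1].
#' @return The updated crossing block (`population`).
#' @export
update_crossing_block <- function(old_block, new_parents,
                                  replace_proportion = 1) {
  if (replace_proportion <= 0 || replace_proportion > 1)
    stop("replace_proportion must lie in (0, 1]")
  size <- pop_size(old_block)
  n_rep <- max(1L, round_half_up(size * replace_proportion))
  n_new <- pop_size(new_parents)
  if (n_rep > n_new)
    stop(sprintf("need %d replacement parents but only %d are available",
                 n_rep, n_new))
  if (n_rep == size) {
    incoming <- if (n_new == size) seq_len(n_new) else sample.int(n_new, size)
    return(subset_population(new_parents, incoming))
  }
  out <- sample.int(size, n_rep)
  keep <- subset_population(old_block, setdiff(seq_len(size), out))
  incoming <- subset_population(new_parents, sample.int(n_new, n_rep))
  concat_populations(list(keep, incoming), cycle = new_parents$cycle)
}

# Per-cycle statistics. The genotypic mean is taken over every individual
# of the populations the new crossing block was selected from (all progeny
# of the advanced families -- never a sampled representative); diversity
# statistics (Hamming, fixation) describe the crossing block itself. At
# cycle 0 the initial parents serve both roles.
cycle_stats <- function(cycle, block, ges, mean_g = NULL) {
  fx <- fixation_rates(block, ges)
  data.frame(cycle = cycle,
             mean_g = mean_g %||% population_genotypic_mean(block, ges),
             hamming_pct = hamming_distance(block, ges),
             fixed_favorable_pct = fx[["favorable"]],
             fixed_nonfavorable_pct = fx[["nonfavorable"]])
}

#' Run one cycle of half-sib recurrent selection
#'
#' One full cycle: the crossing block is polycrossed into half-sib
#' families, the families are phenotyped in the trial, the best families
#' are advanced, plants are selected within each advanced family (random
#' for AHS, best-phenotype for AWHS), and the selected plants replace the
#' crossing block. Per-cycle statistics are computed on the updated block.
#'
#' @param state A `breeding_state` list (`cycle`, `block`, `stats`,
#'   `next_id`) as produced by [run_strategy()] internals.
#' @param ges A `genetic_system`.
#' @param design A `trial_design`.
#' @param error_model A list with `sigma2_R` (see
#'   [calibrate_error_variance()]).
#' @param config A `strategy_config`.
#' @param families Optional pre-built half-sib families for this cycle
#'   (used for the cycle whose families also served the heritability
#'   calibration); generated from the block when `NULL`.
#' @return The updated state.
#' @export
run_cycle <- function(state, ges, design, error_model, config,
                      families = NULL) {
  n <- design$n_total
  if (is.null(families)) {
    # bulk fast path: family objects are materialized only when selected
    k <- pop_size(state$block)
    fem_idx <- rep(seq_len(k), each = n)
    bulk <- polycross_progeny(state$block, fem_idx, ges,
                              ids = state$next_id + seq_along(fem_idx) - 1L)
    female_ids <- state$block$id
    get_family <- function(f) {
      rows <- ((f - 1L) * n + 1L):(f * n)
      structure(list(female_parent_id = female_ids[f],
                     members = subset_population(bulk, rows)),
                class = "halfsib_family")
    }
  } else if (inherits(families, "halfsib_bulk")) {
    if (families$n != n)
      stop(sprintf("every family must supply exactly n_total = %d plants", n))
    k <- families$k
    bulk <- families$bulk
    female_ids <- families$female_ids
    get_family <- function(f) {
      rows <- ((f - 1L) * n + 1L):(f * n)
      structure(list(female_parent_id = female_ids[f],
                     members = subset_population(bulk, rows)),
                class = "halfsib_family")
    }
  } else {
    k <- length(families)
    sizes <- vapply(families, function(f) pop_size(f$members), integer(1))
    if (any(sizes != n))
      stop(sprintf("every family must supply exactly n_total = %d plants", n))
    bulk <- attr(families, "bulk")
    if (is.null(bulk) || pop_size(bulk) != k * n)
      bulk <- concat_populations(lapply(families, `[[`, "members"))
    get_family <- function(f) families[[f]]
  }
  core <- trial_core(genotypic_value(bulk, ges), k, n, error_model$sigma2_R)
  sel <- select_among_families(core$family_means,
                               config$family_selection_proportion)
  new_parents <- concat_populations(lapply(sel, function(f) {
    rows <- ((f - 1L) * n + 1L):(f * n)
    select_within_family(get_family(f), core$phenotype[rows],
                         config$within_family_count,
                         config$within_family_mode)
  }))
  block <- update_crossing_block(state$block, new_parents,
                                 config$crossing_block_replace_proportion)
  block$cycle <- state$cycle + 1L
  sel_rows <- as.vector(vapply(sel, function(f) ((f - 1L) * n + 1L):(f * n),
                               integer(n)))
  list(cycle = state$cycle + 1L,
       block = block,
       stats = rbind(state$stats,
                     cycle_stats(state$cycle + 1L, block, ges,
                                 mean_g = mean(core$g[sel_rows]))),
       next_id = max(bulk$id) + 1L)
}

#' Run a full recurrent-selection strategy
#'
#' Founds an initial parental population, builds the initial half-sib
#' families, calibrates the trial residual variance so the family-mean
#' heritability matches the target (once, at cycle 0; the realized
#' heritability then erodes as genetic variance is exhausted, unless
#' `recalibrate_each_cycle` is set), and runs `config$cycles` selection
#' cycles. Statistics at cycle 0 describe the initial parents; each later
#' entry describes that cycle's updated crossing block.
#'
#' @param config A `strategy_config`.
#' @param ges A `genetic_system`.
#' @param design A `trial_design`.
#' @param target_h2_fm Target family-mean heritability in (0, 1].
#' @param recalibrate_each_cycle Recalibrate `sigma2_R` from each cycle's
#'   families instead of holding the cycle-0 value (default `FALSE`).
#' @return An `hs_run` list: `stats` (data frame, cycles `0..cycles`),
#'   `summary` (see [delta_g90()]), `sigma2_R`, `ideal_value`,
#'   `final_block`, `config`.
#' @export
run_strategy <- function(config, ges, design, target_h2_fm = 0.5,
                         recalibrate_each_cycle = FALSE) {
  block <- initial_population(ges, config$n_parents)
  state <- list(cycle = 0L, block = block,
                stats = cycle_stats(0L, block, ges),
                next_id = config$n_parents + 1L)
  families <- make_halfsib_bulk(block, design$n_total, ges,
                                start_id = state$next_id)
  sigma2_R <- calibrate_error_variance(families, ges, design, target_h2_fm)
  error_model <- list(sigma2_R = sigma2_R, target_h2_fm = target_h2_fm)
  for (cyc in seq_len(config$cycles)) {
    if (cyc > 1 && recalibrate_each_cycle) {
      families <- make_halfsib_bulk(state$block, design$n_total, ges,
                                    start_id = state$next_id)
      error_model$sigma2_R <- calibrate_error_variance(families, ges, design,
                                                       target_h2_fm)
    }
    state <- run_cycle(state, ges, design, error_model, config,
                       families = families)
    families <- NULL
  }
  ideal <- ideal_genotype_value(ges)
  gain0 <- state$stats$mean_g[1]
  stats <- state$stats
  stats$delta_g_pct <- if (ideal > gain0)
    c(0, genetic_gain_percent(stats$mean_g, ideal)) else 0
  structure(list(stats = stats,
                 summary = delta_g90(stats$mean_g,
                                     if (ideal > gain0) ideal else NULL),
                 sigma2_R = sigma2_R,
                 ideal_value = ideal,
                 final_block = state$block,
                 config = config,
                 target_h2_fm = target_h2_fm),
            class = "hs_run")
}

#' @export
print.hs_run <- function(x, ...) {
  s <- x$stats
  cat(sprintf("%s run: %d cycles, %d parents\n", x$config$kind,
              x$config$cycles, x$config$n_parents))
  cat(sprintf("  mean G: %.3f -> %.3f (ideal %.3f)\n",
              s$mean_g[1], s$mean_g[nrow(s)], x$ideal_value))
  cat(sprintf("  dG90 = %.2f%% reached at cycle %d; final Hamming %.2f%%\n",
              x$summary$value, x$summary$cycle, s$hamming_pct[nrow(s)]))
  invisible(x)
}

#' Read a strategy configuration from YAML or JSON
#'
#' The file must contain only keys accepted by [strategy_config()] (plus
#' `target_h2_fm`, returned as an attribute); unknown keys are an error.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A `strategy_config`.
#' @export
read_strategy_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- c("kind", "n_parents", "family_selection_proportion",
             "within_family_count", "within_family_mode", "cycles",
             "crossing_block_replace_proportion", "progeny_test_update",
             "target_h2_fm")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  h2 <- vals$target_h2_fm
  vals$target_h2_fm <- NULL
  cfg <- do.call(strategy_config, vals)
  attr(cfg, "target_h2_fm") <- h2
  cfg
}
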