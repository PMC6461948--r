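#' Field-trial design
#'
#' A balanced multi-environment trial: families are evaluated over
#' `years x locations x reps` plots of `plants_per_plot` spaced plants, so
#' each family contributes `n_total = years * locations * reps *
#' plants_per_plot` phenotyped individuals. Years, locations and
#' replications carry no systematic effects here (a single environment
#' type); all non-genetic variation is pooled into the plant-level residual.
#'
#' @param years,locations,reps,plants_per_plot Positive integers.
#' @return A `trial_design` list with the four counts and `n_total`.
#' @examples
#' trial_design()          # 3 x 3 x 3 x 30 = 810 plants per family
#' trial_design(plants_per_plot = 10)  # reduced plot size, n_total = 270
#' @export
trial_design <- function(years = 3L, locations = 3L, reps = 3L,
                         plants_per_plot = 30L) {
  counts <- c(years, locations, reps, plants_per_plot)
  if (any(counts < 1)) stop("all trial-design counts must be >= 1")
  structure(list(years = as.integer(years), locations = as.integer(locations),
                 reps = as.integer(reps),
                 plants_per_plot = as.integer(plants_per_plot),
                 n_total = as.integer(prod(counts))),
            class = "trial_design")
}

#' Residual variance implied by a family-mean heritability target
#'
#' Under a balanced design with `n_total` plants per family, the half-sib
#' family-mean heritability is
#' `h2_fm = s2_b / (s2_b + (s2_w + s2_R) / n_total)`, where `s2_b` is the
#' variance of true family genotypic means and `s2_w` the mean within-family
#' genotypic variance. Solving for the plant-level residual variance gives
#' `s2_R = n_total * s2_b * (1 - h2) / h2 - s2_w`, floored at 0 (when the
#' design cannot push the heritability down to the target without negative
#' variance, e.g. `h2 = 1`).
#'
#' @param sigma2_b Among-family genotypic variance.
#' @param sigma2_w Mean within-family genotypic variance.
#' @param n_total Plants per family in the trial.
#' @param target_h2_fm Target family-mean heritability in (0, 1].
#' @return The residual variance `sigma2_R` (>= 0).
#' @export
residual_variance_for_h2 <- function(sigma2_b, sigma2_w, n_total,
                                     target_h2_fm) {
  if (target_h2_fm <= 0 || target_h2_fm > 1)
    stop("target_h2_fm must lie in (0, 1]")
  max(0, n_total * sigma2_b * (1 - target_h2_fm) / target_h2_fm - sigma2_w)
}

#' Calibrate trial error variance to a heritability target
#'
#' Estimates the among-family variance of true genotypic means and the mean
#' within-family genotypic variance from a set of half-sib families, then
#' returns the plant-level residual variance that makes the family-mean
#' heritability of the given design equal the target (see
#' [residual_variance_for_h2()]).
#'
#' @param families A list of `halfsib_family` objects (>= 2).
#' @param ges A `genetic_system`.
#' @param design A `trial_design`.
#' @param target_h2_fm Target family-mean heritability in (0, 1].
#' @return The calibrated `sigma2_R`.
#' @export
calibrate_error_variance <- function(families, ges, design, target_h2_fm) {
  if (inherits(families, "halfsib_bulk")) {
    if (families$k < 2)
      stop("need >= 2 families to estimate among-family variance")
    gm <- matrix(genotypic_value(families$bulk, ges), families$n, families$k)
    fam_means <- colMeans(gm)
    sigma2_b <- stats::var(fam_means)
    sigma2_w <- mean(colSums(sweep(gm, 2, fam_means)^2) / (families$n - 1))
  } else {
    if (length(families) < 2)
      stop("need >= 2 families to estimate among-family variance")
    g <- lapply(families, function(f) genotypic_value(f$members, ges))
    fam_means <- vapply(g, mean, numeric(1))
    sigma2_b <- stats::var(fam_means)
    sigma2_w <- mean(vapply(g, stats::var, numeric(1)))
  }
  residual_variance_for_h2(sigma2_b, sigma2_w, design$n_total, target_h2_fm)
}

#' Simulate a field trial for half-sib families
#'
#' Each plant's phenotype is its genotypic value plus an independent
#' `Normal(0, sigma2_R)` residual; the family phenotypic mean is the
#' average over its `n_total` plants. With a single environment type the
#' environment main effect and genotype-by-environment deviations are zero,
#' so phenotype equals genotype exactly when `sigma2_R = 0`.
#'
#' @param families A list of `halfsib_family` objects, each supplying
#'   exactly `design$n_total` members.
#' @param ges A `genetic_system`.
#' @param design A `trial_design`.
#' @param sigma2_R Plant-level residual variance (>= 0).
#' @return A `trial_result` list: `family_means` (numeric, one per family),
#'   `plants` (a data frame with `family` index, `plant_id`, genotypic
#'   value `g` and `phenotype`), and `sigma2_R`.
#' @export
simulate_trial <- function(families, ges, design, sigma2_R) {
  n <- design$n_total
  sizes <- vapply(families, function(f) pop_size(f$members), integer(1))
  if (any(sizes != n))
    stop(sprintf("every family must supply exactly n_total = %d plants", n))
  bulk <- attr(families, "bulk")
  if (is.null(bulk) || pop_size(bulk) != length(families) * n)
    bulk <- concat_populations(lapply(families, `[[`, "members"))
  core <- trial_core(genotypic_value(bulk, ges), length(families), n, sigma2_R)
  structure(list(
    family_means = core$family_means,
    plants = data.frame(family = rep(seq_along(families), each = n),
                        plant_id = bulk$id, g = core$g,
                        phenotype = core$phenotype),
    sigma2_R = sigma2_R
  ), class = "trial_result")
}

# Shared trial arithmetic: plant phenotypes and family means for k families
# of n plants whose genotypic values arrive family-blocked in g.
trial_core <- function(g, k, n, sigma2_R) {
  if (sigma2_R < 0) stop("sigma2_R must be non-negative")
  ph <- g + stats::rnorm(length(g), 0, sqrt(sigma2_R))
  list(g = g, phenotype = ph,
       family_means = colMeans(matrix(ph, nrow = n, ncol = k)))
}

#' Export a trial result as TSV
#'
#' @param trial A `trial_result`.
#' @param path Output path.
#' @export
export_trial <- function(trial, path) {
  write_tsv_full(trial$plants, path)
}
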