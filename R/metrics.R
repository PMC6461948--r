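#' Mean genotypic value of a population
#'
#' The arithmetic mean of the genotypic values of all members (every
#' individual contributes, never a single sampled representative).
#'
#' @param pop A non-empty `population`.
#' @param ges A `genetic_system`.
#' @export
population_genotypic_mean <- function(pop, ges) {
  if (pop_size(pop) < 1) stop("population is empty")
  mean(genotypic_value(pop, ges))
}

#' Per-cycle genetic gain as a percentage
#'
#' The between-cycle change in population genotypic mean, scaled to remove
#' trait units: `dG%_t = 100 * (G_t - G_{t-1}) / (ideal - G_0)`. The
#' normalizing constant is the gap between the ideal genotypic value and
#' the initial mean, so a series that climbs all the way to the ideal
#' accumulates exactly 100%. Cycle counts derived downstream (see
#' [delta_g90()]) are invariant to this choice of constant.
#'
#' @param mean_series Genotypic means for cycles `0..T` (length >= 2).
#' @param ideal_value The ideal genotypic value; must exceed the initial
#'   mean.
#' @return Numeric vector of length `T` (gains for cycles `1..T`).
#' @export
genetic_gain_percent <- function(mean_series, ideal_value) {
  if (length(mean_series) < 2) stop("mean_series must cover >= 2 cycles")
  if (ideal_value <= mean_series[1])
    stop("ideal_value must exceed the initial mean (no improvement possible)")
  100 * diff(mean_series) / (ideal_value - mean_series[1])
}

#' 90% cumulative gain and the cycle at which it is reached
#'
#' `delta_g90` is 90% of the total gain over the run; the associated cycle
#' is the first cycle whose cumulative gain reaches it. The cycle count is
#' invariant under any positive affine transformation of the series. When
#' the run shows no positive total gain, both the value and the cycle are
#' reported as 0.
#'
#' @param mean_series Genotypic means for cycles `0..T`.
#' @param ideal_value Optional; when supplied, `value` is expressed in the
#'   percentage units of [genetic_gain_percent()], otherwise in trait
#'   units.
#' @return A list with `value`, `cycle`, and `per_cycle` (= value / cycle,
#'   0 when cycle is 0).
#' @export
delta_g90 <- function(mean_series, ideal_value = NULL) {
  total <- mean_series[length(mean_series)] - mean_series[1]
  if (total <= 0) return(list(value = 0, cycle = 0L, per_cycle = 0))
  cum <- mean_series - mean_series[1]
  cycle <- which(cum >= 0.9 * total)[1] - 1L  # series index 1 is cycle 0
  value <- if (is.null(ideal_value)) 0.9 * total else
    90 * total / (ideal_value - mean_series[1])
  list(value = value, cycle = cycle,
       per_cycle = if (cycle > 0) value / cycle else 0)
}

# Per-QTL description of the ideal single-locus genotype: the heterozygote
# is ideal only when its value d beats both homozygote values (d > |a|);
# otherwise the favorable homozygote is the one whose value is +|a|. Note
# d > |a| is stricter than |d| > |a|: a large-magnitude negative d on a
# negative-a locus still leaves the positive homozygote on top.
qtl_ideal <- function(ges) {
  eff <- ges$effects
  list(over = eff$d > abs(eff$a),
       fav_allele = ifelse(eff$a >= 0, 1L, 0L))
}

#' Hamming distance to the ideal genotype
#'
#' For each individual, counts the minimal number of allele substitutions
#' needed at each QTL to reach that locus's ideal genotype (for a favorable
#' homozygote: heterozygote 1, other homozygote 2; for an overdominant
#' locus the ideal is the heterozygote: either homozygote 1), sums over
#' QTL, averages over individuals, and scales by the `2 * n_qtl` allele
#' slots to a percentage. Marker loci are excluded.
#'
#' @param pop A non-empty `population`.
#' @param ges A `genetic_system` with >= 1 QTL.
#' @return Mean distance as a percentage in `[0, 100]`.
#' @export
hamming_distance <- function(pop, ges) {
  if (pop_size(pop) < 1) stop("population is empty")
  q <- ges$qtl_col
  if (length(q) == 0) stop("the genetic system has no QTL")
  dos <- pop$h1[, q, drop = FALSE] + pop$h2[, q, drop = FALSE]
  ideal <- qtl_ideal(ges)
  target <- ifelse(ideal$over, 1L, 2L * ideal$fav_allele)
  # distance to target dosage; for heterozygote-ideal loci (target 1) both
  # homozygotes are a single substitution away, so no further capping needed
  subs <- abs(sweep(dos, 2, target))
  100 * mean(rowSums(subs)) / (2 * length(q))
}

#' Allele fixation rates at QTL
#'
#' A QTL is fixed when every individual in the population is homozygous for
#' the same allele. The favorable allele is the allele of the higher-valued
#' homozygote (the sign of `a`), also under overdominance, where fixation of
#' either homozygote forfeits the heterozygote optimum but only the
#' lower-valued one counts as non-favorable.
#'
#' @param pop A non-empty `population`.
#' @param ges A `genetic_system`.
#' @return Named numeric vector: `favorable` and `nonfavorable`
#'   percentages of QTL fixed for the respective allele.
#' @export
fixation_rates <- function(pop, ges) {
  if (pop_size(pop) < 1) stop("population is empty")
  q <- ges$qtl_col
  dos <- pop$h1[, q, drop = FALSE] + pop$h2[, q, drop = FALSE]
  fixed1 <- colSums(dos == 2L) == nrow(dos)
  fixed0 <- colSums(dos == 0L) == nrow(dos)
  fav <- qtl_ideal(ges)$fav_allele
  fixed_fav <- ifelse(fav == 1L, fixed1, fixed0)
  fixed_non <- ifelse(fav == 1L, fixed0, fixed1)
  c(favorable = 100 * mean(fixed_fav), nonfavorable = 100 * mean(fixed_non))
}

# TSV writer that preserves doubles at full precision (%.17g round-trips).
write_tsv_full <- function(df, path) {
  fmt <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(fmt, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Write per-cycle result files for one or more runs
#'
#' Writes the three per-cycle statistics tables of a simulation run in the
#' layout of the classical breeding-simulator output roles:
#' \describe{
#'   \item{fit.tsv}{`run`, `cycle`, `mean_g`, `delta_g_pct` (0 at cycle 0).}
#'   \item{ham.tsv}{`run`, `cycle`, `hamming_pct`.}
#'   \item{fre.tsv}{`run`, `cycle`, `favorable_pct`, `nonfavorable_pct`.}
#' }
#' Values are written at full double precision and round-trip exactly
#' through [utils::read.delim()].
#'
#' @param runs A single run result from [run_strategy()] or a list of them
#'   (run numbers follow list order).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_outputs <- function(runs, dir) {
  if (inherits(runs, "hs_run")) runs <- list(runs)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stack <- function(extract) {
    do.call(rbind, lapply(seq_along(runs), function(i) {
      cbind(run = i, extract(runs[[i]]$stats))
    }))
  }
  fit <- stack(function(s) {
    data.frame(cycle = s$cycle, mean_g = s$mean_g,
               delta_g_pct = s$delta_g_pct)
  })
  ham <- stack(function(s) data.frame(cycle = s$cycle,
                                      hamming_pct = s$hamming_pct))
  fre <- stack(function(s) {
    data.frame(cycle = s$cycle, favorable_pct = s$fixed_favorable_pct,
               nonfavorable_pct = s$fixed_nonfavorable_pct)
  })
  paths <- file.path(dir, c("fit.tsv", "ham.tsv", "fre.tsv"))
  write_tsv_full(fit, paths[1])
  write_tsv_full(ham, paths[2])
  write_tsv_full(fre, paths[3])
  invisible(paths)
}
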