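#' Populations of diploid genotypes
#'
#' A `population` stores its members' haplotypes as two integer matrices
#' (`h1`, `h2`; individuals in rows, loci in map order in columns, alleles
#' coded 0/1 with allele 1 the "A" allele of the effect lookup), plus per-
#' individual pedigree ids (`id`, `female`, `male`) and the breeding cycle
#' the members were created in. A single genotype is simply a population of
#' size 1.
#'
#' @param h1,h2 Integer matrices of identical dimension, entries 0/1.
#' @param id Integer individual ids (unique within a run).
#' @param female,male Integer parent ids (`NA` for founders).
#' @param cycle Breeding cycle index.
#' @return A `population` object.
#' @export
new_population <- function(h1, h2, id, female = NA_integer_,
                           male = NA_integer_, cycle = 0L) {
  if (!is.matrix(h1) || !is.matrix(h2) || nrow(h1) != nrow(h2) ||
      ncol(h1) != ncol(h2))
    stop("h1 and h2 must be matrices of identical dimension")
  n <- nrow(h1)
  structure(list(h1 = h1, h2 = h2,
                 id = as.integer(rep_len(id, n)),
                 female = as.integer(rep_len(female, n)),
                 male = as.integer(rep_len(male, n)),
                 cycle = as.integer(cycle)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d individuals x %d loci (cycle %d)\n",
              nrow(x$h1), ncol(x$h1), x$cycle))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `population`.
#' @export
pop_size <- function(pop) nrow(pop$h1)

#' Extract a subset of a population
#' @param pop A `population`.
#' @param idx Row indices of the members to keep.
#' @export
subset_population <- function(pop, idx) {
  new_population(pop$h1[idx, , drop = FALSE], pop$h2[idx, , drop = FALSE],
                 pop$id[idx], pop$female[idx], pop$male[idx], pop$cycle)
}

#' Concatenate populations
#' @param pops A list of `population` objects over the same map.
#' @param cycle Cycle index of the result (default: first input's).
#' @export
concat_populations <- function(pops, cycle = NULL) {
  stopifnot(length(pops) >= 1)
  new_population(do.call(rbind, lapply(pops, `[[`, "h1")),
                 do.call(rbind, lapply(pops, `[[`, "h2")),
                 unlist(lapply(pops, `[[`, "id")),
                 unlist(lapply(pops, `[[`, "female")),
                 unlist(lapply(pops, `[[`, "male")),
                 cycle %||% pops[[1]]$cycle)
}

#' Found an initial random-mating population
#'
#' Each founder carries exactly `floor(L/2)` heterozygous loci (a fresh
#' random subset per individual); the remaining loci are split as evenly as
#' possible between the two homozygote classes, assigned at random (an odd
#' remainder goes to either class with probability 1/2). The pooled allele
#' frequency is therefore 0.5 in expectation at every locus, matching a
#' base population at intermediate allele frequency with equal fractions of
#' homozygous and heterozygous loci.
#'
#' @param ges A `genetic_system`.
#' @param n Number of founders (>= 1).
#' @return A `population` of `n` founders at cycle 0.
#' @export
initial_population <- function(ges, n) {
  stopifnot(inherits(ges, "genetic_system"))
  if (n < 1) stop("n must be >= 1")
  L <- ges$n_loci
  n_het <- L %/% 2
  h1 <- matrix(0L, n, L)
  h2 <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    het <- sample.int(L, n_het)
    hom <- setdiff(seq_len(L), het)
    n_hom <- length(hom)
    n_AA <- n_hom %/% 2 + (n_hom %% 2) * stats::rbinom(1, 1, 0.5)
    AA <- if (n_AA > 0) sample(hom, n_AA) else integer(0)
    h1[i, AA] <- 1L
    h2[i, AA] <- 1L
    # heterozygotes: phase assigned at random
    phase <- stats::rbinom(n_het, 1, 0.5) == 1
    h1[i, het[phase]] <- 1L
    h2[i, het[!phase]] <- 1L
  }
  new_population(h1, h2, id = seq_len(n), cycle = 0L)
}

get_rswitch <- function(x) {
  if (inherits(x, "genetic_system")) return(x$rswitch)
  if (inherits(x, "genetic_map") || is.data.frame(x)) return(switch_probabilities(x))
  stop("expected a genetic_system or genetic_map")
}

#' Sample gametes by meiosis
#'
#' Simulates meiosis with independent assortment across linkage groups and,
#' within a group, crossovers between adjacent loci with probability
#' `r = (1 - exp(-2 * d / 100)) / 2` for a map distance of `d` cM (Haldane
#' mapping function, no interference).
#'
#' `make_gametes` draws one gamete per entry of `parents` (row indices into
#' `pop`, recycled meioses are independent); `make_gamete` is the single-
#' meiosis convenience form.
#'
#' @param pop A `population` of potential parents.
#' @param map_or_ges A `genetic_system` or `genetic_map` aligned with `pop`.
#' @param parents Integer vector of parent row indices, one per gamete.
#' @return `make_gametes`: an integer matrix (gametes x loci);
#'   `make_gamete`: a single 0/1 haplotype vector.
#' @export
make_gametes <- function(pop, map_or_ges, parents) {
  rs <- get_rswitch(map_or_ges)
  sample_gametes_cpp(pop$h1, pop$h2, as.integer(parents), rs)
}

#' @rdname make_gametes
#' @param parent Row index of the single parent.
#' @export
make_gamete <- function(pop, map_or_ges, parent = 1L) {
  drop(make_gametes(pop, map_or_ges, parent))
}

#' Cross two individuals
#'
#' The offspring receives one independently sampled gamete from each
#' parent; pedigree ids are recorded.
#'
#' @param female,male `population`s; the first member of each is used.
#' @param map_or_ges A `genetic_system` or `genetic_map`.
#' @param id Id to assign to the offspring.
#' @return A `population` of size 1.
#' @export
cross <- function(female, male, map_or_ges, id = NA_integer_) {
  g1 <- make_gametes(female, map_or_ges, 1L)
  g2 <- make_gametes(male, map_or_ges, 1L)
  new_population(g1, g2, id = id,
                 female = female$id[1], male = male$id[1],
                 cycle = max(female$cycle, male$cycle) + 1L)
}

# Batch polycross progeny: females indexed by fem_idx (one entry per
# progeny); each progeny's male is drawn uniformly from the other block
# members (resampled per progeny), so selfs never occur.
polycross_progeny <- function(block, fem_idx, map_or_ges, ids,
                              cycle = block$cycle + 1L) {
  k <- pop_size(block)
  if (k < 2) stop("a crossing block needs >= 2 members (selfing is excluded)")
  m <- length(fem_idx)
  u <- sample.int(k - 1L, m, replace = TRUE)
  male_idx <- u + (u >= fem_idx)
  h1 <- make_gametes(block, map_or_ges, fem_idx)
  h2 <- make_gametes(block, map_or_ges, male_idx)
  new_population(h1, h2, id = ids,
                 female = block$id[fem_idx], male = block$id[male_idx],
                 cycle = cycle)
}

#' Create half-sib families by polycross
#'
#' Every crossing-block member acts as the female of one family; for each
#' progeny the male parent is drawn uniformly at random from the remaining
#' block members (a polycross, with the male resampled per progeny).
#' Self-pollination is excluded, so a block of size 1 is rejected.
#'
#' @param crossing_block A `population` with at least 2 members.
#' @param progeny_per_family Number of progeny bulked per female.
#' @param map_or_ges A `genetic_system` or `genetic_map`.
#' @param start_id First progeny id (defaults to continuing after the
#'   block's largest id).
#' @return A list of `halfsib_family` objects, each with fields
#'   `female_parent_id` and `members` (a `population`).
#' @export
make_halfsib_families <- function(crossing_block, progeny_per_family,
                                  map_or_ges, start_id = NULL) {
  k <- pop_size(crossing_block)
  if (k < 2) stop("a crossing block needs >= 2 members (selfing is excluded)")
  if (progeny_per_family < 1) stop("progeny_per_family must be >= 1")
  m <- as.integer(progeny_per_family)
  start_id <- start_id %||% (max(crossing_block$id, 0L, na.rm = TRUE) + 1L)
  fem_idx <- rep(seq_len(k), each = m)
  prog <- polycross_progeny(crossing_block, fem_idx, map_or_ges,
                            ids = start_id + seq_along(fem_idx) - 1L)
  fams <- lapply(seq_len(k), function(f) {
    rows <- ((f - 1L) * m + 1L):(f * m)
    structure(list(female_parent_id = crossing_block$id[f],
                   members = subset_population(prog, rows)),
              class = "halfsib_family")
  })
  # the bulked progeny population backs a fast path in simulate_trial
  attr(fams, "bulk") <- prog
  attr(fams, "bulk_family_size") <- m
  fams
}

# Lightweight internal form of a set of half-sib families: the bulked
# progeny population plus its family blocking, without per-family copies.
make_halfsib_bulk <- function(crossing_block, progeny_per_family, map_or_ges,
                              start_id = NULL) {
  k <- pop_size(crossing_block)
  if (k < 2) stop("a crossing block needs >= 2 members (selfing is excluded)")
  m <- as.integer(progeny_per_family)
  start_id <- start_id %||% (max(crossing_block$id, 0L, na.rm = TRUE) + 1L)
  fem_idx <- rep(seq_len(k), each = m)
  prog <- polycross_progeny(crossing_block, fem_idx, map_or_ges,
                            ids = start_id + seq_along(fem_idx) - 1L)
  structure(list(bulk = prog, k = k, n = m,
                 female_ids = crossing_block$id),
            class = "halfsib_bulk")
}

#' Reorganize or propagate selected material into populations
#'
#' Implements the family-propagation options of the simulator:
#' \describe{
#'   \item{single_bulk}{bulk everything into one population.}
#'   \item{bulk_per_family}{bulk genotypes by their female parent, one
#'     population per female.}
#'   \item{separate}{one singleton population per genotype.}
#'   \item{half_sib, polycross}{bulk everything into a crossing block and
#'     generate new half-sib families from it (see
#'     [make_halfsib_families()]).}
#' }
#'
#' @param populations A list of `population`s (or `halfsib_family`s).
#' @param mode One of `"single_bulk"`, `"bulk_per_family"`, `"separate"`,
#'   `"half_sib"`, `"polycross"`.
#' @param map_or_ges Required for the half_sib/polycross modes.
#' @param progeny_per_family Required for the half_sib/polycross modes.
#' @return A list of `population`s, or of `halfsib_family`s for the
#'   half_sib/polycross modes.
#' @export
bulk_propagate <- function(populations, mode, map_or_ges = NULL,
                           progeny_per_family = NULL) {
  mode <- match.arg(mode, c("single_bulk", "bulk_per_family", "separate",
                            "half_sib", "polycross"))
  pops <- lapply(populations, function(p) {
    if (inherits(p, "halfsib_family")) p$members else p
  })
  all <- concat_populations(pops)
  switch(mode,
    single_bulk = list(all),
    bulk_per_family = {
      key <- ifelse(is.na(all$female), -all$id, all$female)
      lapply(split(seq_len(pop_size(all)), key), function(i)
        subset_population(all, i))
    },
    separate = lapply(seq_len(pop_size(all)), function(i)
      subset_population(all, i)),
    half_sib = ,
    polycross = {
      if (is.null(map_or_ges) || is.null(progeny_per_family))
        stop("half_sib/polycross modes need map_or_ges and progeny_per_family")
      make_halfsib_families(all, progeny_per_family, map_or_ges)
    }
  )
}

#' Export a population as a genotype matrix
#'
#' Writes a TSV with columns `id`, `female`, `male` and one column per
#' locus (named by locus id) holding the 0/1/2 count of allele 1.
#'
#' @param pop A `population`.
#' @param ges A `genetic_system` supplying the locus ids.
#' @param path Output file path.
#' @export
export_genotypes <- function(pop, ges, path) {
  dos <- pop$h1 + pop$h2
  colnames(dos) <- ges$map$id
  df <- data.frame(id = pop$id, female = pop$female, male = pop$male,
                   dos, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
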