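#' Build a synthetic linkage map
#'
#' Generates a linkage map carrying QTL and neutral marker loci for use when
#' no empirical map is available. Loci counts are distributed across linkage
#' groups as evenly as integer division allows (the first groups receive the
#' remainder), and positions are drawn uniformly on `[0, group_length_cM]`
#' and then sorted within each group.
#'
#' @param n_groups Number of linkage groups (default 7, the perennial
#'   ryegrass karyotype).
#' @param n_qtl Total number of QTL across the map.
#' @param n_markers Total number of neutral marker loci.
#' @param group_length_cM Length of each linkage group in centimorgans.
#' @return A `genetic_map`: a data frame with columns `id`, `group`,
#'   `pos_cM` and `kind` (`"qtl"` or `"marker"`), sorted by group and
#'   position.
#' @examples
#' map <- build_synthetic_map(7, 63, 194, 100)
#' nrow(map)            # 257 loci
#' table(map$kind)
#' @export
build_synthetic_map <- function(n_groups = 7, n_qtl = 63, n_markers = 194,
                                group_length_cM = 100) {
  if (n_groups < 1) stop("n_groups must be >= 1")
  if (n_qtl < 0 || n_markers < 0) stop("locus counts must be non-negative")
  if (n_qtl + n_markers < 1) stop("the map must contain at least one locus")
  if (group_length_cM <= 0) stop("group_length_cM must be positive")

  per_group <- function(total) {
    base <- total %/% n_groups
    counts <- rep(base, n_groups)
    extra <- total %% n_groups
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    counts
  }
  q_counts <- per_group(n_qtl)
  m_counts <- per_group(n_markers)

  rows <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    n_g <- q_counts[g] + m_counts[g]
    if (n_g == 0) next
    kind <- c(rep("qtl", q_counts[g]), rep("marker", m_counts[g]))
    pos <- stats::runif(n_g, 0, group_length_cM)
    ord <- order(pos)
    rows[[g]] <- data.frame(
      group = g,
      pos_cM = pos[ord],
      kind = kind[ord],
      stringsAsFactors = FALSE
    )
  }
  map <- do.call(rbind, rows)
  # stable ids: Q for QTL, M for markers, numbered in map order within kind
  map$id <- NA_character_
  map$id[map$kind == "qtl"] <- sprintf("Q%03d", seq_len(sum(map$kind == "qtl")))
  map$id[map$kind == "marker"] <- sprintf("M%03d", seq_len(sum(map$kind == "marker")))
  map <- map[, c("id", "group", "pos_cM", "kind")]
  rownames(map) <- NULL
  attr(map, "group_length_cM") <- group_length_cM
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Sample QTL effects under a genetic-effects model
#'
#' Additive effects `a` are drawn from a standard normal distribution.
#' Dominance deviations `d` depend on the model:
#' \describe{
#'   \item{additive}{all loci are purely additive (`d = 0`).}
#'   \item{additive_dominance}{`round(n_qtl/2)` loci (round-half-up) are
#'     purely additive; the rest are split as evenly as possible between
#'     partial and over dominance.}
#'   \item{dominance}{all loci split as evenly as possible between partial
#'     and over dominance, none purely additive.}
#' }
#' Partial dominance draws `d = u * |a| * sign(a)` with `u ~ U(0, 1)`, over
#' dominance with `u ~ U(1, 2)`, so the heterozygote deviation always takes
#' the sign of the favorable homozygote.
#'
#' @param model One of `"additive"`, `"additive_dominance"`, `"dominance"`.
#' @param n_qtl Number of QTL to draw effects for.
#' @param qtl_ids Optional character vector of QTL ids (defaults to
#'   `Q001...`); must have length `n_qtl`.
#' @return An `effect_table` data frame with columns `id`, `a`, `d`,
#'   `dominance_class`.
#' @export
sample_qtl_effects <- function(model, n_qtl, qtl_ids = NULL) {
  model <- match.arg(model, c("additive", "additive_dominance", "dominance"))
  if (n_qtl < 0) stop("n_qtl must be non-negative")
  if (is.null(qtl_ids)) qtl_ids <- sprintf("Q%03d", seq_len(n_qtl))
  if (length(qtl_ids) != n_qtl) stop("qtl_ids must have length n_qtl")

  a <- stats::rnorm(n_qtl)
  cls <- rep("none", n_qtl)
  if (model != "additive" && n_qtl > 0) {
    n_none <- if (model == "additive_dominance") round_half_up(n_qtl / 2) else 0L
    n_dom <- n_qtl - n_none
    n_partial <- ceiling(n_dom / 2)
    dom_cls <- c(rep("partial", n_partial), rep("over", n_dom - n_partial))
    cls <- c(rep("none", n_none), dom_cls)
  }
  d <- numeric(n_qtl)
  is_p <- cls == "partial"
  is_o <- cls == "over"
  d[is_p] <- stats::runif(sum(is_p), 0, 1) * abs(a[is_p]) * sign(a[is_p])
  d[is_o] <- stats::runif(sum(is_o), 1, 2) * abs(a[is_o]) * sign(a[is_o])

  eff <- data.frame(id = qtl_ids, a = a, d = d, dominance_class = cls,
                    stringsAsFactors = FALSE)
  class(eff) <- c("effect_table", "data.frame")
  eff
}

round_half_up <- function(x) floor(x + 0.5)

#' Assemble a genotype-environment system
#'
#' Couples a linkage map with a QTL effect table and the model metadata.
#' Epistasis is not supported: the epistatic connectivity `K` must be 0, and
#' a single environment type is assumed (no genotype-by-environment
#' deviations are simulated).
#'
#' @param map A `genetic_map` from [build_synthetic_map()] (or equivalent).
#' @param effects An `effect_table` whose ids match the map's QTL ids.
#' @param model The genetic-effects model name used to draw `effects`.
#' @param n_env_types Number of environment types (must currently be 1).
#' @param epistasis_k Epistatic connectivity; only 0 is accepted.
#' @param init_allele_freq Initial allele frequency used when founding
#'   populations (default 0.5).
#' @return A `genetic_system` list with elements `map`, `effects`, `model`,
#'   `n_env_types`, `epistasis_k`, `init_allele_freq`, plus precomputed
#'   locus bookkeeping used by the simulator.
#' @export
genetic_system <- function(map, effects, model,
                           n_env_types = 1L, epistasis_k = 0L,
                           init_allele_freq = 0.5) {
  model <- match.arg(model, c("additive", "additive_dominance", "dominance"))
  if (epistasis_k != 0) stop("epistasis networks (K > 0) are not supported")
  if (n_env_types != 1) stop("only a single environment type is supported")
  if (init_allele_freq <= 0 || init_allele_freq >= 1)
    stop("init_allele_freq must lie in (0, 1)")
  qtl_ids <- map$id[map$kind == "qtl"]
  if (!setequal(effects$id, qtl_ids) || nrow(effects) != length(qtl_ids))
    stop("effect table ids do not match the map's QTL ids")
  # order effects to map order once; all vectorized code relies on it
  effects <- effects[match(qtl_ids, effects$id), , drop = FALSE]
  rownames(effects) <- NULL
  ges <- list(
    map = map,
    effects = effects,
    model = model,
    n_env_types = as.integer(n_env_types),
    epistasis_k = 0L,
    init_allele_freq = init_allele_freq,
    qtl_col = which(map$kind == "qtl"),
    n_loci = nrow(map),
    rswitch = switch_probabilities(map)
  )
  class(ges) <- "genetic_system"
  ges
}

# Per-locus switch probabilities for gamete sampling: Haldane recombination
# fraction r = (1 - exp(-2 * d_cM / 100)) / 2 with the previous locus; the
# first locus of each group gets 0.5 (independent assortment of groups).
switch_probabilities <- function(map) {
  L <- nrow(map)
  r <- numeric(L)
  first <- !duplicated(map$group)
  r[first] <- 0.5
  if (L > 1) {
    dd <- diff(map$pos_cM)
    idx <- which(!first)
    r[idx] <- 0.5 * (1 - exp(-2 * dd[idx - 1] / 100))
  }
  r
}

#' @export
print.genetic_system <- function(x, ...) {
  cat("Genotype-environment system\n")
  cat(sprintf("  loci: %d (%d QTL, %d markers) on %d linkage groups\n",
              x$n_loci, length(x$qtl_col), x$n_loci - length(x$qtl_col),
              length(unique(x$map$group))))
  cat(sprintf("  model: %s; E = %d; K = %d; p0 = %g\n",
              x$model, x$n_env_types, x$epistasis_k, x$init_allele_freq))
  invisible(x)
}

#' Genotypic value of individuals
#'
#' Computes the genotypic value `G` of each individual as the sum over QTL
#' of the locus value under the standard biallelic parameterization:
#' homozygote for allele 1 contributes `+a`, heterozygote `d`, the other
#' homozygote `-a`. Marker loci contribute nothing.
#'
#' @param pop A `population` (a single genotype is a population of size 1).
#' @param ges A `genetic_system`.
#' @return Numeric vector of genotypic values, one per individual.
#' @export
genotypic_value <- function(pop, ges) {
  stopifnot(inherits(ges, "genetic_system"))
  if (ncol(pop$h1) != ges$n_loci)
    stop("population and genetic system have different locus counts")
  q <- ges$qtl_col
  if (length(q) == 0) return(numeric(nrow(pop$h1)))
  dos <- pop$h1[, q, drop = FALSE] + pop$h2[, q, drop = FALSE]
  a <- ges$effects$a
  d <- ges$effects$d
  # hom contributes a*(dos-1), het contributes d
  hom <- (dos != 1L) * (dos - 1L)
  het <- dos == 1L
  as.numeric(hom %*% a + het %*% d)
}

#' Genotypic value of the ideal genotype
#'
#' The ideal genotype maximizes the genotypic value locus by locus: at each
#' QTL it takes `max(a, d, -a)`, so under overdominance the ideal is
#' heterozygous at that locus.
#'
#' @param ges A `genetic_system` (or an `effect_table`).
#' @return The ideal genotypic value (0 for an empty effect table).
#' @export
ideal_genotype_value <- function(ges) {
  eff <- if (inherits(ges, "genetic_system")) ges$effects else ges
  if (nrow(eff) == 0) return(0)
  sum(pmax(eff$a, eff$d, -eff$a))
}

#' Write / read a genetic system as plain text
#'
#' Serializes a [genetic_system()] to a TSV body (one row per locus: id,
#' group, position, kind, and for QTL the effects `a`, `d` and dominance
#' class) preceded by a `#key value` header block with the scalar metadata.
#' The round trip is loss-free at full double precision.
#'
#' @param ges A `genetic_system`.
#' @param path File path to write to / read from.
#' @return `write_genetic_system` returns `path` invisibly;
#'   `read_genetic_system` returns the reconstructed `genetic_system`.
#' @export
write_genetic_system <- function(ges, path) {
  stopifnot(inherits(ges, "genetic_system"))
  hdr <- c(
    sprintf("#model %s", ges$model),
    sprintf("#n_env_types %d", ges$n_env_types),
    sprintf("#epistasis_k %d", ges$epistasis_k),
    sprintf("#init_allele_freq %s", format(ges$init_allele_freq, digits = 17)),
    sprintf("#group_length_cM %s",
            format(attr(ges$map, "group_length_cM") %||% NA, digits = 17))
  )
  tab <- ges$map
  class(tab) <- "data.frame"
  tab$a <- NA_real_; tab$d <- NA_real_; tab$dominance_class <- NA_character_
  m <- match(ges$effects$id, tab$id)
  tab$a[m] <- ges$effects$a
  tab$d[m] <- ges$effects$d
  tab$dominance_class[m] <- ges$effects$dominance_class
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("id", "group", "pos_cM", "kind", "a", "d",
                     "dominance_class"), collapse = "\t"), con)
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  body <- paste(tab$id, tab$group, num(tab$pos_cM), tab$kind,
                num(tab$a), num(tab$d),
                ifelse(is.na(tab$dominance_class), "NA", tab$dominance_class),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_genetic_system
#' @export
read_genetic_system <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), " ", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  map <- tab[, c("id", "group", "pos_cM", "kind")]
  gl <- suppressWarnings(as.numeric(meta[["group_length_cM"]]))
  if (!is.na(gl)) attr(map, "group_length_cM") <- gl
  class(map) <- c("genetic_map", "data.frame")
  eff <- tab[tab$kind == "qtl", c("id", "a", "d", "dominance_class")]
  rownames(eff) <- NULL
  class(eff) <- c("effect_table", "data.frame")
  genetic_system(map, eff,
                 model = meta[["model"]],
                 n_env_types = as.integer(meta[["n_env_types"]]),
                 epistasis_k = as.integer(meta[["epistasis_k"]]),
                 init_allele_freq = as.numeric(meta[["init_allele_freq"]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
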