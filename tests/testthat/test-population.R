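test_that("founders carry half heterozygous loci and frequency 0.5 overall", {
  ges <- toy_ges(63, 194, n_groups = 7, seed = 20)
  pop <- initial_population(ges, 10)
  expect_equal(pop_size(pop), 10)
  het_counts <- rowSums(pop$h1 != pop$h2)
  expect_equal(het_counts, rep(128, 10), ignore_attr = TRUE)  # floor(257/2)

  two <- toy_ges(1, 1, n_groups = 1, seed = 21)
  p2 <- initial_population(two, 1)
  expect_equal(sum(p2$h1 != p2$h2), 1)  # 1 het + 1 hom locus

  # pooled allele frequency close to 0.5 per locus
  small <- toy_ges(10, 10, seed = 22)
  set.seed(23)
  big <- initial_population(small, 1000)
  freq <- colMeans((big$h1 + big$h2) / 2)
  expect_true(all(abs(freq - 0.5) < 0.05))

  expect_error(initial_population(ges, 0), ">= 1")
})

test_that("meiosis respects the map: Haldane within, free recombination between groups", {
  # a fully homozygous parent transmits its haplotype unchanged
  ges <- toy_ges(4, 0, seed = 24)
  hom <- pop_from_dosage(matrix(c(2, 0, 2, 0), 1), ges)
  g <- make_gamete(hom, ges, 1)
  expect_equal(g, hom$h1[1, ])

  # hand-built two-locus maps at controlled distances
  two_locus_map <- function(d, groups = c(1, 1)) {
    map <- data.frame(id = c("Q001", "Q002"), group = groups,
                      pos_cM = c(0, d), kind = "qtl",
                      stringsAsFactors = FALSE)
    class(map) <- c("genetic_map", "data.frame")
    map
  }
  parent <- new_population(matrix(c(1L, 1L), 1), matrix(c(0L, 0L), 1), id = 1)

  recomb_frac <- function(map, n = 1e5) {
    gam <- make_gametes(parent, map, rep(1L, n))
    mean(gam[, 1] != gam[, 2])
  }
  set.seed(25)
  expect_equal(recomb_frac(two_locus_map(0), 2e4), 0)
  r20 <- 0.5 * (1 - exp(-2 * 20 / 100))
  expect_lt(abs(recomb_frac(two_locus_map(20)) - r20), 0.01)   # ~0.1648
  expect_lt(abs(recomb_frac(two_locus_map(0, groups = c(1, 2))) - 0.5), 0.01)
})

test_that("crossing combines one gamete from each parent", {
  ges <- toy_ges(5, 2, seed = 26)
  L <- ges$n_loci
  AA <- new_population(matrix(1L, 1, L), matrix(1L, 1, L), id = 1)
  aa <- new_population(matrix(0L, 1, L), matrix(0L, 1, L), id = 2)
  off <- cross(AA, aa, ges, id = 3)
  expect_true(all(off$h1 + off$h2 == 1))  # every locus heterozygous
  expect_equal(off$female, 1L)
  expect_equal(off$male, 2L)

  clone <- cross(AA, AA, ges)
  expect_equal(clone$h1[1, ], AA$h1[1, ])
  expect_equal(clone$h2[1, ], AA$h1[1, ])

  # offspring allele frequency matches the mid-parent frequency
  set.seed(27)
  f <- initial_population(ges, 1)
  m <- initial_population(ges, 1)
  mid <- mean((f$h1 + f$h2 + m$h1 + m$h2) / 4)
  kids <- replicate(5e3, {
    o <- cross(f, m, ges)
    mean(o$h1 + o$h2) / 2
  })
  expect_lt(abs(mean(kids) - mid), 0.02)

  # every offspring allele is traceable to a parent haplotype
  set.seed(28)
  o <- cross(f, m, ges)
  expect_true(all(o$h1[1, ] == f$h1[1, ] | o$h1[1, ] == f$h2[1, ]))
  expect_true(all(o$h2[1, ] == m$h1[1, ] | o$h2[1, ] == m$h2[1, ]))
})

test_that("half-sib families exclude selfing and use males uniformly", {
  ges <- toy_ges(6, 2, seed = 29)
  set.seed(30)
  block <- initial_population(ges, 10)
  fams <- make_halfsib_families(block, 20, ges)
  expect_length(fams, 10)
  for (f in fams) {
    expect_s3_class(f, "halfsib_family")
    expect_true(all(f$members$female == f$female_parent_id))
    expect_true(all(f$members$male != f$female_parent_id))
    expect_equal(pop_size(f$members), 20)
  }

  # k = 2: the other parent is always the male
  b2 <- initial_population(ges, 2)
  f2 <- make_halfsib_families(b2, 10, ges)
  expect_true(all(f2[[1]]$members$male == b2$id[2]))
  expect_true(all(f2[[2]]$members$male == b2$id[1]))

  expect_error(make_halfsib_families(subset_population(block, 1), 5, ges),
               "selfing")

  # male usage uniform over the 9 non-self candidates
  set.seed(31)
  fams <- make_halfsib_families(block, 1e4, ges)
  males <- fams[[1]]$members$male
  tab <- table(factor(males, levels = setdiff(block$id, fams[[1]]$female_parent_id)))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("drift without selection keeps allele frequency at 0.5 on average", {
  ges <- toy_ges(8, 0, n_groups = 2, seed = 32)
  set.seed(33)
  final_freq <- replicate(200, {
    pop <- initial_population(ges, 12)
    for (gen in 1:3) {
      fams <- make_halfsib_families(pop, 2, ges)
      pop <- concat_populations(lapply(fams, `[[`, "members"))
      pop <- subset_population(pop, sample.int(pop_size(pop), 12))
    }
    mean(pop$h1 + pop$h2) / 2
  })
  se <- stats::sd(final_freq) / sqrt(length(final_freq))
  expect_lt(abs(mean(final_freq) - 0.5), 3 * se + 1e-12)
})

test_that("bulk_propagate reorganizes genotypes per mode", {
  ges <- toy_ges(4, 0, seed = 34)
  set.seed(35)
  block <- initial_population(ges, 3)
  fams <- make_halfsib_families(block, 5, ges)

  one <- bulk_propagate(fams, "single_bulk")
  expect_length(one, 1)
  expect_equal(pop_size(one[[1]]), 15)

  per <- bulk_propagate(fams, "bulk_per_family")
  expect_length(per, 3)
  expect_true(all(vapply(per, pop_size, integer(1)) == 5))

  sep <- bulk_propagate(fams, "separate")
  expect_length(sep, 15)
  expect_true(all(vapply(sep, pop_size, integer(1)) == 1))

  hs <- bulk_propagate(fams, "half_sib", map_or_ges = ges,
                       progeny_per_family = 4)
  expect_length(hs, 15)  # one family per bulked genotype acting as female
  for (f in hs) {
    expect_true(all(f$members$female == f$female_parent_id))
    expect_true(all(f$members$male != f$female_parent_id))
  }

  expect_error(bulk_propagate(fams, "cloning"))
})

test_that("populations export to a dosage matrix file", {
  ges <- toy_ges(3, 1, seed = 36)
  set.seed(37)
  pop <- initial_population(ges, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_genotypes(pop, ges, path)
  tab <- utils::read.delim(path, check.names = FALSE)
  expect_equal(names(tab), c("id", "female", "male", ges$map$id))
  expect_equal(as.matrix(tab[, ges$map$id]), pop$h1 + pop$h2,
               ignore_attr = TRUE)
})
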