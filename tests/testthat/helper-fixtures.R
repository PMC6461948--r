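# Small genetic systems and populations built in code for the tests.

toy_ges <- function(n_qtl = 5, n_markers = 3, model = "additive",
                    n_groups = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- build_synthetic_map(n_groups, n_qtl, n_markers, 100)
  eff <- sample_qtl_effects(model, n_qtl, map$id[map$kind == "qtl"])
  genetic_system(map, eff, model = model)
}

# A population with explicitly chosen QTL dosages (markers set to 0).
# dosages: matrix individuals x QTL with entries 0/1/2 (heterozygote phase
# is h1 = 1).
pop_from_dosage <- function(dosages, ges) {
  n <- nrow(dosages)
  h1 <- matrix(0L, n, ges$n_loci)
  h2 <- matrix(0L, n, ges$n_loci)
  q <- ges$qtl_col
  h1[, q] <- as.integer(dosages >= 1)
  h2[, q] <- as.integer(dosages == 2)
  new_population(h1, h2, id = seq_len(n))
}

# Independent per-locus lookup oracle for genotypic values.
lookup_value_oracle <- function(dosages, effects) {
  vapply(seq_len(nrow(dosages)), function(i) {
    sum(vapply(seq_len(ncol(dosages)), function(j) {
      switch(dosages[i, j] + 1,
             -effects$a[j],          # dosage 0
             effects$d[j],           # dosage 1
             effects$a[j])           # dosage 2
    }, numeric(1)))
  }, numeric(1))
}

# Enumerate all 3^n_qtl dosage vectors.
all_dosages <- function(n_qtl) {
  as.matrix(expand.grid(rep(list(0:2), n_qtl)))
}

# Exhaustive per-locus substitution-count oracle: try all three genotypes
# at a locus, find the best by value, count allele edits to reach it.
hamming_oracle <- function(dos, eff) {
  locus_vals <- function(j) c(-eff$a[j], eff$d[j], eff$a[j])  # dosage 0,1,2
  per_ind <- vapply(seq_len(nrow(dos)), function(i) {
    sum(vapply(seq_len(ncol(dos)), function(j) {
      vals <- locus_vals(j)
      best <- which(vals == max(vals))  # all optimal dosages
      min(abs(best - 1 - dos[i, j]))    # minimal substitutions to any optimum
    }, numeric(1)))
  }, numeric(1))
  100 * mean(per_ind) / (2 * ncol(dos))
}
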