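# Build a small panel from explicit genotypes.
# male_genos / female_genos: one list element per individual, itself a list
# of length-2 integer vectors (one per locus); NA means a missing genotype.
toy_panel <- function(male_genos, female_genos, loci = NULL) {
  n_loci <- length(c(male_genos, female_genos)[[1]])
  if (is.null(loci)) loci <- paste0("L", seq_len(n_loci))
  row_for <- function(g, sex, i) {
    out <- list(group = "G", population = "P", sex = sex,
                id = sprintf("%s%02d", toupper(substr(sex, 1, 1)), i))
    for (j in seq_len(n_loci)) {
      gj <- g[[j]]
      if (length(gj) == 1 && is.na(gj)) gj <- c(NA_integer_, NA_integer_)
      out[[paste0(loci[j], ".a1")]] <- gj[1]
      out[[paste0(loci[j], ".a2")]] <- gj[2]
    }
    tibble::as_tibble(out)
  }
  rows <- c(
    lapply(seq_along(male_genos),
           function(i) row_for(male_genos[[i]], "male", i)),
    lapply(seq_along(female_genos),
           function(i) row_for(female_genos[[i]], "female", i)))
  as_genotype_panel(dplyr::bind_rows(rows), loci = loci)
}

# repeat one genotype across loci for quick single-individual profiles
rep_geno <- function(g, n_loci) rep(list(g), n_loci)

# random synthetic panel with a random allele-frequency structure
random_panel <- function(seed, n_males = 6, n_females = 6, n_loci = 5,
                         max_alleles = 4, missing_rate = 0) {
  set.seed(seed)
  loci <- lapply(seq_len(n_loci), function(i) {
    a <- sample(2:max_alleles, 1)
    g <- rgamma(a, 1) + 0.1
    locus_spec(paste0("L", i), sample(100:300, a), g / sum(g),
               f_is = runif(1, 0, 0.5))
  })
  simulate_panel(panel_spec(n_males, n_females, loci,
                            missing_rate = missing_rate,
                            seed = seed + 1000L))
}

# all permutations of a small vector (for brute-force matchings)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# brute force: best set of k disjoint pairs by total v
brute_force_matching <- function(pairs, males, females, k) {
  v <- matrix(NA_real_, length(males), length(females),
              dimnames = list(males, females))
  v[cbind(pairs$male_id, pairs$female_id)] <- pairs$v
  best <- -Inf
  for (ms in utils::combn(males, k, simplify = FALSE)) {
    for (fs in utils::combn(females, k, simplify = FALSE)) {
      for (p in perms(fs)) {
        tot <- sum(v[cbind(ms, p)])
        if (tot > best) best <- tot
      }
    }
  }
  best
}
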