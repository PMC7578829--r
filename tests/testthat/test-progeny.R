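# hand-derived Punnett expectations for every genotype shape class
shape_classes <- list(
  list(gm = c(1L, 1L), gf = c(1L, 1L), h = 0.00, ar = 1L, weak = FALSE), # AAxAA
  list(gm = c(1L, 1L), gf = c(1L, 2L), h = 0.50, ar = 2L, weak = TRUE),  # AAxAB
  list(gm = c(1L, 1L), gf = c(2L, 2L), h = 1.00, ar = 2L, weak = FALSE), # AAxBB
  list(gm = c(1L, 1L), gf = c(2L, 3L), h = 1.00, ar = 3L, weak = FALSE), # AAxBC
  list(gm = c(1L, 2L), gf = c(1L, 2L), h = 0.50, ar = 2L, weak = FALSE), # ABxAB
  list(gm = c(1L, 2L), gf = c(1L, 3L), h = 0.75, ar = 3L, weak = FALSE), # ABxAC
  list(gm = c(1L, 2L), gf = c(3L, 4L), h = 1.00, ar = 4L, weak = FALSE)) # ABxCD

test_that("pair_offspring enumerates the 4 equally likely combinations", {
  off <- pair_offspring(c(1L, 2L), c(1L, 2L))
  expect_equal(nrow(off), 4)
  key <- apply(cbind(pmin(off$a1, off$a2), pmax(off$a1, off$a2)), 1, paste,
               collapse = "/")
  expect_equal(sort(key), c("1/1", "1/2", "1/2", "2/2"))  # Punnett AB x AB
  expect_null(pair_offspring(c(1L, NA), c(1L, 2L)))

  hom <- pair_offspring(c(1L, 1L), c(2L, 2L))
  expect_true(all(hom$a1 == 1L & hom$a2 == 2L))
  distinct <- pair_offspring(c(1L, 2L), c(3L, 4L))
  expect_equal(nrow(dplyr::distinct(distinct)), 4)
  expect_true(all(distinct$a1 != distinct$a2))
})

test_that("closed-form pair statistics match hand-derived shape classes", {
  for (sc in shape_classes) {
    expect_equal(pair_expected_heterozygosity(sc$gm, sc$gf), sc$h)
    expect_equal(pair_allele_count(sc$gm, sc$gf), sc$ar)
    expect_equal(pair_is_weak(sc$gm, sc$gf), sc$weak)
    # symmetry in parents and in allele order within a genotype
    expect_equal(pair_expected_heterozygosity(sc$gf, sc$gm), sc$h)
    expect_equal(pair_expected_heterozygosity(rev(sc$gm), sc$gf), sc$h)
    expect_equal(pair_allele_count(rev(sc$gf), rev(sc$gm)), sc$ar)
  }
})

test_that("closed forms equal the 4-outcome enumeration on random genotypes", {
  set.seed(42)
  for (i in 1:200) {
    gm <- sample(1:4, 2, replace = TRUE)
    gf <- sample(1:4, 2, replace = TRUE)
    off <- pair_offspring(gm, gf)
    expect_equal(pair_expected_heterozygosity(gm, gf),
                 mean(off$a1 != off$a2))
    expect_equal(pair_allele_count(gm, gf),
                 length(unique(c(gm, gf))))
    expect_true(pair_expected_heterozygosity(gm, gf) %in%
                  c(0, 0.25, 0.5, 0.75, 1))
  }
})

test_that("predict_pair aggregates per-locus statistics over evaluable loci", {
  p <- toy_panel(
    male_genos = list(list(c(1L, 1L), c(1L, 2L), NA)),
    female_genos = list(list(c(1L, 2L), c(3L, 4L), c(5L, 5L))))
  pred <- predict_pair(p, "M01", "F01")
  s <- glance(pred)
  expect_equal(s$n_loci_evaluable, 2)           # third locus missing in male
  expect_equal(s$h_mean, mean(c(0.5, 1.0)))
  expect_equal(s$ar_total, 2L + 4L)
  expect_equal(s$wh_share, mean(c(0.5, 0)))     # AAAB at locus 1 only
})

test_that("identical fully homozygous parents give H 0 and one allele per locus", {
  p <- toy_panel(male_genos = list(rep_geno(c(7L, 7L), 5)),
                 female_genos = list(rep_geno(c(7L, 7L), 5)))
  s <- glance(predict_pair(p, "M01", "F01"))
  expect_equal(s$h_mean, 0)
  expect_equal(s$ar_total, 5L)
})

test_that("an all-distinct 13-locus pair attains the per-locus maxima", {
  p <- toy_panel(male_genos = list(rep_geno(c(1L, 2L), 13)),
                 female_genos = list(rep_geno(c(3L, 4L), 13)))
  s <- glance(predict_pair(p, "M01", "F01"))
  expect_equal(s$ar_total, 52L)
  expect_equal(s$h_mean, 1)
})

test_that("predict_pair rejects same-sex pairs and unknown ids", {
  p <- random_panel(5)
  m <- sex_ids(p, "male")
  expect_error(predict_pair(p, m[1], m[2]), "female")
  expect_error(predict_pair(p, "ghost", sex_ids(p, "female")[1]),
               "unknown individual id")
})

test_that("predict_group on singletons reproduces predict_pair exactly", {
  for (seed in 1:6) {
    p <- random_panel(seed, missing_rate = 0.1)
    m <- sex_ids(p, "male")[1]
    f <- sex_ids(p, "female")[1]
    pp <- glance(predict_pair(p, m, f))
    pg <- glance(predict_group(p, m, f))
    expect_equal(pg$h_mean, pp$h_mean)
    expect_equal(pg$ar_total, pp$ar_total)
    expect_equal(pg$wh_share, pp$wh_share)
  }
})

test_that("opposite-homozygote sexes give group H 1 with 2 alleles", {
  p <- toy_panel(
    male_genos = list(rep_geno(c(1L, 1L), 1), rep_geno(c(1L, 1L), 1)),
    female_genos = list(rep_geno(c(2L, 2L), 1), rep_geno(c(2L, 2L), 1)))
  pred <- predict_group(p, sex_ids(p, "male"), sex_ids(p, "female"))
  expect_equal(tidy(pred)$h_exp, 1)
  expect_equal(tidy(pred)$alleles_transmitted, 2L)
})

test_that("group H matches a Monte-Carlo offspring simulation", {
  p <- random_panel(17, n_males = 4, n_females = 5, n_loci = 3)
  males <- sex_ids(p, "male")[1:3]
  females <- sex_ids(p, "female")[1:4]
  pred <- predict_group(p, males, females)
  n_draws <- 2e5
  set.seed(7)
  for (li in seq_along(panel_loci(p))) {
    l <- panel_loci(p)[li]
    am <- cbind(p[[paste0(l, ".a1")]], p[[paste0(l, ".a2")]])[match(males, p$id), , drop = FALSE]
    af <- cbind(p[[paste0(l, ".a1")]], p[[paste0(l, ".a2")]])[match(females, p$id), , drop = FALSE]
    am <- am[!is.na(am[, 1]), , drop = FALSE]
    af <- af[!is.na(af[, 1]), , drop = FALSE]
    pat <- am[cbind(sample(nrow(am), n_draws, TRUE), sample(2, n_draws, TRUE))]
    mat <- af[cbind(sample(nrow(af), n_draws, TRUE), sample(2, n_draws, TRUE))]
    h_hat <- mean(pat != mat)
    h <- tidy(pred)$h_exp[li]
    se <- sqrt(h * (1 - h) / n_draws) + 1e-12
    expect_lt(abs(h_hat - h), 3 * se + 0.003)
  }
})

test_that("adding an individual never decreases per-locus transmitted alleles", {
  for (seed in 1:4) {
    p <- random_panel(seed, n_males = 5, n_females = 5)
    males <- sex_ids(p, "male")
    females <- sex_ids(p, "female")
    base <- tidy(predict_group(p, males[1:2], females[1:2]))$alleles_transmitted
    for (extra in c(males[3:5], females[3:5])) {
      grown <- if (extra %in% males) {
        predict_group(p, c(males[1:2], extra), females[1:2])
      } else {
        predict_group(p, males[1:2], c(females[1:2], extra))
      }
      expect_true(all(tidy(grown)$alleles_transmitted >= base))
    }
  }
})

test_that("group usage errors are raised for empty lists and sex mixups", {
  p <- random_panel(9)
  expect_error(predict_group(p, character(0), sex_ids(p, "female")),
               "non-empty")
  expect_error(predict_group(p, sex_ids(p, "female")[1], sex_ids(p, "female")[2]),
               "non-male")
})
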