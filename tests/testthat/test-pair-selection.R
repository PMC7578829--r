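test_that("pair counting follows the product rule", {
  expect_equal(count_pair_combinations(23, 25), 575)
  expect_equal(count_pair_combinations(0, 10), 0)
  expect_equal(count_pair_combinations(7, 11), 77)
})

test_that("enumerate_pairs yields M x F rows in file order", {
  p <- random_panel(1, n_males = 3, n_females = 4)
  pairs <- enumerate_pairs(p)
  expect_equal(nrow(pairs), 12)
  expect_equal(pairs$male_id, rep(sex_ids(p, "male"), each = 4))
  expect_equal(pairs$female_id, rep(sex_ids(p, "female"), 3))

  single <- random_panel(2, n_males = 1, n_females = 1)
  expect_equal(nrow(enumerate_pairs(single)), 1)

  females_only <- toy_panel(male_genos = list(),
                            female_genos = list(list(c(1L, 2L))))
  expect_error(enumerate_pairs(females_only), "at least one male")
})

test_that("enumerate_pairs agrees with per-pair predict_pair", {
  for (seed in c(3, 4)) {
    p <- random_panel(seed, n_males = 3, n_females = 3, missing_rate = 0.1)
    pairs <- enumerate_pairs(p)
    for (i in seq_len(nrow(pairs))) {
      s <- glance(predict_pair(p, pairs$male_id[i], pairs$female_id[i]))
      expect_equal(pairs$h_mean[i], s$h_mean)
      expect_equal(pairs$ar_total[i], s$ar_total)
      expect_equal(pairs$wh_share[i], s$wh_share)
      expect_equal(pairs$n_loci_evaluable[i], s$n_loci_evaluable)
    }
  }
})

test_that("v weights validate and normalize", {
  w <- v_weights(0.9, 0.2, 0.9)
  expect_equal(sum(w), 1)
  expect_equal(unname(w[["i_wh"]]), 0.1)
  expect_error(v_weights(-1, 0, 1), ">= 0")
  expect_error(v_weights(0, 0, 0), "positive")
  # defaults
  expect_equal(unname(unclass(v_weights())), c(0.45, 0.1, 0.45))
})

test_that("v index lies in [0,1] and matches an independent recomputation", {
  p <- random_panel(6, n_males = 5, n_females = 5)
  pairs <- add_v_index(enumerate_pairs(p))
  expect_true(all(pairs$v >= 0 & pairs$v <= 1))
  v2 <- 0.45 * pairs$h_mean / max(pairs$h_mean) +
    0.45 * pairs$ar_total / max(pairs$ar_total) +
    0.1 * (if (max(pairs$wh_share) > 0) 1 - pairs$wh_share / max(pairs$wh_share)
           else rep(1, nrow(pairs)))
  expect_equal(pairs$v, v2)
  expect_equal(order(-pairs$v), order(-v2))
})

test_that("a sole pair with nonzero H and ar and zero wh scores v = 1", {
  p <- toy_panel(male_genos = list(list(c(1L, 2L))),
                 female_genos = list(list(c(3L, 4L))))
  pairs <- add_v_index(enumerate_pairs(p))
  expect_equal(pairs$v, 1)
})

test_that("scaling all weights by a constant leaves the ranking unchanged", {
  p <- random_panel(8, n_males = 5, n_females = 6)
  base <- add_v_index(enumerate_pairs(p), v_weights(0.45, 0.1, 0.45))
  scaled <- add_v_index(enumerate_pairs(p), v_weights(4.5, 1, 4.5))
  expect_equal(base$v, scaled$v)
})

test_that("degenerate weights rank purely by one statistic", {
  p <- random_panel(10, n_males = 5, n_females = 5)
  byh <- add_v_index(enumerate_pairs(p), v_weights(1, 0, 0))
  expect_equal(order(-byh$v), order(-byh$h_mean))
  byar <- add_v_index(enumerate_pairs(p), v_weights(0, 0, 1))
  expect_equal(order(-byar$v), order(-byar$ar_total))
})

test_that("selected pairs are disjoint and ordered by descending v", {
  for (seed in 1:6) {
    p <- random_panel(seed, n_males = 6, n_females = 7)
    for (method in c("greedy", "exact")) {
      sel <- tidy(select_best_pairs(p, 3, method = method))
      expect_equal(nrow(sel), 3)
      expect_false(anyDuplicated(sel$male_id) > 0)
      expect_false(anyDuplicated(sel$female_id) > 0)
      expect_true(all(diff(sel$v) <= 1e-12))
    }
  }
})

test_that("greedy selection equals brute force on 3x3 toy panels", {
  p <- toy_panel(
    male_genos = list(list(c(1L, 2L), c(5L, 5L)),
                      list(c(1L, 1L), c(5L, 6L)),
                      list(c(3L, 4L), c(6L, 6L))),
    female_genos = list(list(c(1L, 3L), c(5L, 5L)),
                        list(c(2L, 2L), c(7L, 7L)),
                        list(c(1L, 1L), c(5L, 7L))))
  pairs <- add_v_index(enumerate_pairs(p))
  for (k in 1:3) {
    sel <- select_best_pairs(p, k, method = "exact")
    best <- brute_force_matching(pairs, sex_ids(p, "male"),
                                 sex_ids(p, "female"), k)
    expect_equal(sum(tidy(sel)$v), best)
    # greedy is optimal on this instance too
    greedy <- select_best_pairs(p, k, method = "greedy")
    expect_equal(sum(tidy(greedy)$v), best)
  }
})

test_that("exact total v is never below greedy total v", {
  for (seed in 1:10) {
    p <- random_panel(seed + 100, n_males = 5, n_females = 6)
    k <- sample(1:4, 1)
    g <- sum(tidy(select_best_pairs(p, k, method = "greedy"))$v)
    e <- sum(tidy(select_best_pairs(p, k, method = "exact"))$v)
    expect_gte(e + 1e-9, g)
  }
})

test_that("exact matching equals brute force on random small panels", {
  for (seed in 1:5) {
    p <- random_panel(seed + 200, n_males = 4, n_females = 4)
    pairs <- add_v_index(enumerate_pairs(p))
    for (k in c(2, 3)) {
      e <- sum(tidy(select_best_pairs(p, k, method = "exact"))$v)
      b <- brute_force_matching(pairs, sex_ids(p, "male"),
                                sex_ids(p, "female"), k)
      expect_equal(e, b, tolerance = 1e-10)
    }
  }
})

test_that("greedy selections nest as k grows", {
  for (seed in 1:20) {
    p <- random_panel(seed, n_males = 9, n_females = 10, n_loci = 5)
    s4 <- tidy(select_best_pairs(p, 4))
    s8 <- tidy(select_best_pairs(p, 8))
    expect_true(all(paste(s4$male_id, s4$female_id) %in%
                      paste(s8$male_id, s8$female_id)))
  }
})

test_that("identical individuals tie-break deterministically to file order", {
  g <- list(c(1L, 2L), c(3L, 3L))
  p <- toy_panel(male_genos = list(g, g, g), female_genos = list(g, g, g))
  sel <- tidy(select_best_pairs(p, 3))
  expect_equal(sel$male_id, c("M01", "M02", "M03"))
  expect_equal(sel$female_id, c("F01", "F02", "F03"))
})

test_that("k outside 1..min(M,F) is a usage error", {
  p <- random_panel(31, n_males = 3, n_females = 5)
  expect_error(select_best_pairs(p, 4), "between 1 and 3")
  expect_error(select_best_pairs(p, 0), "between 1 and 3")
})

test_that("selection summary compares selected means against cohort means", {
  p <- random_panel(12, n_males = 6, n_females = 6)
  sel <- select_best_pairs(p, 3)
  g <- glance(sel)
  pairs <- add_v_index(enumerate_pairs(p))
  expect_equal(g$all_mean_h, mean(pairs$h_mean))
  expect_equal(g$all_mean_v, mean(pairs$v))
  expect_equal(g$mean_v, mean(tidy(sel)$v))
  expect_gte(g$mean_v, g$all_mean_v)
})
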