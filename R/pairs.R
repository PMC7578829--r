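#' Weights of the v index
#'
#' The v index scores a candidate pair as a weighted sum of three relative
#' terms: relative expected progeny heterozygosity (`i_h`), relative
#' expected allele number (`i_ar`), and a reversed weak-heterozygote term
#' (`i_wh`; fewer weak heterozygotes is better). Weights must be
#' non-negative and are normalized to sum to 1, so v lies in `[0, 1]`.
#' Defaults follow common practice of weighting heterozygosity and allele
#' number equally and heavily (0.45 each) with a small weak-heterozygote
#' penalty (0.1).
#'
#' @param i_h,i_wh,i_ar Non-negative weights.
#' @return A `v_weights` object (named numeric vector summing to 1).
#' @export
v_weights <- function(i_h = 0.45, i_wh = 0.1, i_ar = 0.45) {
  w <- c(i_h = i_h, i_wh = i_wh, i_ar = i_ar)
  if (any(w < 0) || any(is.na(w))) abort("v-index weights must be >= 0")
  if (sum(w) == 0) abort("at least one v-index weight must be positive")
  structure(w / sum(w), class = "v_weights")
}

#' Enumerate all candidate breeding pairs
#'
#' Computes the Mendelian progeny prediction for every male-by-female pair
#' in the panel (males in file order, then females in file order), one row
#' per pair. With M males and F females the result has exactly M x F rows.
#'
#' @param panel A `genotype_panel` with at least one male and one female.
#' @return A `pair_grid` tibble with columns `male_id`, `female_id`,
#'   `h_mean`, `ar_total`, `wh_share`, `n_loci_evaluable`.
#' @examples
#' p <- guzy_like_fixture(seed = 1)
#' pairs <- enumerate_pairs(p)
#' nrow(pairs)  # 23 * 25 = 575
#' @export
enumerate_pairs <- function(panel) {
  males <- sex_ids(panel, "male")
  females <- sex_ids(panel, "female")
  if (length(males) == 0 || length(females) == 0) {
    abort("pair enumeration needs at least one male and one female")
  }
  rm_ <- match_ids(panel, males)
  rf_ <- match_ids(panel, females)
  nm <- length(males); nf <- length(females)
  h_sum <- ar_sum <- wh_sum <- n_eval <- matrix(0, nm, nf)
  for (l in panel_loci(panel)) {
    al <- locus_alleles(panel, l)
    m1 <- al[rm_, 1]; m2 <- al[rm_, 2]
    f1 <- al[rf_, 1]; f2 <- al[rf_, 2]
    ok <- outer(!is.na(m1), !is.na(f1), "&")
    # heterozygous offspring fraction: mean of the 4 allele comparisons
    h <- (outer(m1, f1, "!=") + outer(m1, f2, "!=") +
          outer(m2, f1, "!=") + outer(m2, f2, "!=")) / 4
    # distinct parental alleles = |{m}| + |{f}| - |shared|
    mh <- m1 != m2; fh <- f1 != f2
    shared <- (outer(m1, f1, "==") | outer(m1, f2, "==")) +
      ((outer(m2, f1, "==") | outer(m2, f2, "==")) &
         outer(mh, rep(TRUE, nf), "&"))
    ar <- outer(1 + mh, 1 + fh, "+") - shared
    # 3:1 AAAB pattern: one parent homozygous, the other heterozygous
    # carrying exactly one copy of the homozygote's allele
    weak <- (outer(!mh, fh, "&") & (outer(m1, f1, "==") | outer(m1, f2, "=="))) |
            (outer(mh, !fh, "&") & (outer(m1, f1, "==") | outer(m2, f1, "==")))
    h_sum <- h_sum + ifelse(ok, h, 0)
    ar_sum <- ar_sum + ifelse(ok, ar, 0)
    wh_sum <- wh_sum + ifelse(ok, 0.5 * weak, 0)
    n_eval <- n_eval + ok
  }
  out <- tibble::tibble(
    male_id = rep(males, each = nf),
    female_id = rep(females, nm),
    h_mean = as.vector(t(h_sum / n_eval)),
    ar_total = as.integer(as.vector(t(ar_sum))),
    wh_share = as.vector(t(wh_sum / n_eval)),
    n_loci_evaluable = as.integer(as.vector(t(n_eval)))
  )
  structure(out, class = c("pair_grid", class(tibble::tibble())))
}

#' Score pairs with the v index
#'
#' Adds a `v` column to an enumerated pair table. Each pair's score is
#' `i_h * h_mean / max(h_mean) + i_ar * ar_total / max(ar_total) +
#' i_wh * (1 - wh_share / max(wh_share))`, with maxima taken over the
#' cohort (all enumerated pairs). A cohort maximum of zero makes its term
#' contribute its full weight (the best attainable value), so v always
#' lies in `[0, 1]`.
#'
#' @param pairs A `pair_grid` from [enumerate_pairs()].
#' @param weights A [v_weights()] object.
#' @return `pairs` with an added `v` column.
#' @export
add_v_index <- function(pairs, weights = v_weights()) {
  if (nrow(pairs) == 0) abort("empty pair cohort")
  if (!inherits(weights, "v_weights")) weights <- do.call(v_weights, as.list(weights))
  rel <- function(x, reverse = FALSE) {
    mx <- max(x, na.rm = TRUE)
    if (!is.finite(mx) || mx == 0) return(rep(1, length(x)))
    if (reverse) 1 - x / mx else x / mx
  }
  pairs$v <- weights[["i_h"]] * rel(pairs$h_mean) +
    weights[["i_ar"]] * rel(pairs$ar_total) +
    weights[["i_wh"]] * rel(pairs$wh_share, reverse = TRUE)
  pairs
}

#' Number of possible breeding pairs
#'
#' With M males and F females, each male can be paired with each female,
#' so M x F distinct pairs are possible.
#'
#' @param n_males,n_females Non-negative integers.
#' @return `n_males * n_females`.
#' @examples
#' count_pair_combinations(23, 25)  # 575
#' @export
count_pair_combinations <- function(n_males, n_females) {
  stopifnot(n_males >= 0, n_females >= 0)
  n_males * n_females
}

# deterministic pair ordering: v desc, then ar desc, wh asc, ids
order_pairs <- function(pairs) {
  order(-pairs$v, -pairs$ar_total, pairs$wh_share,
        pairs$male_id, pairs$female_id)
}

#' Select disjoint breeding pairs for controlled mating
#'
#' Chooses `k` pairs such that no individual appears in more than one pair.
#' The default `"greedy"` method repeatedly takes the highest-v pair whose
#' sire and dam are both still unused; its selections nest (the set chosen
#' at `k = 4` is contained in the set chosen at `k = 8`), which makes
#' hatchery planning incremental. The `"exact"` method solves the
#' k-cardinality assignment problem (maximum total v over all disjoint
#' k-pair sets) via a padded maximum-weight bipartite matching; its total v
#' is never below the greedy total but its sets need not nest. Ties in v
#' are broken by higher `ar_total`, lower `wh_share`, then ids, so results
#' are deterministic.
#'
#' @param panel A `genotype_panel`.
#' @param k Number of pairs, `1 <= k <= min(males, females)`.
#' @param weights A [v_weights()] object.
#' @param method `"greedy"` or `"exact"`.
#' @return A `pair_selection` object: [tidy()] gives the selected pairs in
#'   descending v, [glance()] a one-row comparison of selected-set means
#'   against all-pair means.
#' @examples
#' p <- guzy_like_fixture(seed = 1)
#' sel <- select_best_pairs(p, k = 4)
#' glance(sel)
#' @export
select_best_pairs <- function(panel, k, weights = v_weights(),
                              method = c("greedy", "exact")) {
  method <- match.arg(method)
  males <- sex_ids(panel, "male")
  females <- sex_ids(panel, "female")
  kmax <- min(length(males), length(females))
  if (k < 1 || k > kmax) {
    abort(sprintf("k must be between 1 and %d (the smaller sex count)", kmax))
  }
  pairs <- add_v_index(enumerate_pairs(panel), weights)
  if (method == "greedy") {
    ord <- order_pairs(pairs)
    used_m <- character(0); used_f <- character(0); take <- integer(0)
    for (i in ord) {
      if (length(take) == k) break
      if (!(pairs$male_id[i] %in% used_m) &&
          !(pairs$female_id[i] %in% used_f)) {
        take <- c(take, i)
        used_m <- c(used_m, pairs$male_id[i])
        used_f <- c(used_f, pairs$female_id[i])
      }
    }
    selected <- pairs[take, , drop = FALSE]
  } else {
    selected <- exact_assignment(pairs, males, females, k)
  }
  selected <- selected[order_pairs(selected), , drop = FALSE]
  mean_row <- function(d, which) {
    tibble::tibble(set = which, n_pairs = nrow(d),
                   mean_h = mean(d$h_mean), mean_ar = mean(d$ar_total),
                   mean_wh = mean(d$wh_share), mean_v = mean(d$v))
  }
  structure(
    list(pairs = selected, all_pairs = pairs, k = k, method = method,
         weights = weights,
         summary = dplyr::bind_rows(mean_row(selected, "selected"),
                                    mean_row(pairs, "all_pairs"))),
    class = "pair_selection")
}

# maximum total-v set of exactly k disjoint pairs, as a padded
# maximum-weight bipartite matching (dummy rows/columns absorb the
# unmatched individuals; a large boost forces a perfect matching, which
# then uses exactly k real edges)
exact_assignment <- function(pairs, males, females, k) {
  nm <- length(males); nf <- length(females)
  w <- matrix(0, nm, nf)
  w[cbind(match(pairs$male_id, males), match(pairs$female_id, females))] <-
    ifelse(is.na(pairs$v), 0, pairs$v)
  boost <- sum(w) + 1
  nr <- nm + (nf - k); nc <- nf + (nm - k)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  ij <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  real <- ij$i <= nm & ij$j <= nf
  dummy_ok <- xor(ij$i <= nm, ij$j <= nf) | real
  keep <- ij[dummy_ok, , drop = FALSE]
  wt <- ifelse(keep$i <= nm & keep$j <= nf,
               w[cbind(pmin(keep$i, nm), pmin(keep$j, nf))] + boost, boost)
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, nr), rep(TRUE, nc)),
    as.vector(rbind(keep$i, nr + keep$j)))
  m <- igraph::max_bipartite_match(g, weights = wt)
  mate <- m$matching[seq_len(nm)] - nr
  sel_m <- which(!is.na(mate) & mate <= nf)
  key <- paste(males[sel_m], females[mate[sel_m]], sep = "\r")
  pairs[match(key, paste(pairs$male_id, pairs$female_id, sep = "\r")), ,
        drop = FALSE]
}

#' @exportS3Method generics::tidy
tidy.pair_selection <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.pair_selection <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    k = x$k, method = x$method,
    mean_h = s$mean_h[1], mean_ar = s$mean_ar[1],
    mean_wh = s$mean_wh[1], mean_v = s$mean_v[1],
    all_mean_h = s$mean_h[2], all_mean_ar = s$mean_ar[2],
    all_mean_wh = s$mean_wh[2], all_mean_v = s$mean_v[2])
}

#' @export
print.pair_selection <- function(x, ...) {
  cat(sprintf("# %d breeding pairs selected (%s method)\n", x$k, x$method))
  print(x$pairs[, c("male_id", "female_id", "h_mean", "ar_total",
                    "wh_share", "v")])
  cat("# selected-set means vs all-pair means:\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn select_best_pairs Heatmap of the v index over the full
#'   male-by-female grid with selected pairs outlined.
#' @param object A `pair_selection`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pair_selection <- function(object, ...) {
  d <- object$all_pairs
  sel <- object$pairs
  ggplot2::ggplot(d, ggplot2::aes(x = .data$female_id, y = .data$male_id,
                                  fill = .data$v)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = sel, fill = NA, colour = "black",
                       linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "female", y = "male", fill = "v") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn enumerate_pairs Heatmap of expected progeny heterozygosity
#'   (or v, if present) over the pair grid.
#' @param object A `pair_grid`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pair_grid <- function(object, ...) {
  fill_var <- if ("v" %in% names(object)) "v" else "h_mean"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$female_id, y = .data$male_id,
                               fill = .data[[fill_var]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "female", y = "male") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
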