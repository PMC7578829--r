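#' Exact binomial coefficient
#'
#' `choose(n, k)` computed by the multiplicative formula with exact integer
#' intermediates (every intermediate is itself a binomial coefficient, so
#' each division is exact), valid as long as the result stays below 2^53.
#' Used for the subset-space accounting of group spawning so that printed
#' counts reproduce exactly.
#'
#' @param n,k Non-negative integers, `k <= n`.
#' @return The exact value of C(n, k) as a numeric.
#' @examples
#' count_subsets(23, 4)  # 8855
#' count_subsets(25, 8)  # 1081575
#' @export
count_subsets <- function(n, k) {
  stopifnot(length(n) == 1, length(k) == 1, n >= 0, k >= 0)
  if (k > n) abort("k must not exceed n")
  k <- min(k, n - k)
  res <- 1
  for (i in seq_len(k)) {
    res <- res * (n - k + i)
    if (res > 2^53) abort("binomial coefficient exceeds exact integer range")
    res <- res / i
  }
  res
}

#' Size of the group-spawning search space
#'
#' Choosing `m` of the panel's M males and `f` of its F females gives
#' C(M, m) male subsets, C(F, f) female subsets, and their product as the
#' number of candidate spawning sets.
#'
#' @param panel A `genotype_panel`.
#' @param m,f Requested male and female subset sizes.
#' @return A one-row tibble: `n_males`, `n_females`, `m`, `f`,
#'   `male_subsets`, `female_subsets`, `total_combinations`.
#' @examples
#' p <- guzy_like_fixture(seed = 1)
#' search_space(p, 8, 8)  # 490314 * 1081575 = 5.30311e11 combinations
#' @export
search_space <- function(panel, m, f) {
  nm <- length(sex_ids(panel, "male"))
  nf <- length(sex_ids(panel, "female"))
  if (m > nm || f > nf || m < 1 || f < 1) {
    abort(sprintf("need 1 <= m <= %d and 1 <= f <= %d", nm, nf))
  }
  ms <- count_subsets(nm, m)
  fs <- count_subsets(nf, f)
  tibble::tibble(n_males = nm, n_females = nf, m = m, f = f,
                 male_subsets = ms, female_subsets = fs,
                 total_combinations = ms * fs)
}

# --- fast set evaluation ----------------------------------------------------
# Per locus: allele codes indexed 1..A, per-individual bitmask over them,
# and an A x N matrix of per-individual allele-copy counts.

group_eval_prep <- function(panel) {
  loci <- panel_loci(panel)
  purrr::map(setNames(loci, loci), function(l) {
    al <- locus_alleles(panel, l)
    codes <- sort(unique(al[!is.na(al)]))
    idx1 <- match(al[, 1], codes)
    idx2 <- match(al[, 2], codes)
    called <- !is.na(idx1) & !is.na(idx2)
    n <- nrow(al)
    mask <- integer(n)
    cnt <- matrix(0L, nrow = length(codes), ncol = n)
    for (i in which(called)) {
      mask[i] <- bitwOr(bitwShiftL(1L, idx1[i] - 1L),
                        bitwShiftL(1L, idx2[i] - 1L))
      cnt[idx1[i], i] <- cnt[idx1[i], i] + 1L
      cnt[idx2[i], i] <- cnt[idx2[i], i] + 1L
    }
    list(codes = codes, mask = mask, cnt = cnt, called = called)
  })
}

popcount <- function(x, nbits) {
  pc <- x - x
  for (b in seq_len(nbits) - 1L) {
    pc <- pc + bitwAnd(bitwShiftR(x, b), 1L)
  }
  pc
}

# lexicographic objective for a candidate set: total transmitted alleles,
# then mean per-locus expected progeny heterozygosity
eval_set <- function(prep, mrows, frows) {
  cover <- 0L
  hsum <- 0
  neval <- 0L
  for (p in prep) {
    u <- Reduce(bitwOr, p$mask[c(mrows, frows)], 0L)
    cover <- cover + popcount(u, length(p$codes))
    cm <- rowSums(p$cnt[, mrows, drop = FALSE])
    cf <- rowSums(p$cnt[, frows, drop = FALSE])
    if (sum(cm) > 0 && sum(cf) > 0) {
      hsum <- hsum + (1 - sum((cm / sum(cm)) * (cf / sum(cf))))
      neval <- neval + 1L
    }
  }
  list(cover = cover, h_mean = if (neval > 0) hsum / neval else NA_real_)
}

# per-subset union masks: L x n_combos integer matrix
combo_masks <- function(prep, combos) {
  L <- length(prep)
  out <- matrix(0L, nrow = L, ncol = ncol(combos))
  for (r in seq_len(nrow(combos))) {
    mask_r <- vapply(prep, function(p) p$mask[combos[r, ]],
                     integer(ncol(combos)))
    mask_r <- if (is.matrix(mask_r)) t(mask_r) else matrix(mask_r, nrow = L)
    out <- matrix(bitwOr(out, mask_r), nrow = L)  # bitwOr drops dims
  }
  out
}

#' Search for the best group-spawning set
#'
#' Finds `m` males and `f` females whose pooled genotypes maximize the
#' number of alleles transmissible to the progeny (the sum over loci of
#' the parental-allele-union size), breaking ties by higher expected
#' progeny heterozygosity, then by lower group weak-heterozygote share,
#' then by the lexicographically smallest id tuple — so the result is
#' deterministic and invariant to panel row order.
#'
#' With `mode = "auto"` the search enumerates all C(M,m) x C(F,f)
#' candidate sets when their number is at most `limit`, and otherwise
#' falls back to `"greedy_exchange"`: greedy construction on the monotone
#' (and submodular) allele-coverage objective, followed by single-
#' individual swaps until no swap improves the (coverage, heterozygosity)
#' objective — a local optimum that matches the exhaustive optimum on all
#' small instances we test.
#'
#' @param panel A `genotype_panel`.
#' @param m,f Subset sizes.
#' @param mode `"auto"`, `"exhaustive"` or `"greedy_exchange"`.
#' @param limit Largest search-space size enumerated exhaustively.
#' @param seed Optional integer recorded with the result; the search
#'   itself is deterministic.
#' @return A `spawning_search` object: [tidy()] gives the per-locus
#'   transmitted-allele and heterozygosity table, [glance()] the one-row
#'   summary with the search-space accounting.
#' @examples
#' p <- guzy_like_fixture(seed = 1)
#' best <- search_best_set(p, m = 4, f = 4)
#' glance(best)
#' @export
search_best_set <- function(panel, m, f,
                            mode = c("auto", "exhaustive", "greedy_exchange"),
                            limit = 1e7, seed = NULL) {
  mode <- match.arg(mode)
  space <- search_space(panel, m, f)
  if (mode == "auto") {
    mode <- if (space$total_combinations <= limit) "exhaustive"
            else "greedy_exchange"
  }
  males <- sex_ids(panel, "male")
  females <- sex_ids(panel, "female")
  mrows_all <- match_ids(panel, males)
  frows_all <- match_ids(panel, females)
  prep <- group_eval_prep(panel)

  if (mode == "exhaustive") {
    if (space$total_combinations > limit) {
      abort(sprintf(
        "exhaustive search over %.3g sets exceeds limit %.3g; use greedy_exchange",
        space$total_combinations, limit))
    }
    hits <- exhaustive_cover_argmax(prep, mrows_all, frows_all, m, f)
    cand <- purrr::map(hits, function(h) {
      list(mrows = h$mrows, frows = h$frows,
           obj = eval_set(prep, h$mrows, h$frows))
    })
    best <- pick_best_candidate(panel, cand)
  } else {
    best <- greedy_exchange_search(panel, prep, mrows_all, frows_all, m, f)
  }
  male_ids <- sort(panel$id[best$mrows])
  female_ids <- sort(panel$id[best$frows])
  pred <- predict_group(panel, male_ids, female_ids)
  structure(
    list(male_ids = male_ids, female_ids = female_ids,
         prediction = pred, mode = mode, space = space, seed = seed),
    class = "spawning_search")
}

# all (male combo, female combo) pairs attaining the maximum total
# allele coverage; vectorized over female combos
exhaustive_cover_argmax <- function(prep, mrows_all, frows_all, m, f) {
  mc <- combn(mrows_all, m)
  fc <- combn(frows_all, f)
  nbits <- vapply(prep, function(p) length(p$codes), integer(1))
  mmask <- combo_masks(prep, mc)
  fmask <- combo_masks(prep, fc)
  best <- -1L
  hits <- list()
  for (i in seq_len(ncol(mc))) {
    u <- bitwOr(mmask[, i], fmask)  # recycles the male mask down columns
    if (!is.matrix(u)) u <- matrix(u, nrow = length(nbits))
    cov <- integer(ncol(u))
    for (l in seq_along(nbits)) {
      cov <- cov + popcount(u[l, ], nbits[l])
    }
    mx <- max(cov)
    if (mx > best) { best <- mx; hits <- list() }
    if (mx == best) {
      for (j in which(cov == mx)) {
        hits[[length(hits) + 1]] <- list(mrows = mc[, i], frows = fc[, j])
      }
    }
  }
  hits
}

# choose among equal-coverage candidates: higher h_mean, lower group
# weak-het share, then lexicographically smallest sorted id tuple
pick_best_candidate <- function(panel, cand) {
  h <- vapply(cand, function(cc) cc$obj$h_mean, numeric(1))
  keep <- which(abs(h - max(h)) < 1e-12)
  if (length(keep) > 1) {
    wh <- vapply(keep, function(i) {
      predict_group(panel, panel$id[cand[[i]]$mrows],
                    panel$id[cand[[i]]$frows])$summary$wh_share
    }, numeric(1))
    keep <- keep[abs(wh - min(wh)) < 1e-12]
  }
  if (length(keep) > 1) {
    key <- vapply(keep, function(i) {
      paste(c(sort(panel$id[cand[[i]]$mrows]),
              sort(panel$id[cand[[i]]$frows])), collapse = "|")
    }, character(1))
    keep <- keep[order(key)][1]
  }
  cand[[keep[1]]]
}

greedy_exchange_search <- function(panel, prep, mrows_all, frows_all, m, f) {
  sel_m <- integer(0)
  sel_f <- integer(0)
  # greedy construction on marginal allele coverage
  repeat {
    cand_rows <- c(if (length(sel_m) < m) setdiff(mrows_all, sel_m),
                   if (length(sel_f) < f) setdiff(frows_all, sel_f))
    if (length(cand_rows) == 0) break
    base <- eval_set(prep, sel_m, sel_f)$cover
    gain <- vapply(cand_rows, function(r) {
      if (r %in% mrows_all) eval_set(prep, c(sel_m, r), sel_f)$cover - base
      else eval_set(prep, sel_m, c(sel_f, r))$cover - base
    }, numeric(1))
    ord <- order(-gain, panel$id[cand_rows])
    pick <- cand_rows[ord[1]]
    if (pick %in% mrows_all) sel_m <- c(sel_m, pick) else sel_f <- c(sel_f, pick)
    if (length(sel_m) == m && length(sel_f) == f) break
  }
  # 1-swap local exchange on the (coverage, heterozygosity) objective
  better <- function(a, b) {
    a$cover > b$cover || (a$cover == b$cover && isTRUE(a$h_mean > b$h_mean + 1e-12))
  }
  first_improving_swap <- function() {
    cur <- eval_set(prep, sel_m, sel_f)
    for (side in c("m", "f")) {
      sel <- if (side == "m") sel_m else sel_f
      pool <- if (side == "m") setdiff(mrows_all, sel_m)
              else setdiff(frows_all, sel_f)
      for (s in sel) for (p in pool) {
        trial_m <- if (side == "m") c(setdiff(sel_m, s), p) else sel_m
        trial_f <- if (side == "f") c(setdiff(sel_f, s), p) else sel_f
        if (better(eval_set(prep, trial_m, trial_f), cur)) {
          return(list(m = trial_m, f = trial_f))
        }
      }
    }
    NULL
  }
  repeat {
    swap <- first_improving_swap()
    if (is.null(swap)) break
    sel_m <- swap$m
    sel_f <- swap$f
  }
  list(mrows = sel_m, frows = sel_f, obj = eval_set(prep, sel_m, sel_f))
}

#' List alternative group-spawning sets
#'
#' Exhaustively enumerates all C(M,m) x C(F,f) candidate sets and returns
#' those transmitting at least `min_alleles` alleles with expected progeny
#' heterozygosity inside `h_range`, ranked by transmitted alleles then
#' heterozygosity (both descending). Useful for finding near-optimal
#' alternatives when the nominal best set is impractical (e.g. a fish
#' dies or fails to spawn).
#'
#' @inheritParams search_best_set
#' @param min_alleles Minimum transmitted-allele count to keep.
#' @param h_range Length-2 numeric: inclusive bounds on `h_mean`.
#' @param limit Refuse enumeration when the search space exceeds this.
#' @return A tibble with list-columns `male_ids`, `female_ids` and columns
#'   `ar_total`, `h_mean`, `rank`.
#' @export
list_alternative_sets <- function(panel, m, f, min_alleles,
                                  h_range = c(0, 1), limit = 1e6) {
  space <- search_space(panel, m, f)
  if (space$total_combinations > limit) {
    abort(sprintf(
      "search space of %.3g sets exceeds limit %.3g; exhaustive listing is infeasible",
      space$total_combinations, limit))
  }
  males <- sex_ids(panel, "male")
  females <- sex_ids(panel, "female")
  mrows_all <- match_ids(panel, males)
  frows_all <- match_ids(panel, females)
  prep <- group_eval_prep(panel)
  mc <- combn(mrows_all, m)
  fc <- combn(frows_all, f)
  rows <- list()
  for (i in seq_len(ncol(mc))) for (j in seq_len(ncol(fc))) {
    obj <- eval_set(prep, mc[, i], fc[, j])
    if (obj$cover >= min_alleles && !is.na(obj$h_mean) &&
        obj$h_mean >= h_range[1] && obj$h_mean <= h_range[2]) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        male_ids = list(sort(panel$id[mc[, i]])),
        female_ids = list(sort(panel$id[fc[, j]])),
        ar_total = obj$cover, h_mean = obj$h_mean)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(male_ids = list(), female_ids = list(),
                          ar_total = integer(), h_mean = numeric(),
                          rank = integer()))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$ar_total, -out$h_mean), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' @exportS3Method generics::tidy
tidy.spawning_search <- function(x, ...) x$prediction$per_locus

#' @exportS3Method generics::glance
glance.spawning_search <- function(x, ...) {
  s <- x$prediction$summary
  tibble::tibble(
    mode = x$mode,
    n_males = s$n_males, n_females = s$n_females,
    ar_total = s$ar_total, h_mean = s$h_mean, wh_share = s$wh_share,
    male_subsets = x$space$male_subsets,
    female_subsets = x$space$female_subsets,
    total_combinations = x$space$total_combinations)
}

#' @export
print.spawning_search <- function(x, ...) {
  s <- x$prediction$summary
  cat(sprintf("# group-spawning set (%s search over %.6g combinations)\n",
              x$mode, x$space$total_combinations))
  cat("# males:  ", paste(x$male_ids, collapse = ", "), "\n")
  cat("# females:", paste(x$female_ids, collapse = ", "), "\n")
  cat(sprintf("# alleles transmitted = %d, progeny H = %.3f, weak-het share = %.3f\n",
              s$ar_total, s$h_mean, s$wh_share))
  invisible(x)
}

#' @describeIn search_best_set Per-locus plot of the chosen set's
#'   transmitted alleles and expected heterozygosity.
#' @param object A `spawning_search`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.spawning_search <- function(object, ...) {
  autoplot(object$prediction)
}
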