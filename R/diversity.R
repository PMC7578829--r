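#' Per-locus diversity statistics
#'
#' Observed heterozygosity `Ho` is the fraction of called genotypes at a
#' locus carrying two distinct alleles; missing genotypes are excluded from
#' numerator and denominator. Expected heterozygosity `He` is computed from
#' the allele frequencies `p_k` over the `2n` called allele copies as
#' `1 - sum(p_k^2)` (the plug-in estimator); with `unbiased = TRUE` it is
#' multiplied by `2n / (2n - 1)` (Nei's small-sample correction).
#'
#' @param panel A `genotype_panel`.
#' @param locus Locus name.
#' @param ids Optional character vector restricting the computation to a
#'   subset of individuals.
#' @param unbiased Apply the `2n/(2n-1)` correction to He.
#' @return A single numeric value.
#' @examples
#' p <- guzy_like_fixture(seed = 1)
#' observed_heterozygosity(p, panel_loci(p)[1])
#' @export
observed_heterozygosity <- function(panel, locus, ids = NULL) {
  al <- locus_alleles(panel, locus, ids)
  called <- !is.na(al[, 1]) & !is.na(al[, 2])
  if (!any(called)) {
    abort(paste0("no called genotype at locus '", locus,
                 "': Ho is undefined"))
  }
  mean(al[called, 1] != al[called, 2])
}

#' @rdname observed_heterozygosity
#' @export
expected_heterozygosity <- function(panel, locus, ids = NULL,
                                    unbiased = FALSE) {
  al <- locus_alleles(panel, locus, ids)
  copies <- al[!is.na(al)]
  if (length(copies) == 0) {
    abort(paste0("no called genotype at locus '", locus,
                 "': He is undefined"))
  }
  p <- tabulate(factor(copies)) / length(copies)
  he <- 1 - sum(p^2)
  if (unbiased) he <- he * length(copies) / (length(copies) - 1)
  he
}

#' Distinct-allele counts per locus
#'
#' Counts the distinct non-missing allele codes at each locus. The total
#' across loci (`sum(allele_counts(panel)$n_alleles)`) is the panel's
#' allele inventory size. Note this is the raw allele count, not
#' rarefaction-corrected allelic richness.
#'
#' @inheritParams observed_heterozygosity
#' @return A tibble with columns `locus` and `n_alleles`.
#' @export
allele_counts <- function(panel, ids = NULL) {
  loci <- panel_loci(panel)
  tibble::tibble(
    locus = loci,
    n_alleles = vapply(loci, function(l) {
      al <- locus_alleles(panel, l, ids)
      length(unique(al[!is.na(al)]))
    }, integer(1), USE.NAMES = FALSE)
  )
}

#' Summarize the genetic diversity of a group
#'
#' Combines observed heterozygosity, expected heterozygosity and allele
#' counts per locus for the whole panel or a named subset, plus across-loci
#' aggregates: unweighted means of Ho and He over loci with at least one
#' called genotype, and the summed allele count `ar_total`.
#'
#' @inheritParams observed_heterozygosity
#' @return A `diversity_summary` object; use [tidy()] for the per-locus
#'   table and [glance()] for the one-row across-loci summary.
#' @examples
#' p <- guzy_like_fixture(seed = 1)
#' s <- diversity_summary(p)
#' glance(s)
#' @export
diversity_summary <- function(panel, ids = NULL, unbiased = FALSE) {
  if (!is.null(ids)) match_ids(panel, ids)  # fail fast on unknown ids
  loci <- panel_loci(panel)
  per_locus <- purrr::map_dfr(loci, function(l) {
    al <- locus_alleles(panel, l, ids)
    called <- !is.na(al[, 1]) & !is.na(al[, 2])
    n_typed <- sum(called)
    tibble::tibble(
      locus = l,
      n_typed = n_typed,
      ho = if (n_typed > 0) mean(al[called, 1] != al[called, 2]) else NA_real_,
      he = if (n_typed > 0) expected_heterozygosity(panel, l, ids, unbiased)
           else NA_real_,
      n_alleles = length(unique(al[!is.na(al)]))
    )
  })
  structure(
    list(per_locus = per_locus,
         overall = tibble::tibble(
           ho = mean(per_locus$ho, na.rm = TRUE),
           he = mean(per_locus$he, na.rm = TRUE),
           ar_total = sum(per_locus$n_alleles),
           n_loci = length(loci),
           n_individuals = if (is.null(ids)) nrow(panel) else length(ids)
         ),
         unbiased = unbiased),
    class = "diversity_summary")
}

#' @exportS3Method generics::tidy
tidy.diversity_summary <- function(x, ...) x$per_locus

#' @exportS3Method generics::glance
glance.diversity_summary <- function(x, ...) x$overall

#' @export
print.diversity_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "# diversity summary: %d individuals, %d loci\n# Ho = %.3f, He = %.3f%s, total alleles = %d\n",
    o$n_individuals, o$n_loci, o$ho, o$he,
    if (x$unbiased) " (unbiased)" else "", o$ar_total))
  print(x$per_locus)
  invisible(x)
}

#' @describeIn diversity_summary Bar chart of per-locus Ho and He.
#' @param object A `diversity_summary`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.diversity_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_locus, c("ho", "he"),
                           names_to = "statistic", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus, y = .data$value,
                                  fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(ho = "#2166ac", he = "#b2182b"),
                               labels = c(ho = "observed", he = "expected")) +
    ggplot2::labs(x = NULL, y = "heterozygosity", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Group-level share of weak heterozygotes
#'
#' One operationalization of a group's weak-heterozygote burden: the mean
#' of the pair-level expected weak-heterozygote share
#' ([pair_weak_het_share()]) over all male-by-female pairs that can be
#' formed within the group. Pair-level shares are well defined by the
#' Mendelian model; how to aggregate them to a group is a modelling
#' choice, and this mean-over-pairs version is the one used throughout
#' the package.
#'
#' @inheritParams observed_heterozygosity
#' @return A fraction in `[0, 0.5]`.
#' @export
group_weak_het_share <- function(panel, ids = NULL) {
  sub <- if (is.null(ids)) panel else panel_subset(panel, ids)
  mean(enumerate_pairs(sub)$wh_share, na.rm = TRUE)
}
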