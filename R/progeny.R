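#' Mendelian offspring enumeration for one locus
#'
#' A dam and a sire each transmit one of their two allele copies with equal
#' probability, so a pair's offspring genotype at a locus is one of four
#' equally likely combinations. This enumeration is the basis (and the
#' brute-force oracle) for all closed-form pair statistics.
#'
#' @param gm,gf Length-2 integer vectors: the male's and female's alleles
#'   at the locus. Either may contain `NA` only as a fully missing
#'   genotype, which makes the locus non-evaluable.
#' @return A tibble with 4 rows (`a1` paternal, `a2` maternal allele), each
#'   an equally likely offspring genotype, or `NULL` if either parent is
#'   uncalled.
#' @examples
#' pair_offspring(c(1L, 2L), c(1L, 2L))  # Punnett square of AB x AB
#' @export
pair_offspring <- function(gm, gf) {
  if (anyNA(gm) || anyNA(gf)) return(NULL)
  tidyr::expand_grid(a1 = as.integer(gm), a2 = as.integer(gf))
}

#' Closed-form per-locus pair statistics
#'
#' For a called sire genotype `gm` and dam genotype `gf`:
#' * `pair_expected_heterozygosity()` — the fraction of the four equally
#'   likely offspring genotypes with two distinct alleles, i.e.
#'   `mean(outer(gm, gf, "!="))`; always one of 0, 0.25, 0.5, 0.75, 1.
#' * `pair_allele_count()` — the number of distinct alleles among the four
#'   parental copies (1 to 4); every parental allele is transmissible, so
#'   this is the allele diversity attainable in a progeny group.
#' * `pair_is_weak()` — `TRUE` when the four parental copies carry exactly
#'   two distinct alleles in a 3:1 pattern (e.g. AAAB): half the offspring
#'   are then heterozygotes differing from homozygosity by a single allele
#'   copy ("weak" heterozygotes).
#'
#' All return `NA` when either genotype is uncalled.
#'
#' @inheritParams pair_offspring
#' @return A scalar (numeric, integer, logical respectively).
#' @export
pair_expected_heterozygosity <- function(gm, gf) {
  if (anyNA(gm) || anyNA(gf)) return(NA_real_)
  mean(outer(gm, gf, "!="))
}

#' @rdname pair_expected_heterozygosity
#' @export
pair_allele_count <- function(gm, gf) {
  if (anyNA(gm) || anyNA(gf)) return(NA_integer_)
  length(unique(c(gm, gf)))
}

#' @rdname pair_expected_heterozygosity
#' @export
pair_is_weak <- function(gm, gf) {
  if (anyNA(gm) || anyNA(gf)) return(NA)
  counts <- sort(tabulate(factor(c(gm, gf))))
  identical(as.integer(counts), c(1L, 3L))
}

#' Share of weak heterozygotes expected in a pair's progeny
#'
#' The mean over evaluable loci (both parents called) of the expected
#' fraction of offspring at that locus that are weak heterozygotes: 0.5
#' where the parental copies show the 3:1 AAAB pattern, 0 otherwise.
#'
#' @param panel A `genotype_panel`.
#' @param male_id,female_id Individual ids of the sire and dam.
#' @return A fraction in `[0, 0.5]`.
#' @export
pair_weak_het_share <- function(panel, male_id, female_id) {
  predict_pair(panel, male_id, female_id)$wh_share
}

#' Predict progeny diversity for one breeding pair
#'
#' Assembles the per-locus Mendelian statistics for a sire/dam pair and
#' aggregates them: `h_mean` is the mean expected progeny heterozygosity
#' over evaluable loci, `ar_total` the summed parental-allele count over
#' evaluable loci, and `wh_share` the expected share of weak heterozygous
#' offspring. A locus where either parent is uncalled is excluded from all
#' three aggregates.
#'
#' @inheritParams pair_weak_het_share
#' @return A `pair_prediction` object; [tidy()] gives the per-locus table,
#'   [glance()] the one-row aggregate.
#' @examples
#' p <- guzy_like_fixture(seed = 1)
#' glance(predict_pair(p, sex_ids(p, "male")[1], sex_ids(p, "female")[1]))
#' @export
predict_pair <- function(panel, male_id, female_id) {
  im <- match_ids(panel, male_id)
  if_ <- match_ids(panel, female_id)
  if (panel$sex[im] != "male" || panel$sex[if_] != "female") {
    abort(sprintf("'%s' must be male and '%s' female", male_id, female_id))
  }
  loci <- panel_loci(panel)
  per_locus <- purrr::map_dfr(loci, function(l) {
    gm <- locus_alleles(panel, l)[im, ]
    gf <- locus_alleles(panel, l)[if_, ]
    tibble::tibble(
      locus = l,
      evaluable = !anyNA(gm) && !anyNA(gf),
      h_exp = pair_expected_heterozygosity(gm, gf),
      n_alleles = pair_allele_count(gm, gf),
      weak = pair_is_weak(gm, gf)
    )
  })
  ev <- per_locus[per_locus$evaluable, , drop = FALSE]
  if (nrow(ev) == 0) {
    abort(sprintf("pair %s x %s has no evaluable locus", male_id, female_id))
  }
  structure(
    list(male_id = male_id, female_id = female_id, per_locus = per_locus,
         summary = tibble::tibble(
           male_id = male_id, female_id = female_id,
           h_mean = mean(ev$h_exp),
           ar_total = sum(ev$n_alleles),
           wh_share = mean(0.5 * ev$weak),
           n_loci_evaluable = nrow(ev))),
    class = "pair_prediction")
}

#' @exportS3Method generics::tidy
tidy.pair_prediction <- function(x, ...) x$per_locus

#' @exportS3Method generics::glance
glance.pair_prediction <- function(x, ...) x$summary

#' @export
print.pair_prediction <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "# pair %s x %s: H = %.3f, alleles = %d, weak-het share = %.3f (%d loci)\n",
    s$male_id, s$female_id, s$h_mean, s$ar_total, s$wh_share,
    s$n_loci_evaluable))
  invisible(x)
}

#' Predict progeny diversity for a group-spawning set
#'
#' Models volitional group spawning under the equal-contribution
#' assumption: every selected sire is equally likely to father an
#' offspring, every dam equally likely to mother it, and each parent
#' transmits either allele copy with probability 1/2. Per locus,
#' `alleles_transmitted` is the size of the union of called parental
#' alleles over the whole set, and `h_exp = 1 - sum_k p_m(k) * p_f(k)`
#' where `p_m` and `p_f` are the allele frequencies in the selected males'
#' and females' called copies. A parent uncalled at a locus drops out of
#' that locus's frequency pool; a locus with no called parent of either
#' sex is non-evaluable and excluded from the aggregates. The group's
#' weak-heterozygote share is the mean of [pair_weak_het_share()] over all
#' male-by-female member pairs with at least one evaluable locus.
#'
#' @param panel A `genotype_panel`.
#' @param male_ids,female_ids Non-empty character vectors of member ids.
#' @return A `spawning_prediction` object; [tidy()] gives the per-locus
#'   table, [glance()] the one-row aggregate (`ar_total`, `h_mean`,
#'   `wh_share`).
#' @export
predict_group <- function(panel, male_ids, female_ids) {
  if (length(male_ids) == 0 || length(female_ids) == 0) {
    abort("male_ids and female_ids must be non-empty")
  }
  rm_ <- match_ids(panel, male_ids)
  rf_ <- match_ids(panel, female_ids)
  if (any(panel$sex[rm_] != "male")) abort("male_ids contains a non-male")
  if (any(panel$sex[rf_] != "female")) abort("female_ids contains a non-female")
  loci <- panel_loci(panel)
  per_locus <- purrr::map_dfr(loci, function(l) {
    al <- locus_alleles(panel, l)
    am <- al[rm_, , drop = FALSE]
    af <- al[rf_, , drop = FALSE]
    pm <- sex_pool_freqs(am)
    pf <- sex_pool_freqs(af)
    union_alleles <- unique(c(am[!is.na(am)], af[!is.na(af)]))
    evaluable <- length(pm) > 0 && length(pf) > 0
    h <- if (evaluable) {
      shared <- intersect(names(pm), names(pf))
      1 - sum(pm[shared] * pf[shared])
    } else NA_real_
    tibble::tibble(locus = l, evaluable = evaluable,
                   alleles_transmitted = length(union_alleles), h_exp = h)
  })
  ev <- per_locus[per_locus$evaluable, , drop = FALSE]
  if (nrow(ev) == 0) abort("spawning set has no evaluable locus")
  wh <- purrr::map_dbl(male_ids, function(m) {
    mean(purrr::map_dbl(female_ids, function(f) {
      tryCatch(predict_pair(panel, m, f)$summary$wh_share,
               error = function(e) NA_real_)
    }), na.rm = TRUE)
  })
  structure(
    list(male_ids = male_ids, female_ids = female_ids, per_locus = per_locus,
         summary = tibble::tibble(
           n_males = length(male_ids), n_females = length(female_ids),
           ar_total = sum(ev$alleles_transmitted),
           h_mean = mean(ev$h_exp),
           wh_share = mean(wh, na.rm = TRUE),
           n_loci_evaluable = nrow(ev))),
    class = "spawning_prediction")
}

# allele frequencies among called copies, each called parent weighted
# equally (each of their two copies weight 1/2)
sex_pool_freqs <- function(al) {
  called <- !is.na(al[, 1]) & !is.na(al[, 2])
  if (!any(called)) return(numeric(0))
  copies <- c(al[called, 1], al[called, 2])
  tab <- table(copies)
  setNames(as.numeric(tab) / length(copies), names(tab))
}

#' @exportS3Method generics::tidy
tidy.spawning_prediction <- function(x, ...) x$per_locus

#' @exportS3Method generics::glance
glance.spawning_prediction <- function(x, ...) x$summary

#' @export
print.spawning_prediction <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "# spawning set: %d males x %d females\n# alleles transmitted = %d, progeny H = %.3f, weak-het share = %.3f\n",
    s$n_males, s$n_females, s$ar_total, s$h_mean, s$wh_share))
  print(x$per_locus)
  invisible(x)
}

#' @describeIn predict_group Per-locus transmitted-allele counts and
#'   expected progeny heterozygosity as a two-panel bar chart.
#' @param object A `spawning_prediction`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.spawning_prediction <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_locus,
                           c("alleles_transmitted", "h_exp"),
                           names_to = "statistic", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus, y = .data$value)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          alleles_transmitted = "alleles transmitted",
                          h_exp = "expected progeny heterozygosity"))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
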