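#' Genotype panels
#'
#' A genotype panel is a tibble holding one row per individual with four
#' metadata columns (`group`, `population`, `sex`, `id`) followed by two
#' integer allele columns per locus, named `<locus>.a1` and `<locus>.a2`.
#' Alleles are positive integer codes (microsatellite fragment lengths in
#' bp, or arbitrary codes); `NA` in both columns of a locus marks a missing
#' genotype. Genotypes are unordered pairs: every statistic in the package
#' is invariant to swapping `.a1` and `.a2`.
#'
#' `as_genotype_panel()` builds a panel from a plain data frame laid out as
#' above (allele columns in locus order, two per locus). It checks
#' structure — unique ids, unique locus names, positive allele codes — but
#' does not reject content problems such as half-called genotypes or a
#' single-sex panel; those are reported by [validate_panel()] and rejected
#' by [read_panel()].
#'
#' @param x A data frame with columns `group`, `population`, `sex`, `id`
#'   and two allele columns per locus.
#' @param loci Character vector of locus names, one per column pair. If
#'   `NULL`, names are derived from the allele column names by stripping a
#'   trailing `.a1`/`.a2` (or `_1`/`_2`, `.1`/`.2`) suffix.
#' @param sex_aliases Named list mapping canonical sex labels (`male`,
#'   `female`) to accepted case-insensitive aliases.
#' @return A `genotype_panel` tibble.
#' @examples
#' df <- data.frame(
#'   group = "G", population = "P", sex = c("M", "F"), id = c("i1", "i2"),
#'   LocA.a1 = c(152L, 152L), LocA.a2 = c(160L, 152L)
#' )
#' as_genotype_panel(df)
#' @export
as_genotype_panel <- function(x, loci = NULL,
                              sex_aliases = default_sex_aliases()) {
  x <- tibble::as_tibble(x, .name_repair = "minimal")
  meta <- c("group", "population", "sex", "id")
  if (!all(meta %in% names(x)[1:4])) {
    abort("first four columns must be 'group', 'population', 'sex', 'id'")
  }
  allele_cols <- setdiff(names(x), meta)
  if (length(allele_cols) %% 2 != 0 || length(allele_cols) == 0) {
    abort("allele columns must come in pairs, two per locus")
  }
  n_loci <- length(allele_cols) / 2
  if (is.null(loci)) {
    first_of_pair <- allele_cols[seq(1, by = 2, length.out = n_loci)]
    loci <- sub("([._](a?[12]))$", "", first_of_pair)
  }
  if (length(loci) != n_loci) abort("`loci` length must match column pairs")
  if (anyDuplicated(loci)) abort("duplicate locus names")
  if (any(!nzchar(loci))) abort("empty locus name")

  out <- x[meta]
  out$group <- as.character(out$group)
  out$population <- as.character(out$population)
  out$id <- as.character(out$id)
  out$sex <- normalize_sex(out$sex, sex_aliases)
  if (anyDuplicated(out$id)) {
    abort(paste0("duplicate individual id: ",
                 paste(unique(out$id[duplicated(out$id)]), collapse = ", ")))
  }
  for (j in seq_len(n_loci)) {
    for (k in 1:2) {
      a <- x[[allele_cols[2 * (j - 1) + k]]]
      a <- suppressWarnings(as.integer(a))
      a[!is.na(a) & a <= 0] <- NA_integer_  # 0 is the missing-data sentinel
      out[[paste0(loci[j], ".a", k)]] <- a
    }
  }
  structure(out, loci = loci,
            class = c("genotype_panel", class(tibble::tibble())))
}

#' @rdname as_genotype_panel
#' @export
default_sex_aliases <- function() {
  list(male = c("m", "male", "1"), female = c("f", "female", "2"))
}

normalize_sex <- function(sex, aliases = default_sex_aliases()) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  for (canon in names(aliases)) {
    out[s %in% tolower(c(canon, aliases[[canon]]))] <- canon
  }
  if (anyNA(out)) {
    abort(paste0("unknown sex label: ",
                 paste(unique(sex[is.na(out)]), collapse = ", ")))
  }
  out
}

#' @rdname as_genotype_panel
#' @export
panel_loci <- function(x) attr(x, "loci", exact = TRUE)

#' Individual ids of one sex
#'
#' @param panel A `genotype_panel`.
#' @param sex `"male"` or `"female"`.
#' @return Character vector of ids in panel (file) order.
#' @export
sex_ids <- function(panel, sex = c("male", "female")) {
  sex <- match.arg(sex)
  panel$id[panel$sex == sex]
}

# n x 2 integer matrix of alleles at one locus, rows in panel order
locus_alleles <- function(panel, locus, ids = NULL) {
  loci <- panel_loci(panel)
  if (!locus %in% loci) abort(paste0("unknown locus: ", locus))
  rows <- if (is.null(ids)) seq_len(nrow(panel)) else match_ids(panel, ids)
  cbind(panel[[paste0(locus, ".a1")]][rows],
        panel[[paste0(locus, ".a2")]][rows])
}

match_ids <- function(panel, ids) {
  rows <- match(ids, panel$id)
  if (anyNA(rows)) {
    abort(paste0("unknown individual id: ",
                 paste(ids[is.na(rows)], collapse = ", ")))
  }
  rows
}

#' @export
print.genotype_panel <- function(x, ...) {
  loci <- panel_loci(x)
  cat(sprintf("# genotype panel: %d individuals (%d male, %d female), %d loci\n",
              nrow(x), sum(x$sex == "male"), sum(x$sex == "female"),
              length(loci)))
  NextMethod()
  invisible(x)
}

#' Check a genotype panel for content problems
#'
#' Returns a tibble of issues rather than raising, so a problematic panel
#' can be inspected. Error-severity issues are: half-called genotypes (one
#' allele present, the other missing) and a sex composition with no males
#' or no females (downstream pair selection needs both). Loci with no
#' called genotype at all are reported as warnings.
#'
#' @param panel A `genotype_panel`.
#' @return A tibble with columns `severity` (`"error"`/`"warning"`), `id`,
#'   `locus`, `message`; zero rows if the panel is clean.
#' @export
validate_panel <- function(panel) {
  issues <- list()
  add <- function(severity, id, locus, message) {
    issues[[length(issues) + 1]] <<-
      tibble::tibble(severity = severity, id = id, locus = locus,
                     message = message)
  }
  for (locus in panel_loci(panel)) {
    al <- locus_alleles(panel, locus)
    half <- xor(is.na(al[, 1]), is.na(al[, 2]))
    for (i in which(half)) {
      add("error", panel$id[i], locus,
          "half-called genotype (one allele present, one missing)")
    }
    if (all(is.na(al))) {
      add("warning", NA_character_, locus, "no called genotype at locus")
    }
  }
  for (s in c("male", "female")) {
    if (!any(panel$sex == s)) {
      add("error", NA_character_, NA_character_,
          paste0("panel contains no ", s, "s; pair selection needs both sexes"))
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(severity = character(), id = character(),
                   locus = character(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Restrict a panel to a subset of individuals
#'
#' @param panel A `genotype_panel`.
#' @param ids Character vector of individual ids (panel order is kept).
#' @return A `genotype_panel` with only those individuals.
#' @export
panel_subset <- function(panel, ids) {
  rows <- sort(match_ids(panel, ids))
  as_genotype_panel(tibble::as_tibble(unclass(panel))[rows, , drop = FALSE],
                    loci = panel_loci(panel))
}
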