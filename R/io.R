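#' Read a genotype panel from a delimited text table
#'
#' Expects the broodstock-table layout: a header row, four leading metadata
#' columns (group, population, sex, id) and then two adjacent allele
#' columns per locus. The locus name is taken from the header of the first
#' column of each pair (a trailing `.a1`/`_1`/`.1` suffix, if present, is
#' stripped); the second header of the pair is ignored, so headers of the
#' form `Loc,Loc` or `Loc,` both work. Allele code 0 and blank cells are
#' missing data.
#'
#' The reader rejects rows of the wrong width, unknown sex labels,
#' duplicate ids, and half-called genotypes (only one allele of a pair
#' present), naming the offending row, individual or locus.
#'
#' @param path Path to the table.
#' @param delim Field delimiter: `","`, `"\t"` or `";"`. `NULL` guesses
#'   from the first line.
#' @param sex_aliases See [as_genotype_panel()].
#' @return A `genotype_panel`.
#' @seealso [write_panel()], [as_genotype_panel()]
#' @export
read_panel <- function(path, delim = NULL,
                       sex_aliases = default_sex_aliases()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort("input has no data rows")
  if (is.null(delim)) {
    delim <- c(",", "\t", ";")[which.max(vapply(
      c(",", "\t", ";"), function(d) lengths(strsplit(lines[1], d, fixed = TRUE)),
      integer(1)))]
  }
  cells <- strsplit(lines, delim, fixed = TRUE)
  header <- trimws(cells[[1]])
  width <- length(header)
  if (width < 6 || (width - 4) %% 2 != 0) {
    abort("header must have 4 metadata columns plus two columns per locus")
  }
  n_loci <- (width - 4) / 2
  loci <- sub("([._](a?[12]))$", "",
              header[4 + seq(1, by = 2, length.out = n_loci)])
  body <- cells[-1]
  bad <- which(lengths(body) != width)
  if (length(bad) > 0) {
    abort(sprintf("row %d has %d fields, expected %d",
                  bad[1] + 1L, lengths(body)[bad[1]], width))
  }
  m <- matrix(trimws(unlist(body)), ncol = width, byrow = TRUE)
  df <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE),
                          .name_repair = "minimal")
  names(df) <- c("group", "population", "sex", "id",
                 paste0(rep(loci, each = 2), ".a", rep(1:2, n_loci)))
  panel <- as_genotype_panel(df, loci = loci, sex_aliases = sex_aliases)
  issues <- validate_panel(panel)
  half <- issues[issues$severity == "error" &
                   grepl("half-called", issues$message), , drop = FALSE]
  if (nrow(half) > 0) {
    abort(sprintf("half-called genotype for individual '%s' at locus '%s'",
                  half$id[1], half$locus[1]))
  }
  panel
}

#' Write a genotype panel
#'
#' `"table"` writes the native delimited layout that [read_panel()] reads
#' back unchanged (missing alleles written as 0); output is bit-stable for
#' a given panel. `"genepop"` writes a Genepop file with one `POP` block
#' and zero-padded 3-digit allele codes (missing = `000`), for use with
#' standard population-genetics software; allele codes above 999 cannot be
#' represented and raise an error suggesting recoding.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @param format `"table"` or `"genepop"`.
#' @param delim Field delimiter for `"table"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("table", "genepop"),
                        delim = ",") {
  format <- match.arg(format)
  loci <- panel_loci(panel)
  if (any(!nzchar(loci))) abort("cannot export a panel with empty locus names")
  if (format == "table") {
    header <- c("group", "population", "sex", "id", rep(loci, each = 2))
    acols <- paste0(rep(loci, each = 2), ".a", rep(1:2, length(loci)))
    body <- cbind(panel$group, panel$population, panel$sex, panel$id,
                  vapply(acols, function(cl) {
                    a <- panel[[cl]]
                    ifelse(is.na(a), "0", as.character(a))
                  }, character(nrow(panel))))
    lines <- c(paste(header, collapse = delim),
               apply(body, 1, paste, collapse = delim))
  } else {
    codes <- unlist(lapply(loci, function(l) locus_alleles(panel, l)))
    if (any(codes > 999, na.rm = TRUE)) {
      abort(paste0("allele codes above 999 cannot be written as Genepop ",
                   "3-digit codes; recode alleles (e.g. rank by size) first"))
    }
    geno <- vapply(loci, function(l) {
      al <- locus_alleles(panel, l)
      al[is.na(al)] <- 0L
      sprintf("%03d%03d", al[, 1], al[, 2])
    }, character(nrow(panel)))
    geno <- matrix(geno, nrow = nrow(panel))
    lines <- c("broodstock genotype panel export", loci, "POP",
               paste0(panel$id, " , ",
                      apply(geno, 1, paste, collapse = " ")))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
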