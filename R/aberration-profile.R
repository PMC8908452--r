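# Per-metaphase classification of aberration events, clonal (CCA) versus
# non-clonal (NCCA) calls, and the per-individual / per-group frequency
# tables of chromosomal variants and alterations.

# Tally columns, in table order.
TALLY_CATEGORIES <- c("monosomies", "trisomies", "scas", "chtb_chrb",
                      "fra_other", "fra_9q12", "cv_1qh", "cv_9qh",
                      "cv_inv9", "cv_16qh")

category_group_of <- function(e) {
  if (e$category == "loss") return("monosomies")
  if (e$category %in% c("gain", "marker_gain")) return("trisomies")
  if (e$category %in% CAT_SCA) return("scas")
  if (e$category %in% CAT_BREAK) return("chtb_chrb")
  if (e$category == "fra") {
    if (identical(e$chromosomes, "9") && identical(e$breakpoints, "q12"))
      return("fra_9q12")
    return("fra_other")
  }
  switch(e$category,
         cv_1qh_plus = "cv_1qh", cv_9qh_plus = "cv_9qh",
         cv_16qh_plus = "cv_16qh", cv_inv9 = "cv_inv9",
         stop(sprintf("unclassifiable category '%s'", e$category)))
}

#' Classify the aberration events of one metaphase
#'
#' Maps each parsed event onto the tally category groups (monosomies,
#' trisomies, structural alterations, breaks, fragilities, heterochromatic
#' variants). Numerical alterations implied by the sex-chromosome complement
#' are resolved against the individual's constitutional sex: a 45,X
#' complement in a constitutionally XY individual is a monosomy of Y, in an
#' XX individual a monosomy of X; an XXX complement in an XX individual is a
#' trisomy of X.
#'
#' If the chromosome count disagrees with what the events explain, a warning
#' is raised and only the events explicit in the string are kept (the
#' complement-derived inference is dropped).
#'
#' @param r a `metaphase_record`.
#' @param constitutional_sex `"XX"` or `"XY"`.
#' @return a tibble with columns `category_group`, `chromosome` (";"-joined
#'   for multi-chromosome events, `NA` for marker gains) and `key`, the
#'   canonical token used for clonality matching.
#' @export
classify_metaphase <- function(r, constitutional_sex = c("XX", "XY")) {
  stopifnot(inherits(r, "metaphase_record"))
  constitutional_sex <- match.arg(constitutional_sex)

  rows <- lapply(r$events, function(e) {
    tibble::tibble(
      category_group = category_group_of(e),
      chromosome = if (length(e$chromosomes))
        paste(e$chromosomes, collapse = ";") else NA_character_,
      key = format_aberration(e))
  })
  out <- if (length(rows)) dplyr::bind_rows(rows)
  else tibble::tibble(category_group = character(0),
                      chromosome = character(0), key = character(0))

  # Sex-complement inference.
  inferred <- NULL
  comp <- r$sex_complement
  if (comp != constitutional_sex) {
    comp_n <- table(factor(strsplit(comp, "")[[1]], c("X", "Y")))
    cons_n <- table(factor(strsplit(constitutional_sex, "")[[1]], c("X", "Y")))
    d <- comp_n - cons_n
    inf_rows <- list()
    for (chr in c("X", "Y")) {
      if (d[[chr]] <= -1L)
        inf_rows <- c(inf_rows, rep(list(tibble::tibble(
          category_group = "monosomies", chromosome = chr,
          key = paste0("-", chr))), -d[[chr]]))
      if (d[[chr]] >= 1L)
        inf_rows <- c(inf_rows, rep(list(tibble::tibble(
          category_group = "trisomies", chromosome = chr,
          key = paste0("+", chr))), d[[chr]]))
    }
    inferred <- dplyr::bind_rows(inf_rows)
  }

  n_gain <- sum(out$category_group == "trisomies") +
    sum(inferred$category_group == "trisomies")
  n_loss <- sum(out$category_group == "monosomies") +
    sum(inferred$category_group == "monosomies")
  expected <- 46L + n_gain - n_loss
  if (r$chromosome_count != expected) {
    warning(sprintf(
      "record %s/%s: chromosome count %d disagrees with events (expected %d); keeping explicit events only",
      r$individual_id, r$metaphase_id, r$chromosome_count, expected),
      call. = FALSE)
    return(out)
  }
  dplyr::bind_rows(out, inferred)
}

#' Call clonal versus non-clonal aberrations for one individual
#'
#' An identical structural aberration or identical gain found in at least 2
#' metaphases, or an identical loss found in at least 3 metaphases, defines
#' a clone (CCA); anything rarer is non-clonal (NCCA). Fragilities, breaks
#' and heterochromatic variants are never given clonality calls.
#'
#' @param records list of `metaphase_record`s for one individual.
#' @param constitutional_sex `"XX"` or `"XY"`.
#' @return tibble with columns `key`, `category_group`, `n_metaphases`,
#'   `call` (`"CCA"` or `"NCCA"`).
#' @export
call_clonality <- function(records, constitutional_sex = c("XX", "XY")) {
  stopifnot(length(records) >= 1L)
  constitutional_sex <- match.arg(constitutional_sex)
  per_meta <- lapply(records, function(r) {
    cl <- classify_metaphase(r, constitutional_sex)
    cl <- cl[cl$category_group %in% c("monosomies", "trisomies", "scas"), ]
    unique(cl[, c("key", "category_group")])
  })
  all_ev <- dplyr::bind_rows(per_meta)
  if (!nrow(all_ev))
    return(tibble::tibble(key = character(0), category_group = character(0),
                          n_metaphases = integer(0), call = character(0)))
  counts <- dplyr::count(all_ev, .data$key, .data$category_group,
                         name = "n_metaphases")
  counts$call <- ifelse(
    counts$n_metaphases >= ifelse(counts$category_group == "monosomies", 3L, 2L),
    "CCA", "NCCA")
  dplyr::arrange(counts, dplyr::desc(.data$n_metaphases), .data$key)
}

#' Tally all aberration events of one individual
#'
#' Every event occurrence counts, clonal or not. The percentage is computed
#' against the total number of metaphases analysed in the individual's
#' group, mirroring how paired frequency tables are reported in
#' biomonitoring studies, and is rounded half-up to 2 decimals.
#'
#' @param records list of `metaphase_record`s for one individual.
#' @param group_metaphase_total total metaphases analysed in this
#'   individual's group (must be at least the individual's own count).
#' @param constitutional_sex `"XX"` or `"XY"`.
#' @param individual_id,group identifiers carried into the output row.
#' @return one-row tibble with per-category counts, `total_events`,
#'   `n_metaphases` and `pct_of_group_metaphases`.
#' @export
tally_individual <- function(records, group_metaphase_total,
                             constitutional_sex = c("XX", "XY"),
                             individual_id = NULL, group = NA_character_) {
  stopifnot(length(records) >= 1L)
  constitutional_sex <- match.arg(constitutional_sex)
  if (!is_count(group_metaphase_total) || group_metaphase_total == 0)
    stop("group_metaphase_total must be a positive integer", call. = FALSE)
  if (group_metaphase_total < length(records))
    stop("group_metaphase_total is smaller than the individual's metaphase count",
         call. = FALSE)

  ev <- dplyr::bind_rows(lapply(records, classify_metaphase,
                                constitutional_sex = constitutional_sex))
  counts <- vapply(TALLY_CATEGORIES,
                   function(g) sum(ev$category_group == g), integer(1))
  total <- sum(counts)
  out <- tibble::tibble(
    individual_id = individual_id %||% records[[1]]$individual_id,
    group = group,
    n_metaphases = length(records))
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(counts)))
  out$total_events <- total
  out$pct_of_group_metaphases <-
    round_half_up(100 * total / group_metaphase_total, 2)
  out
}

#' Tally every individual of a parsed karyotype table
#'
#' @param karyotypes a tibble as returned by [read_karyotypes()].
#' @param metadata a tibble with columns `individual_id`, `group` and
#'   `constitutional_sex`.
#' @return a tibble with one [tally_individual()] row per individual; group
#'   metaphase totals are computed from the data.
#' @export
tally_cohort <- function(karyotypes, metadata) {
  stopifnot(all(c("individual_id", "record") %in% names(karyotypes)),
            all(c("individual_id", "group", "constitutional_sex") %in%
                  names(metadata)))
  meta <- metadata[match(karyotypes$individual_id, metadata$individual_id), ]
  if (anyNA(meta$group))
    stop("metadata is missing some individuals present in the karyotype table",
         call. = FALSE)
  group_totals <- table(meta$group)
  ids <- unique(karyotypes$individual_id)
  dplyr::bind_rows(lapply(ids, function(id) {
    sel <- karyotypes$individual_id == id
    g <- meta$group[sel][1]
    tally_individual(karyotypes$record[sel],
                     group_metaphase_total = group_totals[[g]],
                     constitutional_sex = meta$constitutional_sex[sel][1],
                     individual_id = id, group = g)
  }))
}

#' Carrier table for one aberration category
#'
#' A carrier is an individual with at least one event of the category.
#' Percentages are rounded half-up to 1 decimal; the two-sided p-value comes
#' from Fisher's exact test on the 2x2 carrier table.
#'
#' @param exposed_tallies,unexposed_tallies tibbles of [tally_individual()]
#'   rows for each group.
#' @param categories tally categories to report (default: all).
#' @return a tibble with one row per category: carrier counts, group sizes,
#'   percentages and `p_two_sided`.
#' @export
carriers_table <- function(exposed_tallies, unexposed_tallies,
                           categories = TALLY_CATEGORIES) {
  stopifnot(nrow(exposed_tallies) > 0, nrow(unexposed_tallies) > 0,
            all(categories %in% TALLY_CATEGORIES))
  n_e <- nrow(exposed_tallies)
  n_u <- nrow(unexposed_tallies)
  dplyr::bind_rows(lapply(categories, function(cat) {
    ce <- sum(exposed_tallies[[cat]] > 0)
    cu <- sum(unexposed_tallies[[cat]] > 0)
    # a zero margin (nobody, or everybody, carries the category) admits no
    # association: p = 1 by convention
    p <- if (ce + cu == 0 || (n_e - ce) + (n_u - cu) == 0) 1
    else fisher_exact(matrix(c(ce, n_e - ce, cu, n_u - cu), nrow = 2))$p_two_sided
    tibble::tibble(
      category = cat,
      exposed_carriers = ce, exposed_n = n_e,
      pct_exposed = round_half_up(100 * ce / n_e, 1),
      unexposed_carriers = cu, unexposed_n = n_u,
      pct_unexposed = round_half_up(100 * cu / n_u, 1),
      p_two_sided = p)
  }))
}

#' Paired per-individual event-frequency table
#'
#' Mirrors the paired exposed/unexposed frequency table layout: for pair i,
#' the exposed and unexposed event totals with their percentages of the
#' respective group metaphase totals, and a two-sided Fisher exact p-value
#' on the 2x2 table `[events_i, group_total - events_i]` per group.
#'
#' @param exposed_tallies,unexposed_tallies tallies with one row per
#'   individual, in pair order (equal row counts).
#' @param exposed_total,unexposed_total group metaphase totals.
#' @return tibble with columns `pair`, `exposed_events`, `pct_exposed`,
#'   `unexposed_events`, `pct_unexposed`, `p_two_sided`.
#' @export
paired_event_table <- function(exposed_tallies, unexposed_tallies,
                               exposed_total, unexposed_total) {
  stopifnot(nrow(exposed_tallies) == nrow(unexposed_tallies))
  dplyr::bind_rows(lapply(seq_len(nrow(exposed_tallies)), function(i) {
    e <- exposed_tallies$total_events[i]
    u <- unexposed_tallies$total_events[i]
    p <- if (e + u == 0) 1
    else fisher_exact(matrix(c(e, exposed_total - e,
                               u, unexposed_total - u), nrow = 2))$p_two_sided
    tibble::tibble(
      pair = i,
      exposed_events = e,
      pct_exposed = round_half_up(100 * e / exposed_total, 2),
      unexposed_events = u,
      pct_unexposed = round_half_up(100 * u / unexposed_total, 2),
      p_two_sided = p)
  }))
}

#' Recurrently altered chromosome bands
#'
#' Collects the breakpoints of every structural aberration and counts, for
#' each (chromosome, band) pair, the number of distinct individuals whose
#' karyotypes hit it.
#'
#' @param records_by_individual named list: individual id -> list of
#'   `metaphase_record`s.
#' @param min_individuals keep bands hit in at least this many individuals.
#' @return tibble with columns `chromosome`, `band`, `n_individuals`,
#'   ordered by decreasing recurrence.
#' @export
recurrent_regions <- function(records_by_individual, min_individuals = 1L) {
  stopifnot(is.list(records_by_individual), min_individuals >= 1L)
  hits <- list()
  for (id in names(records_by_individual)) {
    for (r in records_by_individual[[id]]) {
      for (e in r$events) {
        if (!e$category %in% CAT_SCA) next
        if (!length(e$breakpoints)) next
        bp <- e$breakpoints[e$breakpoints != "?"]
        if (!length(bp)) next
        chroms <- if (length(e$chromosomes) == length(bp)) e$chromosomes
                  else rep(e$chromosomes[1], length(bp))
        hits[[length(hits) + 1L]] <- tibble::tibble(
          individual_id = id, chromosome = chroms, band = bp)
      }
    }
  }
  if (!length(hits))
    return(tibble::tibble(chromosome = character(0), band = character(0),
                          n_individuals = integer(0)))
  h <- unique(dplyr::bind_rows(hits))
  out <- dplyr::count(h, .data$chromosome, .data$band, name = "n_individuals")
  out <- out[out$n_individuals >= min_individuals, ]
  dplyr::arrange(out, dplyr::desc(.data$n_individuals), .data$chromosome,
                 .data$band)
}
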