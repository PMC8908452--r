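# Published group-level frequency tables from the occupational
# biomonitoring study this pipeline reanalyses, shipped as plain-text
# fixtures. They serve as worked inputs: the raw per-metaphase records
# behind them were not deposited, but their printed counts let every
# percentage and total be recomputed and checked.

published_table <- function(name) {
  path <- system.file("extdata", name, package = "cinch", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, sep = "\t"))
}

#' Published per-category carrier counts
#'
#' Carrier counts (individuals with at least one event of the category)
#' for the exposed and unexposed groups of 34 individuals each, with the
#' percentages as printed.
#'
#' @return tibble with columns `category`, `exposed_carriers`,
#'   `exposed_n`, `unexposed_carriers`, `unexposed_n`,
#'   `printed_pct_exposed`, `printed_pct_unexposed`.
#' @export
published_carrier_counts <- function() {
  published_table("published_carrier_counts.tsv")
}

#' Published paired per-individual event counts
#'
#' Total aberration events per exposed/unexposed pair, with the printed
#' percentages of the group metaphase totals (see
#' [published_group_totals()]).
#'
#' @return tibble with columns `pair`, `exposed_events`,
#'   `printed_pct_exposed`, `unexposed_events`, `printed_pct_unexposed`.
#' @export
published_paired_counts <- function() {
  published_table("published_paired_counts.tsv")
}

#' Published group metaphase totals
#'
#' Total metaphases analysed per group: 1493 exposed, 1061 unexposed
#' (2554 in all).
#'
#' @return named integer vector with elements `exposed` and `unexposed`.
#' @export
published_group_totals <- function() {
  c(exposed = 1493L, unexposed = 1061L)
}
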