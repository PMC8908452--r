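# Chromosomal-instability (CIN) scoring from per-nucleus centromeric FISH
# signal counts: per-chromosome deviation from the modal signal number,
# averaged over the probe panel, with a low/high classification.

#' Default centromeric probe panel
#'
#' The six-probe panel (chromosomes 2, 3, 8, 11, 15, 17) used for
#' interphase CIN scoring.
#'
#' @return character vector of probe labels.
#' @export
fish_probes <- function() c("chr2", "chr3", "chr8", "chr11", "chr15", "chr17")

#' Construct a per-individual FISH count matrix
#'
#' @param counts nuclei x probes matrix of nonnegative integer signal
#'   counts.
#' @param individual_id identifier.
#' @param probes probe labels; must match `ncol(counts)`.
#' @return a `fish_counts` object: list with `individual_id`, `counts`,
#'   `probes`, `n_nuclei`.
#' @export
fish_counts <- function(counts, individual_id = "", probes = fish_probes()) {
  counts <- as.matrix(counts)
  if (ncol(counts) != length(probes))
    stop(sprintf("counts has %d columns but %d probes were given",
                 ncol(counts), length(probes)), call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != trunc(counts)))
    stop("signal counts must be nonnegative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  colnames(counts) <- probes
  structure(list(individual_id = individual_id, counts = counts,
                 probes = probes, n_nuclei = nrow(counts)),
            class = "fish_counts")
}

#' @export
print.fish_counts <- function(x, ...) {
  cat(sprintf("<fish_counts> %s: %d nuclei x %d probes\n",
              x$individual_id, x$n_nuclei, length(x$probes)))
  invisible(x)
}

#' Read per-nucleus FISH signal counts
#'
#' Expects a TSV with columns `individual_id`, `nucleus_id` and one integer
#' column per probe (default panel: chr2, chr3, chr8, chr11, chr15, chr17).
#'
#' @param path path to the TSV file.
#' @param probes expected probe columns.
#' @return named list of `fish_counts`, one per individual.
#' @export
read_fish_counts <- function(path, probes = fish_probes()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          fileEncoding = "UTF-8")
  miss <- setdiff(c("individual_id", "nucleus_id", probes), names(df))
  if (length(miss))
    stop(sprintf("FISH count file '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  ids <- unique(df$individual_id)
  out <- lapply(ids, function(id) {
    fish_counts(as.matrix(df[df$individual_id == id, probes]),
                individual_id = id, probes = probes)
  })
  names(out) <- ids
  out
}

#' Modal signal count of a cell population
#'
#' The most frequent signal count. Ties are broken by preferring the value
#' nearest the diploid count of 2, then the smaller value.
#'
#' @param x vector of nonnegative integer signal counts.
#' @return the modal count (integer).
#' @export
#' @examples
#' modal_count(c(rep(2, 50), rep(3, 50)))  # tie -> 2
modal_count <- function(x) {
  stopifnot(length(x) >= 1L, !anyNA(x))
  tab <- table(x)
  vals <- as.integer(names(tab))
  cand <- vals[tab == max(tab)]
  cand[order(abs(cand - 2L), cand)][1L]
}

#' Per-chromosome CIN percentage
#'
#' Percentage of nuclei whose signal count differs from the modal count.
#'
#' @param x vector of signal counts for one chromosome.
#' @param modal the modal count (defaults to [modal_count()] of `x`).
#' @param drop_zero drop nuclei with 0 signals as hybridization failures
#'   before scoring. The default keeps them: a 0 differs from the modal
#'   count and scores as deviant.
#' @return percentage in `[0, 100]`.
#' @export
cin_per_chromosome <- function(x, modal = NULL, drop_zero = FALSE) {
  stopifnot(length(x) >= 1L)
  if (drop_zero) x <- x[x > 0]
  if (!length(x)) return(NA_real_)
  modal <- modal %||% modal_count(x)
  100 * mean(x != modal)
}

#' CIN profile of one individual
#'
#' For each of the six probes, the percentage of nuclei deviating from that
#' probe's modal signal count; the individual's CIN is the unweighted
#' arithmetic mean of the six percentages, classified low/high against a
#' 25% threshold (a mean of exactly 25 is high).
#'
#' @param m a `fish_counts` object with the full six-probe panel.
#' @param drop_zero see [cin_per_chromosome()].
#' @param cin_high class boundary in percent (default 25).
#' @param min_nuclei warn (and flag the profile) below this many nuclei.
#' @return a `cin_profile`: list with `individual_id`, `per_chromosome`
#'   (named percentages), `modal_counts`, `mean_cin`, `cin_class`,
#'   `n_nuclei`, `low_n`.
#' @export
cin_individual <- function(m, drop_zero = FALSE, cin_high = 25,
                           min_nuclei = 100L) {
  stopifnot(inherits(m, "fish_counts"))
  if (length(m$probes) < 6L)
    stop("CIN scoring requires the full six-probe panel", call. = FALSE)
  low_n <- m$n_nuclei < min_nuclei
  if (low_n)
    warning(sprintf("individual %s: only %d nuclei (< %d); CIN estimate is unstable",
                    m$individual_id, m$n_nuclei, min_nuclei), call. = FALSE)
  per <- vapply(m$probes, function(p) {
    x <- m$counts[, p]
    if (drop_zero) x <- x[x > 0]
    cin_per_chromosome(x, drop_zero = FALSE)
  }, numeric(1))
  modal <- vapply(m$probes, function(p) {
    x <- m$counts[, p]
    if (drop_zero) x <- x[x > 0]
    modal_count(x)
  }, integer(1))
  mean_cin <- mean(per)
  structure(list(individual_id = m$individual_id,
                 per_chromosome = per, modal_counts = modal,
                 mean_cin = mean_cin,
                 cin_class = if (mean_cin >= cin_high) "high" else "low",
                 n_nuclei = m$n_nuclei, low_n = low_n),
            class = "cin_profile")
}

#' @export
print.cin_profile <- function(x, ...) {
  cat(sprintf("<cin_profile> %s: mean CIN %.2f%% (%s)\n",
              x$individual_id, x$mean_cin, x$cin_class))
  print(round(x$per_chromosome, 2))
  invisible(x)
}

#' CIN profiles for a list of individuals
#'
#' @param fish named list of `fish_counts`.
#' @param ... passed to [cin_individual()].
#' @return list with `profiles` (list of `cin_profile`) and `summary`, a
#'   tibble with one row per individual (mean CIN, class, per-chromosome
#'   percentages).
#' @export
cin_cohort <- function(fish, ...) {
  profiles <- lapply(fish, cin_individual, ...)
  summary <- dplyr::bind_rows(lapply(profiles, function(p) {
    dplyr::bind_cols(
      tibble::tibble(individual_id = p$individual_id,
                     mean_cin = p$mean_cin, cin_class = p$cin_class,
                     n_nuclei = p$n_nuclei),
      tibble::as_tibble(as.list(p$per_chromosome)))
  }))
  list(profiles = profiles, summary = summary)
}

#' Rank chromosome stability within a group
#'
#' Compares the per-individual CIN distributions of the probed chromosomes
#' with a Kruskal-Wallis omnibus test and ranks chromosomes from most
#' stable (lowest mean CIN) to least stable.
#'
#' @param cin_summary tibble as produced by [cin_cohort()]`$summary` (one
#'   row per individual, one column per probe).
#' @param probes probe columns to compare.
#' @return list with `ranking` (tibble of chromosome, mean_cin, ordered
#'   most stable first) and `test` (a [kruskal_wallis()] result).
#' @export
chromosome_stability <- function(cin_summary, probes = fish_probes()) {
  probes <- intersect(probes, names(cin_summary))
  if (length(probes) < 2L)
    stop("chromosome stability ranking needs at least two probed chromosomes",
         call. = FALSE)
  if (nrow(cin_summary) < 2L)
    stop("chromosome stability ranking needs at least two individuals",
         call. = FALSE)
  groups <- lapply(probes, function(p) cin_summary[[p]])
  names(groups) <- probes
  test <- kruskal_wallis(groups)
  ranking <- tibble::tibble(
    chromosome = probes,
    mean_cin = vapply(groups, mean, numeric(1)))
  ranking <- dplyr::arrange(ranking, .data$mean_cin)
  list(ranking = ranking, test = test)
}
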