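# Clonal heterogeneity: clone abundance distributions from FISH signal
# signatures, Shannon diversity (natural log), true diversity exp(H), and
# the low / intermediate / high CH classification.

#' Empirical clone abundance distribution
#'
#' At the individual level, cells are grouped by their full signature (the
#' 6-tuple of signal counts across the probe panel); at the chromosome
#' level, by the single chromosome's count. Abundances are empirical cell
#' frequencies.
#'
#' @param m a `fish_counts` object.
#' @param level `"individual"` (full-signature) or `"chromosome"`.
#' @param chromosome probe label, required for `level = "chromosome"`.
#' @return a `clone_distribution`: list with `signatures` (character
#'   labels), `abundances` (proportions summing to 1), `n_cells`, `level`.
#' @export
clone_distribution <- function(m, level = c("individual", "chromosome"),
                               chromosome = NULL) {
  stopifnot(inherits(m, "fish_counts"), m$n_nuclei >= 1L)
  level <- match.arg(level)
  labels <- if (level == "individual") {
    apply(m$counts, 1L, paste, collapse = ",")
  } else {
    if (is.null(chromosome) || !chromosome %in% m$probes)
      stop("chromosome-level distribution requires a probe label", call. = FALSE)
    as.character(m$counts[, chromosome])
  }
  tab <- table(labels)
  structure(list(signatures = names(tab),
                 abundances = as.numeric(tab) / length(labels),
                 n_cells = length(labels), level = level),
            class = "clone_distribution")
}

#' Shannon Diversity Index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over clone abundances, in nats. The
#' natural logarithm is used throughout so that true diversity is exactly
#' `exp(H)`.
#'
#' @param d a `clone_distribution`, or a bare numeric vector of abundances
#'   summing to 1.
#' @return nonnegative SDI in nats.
#' @export
#' @examples
#' shannon(c(0.5, 0.5))  # ln 2
shannon <- function(d) {
  p <- if (inherits(d, "clone_distribution")) d$abundances else as.numeric(d)
  if (any(p <= 0)) stop("abundances must be strictly positive", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("abundances must sum to 1", call. = FALSE)
  -sum(p * log(p))
}

#' True diversity (effective number of clones)
#'
#' `exp(H)`: the number of equally abundant clones giving the same Shannon
#' index (the Hill number of order 1).
#'
#' @param sdi Shannon index in nats.
#' @return true diversity, at least 1.
#' @export
true_diversity <- function(sdi) {
  stopifnot(is.numeric(sdi), all(sdi >= 0))
  exp(sdi)
}

#' Classify clonal heterogeneity from true diversity
#'
#' TD below 1.5 is low CH, TD from 1.5 to 2 (inclusive) is intermediate,
#' and TD above 2 is high.
#'
#' @param td true diversity value(s), `>= 1`.
#' @return character vector: `"low"`, `"intermediate"` or `"high"`.
#' @export
#' @examples
#' classify_ch(c(1.2, 1.55, 2.4))
classify_ch <- function(td) {
  stopifnot(is.numeric(td))
  if (any(td < 1 - 1e-9))
    stop("true diversity cannot be below 1", call. = FALSE)
  ifelse(td < 1.5, "low", ifelse(td <= 2, "intermediate", "high"))
}

#' Clonal diversity of one individual
#'
#' Convenience wrapper: clone distribution, SDI, TD and CH class in one
#' call.
#'
#' @param m a `fish_counts` object.
#' @inheritParams clone_distribution
#' @return a `diversity_result`: list with `individual_id`, `sdi`, `td`,
#'   `ch_class`, `distribution`.
#' @export
clonal_diversity <- function(m, level = c("individual", "chromosome"),
                             chromosome = NULL) {
  level <- match.arg(level)
  d <- clone_distribution(m, level, chromosome)
  h <- shannon(d)
  td <- true_diversity(h)
  structure(list(individual_id = m$individual_id, sdi = h, td = td,
                 ch_class = classify_ch(td), distribution = d),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result> %s: SDI %.4f, TD %.4f (%s CH; %d clone signature(s))\n",
              x$individual_id, x$sdi, x$td, x$ch_class,
              length(x$distribution$signatures)))
  invisible(x)
}

#' Diversity summary for a list of individuals
#'
#' Individual-level (full-signature) SDI/TD/CH plus per-chromosome SDI and
#' TD for each probe.
#'
#' @param fish named list of `fish_counts`.
#' @return tibble with one row per individual: `sdi`, `td`, `ch_class`,
#'   and `sdi_<probe>` / `td_<probe>` columns.
#' @export
diversity_cohort <- function(fish) {
  dplyr::bind_rows(lapply(fish, function(m) {
    dres <- clonal_diversity(m)
    row <- tibble::tibble(individual_id = m$individual_id,
                          sdi = dres$sdi, td = dres$td,
                          ch_class = dres$ch_class)
    for (p in m$probes) {
      h <- shannon(clone_distribution(m, "chromosome", p))
      row[[paste0("sdi_", p)]] <- h
      row[[paste0("td_", p)]] <- true_diversity(h)
    }
    row
  }))
}
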