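# Statistical comparison layer: Fisher's exact test on 2x2 carrier tables,
# normality/homoscedasticity-gated two-sample comparisons, Kruskal-Wallis
# omnibus tests and the Pearson correlation matrix. Two-sided throughout at
# alpha = 0.05; no multiple-testing correction is applied (the report layer
# annotates the number of tests instead).

test_result <- function(test_name, statistic, p_two_sided, gate_trace = "") {
  tibble::tibble(test_name = test_name, statistic = statistic,
                 p_two_sided = p_two_sided, gate_trace = gate_trace)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value defined as the sum of hypergeometric probabilities of
#' all tables (with the observed margins) no more probable than the
#' observed one — the conventional exact two-sided rule.
#'
#' @param x a 2x2 matrix of nonnegative counts, or a length-4 vector
#'   `c(a, c, b, d)` filled column-wise.
#' @return a one-row tibble: `test_name`, `statistic` (conditional MLE odds
#'   ratio), `p_two_sided`, `gate_trace`.
#' @export
#' @examples
#' fisher_exact(matrix(c(32, 2, 13, 21), nrow = 2))
fisher_exact <- function(x) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 2)
  stopifnot(identical(dim(x), c(2L, 2L)) || identical(dim(x), c(2, 2)))
  if (any(is.na(x)) || any(x < 0) || any(x != trunc(x)))
    stop("table entries must be nonnegative integers", call. = FALSE)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("every margin of the 2x2 table must be positive", call. = FALSE)
  ft <- stats::fisher.test(x, alternative = "two.sided")
  test_result("fisher_exact", unname(ft$estimate), ft$p.value)
}

shapiro_gate <- function(v, label, alpha) {
  if (length(unique(v)) == 1L)
    return(list(normal = FALSE,
                trace = sprintf("shapiro[%s]: constant sample, treated as non-normal", label)))
  p <- stats::shapiro.test(v)$p.value
  list(normal = p > alpha,
       trace = sprintf("shapiro[%s] p=%.4g -> %s", label, p,
                       if (p > alpha) "normal" else "non-normal"))
}

#' Gated two-sample comparison
#'
#' Test selection mirrors the usual biomonitoring workflow: Shapiro-Wilk on
#' both samples gates the choice at `alpha`; if both pass, Student's t-test
#' is used, with Bartlett's test choosing the pooled or unequal-variance
#' form; otherwise the Wilcoxon rank-sum test (or signed-rank when
#' `paired = TRUE`). The `gate_trace` field records which gates fired.
#'
#' @param x,y numeric vectors (each of length at least 3; equal lengths when
#'   paired).
#' @param paired compare as paired samples.
#' @param alpha gate level for the normality/homoscedasticity pretests.
#' @return a one-row `test_result` tibble.
#' @export
compare_groups <- function(x, y, paired = FALSE, alpha = 0.05) {
  if (length(x) < 3L || length(y) < 3L)
    stop("each sample must contain at least 3 values", call. = FALSE)
  if (paired && length(x) != length(y))
    stop("paired comparison requires equal-length samples", call. = FALSE)
  gx <- shapiro_gate(x, "x", alpha)
  gy <- shapiro_gate(y, "y", alpha)
  trace <- c(gx$trace, gy$trace)

  if (gx$normal && gy$normal) {
    if (paired) {
      tt <- stats::t.test(x, y, paired = TRUE)
      trace <- c(trace, "both normal -> paired t-test")
      name <- "t_paired"
    } else {
      pb <- stats::bartlett.test(list(x, y))$p.value
      pooled <- pb > alpha
      trace <- c(trace, sprintf("bartlett p=%.4g -> %s", pb,
                                if (pooled) "pooled t-test" else "Welch t-test"))
      tt <- stats::t.test(x, y, var.equal = pooled)
      name <- if (pooled) "t_pooled" else "t_welch"
    }
    return(test_result(name, unname(tt$statistic), tt$p.value,
                       paste(trace, collapse = "; ")))
  }

  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            exact = FALSE, correct = TRUE))
  name <- if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum"
  trace <- c(trace, paste("non-normal ->", name))
  test_result(name, unname(wt$statistic), wt$p.value,
              paste(trace, collapse = "; "))
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction and a chi-square p-value.
#' When every value across all groups is identical there is no rank
#' variation and the test degenerates to H = 0, p = 1.
#'
#' @param groups list of at least 2 numeric vectors, each of length at
#'   least 2.
#' @return a one-row `test_result` tibble.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskal_wallis needs a list of at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group must contain at least 2 values", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(test_result("kruskal_wallis", 0, 1, "all values tied -> H = 0"))
  kt <- stats::kruskal.test(groups)
  test_result("kruskal_wallis", unname(kt$statistic), kt$p.value,
              sprintf("df=%d", unname(kt$parameter)))
}

#' Pairwise Pearson correlation matrix
#'
#' Computes pairwise Pearson correlations over the supplied variables,
#' flagging coefficients whose absolute value exceeds `flag_threshold`.
#' Character or factor columns with two levels (e.g. sex) are encoded 0/1
#' in level order. Constant columns yield undefined correlations, which are
#' reported as `NA` and marked in `undefined` rather than raising an error.
#'
#' @param data data frame of numeric (or two-level categorical) variables.
#' @param flag_threshold absolute correlation above which a pair is
#'   flagged (default 0.5).
#' @return a `correlation_result`: list with `r` (correlation matrix),
#'   `flagged` (logical matrix), `undefined` (logical matrix), `n`,
#'   `flag_threshold`.
#' @export
correlation_matrix <- function(data, flag_threshold = 0.5) {
  data <- as.data.frame(data)
  if (nrow(data) < 3L)
    stop("correlation matrix needs at least 3 complete rows", call. = FALSE)
  for (nm in names(data)) {
    col <- data[[nm]]
    if (is.character(col) || is.factor(col)) {
      f <- as.factor(col)
      if (nlevels(f) > 2L)
        stop(sprintf("column '%s' has more than two levels; encode it numerically", nm),
             call. = FALSE)
      data[[nm]] <- as.numeric(f) - 1
    }
  }
  r <- suppressWarnings(stats::cor(data, use = "pairwise.complete.obs",
                                   method = "pearson"))
  undefined <- is.na(r)
  flagged <- !undefined & abs(r) > flag_threshold &
    row(r) != col(r)
  structure(list(r = r, flagged = flagged, undefined = undefined,
                 n = nrow(data), flag_threshold = flag_threshold),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> n=%d, flagged |r| > %.2f\n",
              x$n, x$flag_threshold))
  print(round(x$r, 3))
  if (any(x$undefined))
    cat("undefined entries (constant columns) marked NA\n")
  invisible(x)
}
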