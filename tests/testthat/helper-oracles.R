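# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exhaustive enumeration, closed forms and naive
# recounts.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins, via binomial coefficients only.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; n <- a + b + c + d; c1 <- a + c
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  pmf <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  p_obs <- pmf[match(a, xs)]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

# Naive modal value with the tie rule (nearest 2, then smaller) written as
# an explicit loop.
naive_modal <- function(x) {
  best <- NULL
  for (v in sort(unique(x))) {
    f <- sum(x == v)
    if (is.null(best) || f > best$f ||
        (f == best$f && (abs(v - 2) < abs(best$v - 2) ||
                         (abs(v - 2) == abs(best$v - 2) && v < best$v)))) {
      best <- list(v = v, f = f)
    }
  }
  best$v
}

# Record-field equality for round-trip checks.
expect_same_record <- function(r1, r2) {
  expect_equal(r1$chromosome_count, r2$chromosome_count)
  expect_equal(r1$sex_complement, r2$sex_complement)
  expect_equal(length(r1$events), length(r2$events))
  for (i in seq_along(r1$events)) {
    expect_equal(r1$events[[i]]$category, r2$events[[i]]$category)
    expect_equal(r1$events[[i]]$chromosomes, r2$events[[i]]$chromosomes)
    expect_equal(r1$events[[i]]$breakpoints, r2$events[[i]]$breakpoints)
  }
}

# Build a metaphase record from a karyotype string (shorthand).
rec <- function(s, id = "S1", m = "m1") parse_karyotype(s, id, m)
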