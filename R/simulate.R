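# Fully synthetic cohorts with known ground truth: FISH count matrices
# drawn from clone-mixture models with per-probe technical noise, and
# karyotype records drawn from per-category Poisson rate models. All
# randomness flows from an explicit seed; there is no silent clock seeding.

#' Clone specification
#'
#' @param signature integer vector of copy counts, one per probe (values
#'   0-6).
#' @param frequency clone proportion in `(0, 1]`.
#' @return a `clone_spec` list.
#' @export
clone_spec <- function(signature, frequency) {
  signature <- as.integer(signature)
  stopifnot(length(signature) >= 1L, all(signature >= 0L), all(signature <= 6L),
            is.numeric(frequency), length(frequency) == 1L,
            frequency > 0, frequency <= 1)
  structure(list(signature = signature, frequency = frequency),
            class = "clone_spec")
}

#' FISH technical noise model
#'
#' Dropout (a true signal missed) and split (one spurious extra signal)
#' act independently per probe per nucleus; dropout is applied before the
#' split.
#'
#' @param p_dropout per-signal miss probability, in `[0, 0.5]`.
#' @param p_split per-probe probability of one extra observed signal, in
#'   `[0, 0.5]`.
#' @return a `noise_model` list.
#' @export
noise_model <- function(p_dropout = 0.005, p_split = 0.0025) {
  stopifnot(is.numeric(p_dropout), is.numeric(p_split),
            p_dropout >= 0, p_dropout <= 0.5,
            p_split >= 0, p_split <= 0.5)
  structure(list(p_dropout = p_dropout, p_split = p_split),
            class = "noise_model")
}

# Largest-remainder apportionment of n cells to clone frequencies.
apportion_cells <- function(freqs, n) {
  raw <- freqs * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Simulate the FISH count matrix of one individual
#'
#' Each nucleus draws a clone by frequency (or, with `exact = TRUE`, the
#' clone census is fixed by largest-remainder apportionment so planted
#' fractions are hit exactly); each probe's observed count is the clone's
#' signature value minus `Binomial(value, p_dropout)` plus
#' `Bernoulli(p_split)`.
#'
#' @param clones list of [clone_spec()]s; frequencies must sum to 1.
#' @param noise a [noise_model()].
#' @param n_nuclei number of nuclei to draw.
#' @param seed integer seed; required. Pass `NULL` to draw from the current
#'   RNG stream (used internally by [simulate_cohort()]).
#' @param individual_id identifier.
#' @param probes probe labels.
#' @param exact fix the clone census instead of sampling it.
#' @return a `fish_counts` object; the drawn clone indices are attached as
#'   attribute `"clone_assignment"`.
#' @export
simulate_fish_individual <- function(clones, noise = noise_model(),
                                     n_nuclei = 100L, seed,
                                     individual_id = "S1",
                                     probes = fish_probes(), exact = FALSE) {
  if (missing(seed))
    stop("an explicit seed is required (pass NULL to use the current RNG stream)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(clones) >= 1L, n_nuclei >= 1L,
            inherits(noise, "noise_model"))
  freqs <- vapply(clones, function(cl) cl$frequency, numeric(1))
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("clone frequencies must sum to 1", call. = FALSE)
  sig <- do.call(rbind, lapply(clones, function(cl) cl$signature))
  if (ncol(sig) != length(probes))
    stop("clone signatures must have one count per probe", call. = FALSE)

  idx <- if (exact) rep(seq_along(clones), apportion_cells(freqs, n_nuclei))
         else sample(seq_along(clones), n_nuclei, replace = TRUE, prob = freqs)
  base <- sig[idx, , drop = FALSE]
  drops <- matrix(stats::rbinom(length(base), as.vector(base), noise$p_dropout),
                  nrow = n_nuclei)
  splits <- matrix(stats::rbinom(length(base), 1L, noise$p_split),
                   nrow = n_nuclei)
  m <- fish_counts(base - drops + splits, individual_id, probes)
  attr(m, "clone_assignment") <- idx
  m
}

#' Default cohort configuration
#'
#' Parameters of the two-group clone-mixture model. Each individual carries
#' a dominant diploid clone plus two minor aneuploid clones: a broad clone
#' deviating on all six probed chromosomes (frequency `f_s`, the
#' per-individual deviant fraction of the stable chromosomes 8 and 17) and
#' a clone deviating on the unstable set (chromosomes 2, 3, 11, 15;
#' additional frequency `f_u - f_s`). `f_u` and `f_s` are drawn per
#' individual from truncated normals. The exposed-group means place the
#' group mean CIN near 34.6% and the unexposed-group means near 6.5%, with
#' chromosomes 8 and 17 the most stable in both groups; deviant copy
#' numbers are monosomic with probability `p_monosomy` and trisomic
#' otherwise.
#'
#' @return nested list of group parameters, nuclei per individual and the
#'   default [noise_model()].
#' @export
cohort_config <- function() {
  list(
    probes = fish_probes(),
    unstable = c("chr2", "chr3", "chr11", "chr15"),
    stable = c("chr8", "chr17"),
    p_monosomy = 0.6,
    n_nuclei = 100L,
    noise = noise_model(),
    groups = list(
      exposed = list(f_unstable_mean = 0.43, f_unstable_sd = 0.08,
                     f_stable_mean = 0.178, f_stable_sd = 0.05,
                     f_max = 0.60),
      unexposed = list(f_unstable_mean = 0.08, f_unstable_sd = 0.042,
                       f_stable_mean = 0.035, f_stable_sd = 0.025,
                       f_max = 0.30)
    )
  )
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Build one individual's clone list from its two deviant fractions.
build_clones <- function(f_u, f_s, config) {
  probes <- config$probes
  diploid <- rep(2L, length(probes))
  deviate <- function(sig, on) {
    for (p in on) {
      j <- match(p, probes)
      sig[j] <- if (stats::runif(1) < config$p_monosomy) 1L else 3L
    }
    sig
  }
  clones <- list(clone_spec(diploid, 1 - f_u))
  if (f_s > 0)
    clones <- c(clones, list(clone_spec(
      deviate(diploid, c(config$unstable, config$stable)), f_s)))
  if (f_u - f_s > 0)
    clones <- c(clones, list(clone_spec(deviate(diploid, config$unstable),
                                        f_u - f_s)))
  clones
}

#' Simulate a two-group FISH cohort with known ground truth
#'
#' Generates per-individual clone mixtures (see [cohort_config()]), FISH
#' count matrices under the technical noise model, and cohort metadata
#' (age, sex, exposure months, smoking and drinking status) emulating a
#' paired occupational-exposure study of 34 exposed and 34 unexposed
#' individuals.
#'
#' @param n_per_group individuals per group (default 34).
#' @param config see [cohort_config()].
#' @param seed integer seed; required.
#' @param n_nuclei nuclei per individual.
#' @param noise a [noise_model()]; defaults to the config's.
#' @return a `cohort` list: `fish` (named list of `fish_counts`),
#'   `metadata` (tibble), `truth` (tibble of per-chromosome true deviant
#'   fractions per individual, in percent).
#' @export
simulate_cohort <- function(n_per_group = 34L, config = cohort_config(),
                            seed, n_nuclei = config$n_nuclei,
                            noise = config$noise) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  set.seed(seed)
  stopifnot(n_per_group >= 2L)

  meta_rows <- list(); fish <- list(); truth_rows <- list()
  for (grp in c("exposed", "unexposed")) {
    gp <- config$groups[[grp]]
    prefix <- if (grp == "exposed") "E" else "U"
    n_male <- round(n_per_group * 20 / 34)
    sexes <- sample(c(rep("XY", n_male), rep("XX", n_per_group - n_male)))
    ages <- round(rnorm_trunc(n_per_group,
                              if (grp == "exposed") 46.64 else 47.11,
                              if (grp == "exposed") 12.13 else 11.24, 23, 70))
    expo <- if (grp == "exposed")
      pmax(3, round(stats::rgamma(n_per_group, shape = 1.1, scale = 121)))
    else rep(0, n_per_group)
    n_smoke <- round(n_per_group * 4 / 34)
    smoking <- sample(c(rep("smoker", n_smoke),
                        rep("non-smoker", n_per_group - n_smoke)))
    n_drink <- round(n_per_group * (if (grp == "exposed") 25 else 17) / 34)
    drinking <- sample(c(rep("drinker", n_drink),
                         rep("non-drinker", n_per_group - n_drink)))

    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s%02d", prefix, i)
      f_u <- rnorm_trunc(1, gp$f_unstable_mean, gp$f_unstable_sd, 0.005, gp$f_max)
      f_s <- rnorm_trunc(1, gp$f_stable_mean, gp$f_stable_sd, 0.002, f_u)
      clones <- build_clones(f_u, f_s, config)
      m <- simulate_fish_individual(clones, noise = noise,
                                    n_nuclei = n_nuclei, seed = NULL,
                                    individual_id = id,
                                    probes = config$probes)
      fish[[id]] <- m
      truth_rows[[id]] <- tibble::tibble(
        individual_id = id, group = grp, chromosome = config$probes,
        true_deviant_pct = 100 * ifelse(config$probes %in% config$unstable,
                                        f_u, f_s))
      meta_rows[[id]] <- tibble::tibble(
        individual_id = id, group = grp, constitutional_sex = sexes[i],
        age = ages[i], exposure_months = expo[i],
        smoking = smoking[i], drinking = drinking[i])
    }
  }
  structure(list(fish = fish,
                 metadata = dplyr::bind_rows(meta_rows),
                 truth = dplyr::bind_rows(truth_rows),
                 n_per_group = n_per_group),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individuals (%d per group), %d probes\n",
              length(x$fish), x$n_per_group,
              length(x$fish[[1]]$probes)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Karyotype simulation

#' Band catalog used by the karyotype simulator
#'
#' A small fixed list of major bands per arm; sufficient for recurrence
#' analyses without full ideogram resolution.
#'
#' @return list with elements `p` and `q` (character vectors, ordered from
#'   the centromere outward).
#' @export
band_catalog <- function() {
  list(p = c("p11", "p13", "p21", "p22", "p23"),
       q = c("q11", "q13", "q21", "q22", "q24", "q25", "q31", "q33", "q34"))
}

#' Per-category aberration rate model for karyotype simulation
#'
#' Poisson event rates per metaphase for each aberration category. The
#' defaults emulate the per-metaphase frequencies seen in occupational
#' biomonitoring cohorts: the `"exposed"` preset totals roughly one event
#' per metaphase (dominated by fragile-site expression at 9q12), the
#' `"unexposed"` preset roughly 0.2.
#'
#' @param group `"exposed"` or `"unexposed"` preset.
#' @param rates optional named numeric vector overriding preset rates.
#' @param metaphase_range integer range of metaphases per individual.
#' @param clonal_injections list of `list(token =, n_metaphases =)`
#'   entries: each individual gets the aberration copied verbatim into
#'   `n_metaphases` of its metaphases.
#' @return a `karyotype_rate_model` list.
#' @export
karyotype_rate_model <- function(group = c("exposed", "unexposed"),
                                 rates = NULL,
                                 metaphase_range = c(19L, 95L),
                                 clonal_injections = list()) {
  group <- match.arg(group)
  base <- if (group == "exposed") c(
    monosomy = 0.150, trisomy = 0.050, marker_gain = 0.057,
    del = 0.0270, t = 0.0107, add = 0.0066, der = 0.0057, inv = 0.0049,
    dic = 0.0017, dup = 0.0008, iso = 0.0008, ring = 0.0008,
    fra_9q12 = 0.280, fra_other = 0.140, chtb = 0.050, chrb = 0.022,
    cv_1qh = 0.090, cv_9qh = 0.032, cv_inv9 = 0.013, cv_16qh = 0.044
  ) else c(
    monosomy = 0.0300, trisomy = 0.0050, marker_gain = 0.0055,
    del = 0.0061, t = 0.0020, add = 0.0010, der = 0.0010, inv = 0.0010,
    dic = 0.0005, dup = 0.0005, iso = 0.0001, ring = 0.0001,
    fra_9q12 = 0.060, fra_other = 0.031, chtb = 0.017, chrb = 0.0075,
    cv_1qh = 0.010, cv_9qh = 0.009, cv_inv9 = 0.003, cv_16qh = 0.006
  )
  if (!is.null(rates)) {
    bad <- setdiff(names(rates), names(base))
    if (length(bad))
      stop(sprintf("unknown rate name(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    base[names(rates)] <- rates
  }
  if (any(base < 0)) stop("rates must be nonnegative", call. = FALSE)
  stopifnot(length(metaphase_range) == 2L,
            metaphase_range[1] >= 1L,
            metaphase_range[2] >= metaphase_range[1])
  structure(list(rates = base,
                 metaphase_range = as.integer(metaphase_range),
                 clonal_injections = clonal_injections),
            class = "karyotype_rate_model")
}

random_band <- function(arm = sample(c("p", "q"), 1L)) {
  sample(band_catalog()[[arm]], 1L)
}

# Draw the token text for one event of a category.
random_event_token <- function(category) {
  autosome <- function(n = 1L) as.character(sample(1:22, n))
  switch(category,
    monosomy = paste0("-", autosome()),
    trisomy = paste0("+", autosome()),
    marker_gain = "+mar",
    del = {
      chrom <- autosome()
      n_b <- sample(1:2, 1L)
      arm <- sample(c("p", "q"), 1L)
      bands <- sort(sample(band_catalog()[[arm]], n_b))
      paste0("del(", chrom, ")(", paste(bands, collapse = ""), ")")
    },
    t = {
      chrom <- sort(as.integer(autosome(2L)))
      paste0("t(", chrom[1], ";", chrom[2], ")(",
             random_band(), ";", random_band(), ")")
    },
    add = paste0("add(", autosome(), ")(", random_band(), ")"),
    der = paste0("der(", autosome(), ")"),
    inv = {
      # paracentric, so a simulated inversion never collides with the
      # pericentric chromosome-9 heteromorphism
      arm <- sample(c("p", "q"), 1L)
      bands <- sort(sample(band_catalog()[[arm]], 2L))
      paste0("inv(", autosome(), ")(", paste(bands, collapse = ""), ")")
    },
    dic = {
      chrom <- sort(as.integer(autosome(2L)))
      paste0("dic(", chrom[1], ";", chrom[2], ")(",
             random_band(), ";", random_band(), ")")
    },
    dup = {
      arm <- sample(c("p", "q"), 1L)
      bands <- sort(sample(band_catalog()[[arm]], 2L))
      paste0("dup(", autosome(), ")(", paste(bands, collapse = ""), ")")
    },
    iso = paste0("i(", autosome(), ")(", sample(c("p10", "q10"), 1L), ")"),
    ring = paste0("r(", autosome(), ")"),
    fra_9q12 = "fra(9)(q12)",
    fra_other = {
      repeat {
        chrom <- autosome(); band <- random_band()
        if (!(chrom == "9" && band == "q12")) break
      }
      paste0("fra(", chrom, ")(", band, ")")
    },
    chtb = paste0("chtb(", autosome(), ")(", random_band(), ")"),
    chrb = paste0("chrb(", autosome(), ")(", random_band(), ")"),
    cv_1qh = "1qh+", cv_9qh = "9qh+", cv_16qh = "16qh+",
    cv_inv9 = "inv(9)(p21q22)",
    stop(sprintf("unknown category '%s'", category)))
}

count_delta <- function(token) {
  if (token == "+mar" || grepl("^\\+", token)) 1L
  else if (grepl("^-", token)) -1L
  else 0L
}

#' Simulate karyotype records for a group of individuals
#'
#' Per metaphase, the number of events of each category is Poisson with the
#' model's rate; chromosomes and bands are drawn from the band catalog.
#' Clonal injections are copied verbatim into the stated number of
#' metaphases of every individual. All generated strings round-trip through
#' [parse_karyotype()] / [format_karyotype()].
#'
#' @param model a [karyotype_rate_model()].
#' @param n_individuals number of individuals.
#' @param seed integer seed; required. `NULL` uses the current RNG stream.
#' @param sexes optional vector of `"XX"` / `"XY"` per individual.
#' @param individual_prefix prefix for generated ids.
#' @return tibble with columns `individual_id`, `metaphase_id`,
#'   `karyotype`, `constitutional_sex`.
#' @export
simulate_karyotypes <- function(model = karyotype_rate_model("exposed"),
                                n_individuals = 34L, seed,
                                sexes = NULL, individual_prefix = "S") {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(model, "karyotype_rate_model"), n_individuals >= 1L)
  if (is.null(sexes))
    sexes <- sample(c("XX", "XY"), n_individuals, replace = TRUE)
  stopifnot(length(sexes) == n_individuals, all(sexes %in% c("XX", "XY")))

  rows <- list()
  for (i in seq_len(n_individuals)) {
    id <- sprintf("%s%02d", individual_prefix, i)
    n_meta <- sample(model$metaphase_range[1]:model$metaphase_range[2], 1L)
    for (inj in model$clonal_injections) {
      if (inj$n_metaphases > n_meta)
        stop("clonal injection count exceeds the metaphase count", call. = FALSE)
    }
    inject_into <- lapply(model$clonal_injections, function(inj)
      sample(n_meta, inj$n_metaphases))
    for (j in seq_len(n_meta)) {
      n_ev <- stats::rpois(length(model$rates), model$rates)
      tokens <- unlist(lapply(seq_along(n_ev), function(k)
        replicate(n_ev[k], random_event_token(names(model$rates)[k]))))
      for (k in seq_along(model$clonal_injections)) {
        if (j %in% inject_into[[k]])
          tokens <- c(tokens, model$clonal_injections[[k]]$token)
      }
      count <- 46L + sum(vapply(tokens, count_delta, integer(1)))
      kar <- paste(c(count, sexes[i], tokens), collapse = ",")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        individual_id = id, metaphase_id = sprintf("m%03d", j),
        karyotype = kar, constitutional_sex = sexes[i])
    }
  }
  dplyr::bind_rows(rows)
}
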