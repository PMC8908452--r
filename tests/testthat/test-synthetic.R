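# Synthetic cohort generator: determinism, ground-truth recovery, karyotype
# rate model.

test_that("identical seeds give bit-identical FISH matrices", {
  clones <- list(clone_spec(rep(2L, 6), 0.7), clone_spec(c(3L, rep(2L, 5)), 0.3))
  m1 <- simulate_fish_individual(clones, noise_model(), 100L, seed = 11L)
  m2 <- simulate_fish_individual(clones, noise_model(), 100L, seed = 11L)
  expect_identical(m1$counts, m2$counts)

  co1 <- simulate_cohort(n_per_group = 3L, seed = 5L)
  co2 <- simulate_cohort(n_per_group = 3L, seed = 5L)
  expect_identical(lapply(co1$fish, `[[`, "counts"),
                   lapply(co2$fish, `[[`, "counts"))
  expect_identical(co1$metadata, co2$metadata)

  expect_error(simulate_fish_individual(clones, noise_model(), 10L),
               "seed")
})

test_that("a pure diploid clone with zero noise gives CIN 0 and TD 1", {
  m <- simulate_fish_individual(list(clone_spec(rep(2L, 6), 1)),
                                noise_model(0, 0), 100L, seed = 2L)
  expect_equal(cin_individual(m)$mean_cin, 0)
  expect_equal(clonal_diversity(m)$td, 1)
})

test_that("a 0.7/0.3 trisomic mixture reproduces its closed-form CIN and TD", {
  clones <- list(clone_spec(rep(2L, 6), 0.7),
                 clone_spec(c(3L, rep(2L, 5)), 0.3))
  # exact census: chr2 CIN is exactly 30, TD exactly exp(H(0.7, 0.3))
  m <- simulate_fish_individual(clones, noise_model(0, 0), 100L, seed = 7L,
                                exact = TRUE)
  p <- cin_individual(m)
  expect_equal(unname(p$per_chromosome["chr2"]), 30)
  expect_equal(clonal_diversity(m)$td, exp(0.6108643), tolerance = 1e-6)

  # multinomial census: within 3 binomial SEs
  m2 <- simulate_fish_individual(clones, noise_model(0, 0), 100L, seed = 8L)
  expect_lt(abs(cin_per_chromosome(m2$counts[, "chr2"]) - 30),
            3 * sqrt(0.3 * 0.7 / 100) * 100)
})

test_that("invalid clone mixtures and noise models are rejected", {
  expect_error(simulate_fish_individual(list(clone_spec(rep(2L, 6), 0.6)),
                                        noise_model(0, 0), 10L, seed = 1L),
               "sum to 1")
  expect_error(clone_spec(rep(2L, 6), 0), "frequency")
  expect_error(clone_spec(rep(7L, 6), 1), "signature")
  expect_error(noise_model(0.7, 0), "p_dropout")
})

test_that("the CIN estimator is nearly unbiased against the simulator's ground truth", {
  set.seed(400)
  errs <- replicate(200, {
    f <- runif(1, 0.05, 0.45)
    clones <- list(clone_spec(rep(2L, 6), 1 - f),
                   clone_spec(rep(3L, 6), f))
    m <- simulate_fish_individual(clones, noise_model(0, 0), 100L, seed = NULL)
    cin_individual(m)$mean_cin - 100 * f
  })
  expect_lt(abs(mean(errs)), 1)
})

test_that("default cohort recovers the configured group CIN targets", {
  devs <- sapply(1:5, function(s) {
    co <- simulate_cohort(seed = 1000L + s)
    cc <- cin_cohort(co$fish)$summary
    g <- co$metadata$group[match(cc$individual_id, co$metadata$individual_id)]
    truth_mean <- mean(co$truth$true_deviant_pct[co$truth$group == "exposed"])
    mean(cc$mean_cin[g == "exposed"]) - truth_mean
  })
  expect_lt(abs(mean(devs)), 3)
})

test_that("karyotype simulation respects rates, injections and the grammar", {
  # all rates zero -> every record is a normal 46,XX or 46,XY
  model0 <- karyotype_rate_model("exposed",
                                 rates = setNames(
                                   rep(0, length(karyotype_rate_model("exposed")$rates)),
                                   names(karyotype_rate_model("exposed")$rates)),
                                 metaphase_range = c(5L, 8L))
  kar0 <- simulate_karyotypes(model0, n_individuals = 4L, seed = 3L)
  expect_true(all(kar0$karyotype %in% c("46,XX", "46,XY")))

  # Poisson concentration: del rate 0.1 over 1000 metaphases -> ~100 events
  model1 <- karyotype_rate_model("exposed",
                                 rates = c(monosomy = 0, trisomy = 0,
                                           marker_gain = 0, del = 0.1, t = 0,
                                           add = 0, der = 0, inv = 0, dic = 0,
                                           dup = 0, iso = 0, ring = 0,
                                           fra_9q12 = 0, fra_other = 0,
                                           chtb = 0, chrb = 0, cv_1qh = 0,
                                           cv_9qh = 0, cv_inv9 = 0, cv_16qh = 0),
                                 metaphase_range = c(1000L, 1000L))
  kar1 <- simulate_karyotypes(model1, n_individuals = 1L, seed = 13L)
  n_del <- sum(vapply(kar1$karyotype, function(s)
    length(parse_karyotype(s)$events), integer(1)))
  expect_lt(abs(n_del - 100), 3 * sqrt(100))

  # clonal injection of a structural aberration is called CCA downstream
  model2 <- karyotype_rate_model(
    "unexposed", metaphase_range = c(20L, 20L),
    clonal_injections = list(list(token = "del(6)(q25)", n_metaphases = 2L)))
  kar2 <- simulate_karyotypes(model2, n_individuals = 1L, seed = 9L,
                              sexes = "XX")
  records <- lapply(kar2$karyotype, parse_karyotype)
  calls <- call_clonality(records, "XX")
  expect_equal(calls$call[calls$key == "del(6)(q25)"], "CCA")

  expect_error(karyotype_rate_model("exposed", rates = c(bogus = 1)),
               "unknown rate")
})
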