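# Event classification, clonality calls, tallies, carrier and paired
# tables, recurrent regions.

test_that("metaphase classification resolves explicit and complement-implied events", {
  cl <- classify_metaphase(rec("45,XX,-20"), "XX")
  expect_equal(cl$category_group, "monosomies")
  expect_equal(cl$chromosome, "20")

  cl <- classify_metaphase(rec("47,XY,+mar"), "XY")
  expect_equal(cl$category_group, "trisomies")
  expect_true(is.na(cl$chromosome))
  expect_equal(cl$key, "+mar")

  # 45,X against constitutional XY means the Y was lost; against XX the X
  expect_equal(classify_metaphase(rec("45,X"), "XY")$key, "-Y")
  expect_equal(classify_metaphase(rec("45,X"), "XX")$key, "-X")
  expect_equal(classify_metaphase(rec("47,XXX"), "XX")$key, "+X")

  # CV and break tokens pass through with their category group
  cl <- classify_metaphase(rec("46,XX,1qh+,chtb(1)(q21),fra(9)(q12),fra(2)(q21)"), "XX")
  expect_setequal(cl$category_group,
                  c("cv_1qh", "chtb_chrb", "fra_9q12", "fra_other"))
})

test_that("a chromosome count inconsistent with the events warns and keeps explicit events", {
  expect_warning(cl <- classify_metaphase(rec("44,XX,-20"), "XX"),
                 "disagrees")
  expect_equal(nrow(cl), 1L)  # the explicit -20 is retained
  # complement inference is dropped when the count cannot be reconciled
  expect_warning(cl <- classify_metaphase(rec("46,X"), "XY"), "disagrees")
  expect_equal(nrow(cl), 0L)
})

test_that("clonality thresholds: >=2 identical structural/gain, >=3 identical loss", {
  records <- c(
    replicate(2, rec("46,XX,del(6)(q25)"), simplify = FALSE),
    replicate(2, rec("45,XX,-20"), simplify = FALSE),
    replicate(3, rec("45,XX,-7"), simplify = FALSE),
    replicate(2, rec("47,XX,+22"), simplify = FALSE),
    list(rec("46,XX,t(2;12)(q33;p13)")),
    replicate(20, rec("46,XX"), simplify = FALSE)
  )
  calls <- call_clonality(records, "XX")
  get <- function(k) calls$call[calls$key == k]
  expect_equal(get("del(6)(q25)"), "CCA")    # 2 structural -> clone
  expect_equal(get("-20"), "NCCA")           # 2 losses -> below loss threshold
  expect_equal(get("-7"), "CCA")             # 3 losses -> clone
  expect_equal(get("+22"), "CCA")            # 2 gains -> clone
  expect_equal(get("t(2;12)(q33;p13)"), "NCCA")

  # order invariance
  for (i in 1:3) {
    shuffled <- sample(records)
    calls2 <- call_clonality(shuffled, "XX")
    expect_equal(dplyr::arrange(calls2, key), dplyr::arrange(calls, key))
  }

  # fragilities, breaks and CVs never receive calls
  calls3 <- call_clonality(replicate(5, rec("46,XX,fra(9)(q12),1qh+"),
                                     simplify = FALSE), "XX")
  expect_equal(nrow(calls3), 0L)
})

test_that("individual tallies match a naive recount and percentages round half-up", {
  kar <- simulate_karyotypes(karyotype_rate_model("exposed",
                                                  metaphase_range = c(10L, 20L)),
                             n_individuals = 6L, seed = 5L,
                             sexes = rep("XX", 6L))
  for (id in unique(kar$individual_id)) {
    records <- lapply(kar$karyotype[kar$individual_id == id], parse_karyotype)
    tl <- tally_individual(records, group_metaphase_total = 500L,
                           constitutional_sex = "XX")
    # naive recount straight over parsed categories
    cats <- unlist(lapply(records, function(r)
      vapply(r$events, function(e) e$category, character(1))))
    expect_equal(tl$monosomies, sum(cats == "loss"))
    expect_equal(tl$trisomies, sum(cats %in% c("gain", "marker_gain")))
    expect_equal(tl$scas,
                 sum(cats %in% c("del", "t", "add", "der", "inv", "dic",
                                 "dup", "iso", "ring")))
    expect_equal(tl$chtb_chrb, sum(cats %in% c("chtb", "chrb")))
    expect_equal(tl$cv_1qh + tl$cv_9qh + tl$cv_16qh + tl$cv_inv9,
                 sum(grepl("^cv_", cats)))
    expect_equal(tl$fra_other + tl$fra_9q12, sum(cats == "fra"))
    expect_equal(tl$total_events, length(cats))
    expect_equal(tl$pct_of_group_metaphases,
                 floor(100 * length(cats) / 500 * 100 + 0.5) / 100)
  }

  tl0 <- tally_individual(list(rec("46,XY")), 100L, "XY")
  expect_equal(tl0$total_events, 0L)
  expect_equal(tl0$pct_of_group_metaphases, 0)

  expect_error(tally_individual(list(rec("46,XY")), 0L, "XY"), "positive")
  expect_error(tally_individual(list(rec("46,XY")), NA, "XY"), "positive")
})

test_that("carrier tables count carriers, not events, and agree with exact enumeration", {
  mk <- function(monosomies) tibble::tibble(
    individual_id = sprintf("i%02d", seq_along(monosomies)),
    monosomies = monosomies, trisomies = 0L, scas = 0L, chtb_chrb = 0L,
    fra_other = 0L, fra_9q12 = 0L, cv_1qh = 0L, cv_9qh = 0L,
    cv_inv9 = 0L, cv_16qh = 0L,
    total_events = monosomies, n_metaphases = 20L)
  # 32/34 vs 13/34 carriers; multiple events in one carrier count once
  te <- mk(c(rep(3L, 32), 0L, 0L))
  tu <- mk(c(rep(1L, 13), rep(0L, 21)))
  ct <- carriers_table(te, tu, categories = "monosomies")
  expect_equal(ct$exposed_carriers, 32L)
  expect_equal(ct$pct_exposed, 94.1)
  expect_equal(ct$unexposed_carriers, 13L)
  expect_equal(ct$pct_unexposed, 38.2)
  expect_equal(ct$p_two_sided, enum_fisher_p(32, 2, 13, 21), tolerance = 1e-10)

  # identical carrier profiles -> p = 1
  ct2 <- carriers_table(te, te, categories = "monosomies")
  expect_equal(ct2$p_two_sided, 1)

  # adding an event never decreases a carrier count (monotonicity)
  te2 <- te; te2$monosomies[33] <- 1L; te2$total_events[33] <- 1L
  ct3 <- carriers_table(te2, tu, categories = "monosomies")
  expect_gte(ct3$exposed_carriers, ct$exposed_carriers)
})

test_that("paired table reports per-pair percentages of the group totals", {
  mk1 <- function(ev) tibble::tibble(total_events = ev, n_metaphases = 40L)
  pt <- paired_event_table(mk1(c(138L, 0L)), mk1(c(14L, 5L)), 1493L, 1061L)
  expect_equal(pt$pct_exposed, c(9.24, 0))
  expect_equal(pt$pct_unexposed[1], 1.32)  # exact half-up recomputation
  expect_true(all(pt$p_two_sided >= 0 & pt$p_two_sided <= 1))
})

test_that("recurrent regions count distinct individuals per band", {
  by_ind <- list(
    A = list(rec("46,XX,del(12)(p13)"), rec("46,XX,del(12)(p13)")),
    B = list(rec("46,XY,add(12)(p13)"), rec("46,XY,del(6)(p23)")),
    C = list(rec("46,XX,t(5;12)(q23;p13)"))
  )
  rr <- recurrent_regions(by_ind, min_individuals = 2L)
  expect_equal(rr$chromosome[1], "12")
  expect_equal(rr$band[1], "p13")
  expect_equal(rr$n_individuals[1], 3L)  # distinct individuals, not events
  expect_false(any(rr$band == "p23"))    # single-individual band dropped

  # planted recurrent band tops the table on generated data
  model <- karyotype_rate_model(
    "unexposed", metaphase_range = c(10L, 15L),
    clonal_injections = list(list(token = "del(12)(p13)", n_metaphases = 2L)))
  kar <- simulate_karyotypes(model, n_individuals = 6L, seed = 21L)
  by_ind2 <- lapply(split(kar$karyotype, kar$individual_id),
                    function(ss) lapply(ss, parse_karyotype))
  rr2 <- recurrent_regions(by_ind2, min_individuals = 2L)
  expect_equal(rr2$band[1], "p13")
  expect_equal(rr2$chromosome[1], "12")
  expect_equal(rr2$n_individuals[1], 6L)
})
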