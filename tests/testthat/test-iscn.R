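# ISCN subset: tokenizer, karyotype parsing, canonical formatting.

test_that("aberration tokens parse to the right category, chromosomes and bands", {
  cases <- list(
    list("del(6)(q25)", "del", "6", "q25"),
    list("del(X)(q25)", "del", "X", "q25"),
    list("del(1)(q21q31)", "del", "1", c("q21", "q31")),
    list("t(7;14)(p22;q12)", "t", c("7", "14"), c("p22", "q12")),
    list("t(2;12)(q33;p13)", "t", c("2", "12"), c("q33", "p13")),
    list("add(12)(p13)", "add", "12", "p13"),
    list("add(12)(?)", "add", "12", "?"),
    list("inv(2)(p11p13)", "inv", "2", c("p11", "p13")),
    list("inv(9)(p21q22)", "cv_inv9", "9", c("p21", "q22")),
    list("inv(9)(p21q21)", "cv_inv9", "9", c("p21", "q21")),
    list("inv(9)(q21q31)", "inv", "9", c("q21", "q31")),
    list("dic(1;3)(q21;p14)", "dic", c("1", "3"), c("q21", "p14")),
    list("dup(1)(q21q32)", "dup", "1", c("q21", "q32")),
    list("i(17)(q10)", "iso", "17", "q10"),
    list("r(15)", "ring", "15", character(0)),
    list("der(9)", "der", "9", character(0)),
    list("der(9)t(9;12)(q34;p13)", "der", c("9", "12"), character(0)),
    list("fra(9)(q12)", "fra", "9", "q12"),
    list("chtb(1)(q21)", "chtb", "1", "q21"),
    list("chrb(3)(p14)", "chrb", "3", "p14"),
    list("+mar", "marker_gain", character(0), character(0)),
    list("+22", "gain", "22", character(0)),
    list("-20", "loss", "20", character(0)),
    list("-y", "loss", "Y", character(0)),
    list("1qh+", "cv_1qh_plus", "1", character(0)),
    list("9qh+", "cv_9qh_plus", "9", character(0)),
    list("16qh+", "cv_16qh_plus", "16", character(0))
  )
  for (cs in cases) {
    e <- parse_aberration(cs[[1]])
    expect_equal(e$category, cs[[2]], info = cs[[1]])
    expect_equal(e$chromosomes, cs[[3]], info = cs[[1]])
    expect_equal(e$breakpoints, cs[[4]], info = cs[[1]])
  }
})

test_that("malformed tokens are rejected and the error names the offending span", {
  expect_error(parse_aberration("qel(6)(q25)"), "unknown prefix")
  expect_error(parse_aberration("del(23)(q25)"), "bad chromosome label '23'")
  expect_error(parse_aberration("del(0)(q25)"), "bad chromosome label")
  expect_error(parse_aberration("del(6)(z25)"), "bad band")
  expect_error(parse_aberration("del(6)(q25"), "unbalanced|stray")
  expect_error(parse_aberration("del(6)(q25)x"), "unbalanced|stray")
  expect_error(parse_aberration("t(7)(p22)"), "two or more chromosomes")
  expect_error(parse_aberration("t(7;14)(p22)"), "band count")
  expect_error(parse_aberration("del(6;7)(q25;q25)"), "single chromosome")
  expect_error(parse_aberration("del(6)"), "one chromosome group and one band group")
  expect_error(parse_aberration("+23"), "bad chromosome label")
  expect_error(parse_aberration("2qh+"), "unknown prefix")
  expect_error(parse_aberration(""), "empty")
})

test_that("karyotype strings parse into metaphase records", {
  r <- parse_karyotype("46,XX,inv(9)(p21q22)")
  expect_equal(r$chromosome_count, 46L)
  expect_equal(r$sex_complement, "XX")
  expect_length(r$events, 1L)
  expect_equal(r$events[[1]]$category, "cv_inv9")
  expect_equal(r$events[[1]]$chromosomes, "9")

  r <- parse_karyotype("46,XY")
  expect_equal(r$chromosome_count, 46L)
  expect_length(r$events, 0L)
  expect_true(is_normal_karyotype(r))

  r <- parse_karyotype("47,XX,+22")
  expect_equal(r$chromosome_count, 47L)
  expect_equal(r$events[[1]]$category, "gain")
  expect_equal(r$events[[1]]$chromosomes, "22")
  expect_false(is_normal_karyotype(r))

  r <- parse_karyotype("45,X")
  expect_equal(r$sex_complement, "X")

  # whitespace around commas is tolerated; complement case-normalized
  r <- parse_karyotype("46, xy , del(6)(q25)")
  expect_equal(r$sex_complement, "XY")
  expect_equal(r$events[[1]]$category, "del")

  expect_error(parse_karyotype("46"), "count,sexComplement")
  expect_error(parse_karyotype("fortysix,XX"), "not an integer")
  expect_error(parse_karyotype("46,ZZ"), "bad sex complement")
  expect_error(parse_karyotype("46,XX,qel(6)(q25)"), "unknown prefix")
})

test_that("parse/format round-trips on hand-written and generated records", {
  for (s in c("46,XY", "47,XX,+22", "46,XX,inv(9)(p21q22)",
              "45,XY,-20,del(6)(q25)", "46,XX,t(7;14)(p22;q12),1qh+")) {
    expect_equal(format_karyotype(parse_karyotype(s)), s)
  }

  kar <- simulate_karyotypes(karyotype_rate_model("exposed",
                                                  metaphase_range = c(5L, 10L)),
                             n_individuals = 8L, seed = 42L)
  strings <- sample(kar$karyotype, 50L)
  for (s in strings) {
    r1 <- parse_karyotype(s)
    s2 <- format_karyotype(r1)
    expect_equal(s2, s)
    expect_same_record(parse_karyotype(s2), r1)
  }
})

test_that("every accepted token falls in exactly one category family", {
  nca <- c("loss", "gain", "marker_gain")
  sca <- c("del", "t", "add", "der", "inv", "dic", "dup", "iso", "ring")
  brk <- c("chtb", "chrb")
  fra <- "fra"
  cv  <- c("cv_1qh_plus", "cv_9qh_plus", "cv_16qh_plus", "cv_inv9")
  families <- list(nca, sca, brk, fra, cv)
  # pairwise disjoint
  for (i in seq_along(families))
    for (j in seq_along(families))
      if (i < j) expect_length(intersect(families[[i]], families[[j]]), 0L)

  kar <- simulate_karyotypes(karyotype_rate_model("exposed",
                                                  metaphase_range = c(5L, 8L)),
                             n_individuals = 5L, seed = 99L)
  cats <- unlist(lapply(kar$karyotype, function(s)
    vapply(parse_karyotype(s)$events, function(e) e$category, character(1))))
  expect_true(all(cats %in% unlist(families)))
})
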