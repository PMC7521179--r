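make_labels <- function(positive_wells, scored_wells = all_wells()) {
  stats::setNames(ifelse(scored_wells %in% positive_wells,
                         "positive", "negative"), scored_wells)
}

test_that("plate results count positives, scored and missing wells", {
  all_neg <- build_plate_result(make_labels(character(0)), plate_id = "P")
  expect_equal(all_neg$n_positive, 0L)
  expect_equal(all_neg$positive_fraction, 0)

  all_pos <- build_plate_result(make_labels(all_wells()))
  expect_equal(all_pos$positive_fraction, 1)

  left <- all_wells()[well_to_rowcol(all_wells())[, "col"] <= 6]
  half <- build_plate_result(make_labels(left))
  expect_equal(half$n_positive, 48L)
  expect_equal(half$positive_fraction, 0.5)

  # missing wells excluded from n_scored
  sub <- build_plate_result(make_labels("A1", scored_wells = c("A1", "B2")))
  expect_equal(sub$n_scored, 2L)
  expect_equal(sub$positive_fraction, 0.5)
  expect_equal(sum(sub$grid == "missing"), 94L)
})

test_that("text layouts mark wells with + - .", {
  pr <- build_plate_result(make_labels("A1", c("A1", "A2")), plate_id = "P")
  lines <- plate_layout_text(pr)
  expect_length(lines, 9L)
  expect_match(lines[2], "^A  \\+ -( \\.){10}$")
  expect_output(print(pr), "1/2 wells positive")
})

test_that("half-plate counts split by the requested axis and sum to total", {
  left <- all_wells()[well_to_rowcol(all_wells())[, "col"] <= 6]
  pr <- build_plate_result(make_labels(left))
  expect_equal(half_plate_counts(pr), c(half1 = 48L, half2 = 0L))

  checker <- all_wells()[(well_to_rowcol(all_wells())[, "row"] +
                          well_to_rowcol(all_wells())[, "col"]) %% 2 == 0]
  prc <- build_plate_result(make_labels(checker))
  expect_equal(unname(half_plate_counts(prc)), c(24L, 24L))
  expect_equal(unname(half_plate_counts(prc, axis = "row")), c(24L, 24L))

  set.seed(31)
  for (i in 1:20) {
    pos <- sample(all_wells(), sample(0:96, 1))
    pr <- build_plate_result(make_labels(pos))
    for (ax in c("column", "row"))
      expect_equal(sum(half_plate_counts(pr, axis = ax)), pr$n_positive)
  }
})

test_that("exact Mann-Whitney p-values match full enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6)),
               list(u_statistic = 0, p_value = 0.1, method = "exact",
                    n_a = 3L, n_b = 3L))
  set.seed(17)
  for (i in 1:25) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    v <- sample(1:100, na + nb)   # distinct -> no ties
    a <- v[1:na]; b <- v[-(1:na)]
    got <- mann_whitney(a, b)
    ora <- enum_mann_whitney(a, b)
    expect_equal(got$u_statistic, ora$u)
    expect_equal(got$p_value, ora$p, tolerance = 1e-12)
    # group swap reflects U and keeps p
    sw <- mann_whitney(b, a)
    expect_equal(sw$u_statistic, na * nb - got$u_statistic)
    expect_equal(sw$p_value, got$p_value)
  }
})

test_that("tied and degenerate samples fall back gracefully", {
  expect_equal(mann_whitney(5, 5)$p_value, 1)
  expect_equal(mann_whitney(1, 2)$p_value, 1)  # single untied pair
  expect_error(mann_whitney(numeric(0), 1),
               class = "organoidscreen_validation_error")
})

test_that("group comparisons use the plate as the unit of analysis", {
  frac_plate <- function(f, id = "P") {
    k <- round(96 * f)
    build_plate_result(make_labels(all_wells()[seq_len(k)]), plate_id = id)
  }
  a <- lapply(c(0.33, 0.35, 0.31), frac_plate)
  b <- lapply(c(0.20, 0.22, 0.21), frac_plate)
  cmpr <- compare_groups(a, b, c("treated", "control"))
  expect_equal(cmpr$u_statistic, 9)
  expect_equal(cmpr$p_value, 0.1)
  expect_equal(cmpr$values_a, sapply(a, `[[`, "positive_fraction"))

  same <- compare_groups(a, a)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_a, same$mean_b)

  const <- lapply(rep(0.25, 3), frac_plate)
  expect_equal(compare_groups(const, b)$sd_a, 0)

  expect_error(compare_groups(list(), b),
               class = "organoidscreen_validation_error")
  expect_output(print(cmpr), "Mann-Whitney U=9")
})

test_that("organoid-level comparisons pool per-well scores", {
  mk <- function(scores) {
    ids <- all_wells()[seq_along(scores)]
    build_plate_result(make_labels(character(0), ids),
                       stats::setNames(scores, ids))
  }
  cmpr <- compare_groups(list(mk(c(1, 2, 3))), list(mk(c(4, 5, 6))),
                         unit = "organoid")
  expect_equal(cmpr$p_value, 0.1)
  expect_equal(length(cmpr$values_a), 3L)
})
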