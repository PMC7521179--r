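test_that("disk rasterization areas are exact lattice counts", {
  sw <- tiny_spec(patches = list(list(center = c(32, 32), radius = 5,
                                      intensity = 120)))
  rw <- render_well(sw)
  # lattice points with dx^2 + dy^2 <= 25
  expect_equal(rw$truth$positive_area_px,
               sum(outer((-5:5)^2, (-5:5)^2, `+`) <= 25))
  expect_equal(rw$truth$positive_area_px, 81L)
  expect_equal(rw$truth$organoid_area_px,
               sum(outer((-20:20)^2, (-20:20)^2, `+`) <= 400))
  expect_equal(rw$truth$label, "positive")
})

test_that("rendering is deterministic given the seed", {
  sw <- tiny_positive_spec(noise_sd = 4, seed = 99)
  a <- render_well(sw); b <- render_well(sw)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  sw2 <- sw; sw2$seed <- 100L
  expect_false(identical(render_well(sw2)$image$pixels, a$image$pixels))
})

test_that("patchless wells have zero ground truth and zero score", {
  rw <- render_well(tiny_spec())
  expect_equal(rw$truth$positive_area_px, 0L)
  expect_equal(rw$truth$label, "negative")
  expect_equal(compute_score(rw$image)$score, 0L)
})

test_that("patches outside the organoid are rejected", {
  expect_error(
    tiny_spec(patches = list(list(center = c(2, 2), radius = 3,
                                  intensity = 100))),
    class = "organoidscreen_validation_error")
  expect_error(synthetic_well_spec(height = 64, width = 64,
                                   organoid_radius = 40),
               class = "organoidscreen_validation_error")  # disk too big
})

test_that("noiseless scores recover ground-truth patch areas exactly", {
  for (seed in 1:10) {
    rw <- render_well(tiny_positive_spec(seed = seed))
    expect_identical(compute_score(rw$image)$score, rw$truth$positive_area_px)
  }
})

test_that("plate labels follow the positive rate and column gradient", {
  expect_true(all(generate_plate(positive_rate = 0, seed = 1,
                                 render = FALSE)$labels == "negative"))
  expect_true(all(generate_plate(positive_rate = 1, seed = 1,
                                 render = FALSE)$labels == "positive"))

  # binomial moments over an ensemble of label-only plates
  counts <- vapply(1:300, function(s)
    sum(generate_plate(positive_rate = 0.25, seed = s,
                       render = FALSE)$labels == "positive"), numeric(1))
  expect_lt(abs(mean(counts) - 24), 3 * sqrt(96 * 0.25 * 0.75 / 300))

  # 4x rate on columns 1-6: left half must dominate
  grad <- rep(c(4, 1), each = 6)
  lab <- generate_plate(positive_rate = 0.1, edge_gradient = grad,
                        seed = 8, render = FALSE)$labels
  cols <- well_to_rowcol(names(lab))[, "col"]
  left <- sum(lab[cols <= 6] == "positive")
  right <- sum(lab[cols > 6] == "positive")
  expect_gt(left, right)

  expect_error(generate_plate(positive_rate = 2),
               class = "organoidscreen_validation_error")
  expect_error(generate_plate(n_wells = 0),
               class = "organoidscreen_validation_error")
})

test_that("plates are reproducible well-by-well", {
  full <- generate_plate(n_wells = 8, positive_rate = 0.5,
                         positive_spec = tiny_positive_spec(),
                         negative_spec = tiny_spec(), seed = 21)
  # regenerating the same plate reproduces each well independently
  again <- generate_plate(n_wells = 8, positive_rate = 0.5,
                          positive_spec = tiny_positive_spec(),
                          negative_spec = tiny_spec(), seed = 21)
  for (w in names(full$plate$wells))
    expect_identical(full$plate$wells[[w]]$pixels,
                     again$plate$wells[[w]]$pixels)
})

test_that("sampled score sets match their distribution family", {
  s <- sample_scores(0, 10000, seed = 12)
  expect_true(all(s$labels == "negative"))
  expect_lt(abs(median(s$scores) - exp(4)) / exp(4), 0.05)

  s2 <- sample_scores(5, 5, seed = 3)
  expect_identical(sample_scores(5, 5, seed = 3)$scores, s2$scores)

  g <- sample_scores(0, 5000, neg_dist = list(family = "gamma", shape = 2,
                                              rate = 0.1), seed = 4)
  expect_lt(abs(mean(g$scores) - 20) / 20, 0.1)

  expect_error(sample_scores(1, 1, pos_dist = list(family = "weird")),
               class = "organoidscreen_validation_error")
})
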