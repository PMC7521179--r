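test_that("background is the mean of the centered rectangle", {
  expect_equal(estimate_background(matrix(10, 33, 47), 0.5), 10)

  m <- matrix(0, 10, 10); m[c(1, 10), c(1, 10)] <- 100
  expect_equal(estimate_background(m, 0.8), 0)  # central 8x8 excludes corners

  m5 <- matrix(0, 5, 5); m5[3, 3] <- 25
  expect_equal(estimate_background(m5, 0.2), 25)  # 1x1 rectangle at center

  # odd leftover margin: extra row/column at bottom/right
  m6 <- matrix(0, 6, 6); m6[1, ] <- 60; m6[6, ] <- 6
  # rect dim round(0.8*6)=5, offset floor(1/2)=0 -> rows 1..5, top row in
  expect_equal(estimate_background(m6, 0.8), mean(m6[1:5, 1:5]))

  expect_error(estimate_background(m5, 0), class = "organoidscreen_validation_error")
  expect_error(estimate_background(m5, 1.2), class = "organoidscreen_validation_error")
})

test_that("pipeline masks follow subtract-contrast-threshold semantics", {
  p <- scoring_params(alpha = 1, beta = 0, pixel_threshold = 50)

  expect_true(all(apply_pipeline(matrix(123, 32, 32), p) == 0))  # self-subtraction

  img <- matrix(0, 64, 64); img[10, 10] <- 200
  mask <- apply_pipeline(img, p)
  expect_equal(sum(mask == 255), 1L)
  expect_equal(mask[10, 10], 255L)

  # beta = 255 saturates everything to the positive value
  psat <- scoring_params(alpha = 1, beta = 255, pixel_threshold = 255)
  expect_true(all(apply_pipeline(img, psat) == 255))
})

test_that("compute_score counts block pixels as derived by hand", {
  img <- matrix(0, 100, 100)
  img[40:49, 40:49] <- 200
  sc <- compute_score(well_image(img), scoring_params())
  # central 80x80 rectangle holds the whole block: bg = 20000/6400
  expect_equal(sc$background, 20000 / 6400)
  expect_equal(sc$score, 100L)
  expect_equal(sc$area_px, 10000L)
})

test_that("scores match the naive per-pixel oracle exactly on random inputs", {
  set.seed(101)
  for (i in 1:40) {
    img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    rf <- runif(1, 0.1, 1)
    a <- runif(1, 0.2, 3); b <- runif(1, -30, 30)
    thr <- runif(1, 1, 255)
    p <- scoring_params(rect_fraction = rf, alpha = a, beta = b,
                        pixel_threshold = thr)
    expect_identical(compute_score(well_image(img), p)$score,
                     naive_score(img, rf, a, b, thr))
  }
})

test_that("score is monotone in threshold and invariant to uniform shifts", {
  set.seed(7)
  img <- matrix(sample(0:150, 48 * 48, TRUE), 48, 48)
  scores <- vapply(c(5, 20, 50, 120, 200, 255), function(t)
    compute_score(well_image(img),
                  scoring_params(pixel_threshold = t))$score, integer(1))
  expect_true(all(diff(scores) <= 0))

  # a constant offset is absorbed by the background estimate
  p <- scoring_params(pixel_threshold = 40)
  expect_equal(compute_score(well_image(img + 50), p)$score,
               compute_score(well_image(img), p)$score)

  # constant images never score when beta stays below the threshold
  for (c0 in c(0, 17, 255))
    expect_equal(compute_score(well_image(matrix(c0, 20, 20)),
                               scoring_params(beta = 30,
                                              pixel_threshold = 50))$score, 0L)
})

test_that("16-bit input is rescaled so the threshold keeps one meaning", {
  set.seed(13)
  img8 <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  s8 <- compute_score(well_image(img8, bit_depth = 8), scoring_params())
  s16 <- compute_score(well_image(img8 * 257, bit_depth = 16), scoring_params())
  expect_equal(s16$score, s8$score)
})

test_that("area fractions divide score by caller-supplied organoid area", {
  expect_equal(score_to_area_fraction(0, 10000), 0)
  expect_equal(score_to_area_fraction(130, 10000), 0.013)
  expect_warning(f <- score_to_area_fraction(150, 100), "fraction > 1")
  expect_equal(f, 1.5)
  expect_error(score_to_area_fraction(1, 0), class = "organoidscreen_validation_error")
})

test_that("invalid scoring parameters are rejected", {
  expect_error(scoring_params(rect_fraction = 0), class = "organoidscreen_validation_error")
  expect_error(scoring_params(alpha = -1), class = "organoidscreen_validation_error")
  expect_error(scoring_params(pixel_threshold = 0), class = "organoidscreen_validation_error")
  expect_error(scoring_params(pixel_threshold = 300), class = "organoidscreen_validation_error")
})
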