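test_that("anchor rules on canonical constructed series", {
  expect_length(find_anchors_increment(seq(100, 10, by = -10), L = 1), 0)
  expect_length(find_anchors_increment(rep(5, 50), L = 1), 0)
  x <- rep(c(800, 800, 820, 800), 10)
  a <- find_anchors_increment(x, L = 1)
  expect_true(all(x[a] == 820))
  expect_equal(length(a), sum(x == 820) - 0)

  expect_length(find_anchors_averaged(rep(3, 40), M = 9, L = 10), 0)
  inc <- seq_len(60)
  a2 <- find_anchors_averaged(inc, M = 9, L = 10)
  expect_equal(a2, seq(11, 51))  # every eligible interior index
})

test_that("averaged anchors on a slow sinusoid match brute-force evaluation exactly", {
  t_beat <- cumsum(rep(0.8, 200))
  x <- sin(2 * pi * 0.05 * t_beat)
  expect_identical(find_anchors_averaged(x, M = 9, L = 20),
                   as.integer(brute_anchors_averaged(x, M = 9, L = 20)))
})

test_that("prsa_average fulfils its exact arithmetic contract", {
  set.seed(40)
  x <- rnorm(500)
  a <- find_anchors_increment(x, L = 10)
  res <- prsa_average(x, a, L = 10)
  expect_length(res$curve, 20)
  expect_equal(res$anchor_count, length(a))
  expect_lt(max(abs(res$curve - brute_prsa_curve(x, a, 10))), 1e-12)

  one <- prsa_average(x, a[3], L = 10)
  expect_equal(one$curve, x[(a[3] - 10):(a[3] + 9)])

  none <- prsa_average(x, integer(0), L = 10)
  expect_false(none$defined)
  expect_true(is.na(deceleration_capacity(none)))
  expect_true(is.na(prd_from_curve(none)))
})

test_that("windows containing flagged samples are excluded", {
  x <- rep(c(800, 820), 30)
  flags <- rep(FALSE, 60)
  flags[30] <- TRUE
  a <- find_anchors_increment(x, L = 5, flags = flags)
  expect_false(any(a >= 25 & a <= 34))
  a_all <- find_anchors_increment(x, L = 5)
  expect_true(any(a_all >= 25 & a_all <= 34))
})

test_that("DC formula arithmetic on a constructed curve", {
  res <- structure(list(curve = c(rep(800, 10), 798, 800, 810, 812, rep(800, 6)),
                        k = seq(-12, 7), anchor_count = 5L, anchors = 1:5,
                        defined = TRUE, L = 12L),
                   class = "prsa_result")
  expect_equal(deceleration_capacity(res), (810 + 812 - 800 - 798) / 4)
})

test_that("isolated RR prolongations force DC = 5 ms exactly", {
  rr <- rep(800, 200)
  rr[seq(30, 190, by = 30)] <- 820
  out <- dc_from_tachogram(tachogram(rr), L = 12)
  expect_identical(out$dc, 5)
  expect_equal(out$prsa$anchor_count, length(seq(30, 190, by = 30)))
})

test_that("PRD of simple curves is max minus min", {
  mk <- function(curve) structure(list(curve = curve, k = seq_along(curve),
                                       anchor_count = 1L, anchors = 1L,
                                       defined = TRUE, L = length(curve) / 2),
                                  class = "prsa_result")
  expect_equal(prd_from_curve(mk(rep(2, 10))), 0)
  expect_equal(prd_from_curve(mk(c(1, 3, 2))), 2)
})

test_that("PRSA is shift-invariant and scale-equivariant", {
  set.seed(41)
  x <- 800 + 30 * sin(2 * pi * 0.05 * cumsum(rep(0.8, 300))) + rnorm(300, 0, 10)
  a_inc <- find_anchors_increment(x, L = 12)
  a_avg <- find_anchors_averaged(x, M = 9, L = 20)

  expect_identical(find_anchors_increment(x + 55, L = 12), a_inc)
  expect_identical(find_anchors_averaged(x + 55, M = 9, L = 20), a_avg)
  expect_identical(find_anchors_increment(2.5 * x, L = 12), a_inc)

  base_dc <- deceleration_capacity(prsa_average(x, a_inc, 12))
  base_prd <- prd_from_curve(prsa_average(x, a_avg, 20))
  shift_dc <- deceleration_capacity(prsa_average(x + 55, a_inc, 12))
  shift_prd <- prd_from_curve(prsa_average(x + 55, a_avg, 20))
  expect_equal(shift_dc, base_dc, tolerance = 1e-9)
  expect_equal(shift_prd, base_prd, tolerance = 1e-9)

  expect_equal(deceleration_capacity(prsa_average(2.5 * x, a_inc, 12)),
               2.5 * base_dc, tolerance = 1e-9)
  expect_equal(prd_from_curve(prsa_average(2.5 * x, a_avg, 20)),
               2.5 * base_prd, tolerance = 1e-9)
})

test_that("removing anchors re-averages the curve exactly", {
  set.seed(42)
  x <- rnorm(400)
  a <- find_anchors_increment(x, L = 8)
  sub <- a[seq(1, length(a), by = 2)]
  res <- prsa_average(x, sub, 8)
  expect_lt(max(abs(res$curve - brute_prsa_curve(x, sub, 8))), 1e-12)
})

test_that("an acceleration-flavoured anchor rule mirrors DC on mirrored series", {
  # negating the series swaps decelerations and accelerations; the increment
  # rule on -x finds the decrement anchors of x, and the DC statistic of the
  # negated series is minus the acceleration-side statistic of x
  rr <- rep(800, 200)
  rr[seq(30, 190, by = 30)] <- 780
  neg <- prsa_average(-rr, find_anchors_increment(-rr, L = 12), 12)
  expect_identical(-deceleration_capacity(neg), -5)
})
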