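test_that("phospho percentage formulas reproduce hand-evaluated values", {
  # multiplex convention: 100 * 2p / (p + t)
  expect_equal(pctPhosphoMultiplex(1, 3), 50)
  expect_equal(pctPhosphoMultiplex(5, 5), 100)
  expect_equal(pctPhosphoMultiplex(0, 7), 0)
  expect_equal(pctPhosphoMultiplex(3, 1), 150)
  expect_equal(pctPhosphoMultiplex(2, 0), 200)
  # western-blot convention: 100 * p / t
  expect_equal(pctPhosphoWB(2, 8), 25)
  expect_equal(pctPhosphoWB(8, 8), 100)
  expect_equal(pctPhosphoWB(0, 4), 0)
  expect_equal(pctPhosphoWB(9, 3), 300)
  # undefined denominators are signaled
  expect_error(pctPhosphoMultiplex(0, 0), "undefined")
  expect_error(pctPhosphoWB(1, 0), "undefined")
  expect_error(pctPhosphoMultiplex(-1, 2), "non-negative")
})

test_that("phospho percentages are scale invariant and bounded", {
  set.seed(31)
  p <- runif(50, 0, 100); t <- runif(50, 1e-3, 100)
  m <- pctPhosphoMultiplex(p, t)
  expect_true(all(m >= 0 & m <= 200))
  for (k in c(0.01, 3, 1e4)) {
    expect_equal(pctPhosphoMultiplex(k * p, k * t), m)
    expect_equal(pctPhosphoWB(k * p, k * t), pctPhosphoWB(p, t))
  }
})

test_that("orientation fraction counts folded angles within tolerance", {
  expect_equal(orientationFraction(c(0, 1, 4, 6, 90))$fraction, 3 / 5)
  expect_equal(orientationFraction(rep(0, 10))$fraction, 1)
  # 176 folds to -4 and counts as oriented
  expect_equal(foldAngles(176), -4)
  expect_equal(orientationFraction(c(176))$fraction, 1)
  expect_equal(foldAngles(c(-90, 270, 90.5)), c(90, 90, -89.5))
  expect_error(orientationFraction(numeric()), "invalid input")
  # histogram covers (-90, 90] and counts every cell once
  h <- orientationFraction(c(-89, -45, 0, 44, 90), binWidth = 45)$histogram
  expect_equal(sum(h$count), 5)
  expect_equal(h$binStart[1], -90)
  expect_equal(h$binEnd[nrow(h)], 90)
})

test_that("orientation fraction is axis-fold invariant and tolerance-monotone", {
  set.seed(32)
  for (rep in 1:20) {
    a <- runif(40, -720, 720)
    base <- orientationFraction(a)$fraction
    flip <- sample(c(0, 180), 40, replace = TRUE)
    expect_equal(orientationFraction(a + flip)$fraction, base)
    tols <- sort(runif(4, 0, 90))
    fr <- vapply(tols, function(tl)
      orientationFraction(a, tolerance = tl)$fraction, 1)
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("trapezoidal AUC matches hand integration", {
  expect_equal(aucTrapezoid(c(0, 1), c(0, 1)), 0.5)
  expect_equal(aucTrapezoid(c(0, 2, 5, 7), rep(3, 4)), 21)  # c * T
  expect_equal(aucTrapezoid(c(0, 1, 2), c(0, 2, 0)), 2)
  expect_error(aucTrapezoid(c(0, 1, 1), c(1, 2, 3)), "increasing")
  expect_error(aucTrapezoid(c(0), c(1)), "length")
})

test_that("AUC is linear in values and additive over intervals", {
  set.seed(33)
  for (rep in 1:10) {
    tm <- sort(runif(8, 0, 48)); tm <- tm + seq(0, 0.7, by = 0.1)  # strict
    v1 <- runif(8); v2 <- runif(8)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(aucTrapezoid(tm, a * v1 + b * v2),
                 a * aucTrapezoid(tm, v1) + b * aucTrapezoid(tm, v2))
    k <- 4
    expect_equal(aucTrapezoid(tm[1:k], v1[1:k]) +
                   aucTrapezoid(tm[k:8], v1[k:8]),
                 aucTrapezoid(tm, v1))
  }
})

test_that("diameter summary gives per-explant means and is order invariant", {
  one <- data.frame(explant_id = "e1", mean_diameter = c(10, 20, 30))
  res <- diameterSummary(one)
  expect_equal(res$perExplant$mean_diameter, 20)
  expect_equal(res$perExplant$median_diameter, 20)
  expect_equal(res$perExplant$n_segments, 3L)
  two <- data.frame(explant_id = c("a", "b", "a", "b"),
                    mean_diameter = c(5, 8, 15, 12))
  r1 <- diameterSummary(two)
  r2 <- diameterSummary(two[sample(4), ])
  expect_equal(r1$perExplant, r2$perExplant)
  expect_equal(r1$perExplant$mean_diameter, c(10, 10))
  expect_error(diameterSummary(data.frame(explant_id = "x",
                                          mean_diameter = -1)),
               "positive")
})

test_that("bundled segment table matches a hand-computed summary", {
  tab <- utils::read.table(system.file("extdata",
                                       "vessel_segments_example.tsv",
                                       package = "flankQuant"),
                           header = TRUE, sep = "\t")
  res <- diameterSummary(tab)
  pe <- res$perExplant
  expect_equal(pe$explant_id, c("explant1", "explant2", "explant3"))
  expect_equal(pe$mean_diameter, c(12.875, 14.1, 15.3))
  expect_equal(pe$median_diameter, c(11.15, 14.1, 14.3))
  expect_equal(sum(res$pooled$count), nrow(tab))
  expect_equal(sum(res$pooled$freq), 1)
})
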