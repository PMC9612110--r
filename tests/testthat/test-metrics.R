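test_that("equivalent diameter matches the closed form and scales linearly", {
  expect_equal(equivalent_diameter(100, 1.0), 11.2838, tolerance = 1e-4)
  expect_equal(equivalent_diameter(100, 0.5), 5.6419, tolerance = 1e-4)
  expect_error(equivalent_diameter(0.5, 1), ">= 1")
  # strictly increasing in area, exactly linear in pixel scale
  areas <- c(1, 10, 50, 200, 1000)
  expect_true(all(diff(equivalent_diameter(areas, 1)) > 0))
  expect_equal(equivalent_diameter(areas, 0.25),
               0.25 * equivalent_diameter(areas, 1))
  # rasterized disc r = 10: within 3% of 20 px diameter
  disc <- rasterize_ellipse(c(32, 32), c(10, 10), 0, c(64, 64))
  expect_lt(abs(equivalent_diameter(sum(disc), 1) - 20) / 20, 0.03)
})

test_that("moment ellipse agrees with brute-force projection moments", {
  for (ang in c(0, 30, 75, 120, 160)) {
    m <- rasterize_ellipse(c(60, 60), c(20, 5), ang, c(120, 120))
    rc <- which(m, arr.ind = TRUE)
    e <- fit_ellipse(rc[, 1], rc[, 2])
    o <- oracle_ellipse(m)
    expect_equal(e$major_px, o$major_px, tolerance = 0.01)
    expect_equal(e$minor_px, o$minor_px, tolerance = 0.01)
    dang <- abs(e$angle_deg - o$angle_deg) %% 180
    expect_lt(min(dang, 180 - dang), 1)
    # recovered axis direction stays within 2 degrees of the truth
    dtruth <- abs(e$angle_deg - ang) %% 180
    expect_lt(min(dtruth, 180 - dtruth), 2)
  }
  # the 4:1 ellipse at 30 degrees measures aspect ratio 4.0 +/- 0.2
  m30 <- rasterize_ellipse(c(60, 60), c(20, 5), 30, c(120, 120))
  rc <- which(m30, arr.ind = TRUE)
  e30 <- fit_ellipse(rc[, 1], rc[, 2])
  expect_equal(e30$major_px / e30$minor_px, 4, tolerance = 0.05)
})

test_that("discs give aspect ratio 1 and rotation leaves the ratio invariant", {
  disc <- rasterize_ellipse(c(32, 32), c(10, 10), 0, c(64, 64))
  rc <- which(disc, arr.ind = TRUE)
  e <- fit_ellipse(rc[, 1], rc[, 2])
  expect_equal(e$major_px / e$minor_px, 1, tolerance = 0.05)

  e0 <- rasterize_ellipse(c(40, 40), c(15, 5), 0, c(80, 80))
  e90 <- rasterize_ellipse(c(40, 40), c(15, 5), 90, c(80, 80))
  ar <- function(m) {
    rc <- which(m, arr.ind = TRUE)
    f <- fit_ellipse(rc[, 1], rc[, 2])
    f$major_px / f$minor_px
  }
  expect_equal(ar(e0), ar(e90), tolerance = 0.05 * ar(e0))
})

test_that("degenerate regions keep a positive minor axis", {
  # the 1/12 pixel-variance term keeps even a single pixel at the finite
  # regionprops axis length 4*sqrt(1/12), so ratios never blow up
  e <- fit_ellipse(5, 5)           # single pixel
  expect_equal(e$minor_px, 4 * sqrt(1 / 12))
  expect_equal(e$major_px / e$minor_px, 1)
  e2 <- fit_ellipse(rep(5, 4), 5:8)  # 1 px wide line
  expect_gte(e2$minor_px, 1)
  expect_gt(e2$major_px / e2$minor_px, 1)
  expect_true(is.finite(e2$major_px / e2$minor_px))
})

test_that("orientation folds axis angles onto [0, 90] about the front line", {
  # front advancing along +y: front line horizontal at 0 degrees
  expect_equal(orientation_to_front(c(0, 90, 135), "+y"), c(0, 90, 45))
  # major axis parallel to the front line is 0, along travel is 90
  expect_equal(orientation_to_front(90, "+x"), 0)
  expect_equal(orientation_to_front(0, "+x"), 90)
  # 180-degree periodicity and range, against random angles
  a <- seq(-360, 540, by = 7.5)
  for (dir in c("+x", "-x", "+y", "-y")) {
    th <- orientation_to_front(a, dir)
    expect_true(all(th >= 0 & th <= 90))
    expect_equal(th, orientation_to_front(a + 180, dir))
  }
  expect_error(orientation_to_front(45, "up"), "arg")
})

test_that("pore_records measures every label and recovers generator truth", {
  m3 <- make_discs(rbind(c(20, 20), c(20, 45), c(45, 30)), 8, c(64, 64))
  lab <- label_pores_watershed(m3, seg_config())
  rec <- pore_records(lab, 0.5, "+x")
  expect_identical(rec$pore_id, 1:3)
  expect_true(all(rec$low_ar))

  empty <- pore_records(matrix(0L, 32, 32), 0.5, "+x")
  expect_identical(nrow(empty), 0L)

  # dendritic field, AR ~ 3, axes near 0 deg (perpendicular to a +x front):
  # recovered means within 10% (AR) and 3 deg (orientation) of truth
  spec <- microstructure_spec(
    canvas = c(420, 420), pixel_scale = 0.5, n_pores = 200,
    morphology = "dendritic",
    aspect_ratio_dist = list(family = "uniform", min = 2.5, max = 3.5),
    orientation_dist = list(family = "wrapped_normal", mean = 0, sd = 10),
    min_semi_axis_px = 4, seed = 21)
  f <- generate_pore_field(spec)
  rec <- pore_records(segment_pores(f$image, seg_config()), 0.5, "+x")
  truth_theta <- mean(orientation_to_front(f$truth$axis_angle_deg, "+x"))
  expect_lt(abs(mean(rec$aspect_ratio) - mean(f$truth$aspect_ratio)) /
              mean(f$truth$aspect_ratio), 0.10)
  expect_lt(abs(mean(rec$orientation_deg) - truth_theta), 3)
  expect_lt(abs(mean(rec$eq_diameter_um) - mean(f$truth$eq_diameter_um)) /
              mean(f$truth$eq_diameter_um), 0.05)
})

test_that("summaries report t confidence intervals and the table format", {
  rec <- data.frame(eq_diameter_um = rep(5, 4), aspect_ratio = rep(1.5, 4),
                    orientation_deg = rep(45, 4), low_ar = FALSE)
  s <- summarize_pores(rec)
  expect_identical(s$n_pores, 4L)
  expect_equal(s$pore_size_ci, 0)
  expect_equal(s$shape_factor_ci, 0)

  one <- summarize_pores(rec[1, ])
  expect_true(is.na(one$pore_size_ci))

  expect_error(summarize_pores(rec[0, ]), "zero pore records")

  # formatting fixture mirroring the published summary-table style
  s2 <- summarize_pores(data.frame(
    eq_diameter_um = c(3.07, 3.13), aspect_ratio = c(1.499, 1.501),
    orientation_deg = c(44, 46), low_ar = FALSE))
  f <- format(s2)
  expect_match(f["pore_size"], "^3\\.1 ± ")
  expect_match(f["shape_factor"], "^1\\.5 ± ")

  # half-width matches the closed form on a known sample
  x <- c(4, 5, 6, 7, 9)
  s3 <- summarize_pores(data.frame(eq_diameter_um = x, aspect_ratio = x,
                                   orientation_deg = x / 2, low_ar = FALSE))
  expect_equal(s3$pore_size_ci, qt(0.975, 4) * sd(x) / sqrt(5))
})

test_that("t confidence intervals cover at the nominal rate", {
  # 2000 replications of n = 50 standard normal draws (the acceptance suite
  # runs the full 10,000)
  set.seed(404)
  n <- 50; reps <- 2000
  x <- matrix(rnorm(n * reps), n, reps)
  mm <- colMeans(x)
  ss <- sqrt((colSums(x^2) - n * mm^2) / (n - 1))
  hw <- qt(0.975, n - 1) * ss / sqrt(n)
  cover <- mean(abs(mm) <= hw)
  expect_gt(cover, 0.935)
  expect_lt(cover, 0.965)
})

test_that("size distributions normalize, accumulate and order by truth", {
  rec1 <- data.frame(eq_diameter_um = 5)
  h <- size_distribution(rec1, c(0, 10))
  expect_identical(h$count, 1L)
  expect_equal(h$cum_freq, 1)
  expect_identical(attr(h, "out_of_range"), 0L)

  set.seed(2)
  rec <- data.frame(eq_diameter_um = runif(100, 1, 20))
  h2 <- size_distribution(rec, seq(2, 18, by = 2))
  expect_equal(sum(h2$freq), 1)
  expect_equal(tail(h2$cum_freq, 1), 1)
  expect_gt(attr(h2, "out_of_range"), 0)
  expect_error(size_distribution(rec, c(3, 3, 5)), "strictly increasing")

  # stochastic ordering: the 7 um generator dominates the 3 um one
  mk <- function(mu, seed) {
    spec <- microstructure_spec(
      canvas = c(300, 300), pixel_scale = 0.5, n_pores = 120,
      diameter_dist = list(family = "lognormal",
                           meanlog = log(mu) - 0.02, sdlog = 0.2),
      wall_min_thickness = 2, min_semi_axis_px = 1.5, seed = seed)
    generate_pore_field(spec)$truth$eq_diameter_um
  }
  d3 <- mk(3, 31); d7 <- mk(7, 31)
  grid <- seq(1, 15, by = 0.5)
  expect_true(all(ecdf(d7)(grid) <= ecdf(d3)(grid)))
})
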