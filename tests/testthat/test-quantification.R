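disk_label <- function(nr, nc, centers, radius = 5) {
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(nr) - centers[i, 1])^2,
                (seq_len(nc) - centers[i, 2])^2, "+")
    lab[d2 <= radius^2] <- i
  }
  label_image(lab, 1L, "cell")
}

test_that("measure_marker_intensity computes means and corrections", {
  lab <- disk_label(64, 64, cbind(c(20, 45), c(20, 45)))
  img <- matrix(7, 64, 64)
  m <- measure_marker_intensity(lab, img, background = 0)
  expect_equal(m$mean_intensity, c(7, 7))
  expect_equal(m$median_intensity, c(7, 7))
  m2 <- measure_marker_intensity(lab, img, background = 7)
  expect_equal(m2$corrected_mean, c(0, 0))
  expect_equal(m2$corrected_median, c(0, 0))
  expect_error(measure_marker_intensity(lab, matrix(0, 32, 32)), "differ")
})

test_that("integrated intensity conserves mass when labels tile the field", {
  set.seed(4)
  img <- matrix(runif(48 * 48, 0, 100), 48, 48)
  lab <- matrix(0L, 48, 48)
  lab[1:24, ] <- 1L
  lab[25:48, 1:24] <- 2L  # remainder stays background
  m <- measure_marker_intensity(label_image(lab, 1L, "cell"), img, 0)
  expect_equal(sum(m$integrated_intensity) + sum(img[lab == 0L]), sum(img),
               tolerance = 1e-12)
})

test_that("estimate_background follows its documented methods", {
  img <- matrix(42, 32, 32)
  expect_equal(estimate_background(img), 42)
  lab <- disk_label(32, 32, cbind(16, 16))
  img2 <- matrix(100, 32, 32)
  img2[lab$labels > 0] <- 900
  expect_equal(estimate_background(img2, lab), 100)
  # percentile method matches the direct sort computation
  set.seed(5)
  img3 <- matrix(c(rnorm(800, 10, 2), rnorm(224, 100, 5)), 32, 32)
  expect_equal(estimate_background(img3, method = "percentile:5"),
               as.numeric(quantile(img3, 0.05)))
  full <- label_image(matrix(1L, 32, 32), 1L, "cell")
  expect_error(estimate_background(img2, full), "no background pixels")
  expect_equal(estimate_background(img2, method = "fixed", value = 3), 3)
})

test_that("background of a zero-noise synthetic field equals the config level", {
  cfg <- sim_config(n_cells = 10L, field_shape = c(128L, 128L),
                    composition = c(excitatory_neuron = 1.0), noise_sd = 0,
                    drift_sd = 0, background_level = 100, seed = 6L)
  r <- render_round_stacks(simulate_culture(cfg), cfg)
  img <- r$stacks[[1]]$channels$nuclear
  nuc <- segment_nuclei(img)
  cells <- delineate_cell_bodies(nuc, r$stacks[[1]]$channels$actin,
                                 max_expand = 25)
  expect_equal(estimate_background(img, cells), 100)
})

test_that("compute_snr reproduces the n=6 ROI arithmetic", {
  img <- matrix(10, 60, 60)
  img[1:10, 1:10] <- 250
  sig <- replicate(6, c(1, 10, 1, 10), simplify = FALSE)
  bg <- replicate(6, c(40, 50, 40, 50), simplify = FALSE)
  s <- compute_snr(img, sig, bg)
  expect_equal(s$ratio, 25)
  expect_equal(s$n_signal_rois, 6L)

  expect_equal(compute_snr(img, bg, bg)$ratio, 1)

  # ROI means {20,22,18,20,20,20} vs {2,...} -> 10
  img2 <- matrix(2, 10, 70)
  vals <- c(20, 22, 18, 20, 20, 20)
  sig2 <- lapply(1:6, function(k) {
    img2[3:5, (10 * k - 5):(10 * k - 3)] <<- vals[k]
    c(3, 5, 10 * k - 5, 10 * k - 3)
  })
  bg2 <- replicate(6, c(8, 9, 1, 3), simplify = FALSE)
  expect_equal(compute_snr(img2, sig2, bg2)$ratio, 10)

  expect_error(compute_snr(matrix(0, 5, 5), list(c(1, 2, 1, 2)),
                           list(c(3, 4, 3, 4))), "zero background")
})

test_that("compute_snr matches a brute-force recomputation", {
  set.seed(7)
  img <- matrix(runif(64 * 64, 1, 500), 64, 64)
  sig <- lapply(1:6, function(k) c(2 * k, 2 * k + 3, 5, 12))
  bg <- lapply(1:6, function(k) c(40, 45, 3 * k, 3 * k + 2))
  s <- compute_snr(img, sig, bg)
  direct <- mean(vapply(sig, function(r) mean(img[r[1]:r[2], r[3]:r[4]]), 0)) /
    mean(vapply(bg, function(r) mean(img[r[1]:r[2], r[3]:r[4]]), 0))
  expect_equal(s$ratio, direct, tolerance = 1e-9)
})

test_that("pearson_correlation obeys its exact identities", {
  set.seed(8)
  a <- matrix(rnorm(100 * 100), 100, 100)
  expect_equal(pearson_correlation(a, a), 1)
  neg <- -(a - mean(a))
  expect_equal(pearson_correlation(a, neg), -1)
  b <- matrix(rnorm(100 * 100), 100, 100)
  expect_lt(abs(pearson_correlation(a, b)), 0.05)
  expect_error(pearson_correlation(a, matrix(1, 100, 100)), "zero variance")
  # brute-force formula
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_correlation(a, b), direct, tolerance = 1e-9)
  # masked variant
  mask <- matrix(FALSE, 100, 100); mask[20:60, 20:60] <- TRUE
  expect_equal(pearson_correlation(a, b, mask), cor(a[mask], b[mask]),
               tolerance = 1e-12)
})

test_that("count_puncta detects rendered spots and respects prominence", {
  region <- matrix(TRUE, 100, 100)
  expect_equal(count_puncta(matrix(0, 100, 100), region), 0L)

  set.seed(9)
  img <- matrix(0, 100, 100)
  sp <- as.matrix(expand.grid(seq(15, 85, 14), seq(15, 85, 18)))[1:15, ]
  for (k in 1:15)
    img <- cycim:::stamp_gauss(img, sp[k, 1], sp[k, 2], 2.5, 300)
  img <- img + 100 + matrix(rnorm(1e4, 0, 5), 100)
  expect_equal(count_puncta(img, region, spot_sigma = 2), 15L)

  # LoG response scales linearly with amplitude; a spot whose response sits
  # at ~0.5x a fixed prominence threshold must be excluded
  resp_one <- function(amp) {
    im <- cycim:::stamp_gauss(matrix(0, 40, 40), 20, 20, 2.5, amp)
    count_puncta(im, matrix(TRUE, 40, 40), 2, min_prominence = 100)
  }
  expect_equal(resp_one(1000), 1L)   # response ~0.48 * amp >> threshold
  expect_equal(resp_one(105), 0L)    # response ~ 50 = 0.5x threshold
})

test_that("count_puncta is translation invariant", {
  set.seed(10)
  img <- matrix(100, 80, 80)
  for (k in 1:6)
    img <- cycim:::stamp_gauss(img, 20 + 6 * k, 25 + 5 * k, 2.5, 300)
  region <- matrix(FALSE, 80, 80); region[10:70, 10:70] <- TRUE
  img2 <- img[c(77:80, 1:76), c(4:80, 1:3)]        # rolled by (4, -3)
  region2 <- region[c(77:80, 1:76), c(4:80, 1:3)]
  expect_equal(count_puncta(img, region, 2), count_puncta(img2, region2, 2))
})

test_that("filament score separates lines from blobs and noise", {
  region <- matrix(TRUE, 80, 80)
  expect_equal(filament_score(matrix(0, 80, 80), region), 0)

  line <- cycim:::stamp_polyline(matrix(0, 80, 80),
                                 cbind(c(20, 60), c(20, 60)), 1.2, 500)
  total <- sum(line)
  disk <- cycim:::stamp_soma(matrix(0, 80, 80), 40, 40, 8, 1)
  disk <- disk * total / sum(disk)
  s_line <- filament_score(line, region)
  s_disk <- filament_score(disk, region)
  expect_gt(s_line, s_disk)
  expect_gt(s_line, 0.3)

  # pure noise scores below the configured gate in >= 95 of 100 trials
  set.seed(11)
  scores <- vapply(1:100, function(i)
    filament_score(matrix(rnorm(6400, 100, 15), 80, 80), region), 0)
  expect_gte(mean(scores < 0.1), 0.95)
})

test_that("washout residual check flags retained signal", {
  img_ok <- matrix(100, 32, 32)
  res <- washout_residual_check(img_ok, 100)
  expect_equal(res$ratio, 1)
  expect_true(res$pass)
  res2 <- washout_residual_check(matrix(300, 32, 32), 100, tolerance_fold = 1.5)
  expect_false(res2$pass)
  expect_equal(res2$ratio, 3)
  expect_error(washout_residual_check(img_ok, 0), "zero background")

  # synthetic residual round flagged while clean rounds pass
  cfg <- sim_config(n_cells = 10L, field_shape = c(128L, 128L),
                    composition = c(excitatory_neuron = 1.0),
                    background_level = 100, noise_sd = 5, seed = 12L)
  r <- render_round_stacks(simulate_culture(cfg), cfg)
  clean_wash <- matrix(100 + rnorm(128 * 128, 0, 5), 128, 128)
  residual_wash <- r$stacks[[1]]$channels$Tuj1 + 120  # strand not washed out
  expect_true(washout_residual_check(clean_wash, 100)$pass)
  expect_false(washout_residual_check(residual_wash, 100)$pass)
})
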