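test_that("segment_nuclei handles blank and well-separated fields", {
  expect_equal(max(segment_nuclei(matrix(5, 64, 64))$labels), 0L)

  set.seed(2)
  xs <- seq(15, 113, by = 10)[1:10]
  pts <- cbind(sample(xs, 10), sample(xs, 10))
  img <- matrix(100, 128, 128)
  for (i in 1:10)
    img <- cycim:::stamp_gauss(img, pts[i, 1], pts[i, 2], 3, 1000)
  li <- segment_nuclei(img)
  expect_equal(max(li$labels), 10L)
  st <- cycim:::label_stats(li$labels)
  ord <- order(st$row, st$col)
  tr <- pts[order(pts[, 1], pts[, 2]), ]
  expect_lt(max(abs(as.matrix(st[ord, c("row", "col")]) - tr)), 2)
})

test_that("touching nuclei with distinct peaks are split", {
  img <- matrix(100, 60, 60)
  img <- cycim:::stamp_gauss(img, 30, 25, 3, 1000)
  img <- cycim:::stamp_gauss(img, 30, 33, 3, 1000)
  li <- segment_nuclei(img)
  expect_equal(max(li$labels), 2L)
  st <- cycim:::label_stats(li$labels)
  expect_lt(max(abs(sort(st$col) - c(25, 33))), 2)
})

test_that("area bounds discard out-of-range regions", {
  img <- matrix(0, 80, 80)
  img <- cycim:::stamp_gauss(img, 20, 20, 2, 1000)   # small nucleus
  img <- cycim:::stamp_gauss(img, 60, 60, 8, 1000)   # large nucleus
  li_all <- segment_nuclei(img, min_area = 1, max_area = 1e5)
  expect_equal(max(li_all$labels), 2L)
  st <- cycim:::label_stats(li_all$labels)
  li <- segment_nuclei(img, min_area = min(st$area) + 1,
                       max_area = max(st$area) - 1)
  expect_equal(max(li$labels), 0L)
})

test_that("cell bodies grow from nuclei over actin and stay disjoint", {
  set.seed(3)
  img <- matrix(100, 128, 128)
  act <- matrix(100, 128, 128)
  pts <- cbind(c(30, 30, 90), c(30, 46, 90))  # two adjacent, one isolated
  for (i in 1:3) {
    img <- cycim:::stamp_gauss(img, pts[i, 1], pts[i, 2], 3, 1000)
    act <- cycim:::stamp_soma(act, pts[i, 1], pts[i, 2], 6, 400)
  }
  nuc <- segment_nuclei(img)
  cells <- delineate_cell_bodies(nuc, act, max_expand = 10)
  expect_equal(max(cells$labels), 3L)
  # nucleus subset of its cell
  in_nuc <- nuc$labels > 0
  expect_true(all(cells$labels[in_nuc] == nuc$labels[in_nuc]))
  # areas within 20% of the analytic soma disk above the actin threshold:
  # the rendered profile is bg + amp * exp(-0.5 * (d^2/r^2)^2), so the
  # threshold contour sits at d = r * (2 * log(amp / (thr - bg)))^(1/4)
  thr <- as.numeric(otsu_threshold(act))
  u <- sqrt(2 * log(400 / (thr - 100)))
  truth_area <- pi * (6 * sqrt(u))^2
  st <- cycim:::label_stats(cells$labels)
  expect_lt(max(abs(st$area - truth_area)) / truth_area, 0.2)
  # adjacent pair split along the actin valley: centroid columns preserved
  expect_lt(max(abs(sort(st$col) - sort(pts[, 2]))), 2)
})

test_that("zero actin signal leaves cells equal to nuclei", {
  img <- matrix(100, 64, 64)
  img <- cycim:::stamp_gauss(img, 32, 32, 3, 1000)
  nuc <- segment_nuclei(img)
  cells <- delineate_cell_bodies(nuc, matrix(0, 64, 64))
  expect_identical(cells$labels, nuc$labels)
  expect_error(delineate_cell_bodies(nuc, matrix(0, 32, 32)), "differ")
})

make_label <- function(pts, nr = 64, nc = 64) {
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(pts)))
    lab[pts[i, 1] + (-1:1), pts[i, 2] + (-1:1)] <- i
  label_image(lab, 1L, "nucleus")
}

test_that("identical rounds give complete records", {
  pts <- cbind(c(10, 30, 50), c(12, 35, 55))
  rounds <- lapply(1:4, function(r) make_label(pts))
  rec <- match_cells_across_rounds(rounds)
  expect_equal(nrow(rec), 3L)
  expect_true(all(rec$complete))
  expect_equal(rec$n_rounds, rep(4L, 3))
})

test_that("a detached cell yields an incomplete record", {
  pts <- cbind(c(10, 30, 50), c(12, 35, 55))
  rounds <- list(make_label(pts), make_label(pts),
                 make_label(pts[1:2, , drop = FALSE]),
                 make_label(pts[1:2, , drop = FALSE]))
  rec <- match_cells_across_rounds(rounds)
  expect_equal(sum(rec$complete), 2L)
  gone <- rec[!rec$complete, ]
  expect_equal(gone$rounds_present, "1;2")
})

test_that("matching agrees with brute-force optimal assignment", {
  # <= 6 cells on a jittered grid: enumerate all assignments, minimise total
  # distance; greedy ascending-distance matching must find the same pairing
  set.seed(11)
  grid <- as.matrix(expand.grid(c(14, 26, 38, 50), c(14, 26, 38, 50)))
  for (trial in 1:20) {
    n <- sample(2:6, 1)
    p1 <- grid[sample(nrow(grid), n), , drop = FALSE]
    p2 <- round(p1 + matrix(rnorm(2 * n, 0, 1.2), n, 2))
    d <- sqrt(outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2)
    perms <- gtools_permutations(n)
    costs <- apply(perms, 1, function(pp) sum(d[cbind(seq_len(n), pp)]))
    best <- perms[which.min(costs), ]
    rec <- match_cells_across_rounds(list(make_label(p1), make_label(p2)),
                                     max_centroid_distance = 10)
    expect_true(all(rec$complete))
    lab2 <- rec$label_round2[order(rec$label_round1)]
    expect_equal(lab2, as.integer(best))
  }
})

test_that("ambiguous matches break ties deterministically by cell id", {
  # two round-1 cells equidistant from a single round-2 detection: the
  # lower cell_id wins the match, the other record goes incomplete
  p1 <- cbind(c(20, 28), c(20, 20))
  p2 <- cbind(24, 20)
  rec <- match_cells_across_rounds(list(make_label(p1), make_label(p2)),
                                   max_centroid_distance = 6)
  expect_equal(rec$label_round2[rec$cell_id == 1L], 1L)
  expect_true(is.na(rec$label_round2[rec$cell_id == 2L]))
})

test_that("matching is symmetric under round reversal for complete cells", {
  cfg <- small_config(seed = 31L, detachment_rate_per_round = 0)
  r <- render_round_stacks(simulate_culture(cfg), cfg)
  reg <- register_experiment(r$stacks)
  nuc <- lapply(reg$stacks, function(s) segment_nuclei(s$channels$nuclear))
  fwd <- match_cells_across_rounds(nuc)
  rev_ <- match_cells_across_rounds(rev(nuc))
  fc <- fwd[fwd$complete, ]
  rc <- rev_[rev_$complete, ]
  expect_equal(nrow(fc), nrow(rc))
  # same sets of matched label tuples (reversed column order)
  key_f <- unname(apply(fc[, paste0("label_round", 1:5)], 1, paste,
                        collapse = "-"))
  key_r <- unname(apply(rc[, paste0("label_round", 5:1)], 1, paste,
                        collapse = "-"))
  expect_setequal(key_f, key_r)
})

test_that("filter_complete_cells reports exclusions", {
  pts <- cbind(c(10, 30), c(12, 35))
  rounds <- list(make_label(pts), make_label(pts[1, , drop = FALSE]))
  rec <- match_cells_across_rounds(rounds)
  kept <- filter_complete_cells(rec)
  expect_equal(nrow(kept), 1L)
  expect_equal(attr(kept, "excluded_count"), 1L)
  empty <- filter_complete_cells(rec[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "excluded_count"), 0L)
})
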