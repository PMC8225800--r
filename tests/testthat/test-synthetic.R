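test_that("simulate_culture handles degenerate and empty compositions", {
  cfg <- sim_config(n_cells = 10L, field_shape = c(128L, 128L),
                    composition = c(excitatory_neuron = 1.0), seed = 1L)
  cells <- simulate_culture(cfg)
  expect_equal(nrow(cells), 10L)
  expect_true(all(cells$true_class == "excitatory_neuron"))

  cfg0 <- sim_config(n_cells = 0L, composition = c(excitatory_neuron = 1.0))
  expect_equal(nrow(simulate_culture(cfg0)), 0L)
})

test_that("class counts follow the seeded multinomial draw", {
  cfg <- sim_config(n_cells = 1000L, field_shape = c(1024L, 1024L),
                    composition = c(excitatory_neuron = 0.5,
                                    astrocyte_mature = 0.5),
                    seed = 7L)
  cells <- simulate_culture(cfg)
  n_exc <- sum(cells$true_class == "excitatory_neuron")
  sd3 <- 3 * sqrt(1000 * 0.5 * 0.5)
  expect_lt(abs(n_exc - 500), sd3)
})

test_that("simulate_culture rejects bad inputs", {
  expect_error(sim_config(composition = c(excitatory_neuron = 0.6)),
               "sum to 1")
  cfg <- sim_config(n_cells = 5L,
                    composition = c(not_a_class = 1.0))
  expect_error(simulate_culture(cfg), "unknown class")
  packed <- sim_config(n_cells = 200L, field_shape = c(64L, 64L),
                       composition = c(excitatory_neuron = 1.0))
  expect_error(simulate_culture(packed), "infeasible field packing")
})

test_that("expression profiles follow the gating rules", {
  cfg <- sim_config(n_cells = 30L, field_shape = c(256L, 256L),
                    composition = c(astrocyte_mature = 1.0), seed = 2L)
  cells <- simulate_culture(cfg)
  pos_level <- 10 * 30  # separation x baseline
  # required-positive markers centred on the positive level
  for (m in c("CD44", "Vimentin", "GFAP"))
    expect_gt(min(cells[[paste0("expr_", m)]]), 0.3 * pos_level)
  # everything else at baseline
  for (m in c("Tuj1", "MAP2", "Pax6", "Oct4A"))
    expect_lt(max(cells[[paste0("expr_", m)]]), 0.3 * pos_level)
  expect_false(any(cells$has_neurites))
})

test_that("generator is deterministic for a fixed seed", {
  cfg <- small_config(seed = 5L)
  a <- render_round_stacks(simulate_culture(cfg), cfg)
  b <- render_round_stacks(simulate_culture(cfg), cfg)
  expect_identical(a$truth$drifts, b$truth$drifts)
  expect_identical(a$stacks[[3]]$channels, b$stacks[[3]]$channels)
  expect_identical(as.data.frame(a$truth$cells), as.data.frame(b$truth$cells))
})

test_that("zero drift and noise give identical fiducials across rounds", {
  cfg <- sim_config(n_cells = 1L, field_shape = c(96L, 96L),
                    composition = c(excitatory_neuron = 1.0),
                    drift_sd = 0, noise_sd = 0,
                    detachment_rate_per_round = 0, seed = 3L)
  r <- render_round_stacks(simulate_culture(cfg), cfg)
  expect_equal(r$stacks[[2]]$channels$nuclear, r$stacks[[1]]$channels$nuclear)
  expect_equal(r$stacks[[5]]$channels$nuclear, r$stacks[[1]]$channels$nuclear)
})

test_that("an integer-shifted culture renders as the rolled image", {
  # constructed-shift oracle: the same cell placed at (r, c) and at
  # (r + 7, c - 4) yields fiducial images related by an exact roll
  panel <- cortical_panel()
  cfg <- sim_config(n_cells = 1L, field_shape = c(96L, 96L),
                    composition = c(excitatory_neuron = 1.0),
                    drift_sd = 0, noise_sd = 0,
                    detachment_rate_per_round = 0, seed = 1L)
  t1 <- manual_truth(40, 50)
  t2 <- manual_truth(47, 46)
  img1 <- render_round_stacks(t1, cfg, panel)$stacks[[1]]$channels$nuclear
  img2 <- render_round_stacks(t2, cfg, panel)$stacks[[1]]$channels$nuclear
  rolled <- img1[c(90:96, 1:89), c(5:96, 1:4)]
  expect_equal(img2, rolled, tolerance = 1e-12)
})

test_that("total detachment empties later rounds", {
  cfg <- sim_config(n_cells = 5L, field_shape = c(128L, 128L),
                    composition = c(excitatory_neuron = 1.0),
                    detachment_rate_per_round = 1, drift_sd = 0,
                    noise_sd = 0, seed = 4L)
  r <- render_round_stacks(simulate_culture(cfg), cfg)
  expect_true(all(r$stacks[[2]]$channels$nuclear == cfg$background_level))
  expect_true(all(r$stacks[[5]]$channels$actin == cfg$background_level))
  expect_false(all(r$stacks[[1]]$channels$nuclear == cfg$background_level))
})

test_that("make_percell_table reproduces expression exactly at zero noise", {
  cfg <- small_config(seed = 6L)
  cells <- simulate_culture(cfg)
  tab <- make_percell_table(cells, noise_sd = 0)
  panel <- cortical_panel()
  for (m in panel$marker)
    expect_equal(tab[[m]], cells[[paste0("expr_", m)]])
  # schema: marker list plus cell_id/centroid plus structural columns
  expect_true(all(c("cell_id", "row", "col", panel$marker) %in% names(tab)))
  expect_true("Synapsin_puncta_count" %in% names(tab))
  expect_true("Tuj1_filament_score" %in% names(tab))
  # determinism: byte-identical on re-run
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(make_percell_table(cells, noise_sd = 5, seed = 9L), f1,
            row.names = FALSE)
  write.csv(make_percell_table(cells, noise_sd = 5, seed = 9L), f2,
            row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("fixture bundles round-trip exactly", {
  cfg <- sim_config(n_cells = 8L, field_shape = c(96L, 96L),
                    composition = c(excitatory_neuron = 1.0), seed = 8L)
  r <- render_round_stacks(simulate_culture(cfg), cfg)
  d <- withr::local_tempdir()
  mp <- write_fixture_bundle(r, d)
  expect_true(file.exists(mp))
  back <- read_fixture_bundle(d)
  # rounds x (2 fiducials + 2 probe channels) manifest entries
  expect_equal(nrow(back$manifest$images), 5L * 4L)
  for (rd in 1:5)
    for (ch in names(r$stacks[[rd]]$channels))
      expect_equal(back$stacks[[rd]]$channels[[ch]],
                   round(r$stacks[[rd]]$channels[[ch]]))
  expect_error(write_fixture_bundle(r, file.path(d, "nope", "deeper")),
               "does not exist")
})

test_that("composition converges to the configured fractions", {
  cfg <- sim_config(n_cells = 2000L, field_shape = c(2048L, 1024L),
                    composition = c(excitatory_neuron = 0.6,
                                    radial_glia = 0.4), seed = 10L)
  cells <- simulate_culture(cfg)
  frac <- mean(cells$true_class == "excitatory_neuron")
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 2000))
})
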