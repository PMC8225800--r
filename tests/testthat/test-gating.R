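bimodal_table <- function(n = 200, markers = c("A", "B"), seed = 1,
                          lo = 10, hi = 100, sd = 5) {
  set.seed(seed)
  pos <- matrix(runif(n * length(markers)) < 0.5, n)
  tab <- data.frame(cell_id = seq_len(n))
  for (j in seq_along(markers))
    tab[[markers[j]]] <- pmax(ifelse(pos[, j], hi, lo) + rnorm(n, 0, sd), 0)
  attr(tab, "pos") <- pos
  tab
}

test_that("otsu thresholds land strictly between bimodal modes", {
  tab <- bimodal_table(seed = 2)
  thr <- derive_positivity_thresholds(tab, markers = c("A", "B"))
  for (m in c("A", "B")) {
    expect_gt(thr[[m]], 10 + 15)
    expect_lt(thr[[m]], 100 - 15)
  }
})

test_that("fixed and kmad threshold methods behave as documented", {
  tab <- bimodal_table(seed = 3)
  fx <- derive_positivity_thresholds(tab, markers = c("A", "B"),
                                     method = "fixed",
                                     values = c(A = 42, B = 7))
  expect_equal(unname(fx), c(42, 7))
  k0 <- derive_positivity_thresholds(tab, markers = c("A", "B"),
                                     method = "kmad", background = 33, k = 0)
  expect_equal(unname(k0), c(33, 33))
  const <- data.frame(A = rep(5, 20))
  expect_error(derive_positivity_thresholds(const, markers = "A"),
               "fixed threshold")
  expect_error(derive_positivity_thresholds(tab[1:5, ], markers = "A"),
               "at least 10 cells")
})

test_that("the absent-marker guard calls an unexpressed marker all-negative", {
  set.seed(4)
  n <- 300
  tab <- data.frame(
    Present1 = c(rnorm(n / 2, 15, 4), rnorm(n / 2, 200, 30)),
    Present2 = c(rnorm(n / 2, 15, 4), rnorm(n / 2, 180, 25)),
    Absent = pmax(rnorm(n, 5, 4), 0))
  thr <- derive_positivity_thresholds(tab,
                                      markers = c("Present1", "Present2",
                                                  "Absent"))
  expect_gt(thr[["Absent"]], max(tab$Absent))
  expect_lt(thr[["Present1"]], 150)
})

test_that("positivity requires intensity and any structural gate", {
  rs <- cortical_ruleset(structure_gates = TRUE)
  thr <- setNames(rep(50, 10), cortical_panel()$marker)
  rec <- data.frame(cell_id = 1L)
  for (m in cortical_panel()$marker) rec[[m]] <- 0
  rec$Synapsin_puncta_count <- 0L
  rec$Tuj1_filament_score <- 0
  expect_false(any(call_positivity(rec, thr, rs)))

  # bright but amorphous Synapsin stays negative under the puncta gate
  rec2 <- rec
  rec2$Synapsin <- 500
  rec2$Synapsin_puncta_count <- 0L
  expect_false(call_positivity(rec2, thr, rs)[["Synapsin"]])
  rec2$Synapsin_puncta_count <- 5L
  expect_true(call_positivity(rec2, thr, rs)[["Synapsin"]])

  rec3 <- rec[, setdiff(names(rec), "MAP2")]
  expect_error(call_positivity(rec3, thr, rs), "MAP2")
})

test_that("bimodal fixtures are called with >= 95% accuracy per marker", {
  tab <- bimodal_table(n = 500, markers = c("A", "B", "C"), seed = 5)
  thr <- derive_positivity_thresholds(tab, markers = c("A", "B", "C"))
  calls <- call_positivity_table(tab, thr)
  pos <- attr(tab, "pos")
  for (j in 1:3)
    expect_gte(mean(calls[, j] == pos[, j]), 0.95)
})

test_that("classification follows the published class signatures", {
  rs <- cortical_ruleset()
  markers <- cortical_panel()$marker
  mk_calls <- function(positives) {
    m <- matrix(FALSE, 1, length(markers), dimnames = list(NULL, markers))
    m[1, positives] <- TRUE
    m
  }
  expect_equal(classify_cells(mk_calls(c("Tuj1", "MAP2", "VGLUT1")), rs),
               "excitatory_neuron")
  expect_equal(classify_cells(mk_calls(c("Tuj1", "MAP2", "VGAT")), rs),
               "inhibitory_neuron")
  expect_equal(classify_cells(mk_calls(c("Tuj1", "MAP2")), rs), "neuron")
  expect_equal(classify_cells(mk_calls(c("Pax6", "Vimentin")), rs),
               "radial_glia")
  expect_equal(classify_cells(mk_calls("Pax6"), rs), "npc")
  expect_equal(classify_cells(mk_calls(c("CD44", "Vimentin", "GFAP")), rs),
               "astrocyte_mature")
  expect_equal(classify_cells(mk_calls(c("CD44", "Vimentin")), rs),
               "astrocyte_immature")
  expect_equal(classify_cells(mk_calls(c("Oct4A", "Tuj1", "MAP2")), rs),
               "ipsc")  # residual pluripotent outranks everything
  expect_equal(classify_cells(mk_calls(character()), rs), "unclassified")
  # a neuron with both synaptic markers resolves to the excitatory subtype
  expect_equal(classify_cells(mk_calls(c("Tuj1", "MAP2", "VGLUT1", "VGAT")),
                              rs), "excitatory_neuron")
})

test_that("rulesets referencing unknown markers fail at load", {
  rs <- gating_ruleset(list(gating_rule("x", positive = "NotAMarker",
                                        priority = 1L)))
  calls <- matrix(TRUE, 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(classify_cells(calls, rs), "unknown marker")
  expect_error(gating_rule("y", positive = "A", negative = "A",
                           priority = 1L), "both")
  expect_error(gating_ruleset(list(gating_rule("a", priority = 1L),
                                   gating_rule("b", priority = 1L))),
               "unique")
})

test_that("raising a threshold never increases that marker's positive count", {
  tab <- bimodal_table(n = 300, markers = "A", seed = 6)
  base <- derive_positivity_thresholds(tab, markers = "A")
  counts <- vapply(seq(0, 150, by = 5), function(delta) {
    thr <- c(A = unname(base[["A"]]) + delta)
    sum(call_positivity_table(tab, thr)[, "A"])
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("summarize_composition accounts for every cell", {
  comp <- summarize_composition(rep("neuron", 10))
  expect_equal(comp$fraction, 1)
  expect_equal(attr(comp, "analyzed_count"), 10L)

  a <- c(rep("neuron", 6), rep("npc", 3), "unclassified")
  comp2 <- summarize_composition(a, sampled_count = 25)
  expect_equal(sum(comp2$count), 10L)
  expect_equal(sum(comp2$fraction), 1, tolerance = 1e-9)
  expect_equal(attr(comp2, "excluded_count"), 15L)
  expect_error(summarize_composition(character()), "no analyzable cells")
  expect_error(summarize_composition(a, sampled_count = 5), "sampled_count")
  # zero-count classes are reported when requested
  comp3 <- summarize_composition(a, classes = c("neuron", "npc", "ipsc",
                                                "unclassified"))
  expect_equal(comp3$count[comp3$class == "ipsc"], 0L)
})

test_that("classification is deterministic", {
  set.seed(7)
  markers <- cortical_panel()$marker
  calls <- matrix(runif(200 * 10) < 0.4, 200, 10,
                  dimnames = list(NULL, markers))
  rs <- cortical_ruleset()
  expect_identical(classify_cells(calls, rs), classify_cells(calls, rs))
})
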