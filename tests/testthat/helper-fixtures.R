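# Shared fixture builders. Everything is generated in code at test time.

# small standard culture: fast to simulate and render; ... overrides defaults
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_cells = 40L, field_shape = c(160L, 160L),
         composition = c(excitatory_neuron = 0.5, astrocyte_mature = 0.2,
                         radial_glia = 0.2, npc = 0.1),
         drift_sd = 2, detachment_rate_per_round = 0.05, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# hand-built single-cell truth at a chosen position (bypasses placement RNG)
manual_truth <- function(row, col, class = "excitatory_neuron",
                         panel = cortical_panel(),
                         ruleset = cortical_ruleset(),
                         soma_radius = 6, nucleus_radius = 3,
                         has_neurites = FALSE) {
  truth <- data.frame(cell_id = 1L, true_class = class, row = row, col = col,
                      soma_radius = soma_radius,
                      nucleus_radius = nucleus_radius,
                      has_neurites = has_neurites,
                      detaches_after_round = NA_integer_,
                      stringsAsFactors = FALSE)
  for (m in panel$marker) truth[[paste0("expr_", m)]] <- 30
  attr(truth, "geometry") <- list(list(neurites = list(), puncta = list()))
  attr(truth, "positive_level") <- 300
  class(truth) <- c("cell_truth", class(truth))
  truth
}

# independent naive longest-complementary-run oracle: O(L^3) substring scan
naive_complement_run <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bx <- strsplit(b, "")[[1]]
  b_rc <- paste(rev(unname(comp[bx])), collapse = "")
  best <- 0L
  for (len in seq_len(min(nchar(a), nchar(b)))) {
    found <- FALSE
    for (i in seq_len(nchar(a) - len + 1)) {
      sub <- substr(a, i, i + len - 1)
      if (grepl(sub, b_rc, fixed = TRUE)) { found <- TRUE; break }
    }
    if (found) best <- len else break
  }
  best
}

# tiny permutation enumerator (keeps matching oracles dependency-free)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  out
}

# independent brute-force rule interpreter used as the gating oracle
brute_force_classify <- function(calls_row, ruleset) {
  for (r in ruleset$rules) {
    ok <- all(calls_row[r$positive]) && !any(calls_row[r$negative])
    if (ok) return(r$class_name)
  }
  ruleset$fallback
}
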