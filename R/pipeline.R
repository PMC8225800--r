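# Orchestration: simulate -> register -> segment -> quantify -> gate, with
# config handling, run logging and file outputs. All randomness flows from
# the single config seed.

#' Default analysis options
#'
#' One place for every paper-gap default: segmentation thresholds and area
#' bounds, tracking distance, border exclusion, registration weights and
#' quality floor, puncta/filament parameters, gating method.
#'
#' @return named list of defaults
#' @export
default_options <- function() {
  list(
    reference_round = NULL,            # NULL = first round
    fiducial_weights = c(nuclear = 0.5, actin = 0.5),
    quality_floor = 0.5,
    min_nucleus_area = 10, max_nucleus_area = 400,
    max_expand = 10,                   # px a cell body may grow past its nucleus
    max_centroid_distance = 10,        # px, cross-round matching
    exclude_border = TRUE,
    core_dilate = 3,                   # px of nucleus dilation for the soma core
    intensity_quantile = 0.25,         # gating statistic over the soma core
    spot_sigma = 2, puncta_prominence = NULL,   # NULL = 3 x image MAD
    filament_sigma = 1.5, filament_anisotropy = 0.6,
    gating_method = "otsu", rel_floor = 0.25,
    snr_rois = 6L
  )
}

# per-label intensity quantile (named by label)
core_quantile <- function(labels, img, q) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(setNames(numeric(0), character(0)))
  vapply(split(img[idx], labels[idx]), quantile, numeric(1), probs = q,
         names = FALSE)
}

# puncta counts for every label at once: LoG peaks assigned to labels
puncta_counts_by_label <- function(img, labels, spot_sigma = 2,
                                   min_prominence = NULL) {
  min_prominence <- min_prominence %||% (3 * mad(img))
  sm <- gauss_blur(img, spot_sigma)
  resp <- -spot_sigma^2 * laplacian(sm)
  mx <- maxfilter_cpp(resp, max(1L, ceiling(spot_sigma)))
  peaks <- resp >= mx - 1e-9 & resp > min_prominence & labels > 0L
  out <- integer(0)
  if (any(peaks)) {
    comp <- cc_label_cpp(peaks)           # merge plateau maxima
    idx <- which(comp > 0L)
    first <- idx[!duplicated(comp[idx])]  # one pixel per plateau
    tab <- table(labels[first])
    out <- setNames(as.integer(tab), names(tab))
  }
  out
}

# filament ridge fraction for every label at once (same criteria as
# filament_score())
filament_scores_by_label <- function(img, labels, sigma = 1.5,
                                     anisotropy = 0.6) {
  rm_ <- ridge_masks(img, sigma, anisotropy)
  ridge <- rm_$ridge
  active <- rm_$active
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  scores <- setNames(numeric(length(ids)), ids)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  area <- rowsum(rep(1, length(idx)), lab)
  act <- rowsum(as.numeric(active[idx]), lab)
  rid <- rowsum(as.numeric(ridge[idx] & active[idx]), lab)
  for (i in seq_along(ids)) {
    id <- as.character(ids[i])
    scores[i] <- if (act[id, 1] < max(4, 0.01 * area[id, 1])) 0
                 else rid[id, 1] / act[id, 1]
  }
  scores
}

#' Analyze a registered-or-raw multi-round experiment in memory
#'
#' Full analysis chain on a list of [round_stack()]s: registration on the
#' fiducial channels, nuclei segmentation per round, cross-round tracking,
#' completeness and border filtering, cell-body delineation on the reference
#' round, per-cell marker measurement (with puncta counts and filament
#' scores for structural markers), threshold derivation, positivity calling,
#' classification, and composition summary.
#'
#' @param stacks list of [round_stack()]
#' @param panel a [marker_panel()]
#' @param ruleset a [gating_ruleset()]
#' @param options list of parameters; see [default_options()]
#' @return list: `registration`, `records`, `percell` (wide table),
#'   `thresholds`, `calls`, `assignments`, `composition`, `qc`
#' @export
analyze_experiment <- function(stacks, panel = cortical_panel(),
                               ruleset = cortical_ruleset(),
                               options = list()) {
  opt <- modifyList(default_options(), options)
  validate_ruleset(ruleset, panel$marker)

  reg <- register_experiment(stacks, reference_round = opt$reference_round,
                             fiducial_weights = opt$fiducial_weights,
                             quality_floor = opt$quality_floor)
  aligned <- reg$stacks
  ids <- vapply(aligned, function(s) s$round_id, integer(1))
  iref <- match(attr(reg$result, "reference_round"), ids)

  nuclei <- lapply(seq_along(aligned), function(i)
    segment_nuclei(aligned[[i]]$channels$nuclear,
                   min_area = opt$min_nucleus_area,
                   max_area = opt$max_nucleus_area,
                   source_round = aligned[[i]]$round_id))
  records <- match_cells_across_rounds(nuclei, opt$max_centroid_distance)
  sampled <- nrow(records)
  complete <- filter_complete_cells(records)

  bodies <- delineate_cell_bodies(nuclei[[iref]],
                                  aligned[[iref]]$channels$actin,
                                  max_expand = opt$max_expand)
  lab <- bodies$labels

  # restrict the measurement label image to complete cells, re-keyed by record
  reflab_col <- paste0("label_round", iref)
  keep_lab <- complete[[reflab_col]]
  ok <- !is.na(keep_lab)
  complete <- complete[ok, , drop = FALSE]
  keep_lab <- keep_lab[ok]
  if (opt$exclude_border) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                              lab[, 1], lab[, ncol(lab)]))
    on_border <- keep_lab %in% setdiff(border_labels, 0L)
    complete <- complete[!on_border, , drop = FALSE]
    keep_lab <- keep_lab[!on_border]
  }
  if (!nrow(complete)) stop2("no analyzable cells after filtering")
  remap <- integer(max(lab))
  remap[keep_lab] <- complete$cell_id
  meas_lab <- lab
  meas_lab[meas_lab > 0L] <- ifelse(meas_lab[meas_lab > 0L] <= length(remap),
                                    remap[meas_lab[meas_lab > 0L]], 0L)
  meas_img <- label_image(meas_lab, aligned[[iref]]$round_id, "cell")

  # soma core (nucleus dilated by core_dilate px, clipped to the cell):
  # gating intensities are read here because whole-cell regions pick up
  # neurites of neighbouring cells, which bias even robust statistics
  nuc_ref <- nuclei[[iref]]$labels
  dist_nuc <- sqrt(edt_sq_cpp(nuc_ref == 0L))
  core_lab <- watershed_cpp(dist_nuc, nuc_ref, dist_nuc <= opt$core_dilate)
  core_lab[core_lab > 0L] <- ifelse(core_lab[core_lab > 0L] <= length(remap),
                                    remap[core_lab[core_lab > 0L]], 0L)
  core_img <- label_image(core_lab, aligned[[iref]]$round_id, "cell")

  percell <- data.frame(cell_id = complete$cell_id, row = complete$row,
                        col = complete$col, complete = TRUE)
  qc_rows <- list()
  for (k in seq_len(nrow(panel))) {
    m <- panel$marker[k]
    img <- aligned[[match(panel$round[k], ids)]]$channels[[m]]
    if (is.null(img)) stop2("marker %s assigned to round %d but channel missing",
                            m, panel$round[k])
    bg <- estimate_background(img, meas_img)
    gate_lab <- core_lab
    if (panel$kind[k] == "filament") {
      # a neighbour's process transiting the core is ridge-like; the cell's
      # own somatic signal is flat — drop ridge pixels so crossing neurites
      # cannot turn a negative cell positive
      rmk <- ridge_masks(img, opt$filament_sigma, opt$filament_anisotropy)
      gate_lab <- core_lab
      gate_lab[rmk$ridge & rmk$active] <- 0L
    }
    # robust gating intensity: corrected lower quantile over the soma core
    # (contamination must cover most of the core to flip it)
    gq <- core_quantile(gate_lab, img, opt$intensity_quantile)
    v <- pmax(gq[as.character(percell$cell_id)] - bg, 0)
    percell[[m]] <- ifelse(is.na(v), 0, v)
    percell[[m]][is.na(percell[[m]])] <- 0
    if (panel$kind[k] == "puncta") {
      cnt <- puncta_counts_by_label(img, meas_lab, opt$spot_sigma,
                                    opt$puncta_prominence)
      v <- cnt[as.character(percell$cell_id)]
      percell[[paste0(m, "_puncta_count")]] <- ifelse(is.na(v), 0L, v)
    }
    if (panel$kind[k] == "filament") {
      sc <- filament_scores_by_label(img, meas_lab, opt$filament_sigma,
                                     opt$filament_anisotropy)
      v <- sc[as.character(percell$cell_id)]
      percell[[paste0(m, "_filament_score")]] <- ifelse(is.na(v), 0, v)
    }
    snr <- tryCatch({
      rois <- propose_snr_rois(img, meas_img, n = opt$snr_rois,
                               seed = 7L + k)
      compute_snr(img, rois$signal, rois$background)$ratio
    }, error = function(e) NA_real_)
    qc_rows[[k]] <- data.frame(marker = m, round = panel$round[k],
                               background = bg, snr = snr)
  }

  thresholds <- derive_positivity_thresholds(percell, markers = panel$marker,
                                             method = opt$gating_method,
                                             rel_floor = opt$rel_floor)
  calls <- call_positivity_table(percell, thresholds, ruleset)
  assignments <- classify_cells(calls, ruleset)
  rule_classes <- vapply(ruleset$rules, function(r) r$class_name, character(1))
  composition <- summarize_composition(assignments, sampled_count = sampled,
                                       classes = c(rule_classes,
                                                   ruleset$fallback))
  list(registration = reg$result, records = records, percell = percell,
       thresholds = thresholds, calls = calls, assignments = assignments,
       composition = composition,
       qc = do.call(rbind, qc_rows))
}

#' Experiment configuration
#'
#' @param out_dir output directory (created if missing)
#' @param fixture_dir optional input bundle directory (from
#'   [write_fixture_bundle()]); if NULL, a culture is simulated from
#'   `simulation`
#' @param simulation list of [sim_config()] arguments for simulated runs
#' @param panel `"cortical"`, `"motor"`, or a [marker_panel()]
#' @param ruleset `"cortical"`, `"motor"`, a path to a ruleset JSON, or a
#'   [gating_ruleset()]
#' @param options analysis options overriding [default_options()]
#' @param seed master seed; the simulation seed defaults to it
#' @param write_images if TRUE, write registered channel TIFFs
#' @return an `experiment_config` list
#' @export
experiment_config <- function(out_dir, fixture_dir = NULL, simulation = list(),
                              panel = "cortical", ruleset = "cortical",
                              options = list(), seed = 1L,
                              write_images = FALSE) {
  if (is.character(panel))
    panel <- switch(panel, cortical = cortical_panel(), motor = motor_panel(),
                    stop2("unknown panel: %s", panel))
  if (is.character(ruleset)) {
    ruleset <- if (ruleset %in% c("cortical", "motor"))
      switch(ruleset, cortical = cortical_ruleset(), motor = motor_ruleset())
    else read_ruleset(ruleset)
  }
  validate_ruleset(ruleset, panel$marker)
  if (!is.null(fixture_dir) && !dir.exists(fixture_dir))
    stop2("fixture directory does not exist: %s", fixture_dir)
  structure(list(out_dir = out_dir, fixture_dir = fixture_dir,
                 simulation = simulation, panel = panel, ruleset = ruleset,
                 options = options, seed = as.integer(seed),
                 write_images = isTRUE(write_images)),
            class = "experiment_config")
}

# stable polynomial hash of the serialized parameters, for the run log
param_hash <- function(x) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                 digits = NA, force = TRUE)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Run the full pipeline and write its outputs
#'
#' Simulates (or loads) the image stacks, runs [analyze_experiment()], and
#' writes: `registration.csv`, `percell.csv`, `composition.csv`, `qc.csv`,
#' and a machine-readable `runlog.json` (package version, seed, parameter
#' hash, stage timings). Identical config and seed give identical outputs.
#'
#' @param config an [experiment_config()]
#' @return the [analyze_experiment()] result, invisibly, with `paths`
#'   attribute
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  if (is.null(config$fixture_dir)) {
    sim_args <- modifyList(list(seed = config$seed), config$simulation)
    cfg <- do.call(sim_config, sim_args)
    cells <- simulate_culture(cfg, config$panel, config$ruleset)
    rendered <- render_round_stacks(cells, cfg, config$panel)
    stacks <- rendered$stacks
  } else {
    bundle <- read_fixture_bundle(config$fixture_dir)
    stacks <- bundle$stacks
  }
  timings$input <- proc.time()[["elapsed"]] - t0

  t1 <- proc.time()[["elapsed"]]
  res <- analyze_experiment(stacks, config$panel, config$ruleset,
                            config$options)
  timings$analysis <- proc.time()[["elapsed"]] - t1

  paths <- list(
    registration = file.path(config$out_dir, "registration.csv"),
    percell = file.path(config$out_dir, "percell.csv"),
    composition = file.path(config$out_dir, "composition.csv"),
    qc = file.path(config$out_dir, "qc.csv"),
    runlog = file.path(config$out_dir, "runlog.json"))
  write_registration_report(res$registration, paths$registration)
  write.csv(res$percell, paths$percell, row.names = FALSE)
  comp <- res$composition
  write.csv(data.frame(class = comp$class, count = comp$count,
                       fraction = comp$fraction,
                       analyzed = attr(comp, "analyzed_count"),
                       sampled = attr(comp, "sampled_count"),
                       excluded = attr(comp, "excluded_count")),
            paths$composition, row.names = FALSE)
  write.csv(res$qc, paths$qc, row.names = FALSE)
  if (config$write_images) {
    # re-register for export (analysis returns only tables)
    reg <- register_experiment(stacks,
                               reference_round = modifyList(default_options(),
                                 config$options)$reference_round)
    for (st in reg$stacks)
      for (ch in names(st$channels))
        write_tiff(st$channels[[ch]],
                   file.path(config$out_dir,
                             sprintf("registered_round%02d_%s.tif",
                                     st$round_id, ch)))
  }
  runlog <- list(package = "cycim",
                 version = as.character(utils::packageVersion("cycim")),
                 seed = config$seed,
                 parameter_hash = param_hash(list(
                   simulation = config$simulation, options = config$options,
                   panel = as.data.frame(config$panel))),
                 timings_sec = timings,
                 analyzed = attr(res$composition, "analyzed_count"),
                 sampled = attr(res$composition, "sampled_count"))
  jsonlite::write_json(runlog, paths$runlog, auto_unbox = TRUE, digits = NA)
  attr(res, "paths") <- paths
  invisible(res)
}

#' Gate an external per-cell table (no imaging stages)
#'
#' Runs threshold derivation, positivity calling, classification and
#' composition on a per-cell measurement CSV — e.g. a table exported by
#' another tool — without touching images. Column names are adapted through
#' `column_map`; unmapped required markers are reported together.
#'
#' @param table a data.frame or path to a CSV with one row per cell and one
#'   intensity column per marker (plus `<marker>_puncta_count` /
#'   `<marker>_filament_score` when the rule set uses structural gates)
#' @param ruleset a [gating_ruleset()]
#' @param markers markers to gate (default: all markers referenced by the
#'   rule set)
#' @param thresholds optional named thresholds; derived when NULL
#' @param method threshold method when deriving (see
#'   [derive_positivity_thresholds()])
#' @param column_map optional named character vector mapping expected column
#'   names to the table's names, e.g. `c(Tuj1 = "TUJ1_mean")`
#' @param sampled_count cells sampled before upstream filtering (for
#'   exclusion accounting)
#' @param rel_floor absent-marker guard for otsu threshold derivation
#' @return list: `percell`, `thresholds`, `calls`, `assignments`,
#'   `composition`
#' @export
run_gating_from_table <- function(table, ruleset = cortical_ruleset(),
                                  markers = NULL, thresholds = NULL,
                                  method = "otsu", column_map = NULL,
                                  sampled_count = NULL, rel_floor = 0.25) {
  if (is.character(table)) {
    if (!file.exists(table)) stop2("table not found: %s", table)
    table <- read.csv(table)
  }
  if (!is.null(column_map))
    for (want in names(column_map)) {
      have <- column_map[[want]]
      if (is.null(table[[have]]))
        stop2("column_map names absent column '%s'", have)
      table[[want]] <- table[[have]]
    }
  markers <- markers %||% unique(unlist(lapply(ruleset$rules, function(r)
    c(r$positive, r$negative, names(r$structure)))))
  miss <- setdiff(markers, names(table))
  if (length(miss))
    stop2("required marker column(s) missing from table: %s",
          paste(miss, collapse = ", "))
  if (is.null(thresholds))
    thresholds <- derive_positivity_thresholds(table, markers = markers,
                                               method = method,
                                               rel_floor = rel_floor)
  calls <- call_positivity_table(table, thresholds, ruleset)
  assignments <- classify_cells(calls, ruleset)
  rule_classes <- vapply(ruleset$rules, function(r) r$class_name, character(1))
  composition <- summarize_composition(assignments,
                                       sampled_count = sampled_count,
                                       classes = c(rule_classes,
                                                   ruleset$fallback))
  list(percell = table, thresholds = thresholds, calls = calls,
       assignments = assignments, composition = composition)
}
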