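# Synthetic multi-round image stacks with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# several imaging rounds, each with two persistent fiducial channels (nuclear
# stain, actin) and two probe channels; cell populations with class-defined
# marker-expression profiles; per-round translation drift; per-round cell
# detachment; constant background plus additive noise. It is the package's
# source of ground truth for every downstream test.

#' Evaluate code under a temporary RNG seed
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-culture generator. Defaults describe
#' the standard fixture: 500 cells in a 512x512 field, five imaging rounds of
#' two probe channels, a 10x separation between positive and baseline marker
#' expression, additive Gaussian noise at 5% of the positive level, mild
#' per-round drift and a small per-round detachment rate.
#'
#' @param n_cells number of cells to simulate
#' @param field_shape integer `(rows, cols)` of the imaged field
#' @param composition named numeric vector of class fractions (must sum to 1);
#'   names must be classes of the gating rule set used for profile derivation
#' @param rounds number of imaging rounds
#' @param probe_channels_per_round probe channels acquired per round
#' @param drift_sd SD (pixels) of the per-round translation drift
#' @param detachment_rate_per_round probability a cell detaches between
#'   consecutive rounds
#' @param background_level constant background intensity (AU)
#' @param noise_sd SD of additive Gaussian noise (AU)
#' @param baseline_expression mean per-pixel intensity of a non-expressed
#'   (background-level) marker in a cell (AU)
#' @param separation fold-change of a positively expressed marker over
#'   `baseline_expression`
#' @param expression_cv lognormal coefficient of variation of per-cell
#'   expression around the class mean
#' @param soma_radius,nucleus_radius mean cell-body and nucleus radii (px)
#' @param nuclear_amp,actin_amp peak fiducial-channel intensities (AU)
#' @param poisson_noise if TRUE use Poisson (shot) noise instead of Gaussian
#' @param seed integer seed; all generator randomness flows from it
#' @return a `sim_config` list
#' @export
sim_config <- function(n_cells = 500L,
                       field_shape = c(512L, 512L),
                       composition = c(excitatory_neuron = 0.5,
                                       astrocyte_mature = 0.2,
                                       radial_glia = 0.2,
                                       npc = 0.1),
                       rounds = 5L,
                       probe_channels_per_round = 2L,
                       drift_sd = 2,
                       detachment_rate_per_round = 0.02,
                       background_level = 100,
                       noise_sd = 15,
                       baseline_expression = 30,
                       separation = 10,
                       expression_cv = 0.2,
                       soma_radius = 6,
                       nucleus_radius = 3,
                       nuclear_amp = 1000,
                       actin_amp = 400,
                       poisson_noise = FALSE,
                       seed = 1L) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop2("composition fractions must sum to 1 (got %.12f)", sum(composition))
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop2("composition must be a named vector of class fractions")
  stopifnot(n_cells >= 0, length(field_shape) == 2, rounds >= 1,
            probe_channels_per_round >= 1, drift_sd >= 0,
            detachment_rate_per_round >= 0, detachment_rate_per_round <= 1,
            background_level >= 0, noise_sd >= 0, baseline_expression > 0,
            separation > 1)
  structure(list(n_cells = as.integer(n_cells),
                 field_shape = as.integer(field_shape),
                 composition = composition,
                 rounds = as.integer(rounds),
                 probe_channels_per_round = as.integer(probe_channels_per_round),
                 drift_sd = drift_sd,
                 detachment_rate_per_round = detachment_rate_per_round,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 baseline_expression = baseline_expression,
                 separation = separation,
                 expression_cv = expression_cv,
                 soma_radius = soma_radius,
                 nucleus_radius = nucleus_radius,
                 nuclear_amp = nuclear_amp,
                 actin_amp = actin_amp,
                 poisson_noise = poisson_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# class -> per-marker mean expression, derived mechanically from the rule set:
# required-positive markers express at separation x baseline, everything else
# at baseline.
class_profiles <- function(classes, panel, ruleset) {
  validate_ruleset(ruleset, panel$marker)
  rule_classes <- vapply(ruleset$rules, function(r) r$class_name, character(1))
  prof <- matrix(0, nrow = length(classes), ncol = nrow(panel),
                 dimnames = list(classes, panel$marker))
  for (cl in classes) {
    i <- match(cl, rule_classes)
    if (is.na(i)) stop2("unknown class name in composition: '%s'", cl)
    r <- ruleset$rules[[i]]
    prof[cl, ] <- 1
    prof[cl, r$positive] <- NA  # filled below with the separation factor
  }
  prof
}

#' Simulate a cell culture with known classes and expression
#'
#' Draws cell classes from the configured composition (seeded multinomial),
#' places non-overlapping cells by dart throwing, derives each cell's
#' per-marker mean expression from its class's gating rule (required-positive
#' markers at `separation x baseline_expression`, all others at baseline,
#' with mild per-cell lognormal variation), and assigns per-round detachment.
#'
#' @param config a [sim_config()]
#' @param panel a [marker_panel()]
#' @param ruleset the [gating_ruleset()] from which class profiles are derived
#' @return a `cell_truth` data.frame: `cell_id`, `true_class`, `row`, `col`,
#'   `soma_radius`, `nucleus_radius`, `has_neurites`,
#'   `detaches_after_round` (NA = never), and one `expr_<marker>` column per
#'   panel marker. Cell geometry (neurite polylines, puncta offsets) is kept
#'   in the `geometry` attribute for the renderer.
#' @export
simulate_culture <- function(config, panel = cortical_panel(),
                             ruleset = cortical_ruleset()) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(panel) > config$rounds * config$probe_channels_per_round)
    stop2("panel has %d probe markers but only %d round-channel slots",
          nrow(panel), config$rounds * config$probe_channels_per_round)
  if (max(panel$round) > config$rounds)
    stop2("panel assigns markers to round %d but config has %d rounds",
          max(panel$round), config$rounds)
  classes <- names(config$composition)
  prof <- class_profiles(classes, panel, ruleset)
  nr <- config$field_shape[1]; nc <- config$field_shape[2]
  n <- config$n_cells

  with_seed(config$seed, {
    true_class <- if (n > 0)
      sample(classes, n, replace = TRUE, prob = config$composition)
    else character()

    # dart-throwing placement with a minimum centre distance
    margin <- config$soma_radius + 2
    d_min <- 2 * config$soma_radius + 4
    if (n > 0 && (nr - 2 * margin) * (nc - 2 * margin) < n * d_min^2 * 0.9)
      stop2("infeasible field packing: %d cells of radius %g in a %dx%d field",
            n, config$soma_radius, nr, nc)
    rows <- numeric(n); cols <- numeric(n)
    budget <- 200L * max(n, 1L)
    placed <- 0L
    while (placed < n && budget > 0L) {
      budget <- budget - 1L
      r0 <- runif(1, margin, nr - margin)
      c0 <- runif(1, margin, nc - margin)
      if (placed == 0L ||
          min((rows[seq_len(placed)] - r0)^2 + (cols[seq_len(placed)] - c0)^2) >= d_min^2) {
        placed <- placed + 1L
        rows[placed] <- r0; cols[placed] <- c0
      }
    }
    if (placed < n)
      stop2("infeasible field packing: placed only %d of %d cells", placed, n)

    # expression: class profile x lognormal per-cell factor
    pos_level <- config$separation * config$baseline_expression
    expr <- matrix(0, n, nrow(panel), dimnames = list(NULL, panel$marker))
    if (n > 0) {
      base <- prof[true_class, , drop = FALSE]
      base[is.na(base)] <- config$separation
      base <- base * config$baseline_expression
      sdl <- sqrt(log(1 + config$expression_cv^2))
      fac <- matrix(exp(rnorm(n * nrow(panel), -sdl^2 / 2, sdl)), n)
      expr <- base * fac
      colnames(expr) <- panel$marker
    }

    # detachment: geometric survival over round transitions
    detaches <- rep(NA_integer_, n)
    if (config$rounds > 1 && config$detachment_rate_per_round > 0 && n > 0) {
      for (i in seq_len(n)) {
        for (r in seq_len(config$rounds - 1L)) {
          if (runif(1) < config$detachment_rate_per_round) {
            detaches[i] <- r
            break
          }
        }
      }
    }

    filament_markers <- panel$marker[panel$kind == "filament"]
    puncta_markers <- panel$marker[panel$kind == "puncta"]
    is_pos <- expr > sqrt(config$separation) * config$baseline_expression
    has_neurites <- if (n > 0)
      apply(is_pos[, filament_markers, drop = FALSE], 1, any) else logical()

    # per-cell geometry for the renderer: neurite polylines, puncta offsets
    geometry <- vector("list", n)
    for (i in seq_len(n)) {
      g <- list(neurites = list(), puncta = list())
      if (has_neurites[i]) {
        for (k in seq_len(sample(2:4, 1))) {
          len <- runif(1, 25, 60)
          nstep <- max(2L, ceiling(len / 2))
          theta <- runif(1, 0, 2 * pi) + cumsum(c(0, rnorm(nstep - 1, 0, 0.15)))
          pts <- cbind(rows[i] + cumsum(2 * sin(theta)),
                       cols[i] + cumsum(2 * cos(theta)))
          g$neurites[[k]] <- pts
        }
      }
      for (m in puncta_markers) {
        if (is_pos[i, m]) {
          k <- max(4L, rpois(1, 8))
          ang <- runif(k, 0, 2 * pi)
          rad <- runif(k, 0.3, 0.95) * config$soma_radius
          g$puncta[[m]] <- cbind(rows[i] + rad * sin(ang),
                                 cols[i] + rad * cos(ang))
        }
      }
      geometry[[i]] <- g
    }

    truth <- data.frame(cell_id = seq_len(n),
                        true_class = true_class,
                        row = rows, col = cols,
                        soma_radius = rep(config$soma_radius, n),
                        nucleus_radius = rep(config$nucleus_radius, n),
                        has_neurites = has_neurites,
                        detaches_after_round = detaches,
                        stringsAsFactors = FALSE)
    for (m in panel$marker) truth[[paste0("expr_", m)]] <- expr[, m]
    attr(truth, "geometry") <- geometry
    attr(truth, "positive_level") <- pos_level
    class(truth) <- c("cell_truth", class(truth))
    truth
  })
}

# --- rendering primitives -------------------------------------------------

# Copying R wrappers over the in-place C++ stamps (the renderer calls the
# *_ip versions directly on buffers it owns).

# separable Gaussian stamp, subpixel centre (r0, c0), peak `amp`
stamp_gauss <- function(img, r0, c0, sigma, amp) {
  out <- img + 0
  stamp_gauss_ip(out, r0, c0, sigma, amp)
  out
}

# flat-topped soma profile (super-Gaussian of order 4)
stamp_soma <- function(img, r0, c0, radius, amp) {
  out <- img + 0
  stamp_soma_ip(out, r0, c0, radius, amp)
  out
}

# ridge along a polyline, crest height ~`amp`
stamp_polyline <- function(img, pts, sigma, amp) {
  out <- img + 0
  stamp_polyline_ip(out, pts, sigma, amp)
  out
}

#' Render multi-round image stacks from a simulated culture
#'
#' Each round holds the persistent `nuclear` and `actin` fiducial channels
#' plus the round's probe channels, named by marker. Nuclei are Gaussian
#' blobs, somata flat-topped disks, filament markers random-walk neurite
#' ridges and puncta markers discrete Gaussian spots (sigma 2.5 px). Every
#' round r > 1 is translated by a seeded drift vector (recorded in the truth
#' bundle); detached cells vanish from later rounds; constant background and
#' additive noise are applied last.
#'
#' @inheritParams simulate_culture
#' @param cells a `cell_truth` from [simulate_culture()]
#' @return list with `stacks` (list of `round_stack`) and `truth` (list:
#'   `cells`, `drifts` rounds x 2 matrix, `config`, `panel`)
#' @export
render_round_stacks <- function(cells, config, panel = cortical_panel()) {
  stopifnot(inherits(cells, "cell_truth"), inherits(config, "sim_config"))
  nr <- config$field_shape[1]; nc <- config$field_shape[2]
  geometry <- attr(cells, "geometry")
  spot_sigma <- 2.5
  neurite_sigma <- 1.2

  with_seed(config$seed + 1000L, {
    drifts <- matrix(0, config$rounds, 2,
                     dimnames = list(NULL, c("d_row", "d_col")))
    if (config$rounds > 1 && config$drift_sd > 0)
      drifts[-1, ] <- rnorm(2 * (config$rounds - 1), 0, config$drift_sd)

    stacks <- vector("list", config$rounds)
    for (r in seq_len(config$rounds)) {
      present <- which(is.na(cells$detaches_after_round) |
                         cells$detaches_after_round >= r)
      dr <- drifts[r, 1]; dc <- drifts[r, 2]
      chans <- list(nuclear = matrix(0, nr, nc), actin = matrix(0, nr, nc))
      round_markers <- panel$marker[panel$round == r]
      for (m in round_markers) chans[[m]] <- matrix(0, nr, nc)

      for (i in present) {
        r0 <- cells$row[i] + dr; c0 <- cells$col[i] + dc
        stamp_gauss_ip(chans$nuclear, r0, c0, cells$nucleus_radius[i],
                       config$nuclear_amp)
        stamp_soma_ip(chans$actin, r0, c0, cells$soma_radius[i],
                      config$actin_amp)
        if (cells$has_neurites[i])
          for (pts in geometry[[i]]$neurites)
            stamp_polyline_ip(chans$actin, sweep(pts, 2, c(dr, dc), "+"),
                              neurite_sigma, 0.5 * config$actin_amp)
        for (m in round_markers) {
          e <- cells[[paste0("expr_", m)]][i]
          kind <- panel$kind[panel$marker == m]
          pos <- e > sqrt(config$separation) * config$baseline_expression
          if (kind == "filament" && pos && cells$has_neurites[i]) {
            # cytoplasmic filament protein: soma stains at full level too
            stamp_soma_ip(chans[[m]], r0, c0, cells$soma_radius[i], e)
            for (pts in geometry[[i]]$neurites)
              stamp_polyline_ip(chans[[m]], sweep(pts, 2, c(dr, dc), "+"),
                                neurite_sigma, e)
          } else if (kind == "puncta" && pos) {
            sp <- geometry[[i]]$puncta[[m]]
            for (k in seq_len(nrow(sp)))
              stamp_gauss_ip(chans[[m]], sp[k, 1] + dr, sp[k, 2] + dc,
                             spot_sigma, e)
          } else {
            stamp_soma_ip(chans[[m]], r0, c0, cells$soma_radius[i], e)
          }
        }
      }

      for (ch in names(chans)) {
        img <- chans[[ch]] + config$background_level
        if (config$poisson_noise) {
          img[] <- rpois(length(img), pmax(img, 0))
        } else if (config$noise_sd > 0) {
          img <- img + rnorm(length(img), 0, config$noise_sd)
        }
        chans[[ch]] <- pmin(pmax(img, 0), 65535)
      }
      stacks[[r]] <- round_stack(r, chans)
    }
    list(stacks = stacks,
         truth = list(cells = cells, drifts = drifts, config = config,
                      panel = panel))
  })
}

#' Per-cell measurement table straight from ground truth
#'
#' Produces the same wide per-cell schema as image-based quantification
#' (`cell_id`, `row`, `col`, one intensity column per marker, plus
#' `<marker>_puncta_count` / `<marker>_filament_score` for structural
#' markers), but bypasses rendering: intensities are `marker_expression` plus
#' seeded Gaussian noise. Lets the gating stage be tested image-free.
#'
#' @inheritParams simulate_culture
#' @param noise_sd additive Gaussian noise SD (AU); 0 gives exact expression
#' @param seed RNG seed for the measurement noise
#' @return data.frame, one row per cell
#' @export
make_percell_table <- function(cells, noise_sd = 0, seed = 1L,
                               panel = cortical_panel()) {
  stopifnot(inherits(cells, "cell_truth"))
  n <- nrow(cells)
  geometry <- attr(cells, "geometry")
  pos_level <- attr(cells, "positive_level")
  with_seed(seed, {
    tab <- data.frame(cell_id = cells$cell_id, row = cells$row,
                      col = cells$col)
    for (m in panel$marker) {
      x <- cells[[paste0("expr_", m)]]
      if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
      tab[[m]] <- pmax(x, 0)
    }
    for (m in panel$marker[panel$kind == "puncta"]) {
      cnt <- vapply(seq_len(n), function(i) {
        sp <- geometry[[i]]$puncta[[m]]
        if (is.null(sp)) 0L else nrow(sp)
      }, integer(1))
      tab[[paste0(m, "_puncta_count")]] <- cnt
    }
    for (m in panel$marker[panel$kind == "filament"]) {
      pos <- cells[[paste0("expr_", m)]] > 0.5 * pos_level
      sc <- ifelse(pos & cells$has_neurites, 0.9, 0.05)
      if (noise_sd > 0) sc <- sc + rnorm(n, 0, 0.05)
      tab[[paste0(m, "_filament_score")]] <- pmin(pmax(sc, 0), 1)
    }
    tab
  })
}

#' Write a fixture bundle to disk
#'
#' Writes one 16-bit grayscale TIFF per round-channel, the cell truth table
#' and drift table as CSV, and a JSON manifest listing every file plus the
#' generating configuration. Intensities are rounded to integers on export;
#' reading the bundle back reproduces the written arrays exactly.
#'
#' @param rendered output of [render_round_stacks()]
#' @param dir output directory (must exist)
#' @return the manifest path, invisibly
#' @export
write_fixture_bundle <- function(rendered, dir) {
  if (!dir.exists(dir)) stop2("output directory does not exist: %s", dir)
  stacks <- rendered$stacks; truth <- rendered$truth
  entries <- list()
  for (st in stacks) {
    for (ch in names(st$channels)) {
      fn <- sprintf("round%02d_%s.tif", st$round_id, ch)
      write_tiff(st$channels[[ch]], file.path(dir, fn))
      entries[[length(entries) + 1]] <-
        list(round = st$round_id, channel = ch, file = fn)
    }
  }
  truth_csv <- "truth.csv"
  write.csv(as.data.frame(truth$cells), file.path(dir, truth_csv),
            row.names = FALSE)
  drift_csv <- "drifts.csv"
  write.csv(data.frame(round = seq_len(nrow(truth$drifts)), truth$drifts),
            file.path(dir, drift_csv), row.names = FALSE)
  manifest <- list(images = entries, truth = truth_csv, drifts = drift_csv,
                   rounds = length(stacks),
                   config = unclass(truth$config)[
                     setdiff(names(truth$config), "composition")],
                   composition = as.list(truth$config$composition),
                   panel = as.data.frame(truth$panel))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir bundle directory containing `manifest.json`
#' @return list with `stacks` (list of `round_stack`), `truth` data.frame,
#'   `drifts` matrix and the parsed `manifest`
#' @export
read_fixture_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop2("no manifest.json under %s", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  rounds <- sort(unique(manifest$images$round))
  stacks <- lapply(rounds, function(r) {
    sel <- manifest$images[manifest$images$round == r, ]
    chans <- lapply(seq_len(nrow(sel)), function(i)
      read_tiff(file.path(dir, sel$file[i])))
    names(chans) <- sel$channel
    round_stack(r, chans)
  })
  truth <- read.csv(file.path(dir, manifest$truth))
  drifts <- as.matrix(read.csv(file.path(dir, manifest$drifts))[, c("d_row", "d_col")])
  list(stacks = stacks, truth = truth, drifts = drifts, manifest = manifest)
}
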