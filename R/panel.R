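#' Marker panels
#'
#' A marker panel describes the probe markers of a cyclic-imaging experiment:
#' which marker is imaged in which round and probe channel, and what spatial
#' structure its stain exhibits (`"diffuse"`, `"filament"`, or `"puncta"`).
#' Each imaging round additionally carries the two persistent fiducial
#' channels (nuclear stain and actin), which are not part of the panel.
#'
#' @param marker character vector of marker names
#' @param kind structure kind per marker: `"diffuse"`, `"filament"` or
#'   `"puncta"`
#' @param round integer round index per marker (1-based)
#' @param channel integer probe-channel index within the round (1-based)
#' @return a `marker_panel`: a data.frame with columns `marker`, `kind`,
#'   `round`, `channel`
#' @examples
#' cortical_panel()
#' @export
marker_panel <- function(marker, kind, round, channel) {
  stopifnot(length(marker) == length(kind), length(marker) == length(round),
            length(marker) == length(channel))
  if (anyDuplicated(marker)) stop2("duplicated marker names in panel")
  bad <- setdiff(kind, c("diffuse", "filament", "puncta"))
  if (length(bad)) stop2("unknown structure kind: %s", paste(bad, collapse = ", "))
  key <- paste(round, channel)
  if (anyDuplicated(key))
    stop2("each (round, channel) slot may hold at most one marker")
  p <- data.frame(marker = as.character(marker), kind = as.character(kind),
                  round = as.integer(round), channel = as.integer(channel),
                  stringsAsFactors = FALSE)
  class(p) <- c("marker_panel", class(p))
  p
}

#' @rdname marker_panel
#' @details `cortical_panel()` is the default 10-marker cortical-culture
#'   panel: five rounds of two probe channels covering the neuronal markers
#'   Tuj1 (filamentous) and MAP2, the synaptic markers Synapsin (punctate),
#'   VGLUT1 and VGAT, the glial markers GFAP, Vimentin and CD44, the
#'   progenitor transcription factor Pax6 and the pluripotency factor Oct4A.
#' @export
cortical_panel <- function() {
  marker_panel(
    marker  = c("Tuj1", "MAP2", "Synapsin", "VGLUT1", "VGAT",
                "GFAP", "Vimentin", "CD44", "Pax6", "Oct4A"),
    kind    = c("filament", "diffuse", "puncta", "diffuse", "diffuse",
                "diffuse", "diffuse", "diffuse", "diffuse", "diffuse"),
    round   = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L),
    channel = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L)
  )
}

#' @rdname marker_panel
#' @details `motor_panel()` swaps the cortical synaptic subtype markers for
#'   the motor-neuron markers Islet1 and 200 kD neurofilament (NF200).
#' @export
motor_panel <- function() {
  marker_panel(
    marker  = c("Tuj1", "MAP2", "Synapsin", "Islet1", "NF200",
                "GFAP", "Vimentin", "CD44", "Pax6", "Oct4A"),
    kind    = c("filament", "diffuse", "puncta", "diffuse", "filament",
                "diffuse", "diffuse", "diffuse", "diffuse", "diffuse"),
    round   = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L),
    channel = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L)
  )
}

#' Gating rules and rule sets
#'
#' A gating rule names a cell class and the marker-positivity pattern that
#' defines it: every `positive` marker must be called positive and every
#' `negative` marker negative ("all required markers" gating — a cell joins a
#' class only when its full marker signature matches). Rules are evaluated in
#' ascending `priority` order and the first match wins; subtype rules (e.g.
#' excitatory neuron under neuron) are simply listed before their parent, so a
#' cell matching the parent but no subtype keeps the parent class. Optional
#' `structure` requirements gate a marker's positivity on a structural score:
#' `list(Synapsin = c(puncta = 3))` demands at least 3 detected puncta,
#' `list(Tuj1 = c(filament = 0.5))` a filament score of at least 0.5.
#'
#' @param class_name class label assigned on match
#' @param positive character vector of markers that must be positive
#' @param negative character vector of markers that must be negative
#' @param structure named list of structural requirements (see Details)
#' @param priority integer; lower numbers are evaluated first
#' @param parent optional parent class name (documentation only; ordering
#'   carries the subtype semantics)
#' @return `gating_rule()`: a `gating_rule` object; `gating_ruleset()`: a
#'   `gating_ruleset` (priority-sorted list of rules plus a fallback class)
#' @export
gating_rule <- function(class_name, positive = character(), negative = character(),
                        structure = list(), priority, parent = NULL) {
  if (length(intersect(positive, negative)))
    stop2("rule '%s': markers cannot be both required-positive and required-negative",
          class_name)
  for (m in names(structure)) {
    req <- structure[[m]]
    if (!names(req)[1] %in% c("puncta", "filament"))
      stop2("rule '%s': unknown structure requirement kind '%s'", class_name,
            names(req)[1])
  }
  structure(list(class_name = class_name,
                 positive = as.character(positive),
                 negative = as.character(negative),
                 structure = structure,
                 priority = as.integer(priority),
                 parent = parent),
            class = "gating_rule")
}

#' @rdname gating_rule
#' @param rules list of `gating_rule` objects
#' @param fallback class assigned when no rule matches
#' @export
gating_ruleset <- function(rules, fallback = "unclassified") {
  stopifnot(length(rules) >= 1)
  pr <- vapply(rules, function(r) r$priority, integer(1))
  if (anyDuplicated(pr)) stop2("rule priorities must be unique")
  rules <- rules[order(pr)]
  structure(list(rules = rules, fallback = fallback), class = "gating_ruleset")
}

#' @rdname gating_rule
#' @param ruleset a `gating_ruleset`
#' @param markers character vector of available marker names (e.g.
#'   `cortical_panel()$marker`)
#' @details `validate_ruleset()` errors at load time if any rule references a
#'   marker absent from the panel.
#' @export
validate_ruleset <- function(ruleset, markers) {
  stopifnot(inherits(ruleset, "gating_ruleset"))
  for (r in ruleset$rules) {
    used <- unique(c(r$positive, r$negative, names(r$structure)))
    missing <- setdiff(used, markers)
    if (length(missing))
      stop2("rule '%s' references unknown marker(s): %s", r$class_name,
            paste(missing, collapse = ", "))
  }
  invisible(ruleset)
}

#' @rdname gating_rule
#' @param structure_gates if TRUE, add the structural gates used to suppress
#'   staining artifacts: Tuj1 must show a filamentous pattern (filament score
#'   >= 0.1; somatic signal dilutes the ridge fraction, so the gate is
#'   deliberately modest) and Synapsin a punctate one (>= 3 puncta) to count
#'   as positive.
#' @details `cortical_ruleset()` encodes the cortical-culture class tree:
#'   residual pluripotent cells (Oct4A+), excitatory (Tuj1+/MAP2+/VGLUT1+) and
#'   inhibitory (Tuj1+/MAP2+/VGAT+) neurons, generic neurons (Tuj1+/MAP2+),
#'   radial glia (Pax6+/Vimentin+/Tuj1-), neural progenitors (Pax6+/Vimentin-),
#'   and mature (GFAP+) vs immature (GFAP-) astrocytes
#'   (CD44+/Vimentin+/Tuj1-/Pax6-). Unmatched cells fall back to
#'   "unclassified". Note the published class wordings for immature astrocytes
#'   disagree between timepoints on CD44 (CD44+ at day 55 vs CD44- at day 85);
#'   this default keeps CD44+ and the rule set is fully overridable.
#' @export
cortical_ruleset <- function(structure_gates = FALSE) {
  sg_tuj <- if (structure_gates) list(Tuj1 = c(filament = 0.1)) else list()
  sg_syn <- if (structure_gates) list(Synapsin = c(puncta = 3)) else list()
  gating_ruleset(list(
    gating_rule("ipsc", positive = "Oct4A", priority = 1L),
    gating_rule("excitatory_neuron", positive = c("Tuj1", "MAP2", "VGLUT1"),
                structure = sg_tuj, priority = 2L, parent = "neuron"),
    gating_rule("inhibitory_neuron", positive = c("Tuj1", "MAP2", "VGAT"),
                structure = sg_tuj, priority = 3L, parent = "neuron"),
    gating_rule("neuron", positive = c("Tuj1", "MAP2"),
                structure = c(sg_tuj, sg_syn), priority = 4L),
    gating_rule("radial_glia", positive = c("Pax6", "Vimentin"),
                negative = "Tuj1", priority = 5L),
    gating_rule("npc", positive = "Pax6", negative = "Vimentin", priority = 6L),
    gating_rule("astrocyte_mature", positive = c("CD44", "Vimentin", "GFAP"),
                negative = c("Tuj1", "Pax6"), priority = 7L,
                parent = "astrocyte"),
    gating_rule("astrocyte_immature", positive = c("CD44", "Vimentin"),
                negative = c("GFAP", "Tuj1", "Pax6"), priority = 8L,
                parent = "astrocyte")
  ))
}

#' @rdname gating_rule
#' @details `motor_ruleset()` is the motor-neuron variant: motor neurons are
#'   Islet1+/NF200+ neurons; the glial and progenitor classes are shared with
#'   the cortical rule set.
#' @export
motor_ruleset <- function() {
  gating_ruleset(list(
    gating_rule("ipsc", positive = "Oct4A", priority = 1L),
    gating_rule("motor_neuron", positive = c("Tuj1", "MAP2", "Islet1", "NF200"),
                priority = 2L, parent = "neuron"),
    gating_rule("neuron", positive = c("Tuj1", "MAP2"), priority = 3L),
    gating_rule("radial_glia", positive = c("Pax6", "Vimentin"),
                negative = "Tuj1", priority = 4L),
    gating_rule("npc", positive = "Pax6", negative = "Vimentin", priority = 5L),
    gating_rule("astrocyte_mature", positive = c("CD44", "Vimentin", "GFAP"),
                negative = c("Tuj1", "Pax6"), priority = 6L,
                parent = "astrocyte"),
    gating_rule("astrocyte_immature", positive = c("CD44", "Vimentin"),
                negative = c("GFAP", "Tuj1", "Pax6"), priority = 7L,
                parent = "astrocyte")
  ))
}

#' Read and write gating rule sets as JSON
#'
#' The on-disk format is a JSON object with a `fallback` string and a `rules`
#' array; each rule carries `class_name`, `positive`, `negative`, `structure`
#' (object marker -> `{kind, value}`), `priority` and optional `parent`.
#'
#' @param ruleset a `gating_ruleset`
#' @param path file path
#' @return `read_ruleset()` returns a `gating_ruleset`
#' @export
write_ruleset <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "gating_ruleset"))
  rules <- lapply(ruleset$rules, function(r) {
    st <- lapply(r$structure, function(req)
      list(kind = names(req)[1], value = unname(req[1])))
    list(class_name = r$class_name, positive = r$positive,
         negative = r$negative, structure = st, priority = r$priority,
         parent = r$parent)
  })
  jsonlite::write_json(list(fallback = ruleset$fallback, rules = rules),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) stop2("ruleset file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(x$rules, function(r) {
    st <- lapply(r$structure, function(req)
      setNames(as.numeric(req$value), req$kind))
    gating_rule(r$class_name,
                positive = unlist(r$positive) %||% character(),
                negative = unlist(r$negative) %||% character(),
                structure = st,
                priority = r$priority,
                parent = r$parent)
  })
  gating_ruleset(rules, fallback = x$fallback %||% "unclassified")
}

#' @export
print.gating_ruleset <- function(x, ...) {
  cat(sprintf("<gating_ruleset> %d rules, fallback '%s'\n",
              length(x$rules), x$fallback))
  for (r in x$rules) {
    st <- if (length(r$structure))
      paste0(" [", paste(vapply(names(r$structure), function(m)
        sprintf("%s:%s>=%g", m, names(r$structure[[m]])[1], r$structure[[m]][1]),
        character(1)), collapse = ", "), "]") else ""
    cat(sprintf("  %2d %-20s +{%s} -{%s}%s\n", r$priority, r$class_name,
                paste(r$positive, collapse = ","),
                paste(r$negative, collapse = ","), st))
  }
  invisible(x)
}
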