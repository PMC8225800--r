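# Marker positivity calling and rule-based cell classification.
#
# A cell joins a class only when its whole marker signature matches the
# class's rule ("all required markers" gating); rules are evaluated in
# priority order, subtypes before their parent, and unmatched cells are
# counted — not dropped — under the fallback class.

#' Derive per-marker positivity thresholds from a per-cell table
#'
#' Methods: `"otsu"` (default) applies Otsu's threshold to the raw corrected
#' means, with an absent-marker guard: every channel shares one
#' intensity scale, so a marker whose Otsu upper-mode mean falls below
#' `rel_floor` times the panel-median upper-mode mean is treated as not
#' expressed in the culture and all cells are called negative (an absent
#' marker's "positive" mode is just the noise tail, and all-markers-positive
#' gating makes false positives the costly error). `"kmad"` sets
#' `background + k * MAD`; `"fixed"` returns the supplied values verbatim.
#'
#' @param table per-cell data.frame with one intensity column per marker
#' @param markers character vector of marker columns (default: all panel-like
#'   numeric columns except ids/coordinates/structure columns)
#' @param method `"otsu"`, `"kmad"` or `"fixed"`
#' @param values named thresholds for `"fixed"`
#' @param background named or scalar background for `"kmad"`
#' @param k MAD multiplier for `"kmad"`
#' @param mad_value optional noise MAD for `"kmad"` (default: per-marker MAD)
#' @param rel_floor absent-marker guard for `"otsu"` (0 disables); only
#'   meaningful when several markers are derived together
#' @return named numeric vector of thresholds (AU, original scale)
#' @export
derive_positivity_thresholds <- function(table, markers = NULL,
                                         method = c("otsu", "kmad", "fixed"),
                                         values = NULL, background = NULL,
                                         k = 3, mad_value = NULL,
                                         rel_floor = 0.25) {
  method <- match.arg(method)
  markers <- markers %||% setdiff(
    names(table)[vapply(table, is.numeric, logical(1))],
    c("cell_id", "row", "col", "nucleus_area", "n_rounds", "first_round",
      grep("_(puncta_count|filament_score)$|^label_round", names(table),
           value = TRUE)))
  if (method == "fixed") {
    if (is.null(values)) stop2("method 'fixed' needs named threshold values")
    return(values[markers])
  }
  if (nrow(table) < 10)
    stop2("data-driven thresholds need at least 10 cells (got %d)", nrow(table))
  out <- setNames(numeric(length(markers)), markers)
  upper <- setNames(numeric(length(markers)), markers)
  for (m in markers) {
    x <- table[[m]]
    if (is.null(x)) stop2("marker column missing from table: %s", m)
    if (method == "kmad") {
      bg <- if (length(background) > 1) background[[m]] else background
      if (is.null(bg)) stop2("method 'kmad' needs a background level")
      out[m] <- bg + k * (mad_value %||% mad(x))
    } else {
      if (diff(range(x)) == 0)
        stop2("degenerate distribution for marker %s: all values equal; use a fixed threshold", m)
      # Otsu-anchored two-sided rule on the raw corrected means. The raw
      # Otsu split is only an anchor: the positive mode of structural
      # markers is broad (the split can land inside it) and the floored
      # zeros distort a log-scale split. The final threshold must clear the
      # negative mode (median + 3 MAD of the lower class, robust against
      # low-expressing positives leaking into it) and sit well below the
      # positive mode (25% of the upper-class mean).
      t0 <- as.numeric(otsu_threshold(x))
      lo <- x[x <= t0]; up <- x[x > t0]
      upper[m] <- mean(up)
      out[m] <- max(0.25 * mean(up), median(lo) + 3 * mad(lo))
    }
  }
  if (method == "otsu" && rel_floor > 0 && length(markers) > 1) {
    ref <- median(upper, na.rm = TRUE)
    for (m in markers) {
      if (is.na(upper[m]) || upper[m] < rel_floor * ref)
        out[m] <- max(table[[m]]) + 1  # absent marker: everyone negative
    }
  }
  out
}

# structural requirements per marker, pooled over the whole rule set
# (strictest wins when several rules gate the same marker)
collect_structure_requirements <- function(ruleset) {
  req <- list()
  for (r in ruleset$rules) {
    for (m in names(r$structure)) {
      cur <- req[[m]]
      if (is.null(cur) || r$structure[[m]][1] > cur[1])
        req[[m]] <- r$structure[[m]]
    }
  }
  req
}

#' Call marker positivity for a per-cell table
#'
#' A marker is positive when its background-corrected intensity exceeds its
#' threshold AND, if any rule in the set imposes a structural requirement on
#' that marker, the structural criterion passes (minimum puncta count from
#' `<marker>_puncta_count`, or minimum filament score from
#' `<marker>_filament_score`). Structural gating suppresses staining
#' artifacts: bright but amorphous signal does not count.
#'
#' @param table per-cell data.frame (one intensity column per marker)
#' @param thresholds named numeric vector from
#'   [derive_positivity_thresholds()]
#' @param ruleset a [gating_ruleset()] (source of structural requirements)
#' @return logical matrix, cells x markers
#' @export
call_positivity_table <- function(table, thresholds, ruleset = NULL) {
  markers <- names(thresholds)
  miss <- setdiff(markers, names(table))
  if (length(miss))
    stop2("missing marker measurement(s): %s", paste(miss, collapse = ", "))
  calls <- vapply(markers, function(m) table[[m]] > thresholds[[m]],
                  logical(nrow(table)))
  calls <- matrix(calls, nrow = nrow(table),
                  dimnames = list(NULL, markers))
  if (!is.null(ruleset)) {
    req <- collect_structure_requirements(ruleset)
    for (m in intersect(names(req), markers)) {
      kind <- names(req[[m]])[1]
      colname <- paste0(m, if (kind == "puncta") "_puncta_count"
                        else "_filament_score")
      if (is.null(table[[colname]]))
        stop2("structural gate on %s needs column %s", m, colname)
      calls[, m] <- calls[, m] & table[[colname]] >= req[[m]][1]
    }
  }
  calls
}

#' @rdname call_positivity_table
#' @param record a single-row per-cell data.frame (one cell)
#' @return `call_positivity()`: named logical vector for one cell
#' @export
call_positivity <- function(record, thresholds, ruleset = NULL) {
  stopifnot(nrow(record) == 1)
  calls <- call_positivity_table(record, thresholds, ruleset)
  setNames(as.logical(calls[1, ]), colnames(calls))
}

#' Classify cells from their positivity calls
#'
#' Evaluates rules in priority order; a cell receives the first class whose
#' required-positive markers are all positive and required-negative markers
#' all negative. Subtype rules listed before their parent refine it; a cell
#' matching only the parent keeps the parent class. Cells matching no rule
#' get the fallback class.
#'
#' @param calls logical matrix (cells x markers) from
#'   [call_positivity_table()]
#' @param ruleset a [gating_ruleset()]
#' @return character vector of class assignments
#' @export
classify_cells <- function(calls, ruleset) {
  stopifnot(inherits(ruleset, "gating_ruleset"))
  validate_ruleset(ruleset, colnames(calls))
  n <- nrow(calls)
  assigned <- rep(NA_character_, n)
  for (r in ruleset$rules) {
    open <- is.na(assigned)
    if (!any(open)) break
    ok <- rep(TRUE, n)
    for (m in r$positive) ok <- ok & calls[, m]
    for (m in r$negative) ok <- ok & !calls[, m]
    assigned[open & ok] <- r$class_name
  }
  assigned[is.na(assigned)] <- ruleset$fallback
  assigned
}

#' Summarize culture composition
#'
#' Counts and fractions per class over the analyzed cells, with exclusion
#' accounting against the number of cells sampled before filtering.
#'
#' @param assignments character vector of class assignments (analyzed cells)
#' @param sampled_count cells sampled before the completeness/QC filters
#'   (default: the analyzed count)
#' @param classes classes to report (default: observed; pass
#'   e.g. ruleset classes to include zero-count classes)
#' @return a `composition_table` data.frame (`class`, `count`, `fraction`)
#'   with attributes `analyzed_count`, `sampled_count`, `excluded_count`
#' @export
summarize_composition <- function(assignments, sampled_count = NULL,
                                  classes = NULL) {
  n <- length(assignments)
  if (n == 0) stop2("no analyzable cells")
  classes <- classes %||% sort(unique(assignments))
  extra <- setdiff(assignments, classes)
  if (length(extra))
    stop2("assignments outside the reported class list: %s",
          paste(unique(extra), collapse = ", "))
  cnt <- table(factor(assignments, levels = classes))
  sampled_count <- sampled_count %||% n
  if (sampled_count < n) stop2("sampled_count < analyzed count")
  out <- data.frame(class = classes, count = as.integer(cnt),
                    fraction = as.numeric(cnt) / n)
  attr(out, "analyzed_count") <- n
  attr(out, "sampled_count") <- sampled_count
  attr(out, "excluded_count") <- sampled_count - n
  class(out) <- c("composition_table", class(out))
  out
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %d analyzed of %d sampled (%d excluded)\n",
              attr(x, "analyzed_count"), attr(x, "sampled_count"),
              attr(x, "excluded_count")))
  df <- data.frame(class = x$class, count = x$count,
                   pct = sprintf("%.1f%%", 100 * x$fraction))
  print(df, row.names = FALSE)
  invisible(x)
}
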