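# Nuclei/cell-body segmentation on the fiducial channels and cross-round
# cell tracking. Only cells present in every imaging round survive to
# quantification (the completeness filter).

#' Label image container
#'
#' @param labels 2D integer matrix; 0 is background, positive integers are
#'   region identifiers
#' @param source_round round the labels were derived from
#' @param kind `"nucleus"` or `"cell"`
#' @return a `label_image`
#' @export
label_image <- function(labels, source_round = 1L, kind = c("nucleus", "cell")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, source_round = as.integer(source_round),
                 kind = kind), class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %s, round %d, %d regions\n", x$kind,
              x$source_round, length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Otsu's threshold for a numeric sample
#'
#' Maximizes between-class variance over a 256-bin histogram. Also reports
#' the separability ratio eta = sigma2_between / sigma2_total in the
#' `"eta"` attribute (1 = perfectly bimodal, ~0.6 for a unimodal Gaussian).
#'
#' @param x numeric vector or matrix
#' @param nbins histogram resolution
#' @return threshold (numeric scalar) with attribute `eta`
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.vector(x[is.finite(x)])
  rng <- range(x)
  if (diff(rng) == 0) stop2("degenerate distribution: all values equal")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sig_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sig_b[!is.finite(sig_b)] <- 0
  k <- which.max(sig_b)
  thr <- mids[k]
  sig_t <- sum(p * (mids - mu_t)^2)
  attr(thr, "eta") <- if (sig_t > 0) sig_b[k] / sig_t else 0
  thr
}

# centroids/areas of all labelled regions; data.frame(label, row, col, area)
label_stats <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx))
    return(data.frame(label = integer(), row = numeric(), col = numeric(),
                      area = numeric()))
  nr <- nrow(labels)
  lab <- labels[idx]
  r <- (idx - 1L) %% nr + 1L
  c_ <- (idx - 1L) %/% nr + 1L
  a <- rowsum(rep(1, length(idx)), lab)
  rs <- rowsum(as.numeric(r), lab)
  cs <- rowsum(as.numeric(c_), lab)
  data.frame(label = as.integer(rownames(a)), row = rs[, 1] / a[, 1],
             col = cs[, 1] / a[, 1], area = a[, 1])
}

# drop regions outside [min_area, max_area] and relabel 1..n in ascending
# original-label order
filter_relabel <- function(labels, min_area, max_area) {
  st <- label_stats(labels)
  keep <- st$label[st$area >= min_area & st$area <= max_area]
  map <- integer(max(labels, 1L))
  map[keep] <- seq_along(keep)
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Segment nuclei on a nuclear-stain image
#'
#' Thresholds the image (Otsu by default), splits touching nuclei by a
#' distance-transform watershed seeded at distance-map peaks, and discards
#' regions outside the allowed area range.
#'
#' @param nuclear_image 2D numeric matrix
#' @param min_area,max_area region area bounds in px^2
#' @param method `"otsu"`, `"kmad"` (median + k*MAD) or `"fixed"`
#' @param threshold fixed threshold (for `method = "fixed"`)
#' @param k multiplier for `"kmad"`
#' @param source_round recorded in the output
#' @return a `label_image` of kind `"nucleus"`
#' @export
segment_nuclei <- function(nuclear_image, min_area = 10, max_area = 400,
                           method = c("otsu", "kmad", "fixed"),
                           threshold = NULL, k = 5, source_round = 1L) {
  method <- match.arg(method)
  stopifnot(is.matrix(nuclear_image), length(nuclear_image) > 0)
  thr <- switch(method,
    otsu = if (diff(range(nuclear_image)) == 0) Inf
           else as.numeric(otsu_threshold(nuclear_image)),
    kmad = median(nuclear_image) + k * mad(nuclear_image),
    fixed = threshold %||% stop2("method 'fixed' needs a threshold"))
  mask <- nuclear_image > thr
  if (!any(mask))
    return(label_image(matrix(0L, nrow(nuclear_image), ncol(nuclear_image)),
                       source_round, "nucleus"))
  ds <- sqrt(edt_sq_cpp(mask))
  dsm <- gauss_blur(ds, 1)
  mx <- maxfilter_cpp(dsm, 3L)
  peaks <- mask & dsm >= mx - 1e-9 & ds >= 1
  seeds <- cc_label_cpp(peaks)
  lab <- watershed_cpp(-dsm, seeds, mask)
  lab <- filter_relabel(lab, min_area, max_area)
  label_image(lab, source_round, "nucleus")
}

#' Grow cell bodies from nuclei over the actin channel
#'
#' Seeded watershed on inverted actin intensity: each nucleus expands over
#' above-background actin signal, at most `max_expand` px from the nucleus,
#' and neighbouring cells split along actin valleys. Each nucleus yields one
#' cell region containing it.
#'
#' @param nuclei a nucleus `label_image`
#' @param actin_image 2D numeric matrix (same field)
#' @param max_expand maximum expansion distance from the nucleus (px)
#' @param actin_threshold intensity above which actin counts as signal
#'   (default: Otsu)
#' @return a `label_image` of kind `"cell"`
#' @export
delineate_cell_bodies <- function(nuclei, actin_image, max_expand = 10,
                                  actin_threshold = NULL) {
  stopifnot(inherits(nuclei, "label_image"))
  if (!all(dim(nuclei$labels) == dim(actin_image)))
    stop2("nuclei and actin image shapes differ")
  nuc <- nuclei$labels
  thr <- actin_threshold %||% (if (diff(range(actin_image)) == 0) Inf
                               else as.numeric(otsu_threshold(actin_image)))
  dist_to_nuc <- sqrt(edt_sq_cpp(nuc == 0L))
  allowed <- (actin_image > thr & dist_to_nuc <= max_expand) | nuc > 0L
  lab <- watershed_cpp(-actin_image, nuc, allowed)
  lab[nuc > 0L] <- nuc[nuc > 0L]  # nucleus always inside its cell
  label_image(lab, nuclei$source_round, "cell")
}

#' Track cells across registered rounds
#'
#' Greedy nearest-centroid matching between consecutive rounds: candidate
#' pairs closer than `max_centroid_distance` are accepted in order of
#' ascending distance (ties broken by ascending record id, then detection
#' label), so matching is deterministic. Detections in later rounds that
#' match no record start new (necessarily incomplete) records.
#'
#' @param per_round_nuclei list of nucleus `label_image`s, one per round, in
#'   round order and in a common (registered) frame
#' @param max_centroid_distance maximum matching distance in px
#' @return `cell_records` data.frame: `cell_id`, `row`, `col`,
#'   `nucleus_area`, `first_round`, `rounds_present` (";"-separated),
#'   `n_rounds`, `complete`, `label_round<r>` columns giving the matched
#'   label in each round (NA where absent)
#' @export
match_cells_across_rounds <- function(per_round_nuclei,
                                      max_centroid_distance = 10) {
  R <- length(per_round_nuclei)
  stopifnot(R >= 1)
  stats <- lapply(per_round_nuclei, function(li) label_stats(li$labels))

  st1 <- stats[[1]]
  rec <- data.frame(cell_id = seq_len(nrow(st1)), row = st1$row, col = st1$col,
                    nucleus_area = st1$area, first_round = rep(1L, nrow(st1)))
  labmat <- matrix(NA_integer_, nrow(st1), R)
  if (nrow(st1)) labmat[, 1] <- st1$label
  cur_row <- st1$row; cur_col <- st1$col  # last seen position per record

  for (r in seq_len(R)[-1]) {
    st <- stats[[r]]
    n_rec <- nrow(rec); n_det <- nrow(st)
    if (n_rec && n_det) {
      d2 <- outer(cur_row, st$row, "-")^2 + outer(cur_col, st$col, "-")^2
      cand <- which(d2 <= max_centroid_distance^2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d2[cand], rec$cell_id[cand[, 1]], st$label[cand[, 2]])
        cand <- cand[ord, , drop = FALSE]
        used_rec <- logical(n_rec); used_det <- logical(n_det)
        for (i in seq_len(nrow(cand))) {
          ri <- cand[i, 1]; di <- cand[i, 2]
          if (used_rec[ri] || used_det[di]) next
          used_rec[ri] <- TRUE; used_det[di] <- TRUE
          labmat[ri, r] <- st$label[di]
          cur_row[ri] <- st$row[di]; cur_col[ri] <- st$col[di]
        }
      } else used_det <- logical(n_det)
    } else used_det <- logical(n_det)
    new_det <- which(!used_det)
    if (length(new_det)) {
      add <- data.frame(cell_id = nrow(rec) + seq_along(new_det),
                        row = st$row[new_det], col = st$col[new_det],
                        nucleus_area = st$area[new_det],
                        first_round = rep(r, length(new_det)))
      rec <- rbind(rec, add)
      labadd <- matrix(NA_integer_, length(new_det), R)
      labadd[, r] <- st$label[new_det]
      labmat <- rbind(labmat, labadd)
      cur_row <- c(cur_row, st$row[new_det])
      cur_col <- c(cur_col, st$col[new_det])
    }
  }

  present <- !is.na(labmat)
  rec$rounds_present <- apply(present, 1, function(p)
    paste(which(p), collapse = ";"))
  rec$n_rounds <- rowSums(present)
  rec$complete <- rec$n_rounds == R
  colnames(labmat) <- paste0("label_round", seq_len(R))
  out <- cbind(rec, as.data.frame(labmat))
  class(out) <- c("cell_records", class(out))
  out
}

#' Keep only cells present in every round
#'
#' @param records a `cell_records` data.frame
#' @return the complete records; the number excluded is in the
#'   `excluded_count` attribute
#' @export
filter_complete_cells <- function(records) {
  keep <- records[records$complete, , drop = FALSE]
  attr(keep, "excluded_count") <- nrow(records) - nrow(keep)
  keep
}

# Gaussian blur by separable convolution with replicated edges
#' @noRd
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  w <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-w, w), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    padded <- rbind(m[rep(1L, w), , drop = FALSE], m,
                    m[rep(n, w), , drop = FALSE])
    f <- stats::filter(padded, k, sides = 2)
    matrix(f[(w + 1):(w + n), ], n, ncol(m))
  }
  t(blur1(t(blur1(img))))
}
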