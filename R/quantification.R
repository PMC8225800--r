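# Per-cell marker quantification and image QC statistics.

#' Measure per-cell marker intensities
#'
#' Mean, median and integrated intensity of a marker image over each
#' labelled cell region, with background-corrected mean and median floored
#' at zero (negative corrected intensities would break monotone thresholding
#' downstream). The median variant is robust to thin structures from
#' neighbouring cells (e.g. neurites) crossing the region, which inflate the
#' mean; gating uses it by default.
#'
#' @param cells a `label_image` (any kind)
#' @param marker_image 2D numeric matrix, same shape, registered frame
#' @param background scalar background estimate in AU
#' @return data.frame: `cell_id`, `mean_intensity`, `median_intensity`,
#'   `integrated_intensity`, `area`, `background`, `corrected_mean`,
#'   `corrected_median`
#' @export
measure_marker_intensity <- function(cells, marker_image, background = 0) {
  stopifnot(inherits(cells, "label_image"))
  if (!all(dim(cells$labels) == dim(marker_image)))
    stop2("label and marker image shapes differ")
  idx <- which(cells$labels > 0L)
  if (!length(idx))
    return(data.frame(cell_id = integer(), mean_intensity = numeric(),
                      median_intensity = numeric(),
                      integrated_intensity = numeric(), area = numeric(),
                      background = numeric(), corrected_mean = numeric(),
                      corrected_median = numeric()))
  lab <- cells$labels[idx]
  v <- marker_image[idx]
  s <- rowsum(v, lab)
  a <- rowsum(rep(1, length(idx)), lab)
  mean_i <- s[, 1] / a[, 1]
  med_i <- vapply(split(v, lab), median, numeric(1))
  data.frame(cell_id = as.integer(rownames(s)),
             mean_intensity = mean_i,
             median_intensity = unname(med_i),
             integrated_intensity = s[, 1],
             area = a[, 1],
             background = background,
             corrected_mean = pmax(mean_i - background, 0),
             corrected_median = pmax(unname(med_i) - background, 0))
}

#' Estimate the background level of an image
#'
#' Default: median over pixels outside all cell regions. Alternatives: a
#' fixed value, or a lower percentile of the whole image
#' (`method = "percentile:5"`).
#'
#' @param image 2D numeric matrix
#' @param labels optional `label_image` (or integer matrix) of cell regions
#'   to exclude
#' @param method `"median"`, `"fixed"` or `"percentile:<p>"`
#' @param value fixed background (for `method = "fixed"`)
#' @return background estimate in AU
#' @export
estimate_background <- function(image, labels = NULL, method = "median",
                                value = NULL) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (method == "fixed")
    return(value %||% stop2("method 'fixed' needs a value"))
  if (startsWith(method, "percentile:")) {
    p <- as.numeric(sub("percentile:", "", method))
    if (!is.finite(p) || p < 0 || p > 100) stop2("bad percentile: %s", method)
    return(as.numeric(quantile(image, p / 100, type = 7)))
  }
  if (method != "median") stop2("unknown background method: %s", method)
  lab <- if (inherits(labels, "label_image")) labels$labels else labels
  bgpix <- if (is.null(lab)) as.vector(image) else image[lab == 0L]
  if (!length(bgpix))
    stop2("no background pixels: cell regions cover the whole field")
  median(bgpix)
}

#' Signal-to-noise ratio from paired ROI sets
#'
#' The mean over `n` signal-ROI means divided by the mean over `n`
#' background-ROI means (the conventional n = 6 measurements each). ROIs are
#' logical masks or `c(r0, r1, c0, c1)` rectangles.
#'
#' @param image 2D numeric matrix
#' @param signal_rois,background_rois lists of ROIs
#' @return `snr_estimate` list: `mean_signal`, `mean_background`,
#'   `n_signal_rois`, `n_background_rois`, `ratio`
#' @export
compute_snr <- function(image, signal_rois, background_rois) {
  roi_mean <- function(roi) {
    if (is.logical(roi)) {
      if (!all(dim(roi) == dim(image))) stop2("ROI mask shape mismatch")
      if (!any(roi)) stop2("empty ROI")
      mean(image[roi])
    } else {
      stopifnot(length(roi) == 4)
      if (roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(image) || roi[4] > ncol(image))
        stop2("ROI rectangle out of bounds")
      mean(image[roi[1]:roi[2], roi[3]:roi[4]])
    }
  }
  ms <- mean(vapply(signal_rois, roi_mean, numeric(1)))
  mb <- mean(vapply(background_rois, roi_mean, numeric(1)))
  if (mb <= 0) stop2("zero background mean: SNR undefined")
  structure(list(mean_signal = ms, mean_background = mb,
                 n_signal_rois = length(signal_rois),
                 n_background_rois = length(background_rois),
                 ratio = ms / mb),
            class = "snr_estimate")
}

#' Propose signal and background ROIs automatically
#'
#' Signal ROIs are the `n` labelled regions with the highest mean marker
#' intensity; background ROIs are `n` seeded random patches that avoid all
#' cell regions.
#'
#' @param image marker image
#' @param labels `label_image` of cell regions
#' @param n ROIs per set
#' @param patch background patch half-width (px)
#' @param seed RNG seed for patch placement
#' @return list with `signal` and `background` ROI lists for [compute_snr()]
#' @export
propose_snr_rois <- function(image, labels, n = 6L, patch = 5L, seed = 1L) {
  meas <- measure_marker_intensity(labels, image, 0)
  if (nrow(meas) < n) stop2("need at least %d labelled regions", n)
  top <- meas$cell_id[order(-meas$mean_intensity)][seq_len(n)]
  signal <- lapply(top, function(id) labels$labels == id)
  nr <- nrow(image); nc <- ncol(image)
  background <- with_seed(seed, {
    out <- list(); tries <- 0L
    while (length(out) < n && tries < 2000L) {
      tries <- tries + 1L
      r0 <- sample(seq_len(nr - 2 * patch), 1) + patch
      c0 <- sample(seq_len(nc - 2 * patch), 1) + patch
      ri <- (r0 - patch):(r0 + patch); ci <- (c0 - patch):(c0 + patch)
      if (all(labels$labels[ri, ci] == 0L))
        out[[length(out) + 1]] <- c(min(ri), max(ri), min(ci), max(ci))
    }
    if (length(out) < n) stop2("could not place %d background ROIs", n)
    out
  })
  list(signal = signal, background = background)
}

#' Pearson correlation between two images
#'
#' The standard pixel-wise Pearson coefficient, optionally restricted to a
#' mask. Used to compare a marker's cyclic-imaging stain against its
#' conventional immunofluorescence control.
#'
#' @param image_a,image_b 2D numeric matrices of equal shape
#' @param mask optional logical matrix selecting the pixels to correlate
#' @return correlation in `[-1, 1]`
#' @export
pearson_correlation <- function(image_a, image_b, mask = NULL) {
  if (!all(dim(image_a) == dim(image_b))) stop2("image shapes differ")
  a <- if (is.null(mask)) as.vector(image_a) else image_a[mask]
  b <- if (is.null(mask)) as.vector(image_b) else image_b[mask]
  if (sd(a) == 0 || sd(b) == 0)
    stop2("zero variance: Pearson correlation undefined")
  stats::cor(a, b)
}

# Laplacian with replicated edges
laplacian <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1, seq_len(nr - 1)), ]
  dn <- img[c(seq_len(nr - 1) + 1, nr), ]
  lf <- img[, c(1, seq_len(nc - 1))]
  rt <- img[, c(seq_len(nc - 1) + 1, nc)]
  up + dn + lf + rt - 4 * img
}

#' Count fluorescent puncta within a cell region
#'
#' Laplacian-of-Gaussian blob detection: the scale-normalized LoG response
#' (`-sigma^2 * Laplacian(Gaussian(image))`, positive for bright spots) is
#' searched for local maxima above `min_prominence` inside the region;
#' plateau maxima are merged so each spot counts once.
#'
#' @param marker_image 2D numeric matrix
#' @param cell_region logical matrix (same shape) selecting the cell
#' @param spot_sigma expected spot sigma in px
#' @param min_prominence minimum LoG response; default 3 x the image MAD
#' @return integer count
#' @export
count_puncta <- function(marker_image, cell_region, spot_sigma = 2,
                         min_prominence = NULL) {
  if (!all(dim(marker_image) == dim(cell_region)))
    stop2("region shape mismatch")
  if (!any(cell_region)) return(0L)
  min_prominence <- min_prominence %||% (3 * mad(marker_image))
  sm <- gauss_blur(marker_image, spot_sigma)
  resp <- -spot_sigma^2 * laplacian(sm)
  mx <- maxfilter_cpp(resp, max(1L, ceiling(spot_sigma)))
  peaks <- resp >= mx - 1e-9 & resp > min_prominence & cell_region
  if (!any(peaks)) return(0L)
  max(cc_label_cpp(peaks))  # merge plateau maxima
}

# Shared ridge analysis: smoothed Hessian eigenvalues, "active" (above
# background) and "ridge-like" masks. A pixel is ridge-like when its
# principal curvature is negative (bright crest), the curvature is
# anisotropic, and the gradient is small relative to the curvature — the
# last condition separates true crests (gradient ~ 0) from the boundaries of
# isotropic blobs, which are anisotropic in curvature but sit on a steep
# gradient.
ridge_masks <- function(img, sigma, anisotropy) {
  sm <- gauss_blur(img, sigma)
  bg <- median(img)
  noise <- mad(img)
  thr <- bg + max(3 * noise, 0.2 * (max(sm) - bg))
  nr <- nrow(sm); nc <- ncol(sm)
  rr <- sm[c(1, seq_len(nr - 1)), ] + sm[c(seq_len(nr - 1) + 1, nr), ] - 2 * sm
  cc2 <- sm[, c(1, seq_len(nc - 1))] + sm[, c(seq_len(nc - 1) + 1, nc)] - 2 * sm
  gr <- (sm[c(seq_len(nr - 1) + 1, nr), ] - sm[c(1, seq_len(nr - 1)), ]) / 2
  gc <- (sm[, c(seq_len(nc - 1) + 1, nc)] - sm[, c(1, seq_len(nc - 1))]) / 2
  rc <- (gr[, c(seq_len(nc - 1) + 1, nc)] - gr[, c(1, seq_len(nc - 1))]) / 2
  disc <- sqrt(((rr - cc2) / 2)^2 + rc^2)
  l1 <- (rr + cc2) / 2 - disc  # l1 <= l2
  l2 <- (rr + cc2) / 2 + disc
  anis <- (l2 - l1) / (abs(l1) + abs(l2) + 1e-12)
  gmag <- sqrt(gr^2 + gc^2)
  ridge <- l1 < 0 & anis > anisotropy & gmag < 0.5 * sigma * (-l1)
  # widen the 1-px crest to the filament body so the score reflects area
  ridge <- maxfilter_cpp(ridge + 0, 1L) > 0.5
  list(active = sm > thr, ridge = ridge)
}

#' Filamentousness score of a marker stain within a cell region
#'
#' Hessian ridge analysis: after Gaussian smoothing, a pixel is "active" if
#' above background plus a noise margin, and "ridge-like" if it lies on a
#' bright anisotropic intensity crest (principal curvature negative, high
#' curvature anisotropy, near-zero gradient). The score is the fraction of
#' active pixels that are ridge-like — a monotone map of ridge response onto
#' `[0, 1]`. Regions with fewer than 1% active pixels (blank or pure noise)
#' score 0. Elongated structures outscore isotropic blobs of equal
#' integrated intensity because neither blob interiors (flat) nor their
#' boundaries (steep gradient) qualify as crests. The absolute scale is a
#' pipeline convention, not a measured quantity.
#'
#' @param marker_image 2D numeric matrix
#' @param cell_region logical matrix selecting the cell
#' @param sigma smoothing scale in px (about half the filament width)
#' @param anisotropy minimum ridge anisotropy
#' @return score in `[0, 1]`
#' @export
filament_score <- function(marker_image, cell_region, sigma = 1.5,
                           anisotropy = 0.6) {
  if (!all(dim(marker_image) == dim(cell_region)))
    stop2("region shape mismatch")
  if (!any(cell_region)) return(0)
  rm_ <- ridge_masks(marker_image, sigma, anisotropy)
  active <- cell_region & rm_$active
  if (sum(active) < max(4, 0.01 * sum(cell_region))) return(0)
  mean(rm_$ridge[active])
}

#' Check residual signal after imager-strand washout
#'
#' Post-rinse control images confirm imaging strands were removed before the
#' next round: the image mean relative to the pre-stain background must not
#' exceed `tolerance_fold`.
#'
#' @param post_wash_image 2D numeric matrix acquired after the final rinse
#' @param pre_stain_background background level before staining (AU, > 0)
#' @param tolerance_fold maximum allowed fold-change
#' @return list: `ratio`, `pass`
#' @export
washout_residual_check <- function(post_wash_image, pre_stain_background,
                                   tolerance_fold = 1.5) {
  if (pre_stain_background <= 0) stop2("zero background: ratio undefined")
  ratio <- mean(post_wash_image) / pre_stain_background
  list(ratio = ratio, pass = ratio <= tolerance_fold)
}
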