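# Cross-round registration on the persistent fiducial channels.
#
# Rounds of a cyclic-imaging experiment are repeated acquisitions of the same
# well, so misalignment is dominated by stage drift: a rigid translation.
# Shifts are estimated by phase correlation on the nuclear and actin fiducial
# channels, refined to subpixel precision by evaluating the cross-correlation
# on an upsampled grid around the integer peak (matrix-multiply DFT), and a
# single shift per round is applied to every channel of that round.

fftfreq <- function(n, d = 1) {
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * d)
}

# Evaluate the inverse DFT of `P` on an upsampled `size` x `size` grid whose
# origin is offset by (roff, coff) upsampled pixels.
upsampled_idft <- function(P, size, usf, roff, coff) {
  nr <- nrow(P); nc <- ncol(P)
  kr <- exp(2i * pi * outer(seq_len(size) - 1 - roff, fftfreq(nr, usf)))
  kc <- exp(2i * pi * outer(fftfreq(nc, usf), seq_len(size) - 1 - coff))
  kr %*% P %*% kc
}

#' Estimate the translation between two fiducial images
#'
#' Phase correlation with subpixel refinement. The returned shift `s` is the
#' translation that maps the reference onto the moving image: for integer
#' shifts, `moving == roll(reference, s)`. Quality is the Pearson correlation
#' between the reference and the back-shifted moving image over the interior
#' (a normalized correlation in `[-1, 1]`).
#'
#' @param reference,moving 2D numeric matrices of equal shape
#' @param upsample subpixel upsampling factor (shift resolved to
#'   `1/upsample` px)
#' @return list with `shift` (`c(d_row, d_col)`) and `quality`
#' @export
estimate_shift <- function(reference, moving, upsample = 20L) {
  if (!all(dim(reference) == dim(moving)))
    stop2("reference and moving images must share shape")
  if (sd(reference) == 0 || sd(moving) == 0)
    stop2("no fiducial structure: constant image")
  nr <- nrow(reference); nc <- ncol(reference)
  Fr <- fft(reference); Fm <- fft(moving)
  P <- Fm * Conj(Fr)  # peak of ifft(P) sits at the ref -> moving shift
  cc <- fft(P, inverse = TRUE)
  pk <- which.max(Mod(cc)) - 1L
  s <- c(pk %% nr, pk %/% nr)
  if (s[1] > nr / 2) s[1] <- s[1] - nr
  if (s[2] > nc / 2) s[2] <- s[2] - nc
  if (upsample > 1) {
    size <- ceiling(1.5 * upsample)
    dftshift <- floor(size / 2)
    ups <- upsampled_idft(P, size, upsample,
                          dftshift - s[1] * upsample,
                          dftshift - s[2] * upsample)
    pk2 <- which.max(Mod(ups)) - 1L
    s <- s + (c(pk2 %% size, pk2 %/% size) - dftshift) / upsample
  }
  aligned <- apply_shift(moving, -s)
  m <- ceiling(max(abs(s))) + 2L
  ri <- (m + 1):(nr - m); ci <- (m + 1):(nc - m)
  q <- if (length(ri) > 4 && length(ci) > 4 &&
           sd(reference[ri, ci]) > 0 && sd(aligned[ri, ci]) > 0)
    stats::cor(as.vector(reference[ri, ci]), as.vector(aligned[ri, ci]))
  else NA_real_
  list(shift = s, quality = q)
}

#' Translate an image by a (possibly fractional) shift
#'
#' Bilinear interpolation; pixels pulled from outside the field are filled
#' with a background estimate (the image median). `apply_shift(x, s)` moves
#' content down by `s[1]` rows and right by `s[2]` columns, so for integer
#' shifts it agrees with an array roll on interior pixels, and
#' `apply_shift(apply_shift(x, s), -s)` restores `x` away from the borders.
#'
#' @param image 2D numeric matrix
#' @param shift numeric `c(d_row, d_col)`
#' @param fill value for out-of-field pixels (default: image median)
#' @return shifted matrix
#' @export
apply_shift <- function(image, shift, fill = NULL) {
  stopifnot(is.matrix(image), length(shift) == 2, all(is.finite(shift)))
  if (all(shift == 0)) return(image)
  fill <- fill %||% median(image)
  nr <- nrow(image); nc <- ncol(image)
  # output (r, c) samples input at (r - dr, c - dc)
  r <- seq_len(nr) - shift[1]
  c_ <- seq_len(nc) - shift[2]
  r0 <- floor(r); c0 <- floor(c_)
  fr <- r - r0; fc <- c_ - c0
  idx <- function(ri, ci) {
    # ri, ci are integer vectors (length nr / nc); returns matrix of values
    ok_r <- ri >= 1 & ri <= nr
    ok_c <- ci >= 1 & ci <= nc
    ri[!ok_r] <- 1L; ci[!ok_c] <- 1L
    v <- image[ri, ci, drop = FALSE]
    v[!ok_r, ] <- fill
    v[, !ok_c] <- fill
    v
  }
  w00 <- (1 - fr) %o% (1 - fc)
  w01 <- (1 - fr) %o% fc
  w10 <- fr %o% (1 - fc)
  w11 <- fr %o% fc
  w00 * idx(r0, c0) + w01 * idx(r0, c0 + 1) +
    w10 * idx(r0 + 1, c0) + w11 * idx(r0 + 1, c0 + 1)
}

#' Register all rounds of an experiment to a reference round
#'
#' Estimates each round's drift on the nuclear and actin fiducial channels
#' separately, combines the two estimates by quality-weighted averaging
#' (default weights 0.5/0.5), applies the single combined inverse shift to
#' every channel of the round, and flags rounds whose combined fiducial
#' correlation falls below `quality_floor`.
#'
#' @param stacks list of [round_stack()] objects
#' @param reference_round round id used as the fixed frame (default: first)
#' @param fiducial_weights named weights for the fiducial channels
#' @param quality_floor rounds with combined quality below this are flagged
#' @param upsample see [estimate_shift()]
#' @return list with `stacks` (aligned) and `result`, a data.frame
#'   (`round_id`, `d_row`, `d_col`, `quality`, `flagged`) with attribute
#'   `reference_round`
#' @export
register_experiment <- function(stacks, reference_round = NULL,
                                fiducial_weights = c(nuclear = 0.5, actin = 0.5),
                                quality_floor = 0.5, upsample = 20L) {
  stopifnot(length(stacks) >= 1)
  ids <- vapply(stacks, function(s) s$round_id, integer(1))
  reference_round <- reference_round %||% ids[1]
  iref <- match(reference_round, ids)
  if (is.na(iref)) stop2("reference round %d not present", reference_round)
  fids <- names(fiducial_weights)
  for (s in stacks) {
    miss <- setdiff(fids, names(s$channels))
    if (length(miss))
      stop2("round %d is missing fiducial channel(s): %s", s$round_id,
            paste(miss, collapse = ", "))
  }
  ref <- stacks[[iref]]
  res <- data.frame(round_id = ids, d_row = 0, d_col = 0, quality = 1,
                    flagged = FALSE)
  aligned <- stacks
  for (i in seq_along(stacks)) {
    if (i == iref) next
    est <- lapply(fids, function(f)
      estimate_shift(ref$channels[[f]], stacks[[i]]$channels[[f]], upsample))
    q <- vapply(est, function(e) e$quality, numeric(1))
    w <- fiducial_weights * pmax(ifelse(is.na(q), 0, q), 0)
    if (sum(w) <= 0) w <- fiducial_weights  # degenerate: fall back to priors
    w <- w / sum(w)
    sh <- Reduce(`+`, Map(function(e, wi) wi * e$shift, est, as.list(w)))
    qc <- sum(w * ifelse(is.na(q), 0, q))
    res$d_row[i] <- sh[1]; res$d_col[i] <- sh[2]
    res$quality[i] <- qc
    res$flagged[i] <- qc < quality_floor
    aligned[[i]]$channels <- lapply(stacks[[i]]$channels, apply_shift,
                                    shift = -sh)
  }
  attr(res, "reference_round") <- reference_round
  list(stacks = aligned, result = res)
}

#' Write a registration report as CSV
#' @param result the `result` data.frame from [register_experiment()]
#' @param path output CSV path
#' @export
write_registration_report <- function(result, path) {
  write.csv(result, path, row.names = FALSE)
  invisible(path)
}
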