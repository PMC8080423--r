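# Image pre-processing pipeline: zero-pad to square (so resizing cannot
# distort cell shape), resize to the 224x224 network input, standardise
# with the ImageNet channel statistics, and label-preserving augmentation.

imagenet_mean <- c(0.485, 0.456, 0.406)
imagenet_sd <- c(0.229, 0.224, 0.225)

as_3channel <- function(img) {
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  img
}

#' Zero-pad an image to a square
#'
#' Pads the shorter dimension with zeros, centring the original content,
#' so that a later resize preserves the aspect ratio of the cell.
#'
#' @param img Numeric matrix (`h x w`) or array (`h x w x c`).
#' @return Array/matrix with both spatial sides equal to `max(h, w)`.
#' @examples
#' dim(zero_pad_to_square(matrix(1, 100, 60)))  # 100 100
#' @export
zero_pad_to_square <- function(img) {
  d <- dim(img)
  h <- d[1L]; w <- d[2L]
  if (h == w) return(img)
  side <- max(h, w)
  nch <- if (length(d) == 3L) d[3L] else 1L
  out <- array(0, c(side, side, nch))
  r0 <- floor((side - h) / 2)
  c0 <- floor((side - w) / 2)
  src <- if (length(d) == 3L) img else array(img, c(h, w, 1L))
  out[r0 + seq_len(h), c0 + seq_len(w), ] <- src
  if (length(d) == 2L) out[, , 1L] else out
}

#' Resize to the network input size and normalise
#'
#' Bilinearly resizes to `size x size` (no resampling if already that
#' size) and standardises each channel with the ImageNet means and
#' standard deviations, the convention used when fine-tuning
#' ImageNet-pretrained backbones.  Grayscale input is replicated to three
#' channels first.
#'
#' @param img Numeric matrix or `h x w x 3` array with values in `[0, 1]`.
#' @param size Output side in pixels.
#' @return `size x size x 3` array of standardised values.
#' @export
resize_and_normalize <- function(img, size = 224L) {
  img <- as_3channel(img)
  if (!all(dim(img)[1:2] == size))
    img <- EBImage::imageData(EBImage::resize(img, w = size, h = size))
  for (ch in 1:3)
    img[, , ch] <- (img[, , ch] - imagenet_mean[ch]) / imagenet_sd[ch]
  img
}

#' Random label-preserving augmentation
#'
#' Applies, in order: zoom (resize then centre crop/pad), rotation about
#' the image centre, horizontal/vertical flips, translation, and
#' saturation jitter (interpolation between the image and its per-pixel
#' gray value).  All draws come from `seed`, so the same seed reproduces
#' the same augmented image bit for bit, and neutral parameter ranges
#' (`shift_frac = 0`, `zoom_range = c(1, 1)`, `rotation_deg = 0`,
#' `flip = FALSE`, `saturation_range = c(1, 1)`) return the input
#' unchanged.  Output size always equals input size; padding introduced
#' by the geometric transforms is zero-valued.
#'
#' @param img `h x w x 3` array with values in `[0, 1]`.
#' @param seed Integer seed for the transform draws.
#' @param shift_frac Maximum shift as a fraction of each dimension.
#' @param zoom_range Zoom factor range.
#' @param rotation_deg Maximum absolute rotation in degrees.
#' @param flip Allow horizontal and vertical flips (each with
#'   probability 1/2).
#' @param saturation_range Saturation factor range (1 = unchanged).
#' @return Augmented array of the same dimensions.
#' @export
augment <- function(img, seed, shift_frac = 0.1, zoom_range = c(0.9, 1.1),
                    rotation_deg = 15, flip = TRUE,
                    saturation_range = c(0.8, 1.2)) {
  img <- as_3channel(img)
  d <- dim(img)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  zoom <- stats::runif(1, zoom_range[1L], zoom_range[2L])
  angle <- stats::runif(1, -rotation_deg, rotation_deg)
  dh <- round(stats::runif(1, -shift_frac, shift_frac) * d[1L])
  dw <- round(stats::runif(1, -shift_frac, shift_frac) * d[2L])
  hflip <- flip && stats::runif(1) < 0.5
  vflip <- flip && stats::runif(1) < 0.5
  sat <- stats::runif(1, saturation_range[1L], saturation_range[2L])

  if (zoom != 1) {
    zh <- max(1L, round(d[1L] * zoom))
    zw <- max(1L, round(d[2L] * zoom))
    img <- EBImage::imageData(EBImage::resize(img, w = zh, h = zw))
    img <- crop_or_pad(img, d[1L], d[2L])
  }
  if (angle != 0)
    img <- EBImage::imageData(EBImage::rotate(img, angle,
                                              output.dim = d[1:2],
                                              bg.col = 0))
  if (hflip) img <- img[, rev(seq_len(d[2L])), , drop = FALSE]
  if (vflip) img <- img[rev(seq_len(d[1L])), , , drop = FALSE]
  if (dh != 0 || dw != 0)
    img <- EBImage::imageData(EBImage::translate(img, c(dh, dw), bg.col = 0))
  if (sat != 1) {
    gray <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
    for (ch in 1:3)
      img[, , ch] <- pmin(pmax(gray + sat * (img[, , ch] - gray), 0), 1)
  }
  img
}

# Centre crop (larger input) or zero-pad (smaller input) to h x w.
crop_or_pad <- function(img, h, w) {
  d <- dim(img)
  out <- array(0, c(h, w, d[3L]))
  ch <- min(h, d[1L]); cw <- min(w, d[2L])
  sr <- floor((d[1L] - ch) / 2); sc <- floor((d[2L] - cw) / 2)
  dr <- floor((h - ch) / 2); dc <- floor((w - cw) / 2)
  out[dr + seq_len(ch), dc + seq_len(cw), ] <-
    img[sr + seq_len(ch), sc + seq_len(cw), , drop = FALSE]
  out
}
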