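#' Specification of toy stained-cell images
#'
#' Describes a deliberately simple renderer of single-cell cytology-like
#' images: an elliptical cytoplasm, a circular nucleus whose radius grows
#' with the abnormality grade (abnormal cells have larger nuclei than
#' healthy ones), and additive stain noise.  These images exist so the
#' image pipeline — padding, resizing, normalisation, augmentation — can
#' be exercised end to end; they are synthetic and make no attempt at
#' photo-realism.
#'
#' @param K Number of grades.
#' @param image_size Square image side in pixels.
#' @param nucleus_radius_by_class Monotone non-decreasing length-`K`
#'   vector of nucleus radii in pixels; the default spans small to large
#'   within the cytoplasm.
#' @param cytoplasm_radius Major semi-axis of the cytoplasm ellipse in
#'   pixels (the minor semi-axis is 75% of it); every nucleus must fit
#'   inside the minor semi-axis.
#' @param stain_noise_sd Standard deviation of the additive Gaussian
#'   stain noise (0 gives deterministic shading).
#' @param seed Integer seed; rendering is fully reproducible.
#' @return An object of class `"toy_cell_spec"`.
#' @export
toy_cell_spec <- function(K = 7L, image_size = 64L,
                          nucleus_radius_by_class = NULL,
                          cytoplasm_radius = round(0.38 * image_size),
                          stain_noise_sd = 0.02, seed = 1L) {
  stopifnot(K >= 2, image_size >= 16, cytoplasm_radius > 2,
            stain_noise_sd >= 0)
  minor <- 0.75 * cytoplasm_radius
  if (is.null(nucleus_radius_by_class))
    nucleus_radius_by_class <- seq(0.15 * minor, 0.8 * minor, length.out = K)
  stopifnot(length(nucleus_radius_by_class) == K,
            !is.unsorted(nucleus_radius_by_class))
  if (max(nucleus_radius_by_class) >= minor)
    stop("nucleus radius must stay inside the cytoplasm", call. = FALSE)
  structure(list(K = as.integer(K), image_size = as.integer(image_size),
                 nucleus_radius_by_class = nucleus_radius_by_class,
                 cytoplasm_radius = cytoplasm_radius,
                 stain_noise_sd = stain_noise_sd, seed = as.integer(seed)),
            class = "toy_cell_spec")
}

#' Render toy cell images with grade-dependent nuclear size
#'
#' For each requested label draws one image (array `size x size x 3`,
#' values in `[0, 1]`) and its ground-truth mask (`0` background, `1`
#' cytoplasm, `2` nucleus).  The cytoplasm ellipse gets a random
#' orientation per image, the nucleus radius is fixed by the grade, and
#' stain noise is added to all channels, so the nucleus/cytoplasm area
#' ratio is non-decreasing in grade in expectation.
#'
#' @param spec A [toy_cell_spec()].
#' @param labels Integer vector of grades in `1..K`.
#' @return A list with elements `images` (list of arrays), `masks` (list
#'   of integer matrices) and `labels`.
#' @export
render_toy_cells <- function(spec, labels) {
  stopifnot(inherits(spec, "toy_cell_spec"))
  labels <- as.integer(labels)
  stopifnot(all(labels >= 1L & labels <= spec$K))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  s <- spec$image_size
  ctr <- (s + 1) / 2
  gx <- matrix(seq_len(s), s, s)          # row coordinate
  gy <- t(gx)                              # column coordinate
  bg  <- c(0.93, 0.93, 0.95)               # slide background
  cyt <- c(0.93, 0.62, 0.78)               # eosin-pink cytoplasm
  nuc <- c(0.38, 0.18, 0.50)               # haematoxylin-purple nucleus
  a <- spec$cytoplasm_radius
  b <- 0.75 * a
  images <- vector("list", length(labels))
  masks <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    th <- stats::runif(1, 0, pi)
    dx <- gx - ctr; dy <- gy - ctr
    rx <- cos(th) * dx + sin(th) * dy
    ry <- -sin(th) * dx + cos(th) * dy
    in_cyto <- (rx / a)^2 + (ry / b)^2 <= 1
    r_nuc <- spec$nucleus_radius_by_class[labels[i]]
    in_nuc <- dx^2 + dy^2 <= r_nuc^2
    mask <- matrix(0L, s, s)
    mask[in_cyto] <- 1L
    mask[in_nuc] <- 2L
    img <- array(0, c(s, s, 3))
    for (ch in 1:3) {
      plane <- matrix(bg[ch], s, s)
      plane[in_cyto] <- cyt[ch]
      plane[in_nuc] <- nuc[ch]
      if (spec$stain_noise_sd > 0)
        plane <- plane + matrix(stats::rnorm(s * s, sd = spec$stain_noise_sd),
                                s, s)
      img[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    images[[i]] <- img
    masks[[i]] <- mask
  }
  list(images = images, masks = masks, labels = labels)
}

#' Write a rendered image set to disk
#'
#' Writes each image (and mask, if present) as PNG, a `labels.csv`
#' manifest with columns `path,label`, and a `provenance.json` recording
#' the generator settings and seed.
#'
#' @param rendered Output of [render_toy_cells()].
#' @param dir Output directory (created if missing).
#' @param spec The [toy_cell_spec()] used, recorded in the provenance.
#' @return The manifest data frame, invisibly.
#' @export
write_image_dataset <- function(rendered, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(rendered$images)
  paths <- sprintf("cell_%03d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(rendered$images[[i]], file.path(dir, paths[i]))
    if (!is.null(rendered$masks))
      png::writePNG(rendered$masks[[i]] / 2, # 3 levels in [0,1]
                    file.path(dir, sub("\\.png$", "_mask.png", paths[i])))
  }
  manifest <- data.frame(path = paths, label = rendered$labels)
  utils::write.csv(manifest, file.path(dir, "labels.csv"), row.names = FALSE)
  prov <- c(sprintf('"n_images": %d', n),
            if (!is.null(spec))
              sprintf('"seed": %d, "image_size": %d, "K": %d',
                      spec$seed, spec$image_size, spec$K))
  writeLines(paste0("{", paste(prov, collapse = ", "), "}"),
             file.path(dir, "provenance.json"))
  invisible(manifest)
}

#' Read an image directory with a CSV label manifest
#'
#' Loads the `path,label` manifest written by [write_image_dataset()] (or
#' any directory following that layout) and the PNG images it points to.
#'
#' @param dir Directory containing `labels.csv` and the images.
#' @return A list with `images` (list of arrays) and `labels` (integer).
#' @export
read_image_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "labels.csv"),
                              stringsAsFactors = FALSE)
  stopifnot(all(c("path", "label") %in% names(manifest)))
  images <- lapply(file.path(dir, manifest$path), png::readPNG)
  list(images = images, labels = as.integer(manifest$label))
}
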