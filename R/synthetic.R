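#' Specification of a synthetic ordinal feature dataset
#'
#' Describes class-conditional Gaussian features whose means sit on a line
#' through feature space, ordered by class — a latent severity axis with
#' overlapping neighbours, the structure that makes a problem ordinal
#' rather than nominal.  `class_separation` is the distance between
#' adjacent class means in units of the within-class spread, so values
#' near 1 give heavy adjacent-class overlap and values above ~4 are close
#' to separable.
#'
#' @param K Number of ordered classes.
#' @param n_per_class Either a single count (balanced), a length-`K`
#'   vector of counts, or the string `"herlev"` combined with `n_total`
#'   to match the 8/7/11/19/16/22/17% class imbalance of the Herlev
#'   cervical-cytology dataset.
#' @param feature_dim Number of features.
#' @param class_separation Positive distance between adjacent class means
#'   in within-class standard-deviation units (0 allowed: labels carry no
#'   signal).
#' @param noise_sd Within-class standard deviation.
#' @param n_total Total size when `n_per_class = "herlev"`.
#' @param seed Integer seed; the sampler is fully reproducible.
#' @return An object of class `"ordinal_dataset_spec"`.
#' @export
ordinal_dataset_spec <- function(K = 7L, n_per_class = 50L,
                                 feature_dim = 4L, class_separation = 1,
                                 noise_sd = 1, n_total = NULL, seed = 1L) {
  stopifnot(K >= 2, K == round(K), feature_dim >= 1,
            class_separation >= 0, noise_sd > 0)
  if (identical(n_per_class, "herlev")) {
    if (is.null(n_total)) stop("n_total is required with the herlev profile")
    n_per_class <- round(herlev_class_proportions() * n_total)
  } else if (length(n_per_class) == 1L) {
    n_per_class <- rep(as.integer(n_per_class), K)
  }
  n_per_class <- as.integer(n_per_class)
  stopifnot(length(n_per_class) == K, all(n_per_class >= 1L))
  structure(list(K = as.integer(K), n_per_class = n_per_class,
                 feature_dim = as.integer(feature_dim),
                 class_separation = class_separation,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ordinal_dataset_spec")
}

#' Sample ordinal features along a latent severity axis
#'
#' Draws the dataset described by an [ordinal_dataset_spec()]: class `k`
#' has mean `(k - 1) * class_separation * noise_sd` along a fixed unit
#' direction (equal loading on every feature) plus isotropic Gaussian
#' noise.  Adjacent-class Bayes overlap shrinks as `class_separation`
#' grows; with separation 0 all classes share one distribution.
#'
#' @param spec An [ordinal_dataset_spec()].
#' @return A data frame with integer column `grade` (1..K) and features
#'   `x1..xd`; the spec is attached as attribute `"spec"`.
#' @export
sample_ordinal_features <- function(spec) {
  stopifnot(inherits(spec, "ordinal_dataset_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  d <- spec$feature_dim
  u <- rep(1 / sqrt(d), d)
  y <- rep(seq_len(spec$K), times = spec$n_per_class)
  n <- length(y)
  mu <- outer((y - 1) * spec$class_separation * spec$noise_sd, u)
  X <- mu + matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
  out <- data.frame(grade = y, X)
  names(out) <- c("grade", paste0("x", seq_len(d)))
  attr(out, "spec") <- spec
  out
}

#' Per-class counts of the Herlev cervical-cytology dataset
#'
#' Reads the shipped fixture with the seven WHO-system Pap smear classes
#' (three normal, four abnormal grades) and their published cell counts;
#' `herlev_class_proportions()` returns the counts normalised to
#' proportions (about 8/7/11/19/16/22/17%).
#'
#' @return `herlev_class_counts()`: a data frame with columns
#'   `who_class`, `tbs_class`, `group`, `cell_type`, `count`;
#'   `herlev_class_proportions()`: a numeric length-7 vector summing to 1.
#' @export
herlev_class_counts <- function() {
  path <- system.file("extdata", "herlev_class_counts.csv",
                      package = "ordinalco", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname herlev_class_counts
#' @export
herlev_class_proportions <- function() {
  counts <- herlev_class_counts()$count
  counts / sum(counts)
}
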