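# Intensity normalization and dataset splitting.

#' CT display window
#'
#' A value-of-interest window on the Hounsfield scale.  The soft-tissue
#' window used throughout this package is center 0 HU, width 200 HU, which
#' places orbital fat, muscle, nerve and vitreous on a well-spread [0, 1]
#' scale while saturating bone and air.
#'
#' @param center Window center in HU (default 0).
#' @param width Window width in HU (default 200; must be > 0).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(center = 0, width = 200) {
  if (!is.finite(width) || width <= 0) {
    stop("window width must be > 0", call. = FALSE)
  }
  structure(list(center = center, width = width), class = "window_spec")
}

#' Windowed intensity normalization
#'
#' Maps Hounsfield units to \[0, 1\] linearly across the window and clamps
#' outside it: `y = clip((x - (center - width/2)) / width, 0, 1)`.  This is
#' the plain center/width VOI-LUT mapping; set `ps33 = TRUE` for the DICOM
#' PS3.3 linear variant, which uses `width - 1` in the denominator and
#' `center - 0.5` in the offset (sub-1% difference at width 200).
#'
#' @param image Numeric matrix or array of HU values (finite).
#' @param window A [window_spec()].
#' @param ps33 Use the DICOM PS3.3 linear formula instead of the plain one.
#' @return Array of the same shape with values in \[0, 1\].
#' @examples
#' apply_window(matrix(c(-1024, 0, 50, 3071), 2), window_spec())
#' @export
apply_window <- function(image, window = window_spec(), ps33 = FALSE) {
  stopifnot(inherits(window, "window_spec"))
  if (!all(is.finite(image))) stop("image must be finite", call. = FALSE)
  if (ps33) {
    lo <- window$center - 0.5 - (window$width - 1) / 2
    y <- (image - lo) / (window$width - 1)
  } else {
    y <- (image - (window$center - window$width / 2)) / window$width
  }
  y[y < 0] <- 0
  y[y > 1] <- 1
  y
}

#' Repeated-split specification
#'
#' Train/validation/test ratios with a base seed and a repetition count for
#' the repeated random-split evaluation protocol (default 0.70/0.15/0.15,
#' ten repetitions).
#'
#' @param ratios Length-3 positive fractions summing to 1.
#' @param seed Integer base seed.
#' @param repetitions Number of independent splits (>= 1).
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(train = 0.7, val = 0.15, test = 0.15),
                       seed = 1L, repetitions = 10L) {
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be 3 positive fractions summing to 1", call. = FALSE)
  }
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  structure(list(ratios = ratios, seed = as.integer(seed),
                 repetitions = as.integer(repetitions)),
            class = "split_spec")
}

#' Split ids into train / validation / test sets
#'
#' Shuffles the ids with seed `spec$seed + repetition` and cuts the
#' permutation into `floor(r_train * n)` training ids, `floor(r_val * n)`
#' validation ids, and the remainder as test ids, so the three sets always
#' partition the input.  With the default ratios, 701 ids split as
#' 490 / 105 / 106.  Each repetition index gives a distinct, reproducible
#' split.
#'
#' @param ids Character or integer vector of unique ids.
#' @param spec A [split_spec()].
#' @param repetition 0-based repetition index in `[0, repetitions)`.
#' @return List with elements `train`, `val`, `test`.
#' @export
split_ids <- function(ids, spec = split_spec(), repetition = 0L) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(ids)
  if (n == 0L) stop("ids must be non-empty", call. = FALSE)
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  if (repetition < 0 || repetition >= spec$repetitions) {
    stop("repetition out of range", call. = FALSE)
  }
  perm <- with_seed(spec$seed + as.integer(repetition), sample.int(n))
  n_train <- floor(spec$ratios[[1]] * n)
  n_val <- floor(spec$ratios[[2]] * n)
  list(train = ids[perm[seq_len(n_train)]],
       val = ids[perm[n_train + seq_len(n_val)]],
       test = ids[perm[(n_train + n_val + 1):n]])
}
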