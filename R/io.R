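# On-disk formats.
#
# CT images: 16-bit unsigned grayscale TIFF storing HU + 1024, so the CT
# range [-1024, 3071] maps to [0, 4095] and round-trips losslessly.
# Masks: 8-bit grayscale PNG with values {0, 255}.

HU_OFFSET <- 1024L

#' Write / read a CT slice as 16-bit TIFF
#'
#' Images are stored as 16-bit unsigned grayscale with the documented offset
#' `stored = HU + 1024`; reading reverses the offset, so integer Hounsfield
#' units round-trip exactly.
#'
#' @param hu Integer matrix of Hounsfield units in \[-1024, 3071\].
#' @param path File path.
#' @return `read_ct_image()` returns an integer HU matrix.
#' @export
write_ct_image <- function(hu, path) {
  if (min(hu) < -1024 || max(hu) > 3071) {
    stop("HU values outside [-1024, 3071]", call. = FALSE)
  }
  tiff::writeTIFF((hu + HU_OFFSET) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_ct_image
#' @export
read_ct_image <- function(path) {
  v <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(v) <- "integer"
  v - HU_OFFSET
}

#' Write / read a binary tissue mask as 8-bit PNG
#'
#' @param mask Logical (or 0/1) matrix.
#' @param path File path.
#' @return `read_mask()` returns a logical matrix (pixel > 127 is foreground).
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  png::writePNG(m, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  v > 0.5
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.csv` written by [generate_dataset()] (or a
#'   user-supplied file with the same columns).
#' @return Manifest data frame with attribute `root` set to the manifest's
#'   directory.
#' @export
read_manifest <- function(path) {
  manifest <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "plane", "image_path", "tissue", "mask_path", "seed")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols)) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  attr(manifest, "root") <- dirname(path)
  manifest
}

#' Load manifest items into memory
#'
#' Reads the image and the mask of one tissue for each slice id listed in a
#' manifest.
#'
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @param tissue Tissue whose masks to load; must appear in the manifest.
#' @param ids Optional subset of slice ids (defaults to all).
#' @return List with `ids`, `images` (list of HU matrices) and `masks`
#'   (list of logical matrices), in the order of `ids`.
#' @export
load_dataset <- function(manifest, tissue, ids = NULL) {
  root <- attr(manifest, "root")
  if (is.null(root)) root <- "."
  rows <- manifest[manifest$tissue == tissue, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("tissue not present in manifest: ", tissue, call. = FALSE)
  }
  if (is.null(ids)) ids <- rows$id
  rows <- rows[match(ids, rows$id), , drop = FALSE]
  if (anyNA(rows$id)) stop("unknown ids requested", call. = FALSE)
  list(
    ids = ids,
    images = lapply(file.path(root, rows$image_path), read_ct_image),
    masks = lapply(file.path(root, rows$mask_path), read_mask)
  )
}

#' Write a qualitative overlay PNG
#'
#' Renders the windowed CT image in grayscale, paints predicted foreground
#' white, and draws the ground-truth boundary in red, giving a quick visual
#' check of segmentation quality.
#'
#' @param hu HU matrix.
#' @param truth Logical ground-truth mask.
#' @param pred Logical / 0-1 predicted mask.
#' @param path Output PNG path.
#' @param window [window_spec()] for display normalization.
#' @return The path, invisibly.
#' @export
write_overlay <- function(hu, truth, pred, path, window = window_spec()) {
  g <- apply_window(hu, window)
  rgb <- array(g, c(nrow(g), ncol(g), 3))
  pred <- pred != 0
  rgb[, , 1][pred] <- 1; rgb[, , 2][pred] <- 1; rgb[, , 3][pred] <- 1
  # boundary: truth pixels with at least one non-truth 4-neighbour
  t <- truth != 0
  inner <- t
  inner[-1, ] <- inner[-1, ] & t[-nrow(t), ]
  inner[-nrow(t), ] <- inner[-nrow(t), ] & t[-1, ]
  inner[, -1] <- inner[, -1] & t[, -ncol(t)]
  inner[, -ncol(t)] <- inner[, -ncol(t)] & t[, -1]
  edge <- t & !inner
  rgb[, , 1][edge] <- 1; rgb[, , 2][edge] <- 0; rgb[, , 3][edge] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}
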