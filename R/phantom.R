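# Synthetic orbital CT phantom generator.
#
# The phantom emulates the structure of the three clinical slice types used
# for Graves' orbitopathy assessment: an axial slice through the largest
# eyeball section ("axial1"), an axial slice through the lacrimal glands
# ("axial2"), and a coronal slice behind the globe ("coronal").  Geometry is
# deliberately simple (discs, tapered bands, crescents, rings); what matters
# is that each plane carries the same tissue inventory as the clinical
# protocol, that intensities are plausible Hounsfield units, and that every
# slice comes with exact ground-truth masks.

PLANE_TISSUES <- list(
  axial1  = c("eyeball", "optic_nerve", "MRM", "LRM"),
  axial2  = c("lacrimal_gland"),
  coronal = c("optic_nerve", "MRM", "LRM", "SRM", "IRM")
)

#' Phantom specification
#'
#' Parameters of the synthetic orbital CT slice generator: image size,
#' per-tissue Hounsfield-unit means (and optional within-tissue texture SDs),
#' global additive noise, geometry ranges, and a muscle enlargement factor
#' emulating the extraocular-muscle swelling characteristic of Graves'
#' orbitopathy.
#'
#' @param image_size Side length in pixels; must be at least 64 and divisible
#'   by 32 so that five exact 2x halvings are possible.  512 matches clinical
#'   CT; tests use smaller sizes.
#' @param hu_mean Named numeric vector of mean HU per rendered tissue.
#'   Defaults: orbital fat -80, eyeball interior (vitreous) +5, sclera ring
#'   +60, extraocular muscle +50, optic nerve +35, lacrimal gland +40,
#'   bone +1000.
#' @param hu_sd Named numeric vector of within-tissue texture SD in HU
#'   (default 0 for every tissue: tissues render flat and only `noise_sd`
#'   adds noise).
#' @param noise_sd Global additive Gaussian noise SD in HU (default 10).
#' @param geometry List of geometry ranges as fractions of `image_size`:
#'   `eye_radius`, `nerve_width`, `muscle_thickness`, `lacrimal_size`; each a
#'   length-2 range sampled uniformly per slice.
#' @param enlargement_factor Multiplier (>= 1) on muscle band thickness.
#' @param pixel_size_mm Isotropic pixel spacing recorded on each slice.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(image_size = 128)
#' sl <- render_slice(spec, "axial1", seed = 1)
#' range(sl$image$hu)
#' @export
phantom_spec <- function(image_size = 512,
                         hu_mean = c(fat = -80, eyeball = 5, sclera = 60,
                                     muscle = 50, optic_nerve = 35,
                                     lacrimal_gland = 40, bone = 1000),
                         hu_sd = NULL,
                         noise_sd = 10,
                         geometry = list(eye_radius = c(0.10, 0.125),
                                         nerve_width = c(0.016, 0.024),
                                         muscle_thickness = c(0.022, 0.030),
                                         lacrimal_size = c(0.05, 0.07)),
                         enlargement_factor = 1,
                         pixel_size_mm = 0.4) {
  if (image_size < 64 || image_size %% 32 != 0) {
    stop("image_size must be >= 64 and divisible by 32", call. = FALSE)
  }
  defaults <- c(fat = -80, eyeball = 5, sclera = 60, muscle = 50,
                optic_nerve = 35, lacrimal_gland = 40, bone = 1000)
  hu <- defaults
  hu[names(hu_mean)] <- hu_mean
  sds <- setNames(numeric(length(hu)), names(hu))
  if (!is.null(hu_sd)) sds[names(hu_sd)] <- hu_sd
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (enlargement_factor < 1) {
    stop("enlargement_factor must be >= 1", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size), hu_mean = hu,
                 hu_sd = sds, noise_sd = noise_sd, geometry = geometry,
                 enlargement_factor = enlargement_factor,
                 pixel_size_mm = pixel_size_mm),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Orbital CT phantom spec\n")
  cat(sprintf("  image size: %d x %d px (%.2f mm/px)\n", x$image_size,
              x$image_size, x$pixel_size_mm))
  cat(sprintf("  noise SD: %g HU; muscle enlargement: %.2fx\n",
              x$noise_sd, x$enlargement_factor))
  cat("  tissue HU means:",
      paste(sprintf("%s=%g", names(x$hu_mean), x$hu_mean), collapse = ", "),
      "\n")
  invisible(x)
}

# geometric primitives on a normalized [0,1] x [0,1] grid ---------------------

phantom_grid <- function(size) {
  v <- (seq_len(size) - 0.5) / size
  list(X = matrix(v, size, size), Y = matrix(v, size, size, byrow = TRUE))
}

disc <- function(g, cx, cy, r) (g$X - cx)^2 + (g$Y - cy)^2 <= r^2

annulus <- function(g, cx, cy, r0, r1) {
  d2 <- (g$X - cx)^2 + (g$Y - cy)^2
  d2 > r0^2 & d2 <= r1^2
}

ellipse <- function(g, cx, cy, rx, ry, theta = 0) {
  dx <- g$X - cx; dy <- g$Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

# vertical band of half-width w/2 around x = cx, tapering linearly from full
# width at y0 to `taper` x width at y1
vband <- function(g, cx, y0, y1, w, taper = 0.6) {
  frac <- pmin(pmax((g$Y - y0) / max(y1 - y0, 1e-9), 0), 1)
  half <- w / 2 * (1 - (1 - taper) * frac)
  abs(g$X - cx) <= half & g$Y >= y0 & g$Y <= y1
}

#' Render one synthetic orbital CT slice with ground-truth masks
#'
#' Draws the tissue inventory of the requested plane into an integer
#' Hounsfield-unit image and returns pairwise-disjoint binary masks for the
#' segmentation targets of that plane:
#' \describe{
#'   \item{axial1}{eyeball, optic nerve, medial and lateral rectus muscles,
#'     for both orbits; sclera and bone are rendered but not masked.}
#'   \item{axial2}{lacrimal gland (supero-temporal crescent at each globe);
#'     eyeballs are rendered for context but not masked.}
#'   \item{coronal}{optic nerve (central disc) and the four rectus muscles
#'     (MRM, LRM, SRM, IRM) at compass positions inside a bone ring.}
#' }
#' Pixel values are clipped to the CT range \[-1024, 3071\].  The same
#' `(spec, plane, seed)` always renders bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param plane One of `"axial1"`, `"axial2"`, `"coronal"`.
#' @param seed Integer seed for this slice.
#' @return A list with `image` (class `ct_slice`: integer HU matrix `hu`,
#'   `plane`, `pixel_size_mm`) and `masks` (class `tissue_mask_set`: named
#'   list of logical matrices).
#' @export
render_slice <- function(spec, plane = c("axial1", "axial2", "coronal"),
                         seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(plane) != 1L || !plane %in% names(PLANE_TISSUES)) {
    stop("unknown plane tag: ", paste(plane, collapse = ", "),
         " (expected axial1, axial2 or coronal)", call. = FALSE)
  }
  with_seed(seed, render_slice_impl(spec, plane))
}

render_slice_impl <- function(spec, plane) {
  size <- spec$image_size
  g <- phantom_grid(size)
  hu <- spec$hu_mean
  img <- matrix(hu[["fat"]], size, size)
  masks <- list()
  paint <- function(region, value) {
    img[region] <<- value
    invisible(NULL)
  }
  claimed <- matrix(FALSE, size, size)
  add_mask <- function(name, region, value) {
    region <- region & !claimed
    claimed <<- claimed | region
    img[region] <<- value
    masks[[name]] <<- if (is.null(masks[[name]])) region
                      else masks[[name]] | region
    invisible(NULL)
  }
  geo <- spec$geometry
  r_eye <- runif(1, geo$eye_radius[1], geo$eye_radius[2])
  w_nerve <- runif(1, geo$nerve_width[1], geo$nerve_width[2])
  t_mus <- runif(1, geo$muscle_thickness[1], geo$muscle_thickness[2]) *
    spec$enlargement_factor
  lac <- runif(1, geo$lacrimal_size[1], geo$lacrimal_size[2])
  jit <- runif(4, -0.01, 0.01)

  if (plane %in% c("axial1", "axial2")) {
    # skull: posterior arc + nasal septum between the orbits
    paint(annulus(g, 0.5, 0.55, 0.43, 0.48) & g$Y > 0.45, hu[["bone"]])
    paint(abs(g$X - 0.5) < 0.02 & g$Y > 0.30 & g$Y < 0.60, hu[["bone"]])
    for (side in c(-1, 1)) {
      cx <- 0.5 + side * 0.22 + jit[1] * side
      cy <- 0.32 + jit[2]
      eye <- disc(g, cx, cy, r_eye)
      ring <- annulus(g, cx, cy, r_eye, r_eye + 0.012)
      if (plane == "axial1") {
        # muscles first so an enlarged band is never clipped by the nerve
        nerve_x <- cx
        y0 <- cy + r_eye + 0.015; y1 <- min(cy + r_eye + 0.30, 0.95)
        add_mask("MRM", vband(g, nerve_x - side * (w_nerve / 2 + 0.035 +
                                                   t_mus / 2),
                              y0 - 0.02, y1, t_mus), hu[["muscle"]])
        add_mask("LRM", vband(g, nerve_x + side * (w_nerve / 2 + 0.035 +
                                                   t_mus / 2),
                              y0 - 0.02, y1, t_mus), hu[["muscle"]])
        add_mask("optic_nerve", vband(g, nerve_x, y0, y1, w_nerve),
                 hu[["optic_nerve"]])
        add_mask("eyeball", eye, hu[["eyeball"]])
        paint(ring & !claimed, hu[["sclera"]])
      } else {
        # supero-temporal crescent hugging the globe
        ang <- side * 0.75 * pi / 2
        ccx <- cx + side * (r_eye + lac / 3) * 0.9
        ccy <- cy - (r_eye + lac / 3) * 0.4
        crescent <- disc(g, ccx, ccy, lac) & !disc(g, cx, cy, r_eye + 0.008)
        add_mask("lacrimal_gland", crescent, hu[["lacrimal_gland"]])
        paint(eye & !claimed, hu[["eyeball"]])
        paint(ring & !claimed, hu[["sclera"]])
        invisible(ang)
      }
    }
  } else {  # coronal: orbit cross-section behind the globe
    cx <- 0.5 + jit[1]; cy <- 0.5 + jit[2]
    paint(annulus(g, cx, cy, 0.33, 0.40), hu[["bone"]])
    r_orbit <- 0.22
    mus_len <- 0.10
    add_mask("MRM", ellipse(g, cx - r_orbit, cy, t_mus / 2 * 2.2, mus_len,
                            pi / 2), hu[["muscle"]])
    add_mask("LRM", ellipse(g, cx + r_orbit, cy, t_mus / 2 * 2.2, mus_len,
                            pi / 2), hu[["muscle"]])
    add_mask("SRM", ellipse(g, cx, cy - r_orbit, t_mus / 2 * 2.2, mus_len,
                            0), hu[["muscle"]])
    add_mask("IRM", ellipse(g, cx, cy + r_orbit, t_mus / 2 * 2.2, mus_len,
                            0), hu[["muscle"]])
    add_mask("optic_nerve", disc(g, cx, cy, w_nerve * 1.6),
             hu[["optic_nerve"]])
  }

  # within-tissue texture, then global noise, then integer HU + CT clipping
  for (nm in names(masks)) {
    tissue <- sub("^(MRM|LRM|SRM|IRM)$", "muscle", nm)
    s <- spec$hu_sd[[tissue]]
    if (!is.null(s) && s > 0) {
      n_px <- sum(masks[[nm]])
      img[masks[[nm]]] <- img[masks[[nm]]] + rnorm(n_px, 0, s)
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(size * size, 0, spec$noise_sd), size, size)
  }
  img <- pmin(pmax(round(img), -1024), 3071)
  storage.mode(img) <- "integer"

  masks <- masks[intersect(PLANE_TISSUES[[plane]], names(masks))]
  image <- structure(list(hu = img, plane = plane,
                          pixel_size_mm = spec$pixel_size_mm),
                     class = "ct_slice")
  masks <- structure(masks, plane = plane, class = "tissue_mask_set")
  list(image = image, masks = masks)
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("CT slice (%s): %d x %d px, HU range [%d, %d]\n", x$plane,
              nrow(x$hu), ncol(x$hu), min(x$hu), max(x$hu)))
  invisible(x)
}

#' @export
print.tissue_mask_set <- function(x, ...) {
  cat(sprintf("Tissue mask set (%s):\n", attr(x, "plane")))
  for (nm in names(x)) {
    cat(sprintf("  %-15s %6d px\n", nm, sum(x[[nm]])))
  }
  invisible(x)
}

#' Simulate phantom slices from a specification
#'
#' `simulate()` on a [phantom_spec()] renders `nsim` independent slices,
#' seeded reproducibly as `seed + 1, ..., seed + nsim`.
#'
#' @param object A `phantom_spec`.
#' @param nsim Number of slices.
#' @param seed Base seed (default 1).
#' @param plane Slice plane passed to [render_slice()].
#' @param ... Unused.
#' @return List of `nsim` `render_slice()` results.
#' @export
simulate.phantom_spec <- function(object, nsim = 1, seed = 1L,
                                  plane = "axial1", ...) {
  lapply(seq_len(nsim), function(i) render_slice(object, plane, seed + i))
}

#' Generate an on-disk phantom dataset
#'
#' Renders `n` slices of one plane and writes them in the package's standard
#' layout: a 16-bit grayscale TIFF per image storing `HU + 1024`, one 8-bit
#' PNG per tissue mask (`<id>_<tissue>.png`, values 0/255), and a
#' `manifest.csv` with one row per (slice, tissue).  Slice `i` is rendered
#' with seed `seed + i`, so any item can be reproduced independently.
#'
#' @param n Number of slices (>= 1).
#' @param spec A [phantom_spec()].
#' @param plane Slice plane.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer base seed.
#' @return The manifest as a data frame with columns
#'   `id, plane, image_path, tissue, mask_path, seed` (paths relative to
#'   `out_dir`, which is recorded as attribute `root`).
#' @export
generate_dataset <- function(n, spec, plane = "axial1", out_dir, seed = 1L) {
  stopifnot(n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(n)) {
    item_seed <- seed + i
    sl <- render_slice(spec, plane, item_seed)
    id <- sprintf("%s_%04d", plane, i)
    image_path <- paste0(id, ".tif")
    write_ct_image(sl$image$hu, file.path(out_dir, image_path))
    for (tissue in names(sl$masks)) {
      mask_path <- paste0(id, "_", tissue, ".png")
      write_mask(sl$masks[[tissue]], file.path(out_dir, mask_path))
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, plane = plane, image_path = image_path, tissue = tissue,
        mask_path = mask_path, seed = item_seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "root") <- out_dir
  manifest
}
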