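#' Specification for a synthetic IHC core image
#'
#' Describes one synthetic CK/DAB-stained TMA core: a tissue disc on a
#' saturated white background, brown (DAB-like) tumor nests, off-white
#' stroma with a slight pink cast, and optional blue hematoxylin-like
#' nucleus speckles scattered in the stroma. Scanner background is
#' modelled as clipped white (no noise), tissue carries Gaussian sensor
#' noise.
#'
#' @param width,height Frame size in pixels (>= 64).
#' @param core_radius_frac Core disc radius as a fraction of `min(width,
#'   height)`; the disc is centred, so values < 0.5 keep it inside the
#'   frame.
#' @param n_nests Maximum number of tumor nests to place. `0` yields a
#'   pure-stroma core (only consistent with `true_stroma_frac = 1`).
#' @param nest_radius_range Numeric length-2, nest radius range in
#'   pixels.
#' @param true_stroma_frac Target stromal fraction of the core in
#'   \[0, 1\]; nests are added until the realized fraction is within
#'   `tol` of the target.
#' @param nucleus_density Nucleus speckles per 1000 core pixels.
#' @param nucleus_radius Speckle radius in pixels.
#' @param noise_sd Gaussian noise standard deviation in 8-bit intensity
#'   units, applied inside the core only.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param tol Placement tolerance on the realized stromal fraction.
#' @param color_tumor,color_stroma,color_nucleus,color_background RGB
#'   triples on the 0-255 scale.
#'
#' @return An object of class `image_spec`.
#' @seealso [generate_core_image()]
#' @export
image_spec <- function(width = 512, height = 512,
                       core_radius_frac = 0.42,
                       n_nests = 80,
                       nest_radius_range = c(20, 70),
                       true_stroma_frac = 0.6,
                       nucleus_density = 1.0,
                       nucleus_radius = 2,
                       noise_sd = 3,
                       seed = 1,
                       tol = 0.03,
                       color_tumor = c(150, 100, 55),
                       color_stroma = c(242, 235, 238),
                       color_nucleus = c(70, 70, 150),
                       color_background = c(255, 255, 255)) {
  stopifnot(width >= 64, height >= 64,
            true_stroma_frac >= 0, true_stroma_frac <= 1,
            core_radius_frac > 0, core_radius_frac < 0.5,
            n_nests >= 0, length(nest_radius_range) == 2,
            nest_radius_range[1] > 0,
            nest_radius_range[1] <= nest_radius_range[2],
            nucleus_density >= 0, nucleus_radius >= 1,
            noise_sd >= 0, tol > 0)
  structure(list(width = width, height = height,
                 core_radius_frac = core_radius_frac,
                 n_nests = n_nests,
                 nest_radius_range = nest_radius_range,
                 true_stroma_frac = true_stroma_frac,
                 nucleus_density = nucleus_density,
                 nucleus_radius = nucleus_radius,
                 noise_sd = noise_sd, seed = as.integer(seed), tol = tol,
                 color_tumor = color_tumor, color_stroma = color_stroma,
                 color_nucleus = color_nucleus,
                 color_background = color_background),
            class = "image_spec")
}

#' A single RGB core image
#'
#' Thin container for an 8-bit RGB raster. Pixels are stored as a
#' `height x width x 3` array on the \[0, 1\] scale, quantized to 8-bit
#' steps.
#'
#' @param pixels `h x w x 3` numeric array in \[0, 1\].
#' @param id Core identifier string.
#' @param pixel_size Physical pixel size in micrometres per pixel, or
#'   `NA` when unknown.
#' @return An object of class `core_image`.
#' @export
core_image <- function(pixels, id = "core", pixel_size = NA_real_) {
  if (!(is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3))
    stop("core_image: 'pixels' must be an h x w x 3 RGB array", call. = FALSE)
  if (dim(pixels)[1] < 64 || dim(pixels)[2] < 64)
    stop("core_image: image must be at least 64 x 64 pixels", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("core_image: pixel values must lie in [0, 1]", call. = FALSE)
  structure(list(pixels = pixels, id = id, pixel_size = pixel_size),
            class = "core_image")
}

#' @export
print.core_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<core_image '%s'> %d x %d px, RGB 8-bit%s\n", x$id, d[2], d[1],
              if (is.na(x$pixel_size)) "" else
                sprintf(", %.3g um/px", x$pixel_size)))
  invisible(x)
}

# Logical disc mask helpers (pixel-centre, 0-based row/col convention:
# pixel (i, j) is tested at its centre).
disc_mask <- function(h, w, cx, cy, r) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - cx)^2 + (cc - cy)^2 <= r^2
}

stamp_disc <- function(mask, i, j, r) {
  h <- nrow(mask); w <- ncol(mask)
  ii <- max(1, floor(i - r)):min(h, ceiling(i + r))
  jj <- max(1, floor(j - r)):min(w, ceiling(j + r))
  sub <- outer(ii - i, jj - j, function(a, b) a^2 + b^2 <= r^2)
  mask[ii, jj] <- mask[ii, jj] | sub
  mask
}

#' Generate a synthetic IHC core image with ground truth
#'
#' Draws a centred tissue disc, then places solid tumor nests (unions of
#' overlapping discs, hole-filled so the stromal compartment never gets
#' fully enclosed, as in the anastomosing stromal network of real
#' tissue) by rejection sampling until the realized stromal fraction is
#' within `spec$tol` of `spec$true_stroma_frac`. Nucleus speckles are
#' drawn inside the stroma but belong to the stroma in the ground truth.
#'
#' @param spec An [image_spec()].
#' @return A list of class `synthetic_core` with elements
#'   * `image`: a [core_image()];
#'   * `truth`: list with logical matrices `tumor_mask`, `stroma_mask`,
#'     `core_mask` and the scalar `true_tsr` (= stroma / core pixels).
#' @examples
#' syn <- generate_core_image(image_spec(seed = 7, true_stroma_frac = 0.6))
#' syn$truth$true_tsr
#' @export
generate_core_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  local_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    cx <- (h + 1) / 2; cy <- (w + 1) / 2
    R <- spec$core_radius_frac * min(h, w)
    core <- disc_mask(h, w, cx, cy, R)
    n_core <- sum(core)

    target_tumor <- 1 - spec$true_stroma_frac
    tumor <- matrix(FALSE, h, w)
    frac <- 0
    accepted <- 0L
    tries <- 0L
    max_tries <- 60L * max(spec$n_nests, 1L) + 200L
    while (frac < target_tumor - spec$tol &&
           accepted < spec$n_nests && tries < max_tries) {
      tries <- tries + 1L
      r <- runif(1, spec$nest_radius_range[1], spec$nest_radius_range[2])
      th <- runif(1, 0, 2 * pi)
      d <- sqrt(runif(1))
      x <- cx + d * R * cos(th)
      y <- cy + d * R * sin(th)
      cand <- stamp_disc(tumor, x, y, r)
      cand <- matrix(as.logical(EBImage::fillHull(cand)), h, w)
      f <- sum(cand & core) / n_core
      if (f <= target_tumor + spec$tol) {
        tumor <- cand
        frac <- f
        accepted <- accepted + 1L
      }
    }
    if (abs(frac - target_tumor) > spec$tol)
      stop(sprintf(paste0("generate_core_image: target stroma fraction %.2f ",
                          "unreachable with the given nest geometry ",
                          "(realized %.3f after %d tries)"),
                   spec$true_stroma_frac, 1 - frac, tries), call. = FALSE)

    tumor <- tumor & core
    stroma <- core & !tumor

    nuc <- matrix(FALSE, h, w)
    n_nuc <- round(spec$nucleus_density * n_core / 1000)
    if (n_nuc > 0 && any(stroma)) {
      idx <- sample(which(stroma), min(n_nuc, sum(stroma)))
      for (p in idx) {
        i <- (p - 1) %% h + 1
        j <- (p - 1) %/% h + 1
        nuc <- stamp_disc(nuc, i, j, spec$nucleus_radius)
      }
      nuc <- nuc & stroma
    }

    img <- array(0, c(h, w, 3))
    for (k in 1:3) {
      ch <- matrix(spec$color_background[k], h, w)
      ch[stroma] <- spec$color_stroma[k]
      ch[tumor] <- spec$color_tumor[k]
      ch[nuc] <- spec$color_nucleus[k]
      if (spec$noise_sd > 0) {
        noise <- matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
        ch[core] <- ch[core] + noise[core]
      }
      img[, , k] <- pmin(255, pmax(0, round(ch))) / 255
    }

    structure(list(
      image = core_image(img, id = sprintf("synthetic-seed%d", spec$seed)),
      truth = list(tumor_mask = tumor, stroma_mask = stroma,
                   core_mask = core,
                   true_tsr = sum(stroma) / n_core),
      spec = spec
    ), class = "synthetic_core")
  })
}

#' Write a synthetic core to disk
#'
#' Emits the RGB image as PNG (or TIFF by extension), the three ground
#' truth masks as PNG, and a JSON sidecar holding `true_tsr`, the seed
#' and the full spec.
#'
#' @param syn A `synthetic_core` from [generate_core_image()].
#' @param path Output path for the image (`.png` or `.tif`/`.tiff`);
#'   masks and sidecar are written next to it.
#' @param masks Write ground-truth mask PNGs as well?
#' @return Invisibly, the paths written.
#' @export
write_synthetic_core <- function(syn, path, masks = TRUE) {
  stopifnot(inherits(syn, "synthetic_core"))
  write_core_image(syn$image, path)
  out <- path
  stem <- sub("\\.(png|tiff?|PNG|TIFF?)$", "", path)
  if (masks) {
    for (m in c("tumor_mask", "stroma_mask", "core_mask")) {
      p <- paste0(stem, "_", m, ".png")
      png::writePNG(syn$truth[[m]] * 1, p)
      out <- c(out, p)
    }
  }
  side <- paste0(stem, ".json")
  spec <- syn$spec
  jsonlite::write_json(
    list(true_tsr = syn$truth$true_tsr, seed = spec$seed,
         spec = unclass(spec)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(out, side))
}
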