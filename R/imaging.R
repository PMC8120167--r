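#' Parameters of the TSR segmentation pipeline
#'
#' @param struct_radius Disc radius (pixels) of the structuring element
#'   used for the dilate -> fill -> erode tumor-object step. Default 3
#'   at the 512-px fixture scale: large radii weld thin stromal
#'   corridors between adjacent nests into tumor.
#' @param min_object_area Connected components of the tumor mask smaller
#'   than this many pixels are discarded. This is the critical knob that
#'   removes hematoxylin-stained nuclei from the tumor mask; expressed
#'   in um^2 by callers when the pixel size is known. Default 200 px^2
#'   at fixture scale.
#' @param gradient_threshold_mode `"otsu"` (Otsu on the gradient
#'   magnitude, the default) or `"fixed"`.
#' @param gradient_threshold_value Threshold on the raw gradient
#'   magnitude when `gradient_threshold_mode = "fixed"`.
#' @param gradient_floor Minimum absolute gradient magnitude (per-pixel
#'   luminance change, Sobel scale) for a contour to count as an object
#'   boundary under `"otsu"` thresholding. DAB tumor edges sit around
#'   1.9 and nucleus edges around 2.3 on this scale, while the faint
#'   tissue/background rim of an unstained core is about 0.2; the floor
#'   keeps Otsu from latching onto the rim when no strong edge exists
#'   (e.g. a core without tumor).
#' @param core_min_area_frac Keep core-mask components at least this
#'   fraction of the frame area (tolerates fragmented cores).
#' @param core_close_radius Disc radius of the morphological closing
#'   applied to the Otsu tissue class before hole filling; bridges
#'   noise-induced speckle so the core disc fills as one object.
#' @return An object of class `pipeline_params`.
#' @export
pipeline_params <- function(struct_radius = 3,
                            min_object_area = 200,
                            gradient_threshold_mode = c("otsu", "fixed"),
                            gradient_threshold_value = NULL,
                            gradient_floor = 0.5,
                            core_min_area_frac = 0.05,
                            core_close_radius = 3) {
  gradient_threshold_mode <- match.arg(gradient_threshold_mode)
  stopifnot(struct_radius >= 1, min_object_area >= 0,
            core_min_area_frac > 0, core_min_area_frac < 1,
            core_close_radius >= 0)
  if (gradient_threshold_mode == "fixed" &&
      (is.null(gradient_threshold_value) || gradient_threshold_value < 0))
    stop("pipeline_params: fixed mode needs a non-negative gradient_threshold_value",
         call. = FALSE)
  stopifnot(gradient_floor >= 0)
  structure(list(struct_radius = struct_radius,
                 min_object_area = min_object_area,
                 gradient_threshold_mode = gradient_threshold_mode,
                 gradient_threshold_value = gradient_threshold_value,
                 gradient_floor = gradient_floor,
                 core_min_area_frac = core_min_area_frac,
                 core_close_radius = core_close_radius),
            class = "pipeline_params")
}

as_gray_matrix <- function(x) {
  if (inherits(x, "core_image")) return(to_grayscale(x))
  if (is.matrix(x)) return(x)
  stop("expected a core_image or a single-channel matrix", call. = FALSE)
}

#' Convert an RGB core image to grayscale
#'
#' Luminance-weighted combination 0.299 R + 0.587 G + 0.114 B (the
#' Rec. 601 triple).
#'
#' @param img A [core_image()].
#' @return A numeric `h x w` matrix in \[0, 1\].
#' @export
to_grayscale <- function(img) {
  if (!inherits(img, "core_image"))
    stop("to_grayscale: input must be a core_image (RGB 8-bit)", call. = FALSE)
  p <- img$pixels
  0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
}

#' Sobel gradient magnitude
#'
#' Convolves with the horizontal and vertical 3x3 Sobel kernels (border
#' handled by edge replication) and returns the Euclidean magnitude,
#' which concentrates on object contours.
#'
#' @param gray Single-channel matrix (values in \[0, 1\]).
#' @return Non-negative gradient-magnitude matrix of the same size.
#' @export
compute_gradient <- function(gray) {
  gray <- as_gray_matrix(gray)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(gray, kx, boundary = "replicate")
  gy <- EBImage::filter2(gray, t(kx), boundary = "replicate")
  m <- sqrt(gx^2 + gy^2)
  m[m < 1e-9] <- 0  # FFT convolution leaves numerical dust on constants
  matrix(pmax(m, 0), nrow(gray), ncol(gray))
}

disc_brush <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")

#' Extract tumor objects from a gradient map
#'
#' Thresholds the gradient magnitude (Otsu on the normalized magnitude
#' by default), then dilate -> fill holes -> erode with a disc of
#' `struct_radius`, and finally removes connected components smaller
#' than `min_object_area` pixels. An empty result is legal (no tumor
#' detected).
#'
#' @param grad Gradient-magnitude matrix from [compute_gradient()].
#' @param params A [pipeline_params()].
#' @return Logical tumor-object mask.
#' @export
extract_tumor_objects <- function(grad, params = pipeline_params()) {
  stopifnot(is.matrix(grad), inherits(params, "pipeline_params"))
  mx <- max(grad)
  if (params$gradient_threshold_mode == "otsu") {
    if (mx <= 0) return(matrix(FALSE, nrow(grad), ncol(grad)))
    gn <- grad / mx
    th <- EBImage::otsu(EBImage::Image(gn), range = c(0, 1))
    bin <- grad > max(th * mx, params$gradient_floor)
  } else {
    bin <- grad > params$gradient_threshold_value
  }
  if (!any(bin)) return(matrix(FALSE, nrow(grad), ncol(grad)))
  br <- disc_brush(params$struct_radius)
  m <- EBImage::dilate(bin, br)
  m <- EBImage::fillHull(m)
  m <- EBImage::erode(m, br)
  lab <- EBImage::bwlabel(m)
  if (params$min_object_area > 0 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < params$min_object_area)
    if (length(drop)) lab[lab %in% drop] <- 0
  }
  matrix(lab > 0, nrow(grad), ncol(grad))
}

#' Segment the whole core object
#'
#' Histogram-equalizes the grayscale image, Otsu-thresholds it into
#' tissue (dark class) versus background, closes and fills holes, and
#' keeps components covering at least `core_min_area_frac` of the
#' frame.
#'
#' @param gray Single-channel matrix in \[0, 1\] (or a [core_image()]).
#' @param params A [pipeline_params()].
#' @return Logical core mask.
#' @export
segment_core <- function(gray, params = pipeline_params()) {
  gray <- as_gray_matrix(gray)
  stopifnot(inherits(params, "pipeline_params"))
  if (diff(range(gray)) < 1e-6)
    stop("no core detected", call. = FALSE)
  eq <- EBImage::equalize(EBImage::Image(gray), range = c(0, 1), levels = 256)
  eq <- pmin(pmax(as.matrix(eq), 0), 1)
  th <- EBImage::otsu(EBImage::Image(eq), range = c(0, 1))
  tissue <- eq < th
  if (params$core_close_radius > 0) {
    br <- disc_brush(params$core_close_radius)
    tissue <- EBImage::erode(EBImage::dilate(tissue, br), br)
  }
  tissue <- EBImage::fillHull(tissue)
  lab <- EBImage::bwlabel(tissue)
  if (max(lab) == 0) stop("no core detected", call. = FALSE)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= params$core_min_area_frac * length(gray))
  if (!length(keep)) stop("no core detected", call. = FALSE)
  lab[!(lab %in% keep)] <- 0
  mask <- EBImage::fillHull(lab > 0)
  matrix(as.logical(mask), nrow(gray), ncol(gray))
}

#' Assess one core image: full segmentation and TSR
#'
#' Runs the whole chain: grayscale -> Sobel gradient -> tumor objects
#' (clipped to the core mask) -> core mask -> stroma = core minus tumor
#' -> TSR = stroma area / core area. Also produces the standard overlay
#' (tumor magenta, stroma cyan, non-cell black).
#'
#' @param img A [core_image()].
#' @param params A [pipeline_params()].
#' @return Object of class `tsr_segmentation`: `tumor_mask`,
#'   `stroma_mask`, `core_mask`, `tsr`, `areas` (named pixel counts),
#'   `overlay` (h x w x 3 array), `id`.
#' @examples
#' syn <- generate_core_image(image_spec(seed = 7))
#' seg <- assess_core(syn$image)
#' seg$tsr
#' @export
assess_core <- function(img, params = pipeline_params()) {
  stopifnot(inherits(img, "core_image"))
  gray <- to_grayscale(img)
  grad <- compute_gradient(gray)
  tumor_raw <- extract_tumor_objects(grad, params)
  core <- segment_core(gray, params)
  tumor <- tumor_raw & core
  stroma <- core & !tumor

  h <- nrow(gray); w <- ncol(gray)
  overlay <- array(0, c(h, w, 3))
  overlay[, , 1][tumor] <- 1                     # magenta = R + B
  overlay[, , 3][tumor] <- 1
  overlay[, , 2][stroma] <- 1                    # cyan = G + B
  overlay[, , 3][stroma] <- 1

  areas <- c(tumor = sum(tumor), stroma = sum(stroma), core = sum(core))
  structure(list(tumor_mask = tumor, stroma_mask = stroma,
                 core_mask = core,
                 tsr = unname(areas["stroma"] / areas["core"]),
                 areas = areas, overlay = overlay, id = img$id,
                 params = params),
            class = "tsr_segmentation")
}

#' @export
print.tsr_segmentation <- function(x, ...) {
  cat(sprintf("<tsr_segmentation '%s'> TSR = %.3f (stroma %d / core %d px)\n",
              x$id, x$tsr, x$areas["stroma"], x$areas["core"]))
  invisible(x)
}

#' Specimen-level TSR: field of highest stromal percentage
#'
#' A specimen is represented by several cores; the specimen TSR is the
#' maximum core-level TSR (the field of highest stromal percentage is
#' the one considered crucial).
#'
#' @param results List of `tsr_segmentation` objects, or a numeric
#'   vector of core TSR values.
#' @return Scalar specimen TSR.
#' @examples
#' assess_specimen(c(0.379, 0.781))
#' @export
assess_specimen <- function(results) {
  if (is.list(results))
    results <- vapply(results, function(r) {
      if (inherits(r, "tsr_segmentation")) r$tsr else as.numeric(r)
    }, numeric(1))
  if (!length(results))
    stop("assess_specimen: need at least one core result", call. = FALSE)
  stopifnot(is.numeric(results), all(results >= 0 & results <= 1))
  max(results)
}

#' Assess a batch of core images
#'
#' @param paths Character vector of PNG/TIFF files, or a directory.
#' @param params A [pipeline_params()].
#' @param overlay_dir Optional directory to write overlay PNGs to.
#' @return `data.frame` (core_id, tumor_px, stroma_px, core_px, tsr).
#' @export
assess_batch <- function(paths, params = pipeline_params(),
                         overlay_dir = NULL) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(png|tiff?)$",
                        ignore.case = TRUE, full.names = TRUE)
  if (!length(paths)) stop("assess_batch: no images found", call. = FALSE)
  rows <- lapply(paths, function(p) {
    img <- read_core_image(p)
    seg <- assess_core(img, params)
    if (!is.null(overlay_dir)) {
      dir.create(overlay_dir, showWarnings = FALSE, recursive = TRUE)
      png::writePNG(seg$overlay,
                    file.path(overlay_dir, paste0(img$id, "_overlay.png")))
    }
    data.frame(core_id = img$id, tumor_px = seg$areas[["tumor"]],
               stroma_px = seg$areas[["stroma"]],
               core_px = seg$areas[["core"]], tsr = seg$tsr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
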