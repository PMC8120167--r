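#' Read an RGB core image from PNG or TIFF
#'
#' @param path File path (`.png`, `.tif`, `.tiff`).
#' @param id Core identifier; defaults to the file stem.
#' @param pixel_size Micrometres per pixel, if known.
#' @return A [core_image()].
#' @export
read_core_image <- function(path, id = NULL, pixel_size = NA_real_) {
  if (!file.exists(path)) stop("read_core_image: no such file: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = tiff::readTIFF(path),
               stop("read_core_image: unsupported format '", ext, "'",
                    call. = FALSE))
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3] # drop alpha
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("read_core_image: expected an RGB (3-channel) image", call. = FALSE)
  core_image(px, id = id %||% sub("\\.[^.]+$", "", basename(path)),
             pixel_size = pixel_size)
}

#' Write an RGB core image to PNG or TIFF
#'
#' @param img A [core_image()].
#' @param path Output path; format chosen by extension.
#' @return Invisibly, `path`.
#' @export
write_core_image <- function(img, path) {
  stopifnot(inherits(img, "core_image"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img$pixels, path),
         tif = ,
         tiff = tiff::writeTIFF(img$pixels, path, bits.per.sample = 8L),
         stop("write_core_image: unsupported format '", ext, "'",
              call. = FALSE))
  invisible(path)
}

# Clinical table schema: allowed factor levels per column.
clinical_schema <- function() {
  list(age        = c("<=50", ">50"),
       menopausal = c("pre", "post"),
       histotype  = c("IDC", "other"),
       t_stage    = c("T1", "T2", "T3"),
       n_status   = c("neg", "pos"),
       grade      = c("I", "II", "III"),
       er         = c("pos", "neg"),
       pr         = c("pos", "neg"),
       her2       = c("amp", "non-amp"))
}

#' Read and validate a clinical table
#'
#' The clinical CSV schema has one row per patient with columns
#' `patient_id`, the categorical covariates (`age`, `menopausal`,
#' `histotype`, `t_stage`, `n_status`, `grade`, `er`, `pr`, `her2` with
#' the level sets of the motivating cohort), the continuous `tsr`
#' fraction (may be missing), follow-up `time_months` and the `event`
#' indicator. Unknown levels, negative times and non-binary events are
#' rejected with row-level diagnostics. Lines starting with `#` are
#' treated as comments.
#'
#' @param path CSV path.
#' @return Validated `data.frame`; categorical columns as factors.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("read_clinical: no such file: ", path,
                               call. = FALSE)
  tbl <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                           comment.char = "#"),
                  error = function(e) stop("read_clinical: ", conditionMessage(e),
                                           call. = FALSE))
  if (!nrow(tbl)) stop("read_clinical: empty table", call. = FALSE)
  validate_clinical(tbl)
}

#' @rdname read_clinical
#' @param tbl A data frame in the clinical schema.
#' @export
validate_clinical <- function(tbl) {
  schema <- clinical_schema()
  required <- c("patient_id", names(schema), "tsr", "time_months", "event")
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    stop("clinical table: missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  problems <- character(0)
  for (col in names(schema)) {
    bad <- which(!is.na(tbl[[col]]) & !(tbl[[col]] %in% schema[[col]]))
    if (length(bad))
      problems <- c(problems,
                    sprintf("column '%s': invalid level '%s' at row(s) %s",
                            col, tbl[[col]][bad[1]],
                            paste(head(bad, 5), collapse = ",")))
    tbl[[col]] <- factor(tbl[[col]], levels = schema[[col]])
  }
  bad_t <- which(!is.na(tbl$time_months) & tbl$time_months < 0)
  if (length(bad_t))
    problems <- c(problems, sprintf("negative time_months at row(s) %s",
                                    paste(head(bad_t, 5), collapse = ",")))
  bad_e <- which(!tbl$event %in% c(0, 1))
  if (length(bad_e))
    problems <- c(problems, sprintf("event not in {0,1} at row(s) %s",
                                    paste(head(bad_e, 5), collapse = ",")))
  bad_r <- which(!is.na(tbl$tsr) & (tbl$tsr < 0 | tbl$tsr > 1))
  if (length(bad_r))
    problems <- c(problems, sprintf("tsr outside [0,1] at row(s) %s",
                                    paste(head(bad_r, 5), collapse = ",")))
  if (length(problems))
    stop("clinical table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  tbl
}

#' Write a clinical table, segmentation batch, or KM curve as CSV
#'
#' CSVs are written with a `#`-prefixed header line echoing the package
#' version, so [read_clinical()] round-trips them exactly.
#'
#' @param x Object to write: clinical `data.frame`, output of
#'   [assess_batch()], or a [km_estimate()] curve.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(x, path) {
  if (inherits(x, "km_curve")) x <- x$table
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stromascope %s", as.character(packageVersion("stromascope"))),
             con)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a nomogram as JSON
#'
#' Writes the per-predictor points map, the point scale and the baseline
#' survival curve; `read_nomogram_json()` restores an object that
#' scores and predicts identically.
#'
#' @param nomo A [build_nomogram()] object.
#' @param path JSON path.
#' @return `write_nomogram_json()`: invisibly `path`;
#'   `read_nomogram_json()`: a `tsr_nomogram`.
#' @export
write_nomogram_json <- function(nomo, path) {
  stopifnot(inherits(nomo, "tsr_nomogram"))
  payload <- list(
    version = as.character(packageVersion("stromascope")),
    points = lapply(nomo$points, as.list),  # keep level names in JSON
    points_per_unit_beta = nomo$points_per_unit_beta,
    baseline = if (is.null(nomo$baseline)) NULL else
      list(time = nomo$baseline$time, surv = nomo$baseline$surv)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nomogram_json
#' @export
read_nomogram_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  points <- lapply(p$points, function(v) unlist(v))
  baseline <- if (!is.null(p$baseline))
    list(time = as.numeric(p$baseline$time), surv = as.numeric(p$baseline$surv))
  structure(list(points = points,
                 points_per_unit_beta = p$points_per_unit_beta,
                 baseline = baseline),
            class = "tsr_nomogram")
}
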