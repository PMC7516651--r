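#' Read a grayscale image from PNG or TIFF
#'
#' Decodes the file to native integer intensities: an 8-bit file yields
#' values in 0..255, a 16-bit file 0..65535.  Multi-channel images are
#' collapsed to luminance (Rec. 709 weights) with a warning.  Thresholded
#' extrema are defined in intensity units, so no rescaling is applied by
#' default; `rescale_to_8bit = TRUE` maps the full bit-depth range onto
#' 0..255 for cross-depth comparability.
#'
#' DICOM files are not decoded by this package; convert single-frame DICOM
#' to 16-bit TIFF or PNG first (applying the rescale slope/intercept, see
#' [apply_rescale()]).
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param rescale_to_8bit logical; map intensities onto 0..255.
#' @return A [grayscale_image()] with a `bit_depth` attribute.
#' @export
read_image <- function(path, rescale_to_8bit = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom", "ima")) {
    stop("DICOM input is not decoded here; convert the frame to 16-bit ",
         "TIFF/PNG (after applying the DICOM rescale slope/intercept, ",
         "see apply_rescale()) and retry: ", path, call. = FALSE)
  }
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    bits <- attr(raw, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    if (is.list(raw)) stop("multi-frame TIFF not supported: ", path,
                           call. = FALSE)
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else {
    stop("unsupported image format '.", ext, "' (use PNG or TIFF): ", path,
         call. = FALSE)
  }
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    if (nc >= 3L) {
      warning("multi-channel image collapsed to luminance: ", path,
              call. = FALSE)
      raw <- 0.2126 * raw[, , 1] + 0.7152 * raw[, , 2] + 0.0722 * raw[, , 3]
    } else {
      raw <- raw[, , 1]  # gray + alpha: drop alpha
    }
  }
  maxval <- 2^bits - 1
  px <- round(raw * maxval)
  if (rescale_to_8bit && bits != 8L) {
    px <- round(px / maxval * 255)
    bits <- 8L
  }
  out <- grayscale_image(px, source_id = basename(path))
  attr(out, "bit_depth") <- as.integer(bits)
  out
}

#' Write a grayscale image to PNG (8-bit) or TIFF (8- or 16-bit)
#'
#' @param image a [grayscale_image()]; intensities must fit the target depth.
#' @param path output path ending in .png, .tif or .tiff.
#' @param bit_depth 8 or 16 (PNG output is written 8-bit or 16-bit;
#'   defaults to the image's `bit_depth` attribute, else 8).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = NULL) {
  image <- as_image(image)
  if (is.null(bit_depth)) {
    bit_depth <- attr(image, "bit_depth")
    if (is.null(bit_depth)) bit_depth <- 8L
  }
  stopifnot(bit_depth %in% c(8, 16))
  maxval <- 2^bit_depth - 1
  px <- pixels(image)
  if (max(px) > maxval) {
    stop("intensities exceed ", bit_depth, "-bit range", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px / maxval, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px / maxval, where = path, bits.per.sample = bit_depth)
  } else {
    stop("unsupported output format '.", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Apply the DICOM linear rescale transform
#'
#' Maps stored pixel values to physical intensities,
#' `round(stored * slope + intercept)`, the transform DICOM headers carry as
#' rescale slope/intercept.  Values pushed below zero are clamped at zero so
#' the result remains a valid intensity grid.
#'
#' @param stored numeric vector or matrix of stored pixel values.
#' @param slope,intercept rescale parameters.
#' @return Rescaled integer intensities with the input's shape.
#' @examples
#' apply_rescale(10, slope = 2, intercept = -1)  # 19
#' @export
apply_rescale <- function(stored, slope = 1, intercept = 0) {
  pmax(round(stored * slope + intercept), 0)
}

#' Read and write quality-score tables
#'
#' Score tables are plain CSV with columns `image_id`, `S`, `neighborhood`,
#' `score`; MOS tables have columns `image_id`, `mos`.  Scores are written
#' with 15 significant digits, so a write/read round trip is lossless to
#' well beyond 12 digits.
#'
#' @param scores list of `enmiqa_score` objects or a data.frame with the
#'   score-table columns.
#' @param path CSV path.
#' @return `read_scores` returns a data.frame; `write_scores` returns
#'   `path` invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- if (is.data.frame(scores)) scores else {
    do.call(rbind, lapply(scores, function(s) {
      data.frame(image_id = s$image_id, S = s$S,
                 neighborhood = s$neighborhood_size,
                 score = s$value, stringsAsFactors = FALSE)
    }))
  }
  df$score <- formatC(df$score, digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Join objective scores with subjective MOS and evaluate
#'
#' Strict inner join on `image_id`: any id present in one table but not the
#' other is an error, so silent misalignment cannot occur.
#'
#' @param scores data.frame with columns `image_id`, `score` (extra columns
#'   ignored) or path to such a CSV.
#' @param mos data.frame with columns `image_id`, `mos`, or path to a CSV.
#' @return An [evaluate_iqa()] report.
#' @export
evaluate_scores <- function(scores, mos) {
  if (is.character(scores)) scores <- read_scores(scores)
  if (is.character(mos)) mos <- read_scores(mos)
  stopifnot(all(c("image_id", "score") %in% names(scores)),
            all(c("image_id", "mos") %in% names(mos)))
  missing_mos <- setdiff(scores$image_id, mos$image_id)
  missing_score <- setdiff(mos$image_id, scores$image_id)
  if (length(missing_mos) || length(missing_score)) {
    stop("unmatched image ids; missing MOS for: ",
         paste(missing_mos, collapse = ", "),
         "; missing scores for: ",
         paste(missing_score, collapse = ", "), call. = FALSE)
  }
  merged <- merge(scores[, c("image_id", "score")],
                  mos[, c("image_id", "mos")], by = "image_id")
  evaluate_iqa(merged$score, merged$mos, ids = merged$image_id)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [evaluate_iqa()] result.
#' @param path output JSON path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly if written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "iqa_evaluation"))
  obj <- list(
    n = report$n,
    criteria = list(plcc = report$plcc, srcc = report$srcc,
                    krcc = report$krcc, rmse = report$rmse),
    beta = as.list(report$beta),
    jarque_bera = if (!is.null(report$jb)) {
      list(statistic = report$jb$statistic, critical = report$jb$critical,
           normality_rejected = report$jb$reject, method = report$jb$method)
    },
    residuals = as.numeric(report$residuals),
    ids = report$ids)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
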