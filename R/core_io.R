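# Image, mask, and table I/O. Images are numeric matrices [row, col],
# origin top-left, raw intensity units (no rescaling on read).

#' Read a single-plane grayscale TIFF as an intensity matrix
#'
#' Integer TIFFs (8/16-bit) are read at their native dynamic range;
#' 32-bit float TIFFs are read as-is. No intensity normalization is
#' applied.
#'
#' @param path Path to a single-plane 2D grayscale TIFF.
#' @return Numeric matrix of non-negative intensities, `[row, col]`.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' write_image(matrix(100, 8, 8), f, bits = 16)
#' img <- read_image(f)
#' stopifnot(all(img == 100))
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  planes <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (length(planes) != 1) {
    stop("multi-plane TIFF stack requires plane selection: ", path)
  }
  px <- planes[[1]]
  if (length(dim(px)) == 3) {
    stop("multichannel input requires plane selection: ", path)
  }
  px <- px * 1.0
  if (!all(is.finite(px))) stop("non-finite pixel values in ", path)
  if (any(px < 0)) stop("negative intensities in ", path)
  px
}

#' Read an integer-valued TIFF as a label mask
#'
#' Value 0 is background; each positive integer labels one object.
#' Float TIFFs are accepted when all values are integral.
#'
#' @param path Path to the mask TIFF.
#' @return Integer matrix of labels, same orientation as [read_image()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3) stop("multichannel mask not supported: ", path)
  if (any(px < 0)) stop("negative label values in ", path)
  if (any(abs(px - round(px)) > 1e-9)) {
    stop("non-integral values in mask: ", path)
  }
  m <- round(px)
  storage.mode(m) <- "integer"
  m
}

#' Write an intensity matrix or label mask as a grayscale TIFF
#'
#' Output is integer TIFF (8 or 16 bit); values must be integral and
#' within the sample range. Integer TIFFs round-trip bit-identically
#' through [read_image()]/[read_mask()]. Float-valued results (e.g.
#' per-pixel anisotropy maps) are stored in fixed point; see
#' [write_unit_map()].
#'
#' @param pixels Numeric matrix of integral values in `[0, 2^bits - 1]`.
#' @param path Output path.
#' @param bits 8 or 16.
#' @return The path, invisibly.
#' @export
write_image <- function(pixels, path, bits = 16) {
  stopifnot(is.matrix(pixels), bits %in% c(8, 16))
  maxv <- 2^bits - 1
  if (any(is.na(pixels))) stop("NA pixels are not representable; see write_unit_map")
  if (any(pixels < 0) || any(pixels > maxv) ||
      any(abs(pixels - round(pixels)) > 1e-9)) {
    stop("integer TIFF output requires integral values in [0, ", maxv, "]")
  }
  # writeTIFF scales [0,1] to the integer range
  tiff::writeTIFF(round(pixels) / maxv, path, bits.per.sample = bits,
                  reduce = FALSE)
  invisible(path)
}

#' Write a unit-interval map as 16-bit fixed-point TIFF
#'
#' Values in `[0, 1]` are stored as `round(value * 65534)`; NA
#' (unevaluated) pixels are stored as 65535. [read_unit_map()] inverts
#' the encoding. Resolution is 1/65534, far below the reproducibility of
#' any image-derived score.
#'
#' @param map Numeric matrix with values in `[0, 1]` or NA.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_unit_map <- function(map, path) {
  stopifnot(is.matrix(map))
  vals <- map[!is.na(map)]
  if (any(vals < 0 | vals > 1)) stop("map values must be in [0, 1] or NA")
  enc <- round(map * 65534)
  enc[is.na(enc)] <- 65535
  write_image(enc, path, bits = 16)
}

#' Read a fixed-point unit map written by [write_unit_map()]
#' @param path TIFF path.
#' @return Numeric matrix in `[0, 1]` with NA for unevaluated pixels.
#' @export
read_unit_map <- function(path) {
  enc <- read_image(path)
  out <- enc / 65534
  out[enc == 65535] <- NA_real_
  out
}

#' Write keyed records to CSV
#'
#' Accepts a data.frame or a list of identically keyed named lists; the
#' written CSV (header row, RFC-4180) round-trips through [read_table()].
#'
#' @param records data.frame or list of named lists with identical keys.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0) stop("empty record list: pass a 0-row data.frame for a header-only table")
    keys <- lapply(records, names)
    if (length(unique(vapply(keys, paste, "", collapse = "\r"))) != 1) {
      stop("records with mismatched keys")
    }
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    stop("records must be a data.frame or list of named lists")
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

# shared geometry/validation helpers ---------------------------------------

.check_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img)) stop(name, " must be a numeric matrix")
  if (nrow(img) < 1 || ncol(img) < 1) stop(name, " must be non-empty")
  if (!all(is.finite(img))) stop(name, " contains non-finite values")
  invisible(img)
}

.check_mask <- function(mask, img = NULL, name = "mask") {
  if (!is.matrix(mask)) stop(name, " must be an integer matrix")
  if (any(mask < 0)) stop(name, " contains negative labels")
  if (any(abs(mask - round(mask)) > 1e-9)) stop(name, " contains non-integral labels")
  if (!is.null(img) && !identical(dim(mask), dim(img))) {
    stop(name, " shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ", paste(dim(img), collapse = "x"))
  }
  invisible(mask)
}

.labels_of <- function(mask) sort(unique(mask[mask > 0]))
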