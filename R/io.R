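# Grayscale image I/O (PNG and TIFF). Images live in memory as numeric
# matrices on the 0-255 scale; files are 8-bit (or 32-bit float TIFF out).

#' Read a grayscale image
#'
#' Reads PNG or TIFF (by file extension) and returns a numeric matrix on
#' the 0-255 scale. RGB(A) inputs are converted by the Rec. 601 luminance
#' weights (0.299, 0.587, 0.114).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric image matrix.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  )
  if (length(dim(x)) == 3L) {
    ch <- dim(x)[3L]
    x <- if (ch >= 3L) {
      0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else {
      x[, , 1L]
    }
  }
  x * 255
}

#' Write a grayscale image
#'
#' Writes an image matrix on the 0-255 scale as 8-bit PNG/TIFF (default)
#' or 32-bit float TIFF (`bitdepth = "float"`, TIFF only), clamping to
#' [0, 255] for 8-bit output.
#'
#' @param img Numeric image matrix (0-255 scale).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bitdepth `"8"` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, bitdepth = c("8", "float")) {
  assert_image(img)
  bitdepth <- match.arg(bitdepth)
  ext <- tolower(tools::file_ext(path))
  if (bitdepth == "float") {
    if (!ext %in% c("tif", "tiff")) {
      stop("float output requires a TIFF path", call. = FALSE)
    }
    tiff::writeTIFF(img / 255, path, bits.per.sample = 32L)
    return(invisible(path))
  }
  x <- clamp(round(img), 0, 255) / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

#' Serialize contourlet coefficients to a directory of CSV bands
#'
#' One plain-text matrix per band (`lowpass.csv`, `scale<j>_dir<d>.csv`)
#' plus a small JSON manifest with the decomposition settings.
#'
#' @param coeffs An `nsct_coeffs` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_nsct_coeffs <- function(coeffs, dir) {
  if (!inherits(coeffs, "nsct_coeffs")) {
    stop("`coeffs` must be an `nsct_coeffs` object", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, name) {
    utils::write.table(m, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE, col.names = FALSE, sep = ",")
  }
  wr(coeffs$lowpass, "lowpass")
  for (j in seq_along(coeffs$bands)) {
    for (d in seq_along(coeffs$bands[[j]])) {
      wr(coeffs$bands[[j]][[d]], sprintf("scale%d_dir%d", j, d))
    }
  }
  jsonlite::write_json(
    list(scales = coeffs$spec$scales, kernel = coeffs$spec$kernel,
         levels = coeffs$dspec$levels, mode = coeffs$mode,
         dim = dim(coeffs$lowpass)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read contourlet coefficients written by [write_nsct_coeffs()]
#'
#' @param dir Directory containing the band CSVs and manifest.
#' @return An `nsct_coeffs` object.
#' @export
read_nsct_coeffs <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rd <- function(name) {
    as.matrix(utils::read.table(file.path(dir, paste0(name, ".csv")),
                                sep = ",", colClasses = "numeric"))
  }
  lowpass <- unname(rd("lowpass"))
  bands <- lapply(seq_len(man$scales), function(j) {
    lapply(seq_len(2L^man$levels[j]), function(d) {
      unname(rd(sprintf("scale%d_dir%d", j, d)))
    })
  })
  structure(list(lowpass = lowpass, bands = bands,
                 spec = pyramid_spec(man$scales, man$kernel),
                 dspec = directional_spec(man$levels), mode = man$mode),
            class = "nsct_coeffs")
}
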