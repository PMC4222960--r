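#' Read and write greyscale TIFF rasters
#'
#' `read_raster()` reads an 8- or 16-bit greyscale TIFF as an integer-valued
#' numeric matrix (a list of matrices for a multi-page stack, in page
#' order).  RGB and floating-point TIFFs are rejected.  `write_raster()`
#' writes a matrix, or a list of matrices as a multi-page stack, as 8-bit
#' greyscale; the round trip is lossless for 8-bit data.
#'
#' @param path file path.
#' @param img numeric matrix with values in \[0, 255\], or a list of them.
#' @return `read_raster()`: a numeric matrix or list of matrices;
#'   `write_raster()`: the path, invisibly.
#' @export
read_raster <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop_config(sprintf("cannot read '%s' as TIFF: %s",
                                          path, conditionMessage(e))))
  check_page <- function(p) {
    if (length(dim(p)) != 2L)
      stop_config("unsupported format: multi-channel (RGB) TIFF")
    if (any(p != floor(p)))
      stop_config("unsupported format: floating-point TIFF")
    storage.mode(p) <- "double"
    p
  }
  pages <- lapply(pages, check_page)
  if (length(pages) == 1L) pages[[1L]] else pages
}

#' @rdname read_raster
#' @export
write_raster <- function(img, path) {
  as_page <- function(m) {
    if (min(m) < 0 || max(m) > 255)
      stop_config("image values must lie in [0, 255] for 8-bit output")
    round_half_up(m) / 255
  }
  pages <- if (is.list(img)) lapply(img, as_page) else as_page(img)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a measurement table as CSV
#'
#' Tidy one-row-per-measurement CSV with a header, '.' decimal separator,
#' UTF-8 and Unix newlines, independent of the locale.
#'
#' @param x a data frame (e.g. from [run_table1()] or the sweeps), or a
#'   `coloc_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "coloc_report")) x <- as.data.frame(x)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(x, con, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Round-trip a run configuration
#'
#' Every stochastic run records its parameters and seed in a flat key=value
#' sidecar file so a run can be reproduced exactly.
#'
#' @param config named list of scalar parameters (must include `seed` for
#'   stochastic runs).
#' @param path sidecar file path.
#' @return `read_run_config()`: the named list (numbers restored).
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s=%s", k, format(config[[k]], digits = 17, scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- paste(p[-1L], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, `[[`, character(1), 1L)
  out
}
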