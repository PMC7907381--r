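# Interchange formats: multi-page 32-bit TIFF stacks with a JSON sidecar
# carrying the affine value scaling (TIFF stores [0, 1]); reports as CSV
# and JSON; run manifests as JSON.

#' Write a volume or image stack as multi-page TIFF
#'
#' Values are affinely mapped to `[0, 1]` for 32-bit storage; the mapping
#' is recorded in a `<path>.json` sidecar so [read_tiff_stack()] restores
#' the original values.
#'
#' @param x Matrix or 3D array (third dimension = pages).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(x, path) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  rng <- range(x)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(x)[3]),
                  function(k) (x[, , k] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(offset = rng[1], scale = scale,
                            dim = dim(x)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stack written by [write_tiff_stack()]
#'
#' @param path TIFF path (sidecar `<path>.json` expected).
#' @return 3D numeric array.
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    arr <- arr * meta$scale + meta$offset
  }
  arr
}

#' Write a morphometry report as CSV and JSON
#'
#' @param report A `morphometry_report`.
#' @param stem Output path without extension.
#' @return The two paths, invisibly.
#' @export
write_morphometry_report <- function(report, stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  out <- as.list(as.data.frame(report))
  out$note <- attr(report, "note")
  jsonlite::write_json(out, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
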