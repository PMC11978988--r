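# FrameStack persistence: multi-page 32-bit float TIFF plus a CSV metadata
# table. TIFF samples are stored scaled into [0, 1]; the affine scale and
# offset restoring physical ADU values travel in the CSV (constant columns
# tiff_scale / tiff_offset), so the pair is self-describing.

STACK_META_COLS <- c("frame", "time_s", "voltage_V", "phase_idx",
                     "phase_rad", "flow_um", "rep")

#' Write a frame stack as multi-page TIFF + CSV metadata
#'
#' Frames are scaled into \[0, 1\], quantized to IEEE float32 and written as
#' a multi-page 32-bit TIFF; the per-stack scale/offset and pixel size are
#' recorded in the CSV next to the per-frame metadata. Precision is that of
#' float32 (about 1e-7 relative); repeated write -> read cycles stay at
#' float32 precision (scale and offset are re-derived from the data, so
#' re-quantization can move values by at most one ulp).
#'
#' @param stack a [frame_stack()].
#' @param tiff_path output TIFF path.
#' @param csv_path output CSV path.
#' @return `tiff_path`, invisibly.
#' @export
write_frame_stack <- function(stack, tiff_path, csv_path) {
  vals <- range(vapply(stack$frames, range, numeric(2)))
  off <- vals[1]
  sc <- max(vals[2] - vals[1], .Machine$double.eps)
  pages <- lapply(stack$frames, function(f) as_float32((f - off) / sc))
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L, reduce = FALSE)
  meta <- stack$meta
  for (col in setdiff(STACK_META_COLS, names(meta))) meta[[col]] <- NA
  meta$tiff_scale <- sc
  meta$tiff_offset <- off
  meta$pixel_um <- stack$pixel_um
  utils::write.csv(meta, csv_path, row.names = FALSE)
  invisible(tiff_path)
}

#' Read a frame stack from multi-page TIFF + CSV metadata
#'
#' Restores ADU values using the scale/offset columns written by
#' [write_frame_stack()]. External 8/16-bit integer TIFFs (which the reader
#' receives scaled into \[0, 1\]) are promoted to float by multiplying with
#' `2^bits - 1`; the promotion is reported with a message and flagged in the
#' returned object's `promoted` attribute.
#'
#' @param tiff_path input TIFF path.
#' @param csv_path input CSV path.
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(tiff_path, csv_path) {
  meta <- utils::read.csv(csv_path)
  missing <- setdiff(STACK_META_COLS, names(meta))
  if (length(missing))
    stop("metadata CSV lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != nrow(meta))
    stop(sprintf("frame-count mismatch: TIFF has %d pages, CSV has %d rows",
                 length(pages), nrow(meta)), call. = FALSE)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 32L
  promoted <- FALSE
  if (!is.null(bits) && bits < 32L) {
    pages <- lapply(pages, function(p) p * (2^bits - 1))
    promoted <- TRUE
    message(sprintf("promoted %d-bit integer TIFF to float ADU", bits))
  }
  sc <- if ("tiff_scale" %in% names(meta)) meta$tiff_scale[1] else 1
  off <- if ("tiff_offset" %in% names(meta)) meta$tiff_offset[1] else 0
  frames <- lapply(pages, function(p) {
    m <- as.matrix(p)
    attributes(m) <- list(dim = dim(m))
    m * sc + off
  })
  px <- if ("pixel_um" %in% names(meta)) meta$pixel_um[1] else NA_real_
  meta <- meta[, setdiff(names(meta), c("tiff_scale", "tiff_offset", "pixel_um")),
               drop = FALSE]
  out <- frame_stack(frames, meta, px)
  attr(out, "promoted") <- promoted
  out
}
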