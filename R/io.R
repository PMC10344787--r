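#' Phosphopeptide intensity table
#'
#' Container for a site-by-sample intensity matrix with protein annotations
#' and a group design. Intensities are positive on the linear scale (or
#' log2-scale values after [preprocess()]); missing values are `NA`.
#'
#' @param intensity Numeric matrix, sites in rows (rownames = site ids),
#'   samples in columns (colnames = sample ids).
#' @param protein_id Character vector, one protein id per site.
#' @param design Factor of group labels, one per sample.
#' @param log2 Logical; whether values are already on the log2 scale.
#' @return An object of class `phospho_table`.
#' @export
phospho_table <- function(intensity, protein_id, design, log2 = FALSE) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    stop("intensity must have site rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(intensity)))
    stop("duplicate site ids", call. = FALSE)
  if (length(protein_id) != nrow(intensity))
    stop("protein_id must have one entry per site", call. = FALSE)
  if (length(design) != ncol(intensity))
    stop("design must have one group label per sample", call. = FALSE)
  if (!log2 && any(intensity <= 0, na.rm = TRUE))
    stop("linear-scale intensities must be positive", call. = FALSE)
  structure(list(intensity = intensity,
                 site_id = rownames(intensity),
                 protein_id = as.character(protein_id),
                 design = as.factor(design),
                 log2 = log2),
            class = "phospho_table")
}

#' @export
print.phospho_table <- function(x, ...) {
  cat(sprintf("phospho_table: %d sites x %d samples (%d proteins), %s scale\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$protein_id)),
              if (x$log2) "log2" else "linear"))
  cat("groups:", paste(sprintf("%s (n=%d)", levels(x$design),
                               table(x$design)), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a phosphopeptide table as TSV
#'
#' Columns are `site_id`, `protein_id`, then one intensity column per sample
#' named `group:sample`. Missing values are written as empty cells and read
#' back as `NA`, never as 0. Reading rejects duplicate site ids and malformed
#' headers.
#'
#' @param table A [phospho_table()].
#' @param path File path.
#' @return `write_phospho_table` returns `path` invisibly;
#'   `read_phospho_table` returns a `phospho_table`.
#' @export
write_phospho_table <- function(table, path) {
  stopifnot(inherits(table, "phospho_table"))
  df <- data.frame(site_id = table$site_id, protein_id = table$protein_id,
                   check.names = FALSE)
  m <- table$intensity
  colnames(m) <- paste0(table$design, ":", colnames(m))
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_phospho_table
#' @param log2 Whether stored values are log2-scale.
#' @export
read_phospho_table <- function(path, log2 = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = "", stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(colnames(df)[1:2],
                                 c("site_id", "protein_id")))
    stop("malformed header: expected site_id, protein_id, then sample columns",
         call. = FALSE)
  if (anyDuplicated(df$site_id)) {
    dup <- df$site_id[duplicated(df$site_id)][1]
    stop(sprintf("duplicate site_id '%s' (row %d)", dup,
                 which(df$site_id == dup)[2]), call. = FALSE)
  }
  sample_cols <- colnames(df)[-(1:2)]
  parts <- strsplit(sample_cols, ":", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("malformed header: sample columns must be named group:sample",
         call. = FALSE)
  groups <- vapply(parts, `[[`, character(1), 1)
  samples <- vapply(parts, `[[`, character(1), 2)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(df$site_id, samples)
  phospho_table(m, protein_id = df$protein_id,
                design = factor(groups, levels = unique(groups)),
                log2 = log2)
}

#' Calibrated image stack
#'
#' Container for time-lapse frames with spatial and temporal calibration and
#' (optionally) per-frame integer label masks.
#'
#' @param frames Numeric array `H x W x T` (a 2D image is promoted to T = 1).
#' @param labels Optional integer array of the same shape; 0 = background.
#' @param pixel_size Pixel size in micrometres.
#' @param frame_interval Seconds between frames.
#' @return An object of class `labeled_stack`.
#' @export
labeled_stack <- function(frames, labels = NULL, pixel_size, frame_interval) {
  if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3)
    stop("frames must be a 2D image or an H x W x T array", call. = FALSE)
  if (!is.null(labels)) {
    if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1L)
    if (!identical(dim(labels), dim(frames)))
      stop("labels must align with frames", call. = FALSE)
    storage.mode(labels) <- "integer"
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0", call. = FALSE)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0", call. = FALSE)
  structure(list(frames = frames, labels = labels, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "labeled_stack")
}

#' @export
print.labeled_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "labeled_stack: %d x %d px, %d frame(s), %.3g um/px, %.3g s/frame%s\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval,
    if (is.null(x$labels)) "" else ", with labels"))
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF with a calibration sidecar
#'
#' Frames are rescaled to [0, 1] and stored as 32-bit float TIFF pages; the
#' original intensity range is recorded in a JSON sidecar `<path>.json`
#' together with the calibration (pixel size in micrometres, frame interval
#' in seconds), since baseline TIFF tags cannot carry the frame interval.
#' On read, calibration is taken from the sidecar unless overridden by the
#' `pixel_size`/`frame_interval` arguments; if neither source provides it,
#' reading fails.
#'
#' @param stack A [labeled_stack()].
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns a
#'   `labeled_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "labeled_stack"))
  lo <- min(stack$frames); hi <- max(stack$frames)
  scaled <- if (hi > lo) (stack$frames - lo) / (hi - lo)
            else array(0, dim(stack$frames))
  pages <- lapply(seq_len(dim(scaled)[3]), function(f) scaled[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(pixel_size = stack$pixel_size,
                            frame_interval = stack$frame_interval,
                            range = c(lo, hi)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param pixel_size,frame_interval Optional calibration overrides.
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse grayscale channels
    p
  })
  frames <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (!is.null(meta$range)) {
    rg <- as.numeric(unlist(meta$range))
    if (rg[2] > rg[1]) frames <- frames * (rg[2] - rg[1]) + rg[1]
    else frames <- frames + rg[1]
  }
  pixel_size <- pixel_size %||% meta$pixel_size
  frame_interval <- frame_interval %||% meta$frame_interval
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("calibration missing: supply pixel_size and frame_interval or a ",
         sidecar, " sidecar", call. = FALSE)
  labeled_stack(frames, pixel_size = as.numeric(pixel_size),
                frame_interval = as.numeric(frame_interval))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
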