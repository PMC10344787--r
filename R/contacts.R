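#' ER-mitochondria contact quantification from label masks
#'
#' For each mitochondrion, the minimum edge-to-edge distance to the ER is
#' measured via the Euclidean distance transform of the ER complement sampled
#' at the mitochondrion's pixels, converting centre-to-centre pixel distance
#' to a membrane gap by subtracting one pixel (touching objects read 0 nm).
#' A mitochondrion is in contact when its gap lies inside the inclusive band
#' (default 10-30 nm, the conventional MAM apposition range); the summary
#' percentage is contacted mitochondria over all mitochondria. Gaps below the
#' lower bound are excluded by default, honouring the strict band; set
#' `include_closer = TRUE` to count sub-band appositions as contacts.
#'
#' Pixel distances are converted by `pixel_size_nm` without interpolation, so
#' the sampling must resolve the band (<= 5 nm/px recommended).
#'
#' @param mito Integer label matrix (0 = background) or logical mask (labelled
#'   with 8-connectivity).
#' @param er Logical ER mask of the same shape.
#' @param pixel_size_nm Pixel size in nm (> 0).
#' @param band Inclusive contact band in nm (default `c(10, 30)`).
#' @param include_closer Count gaps below `band[1]` as contacts.
#' @return A list with `per_mito` (data frame: `label`, `min_distance_nm`,
#'   `contact`), `percentage`, and `n_mito`.
#' @export
contact_percentage <- function(mito, er, pixel_size_nm, band = c(10, 30),
                               include_closer = FALSE) {
  if (!identical(dim(mito), dim(er)))
    stop("masks must have the same shape", call. = FALSE)
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0", call. = FALSE)
  labels <- if (is.logical(mito) || all(mito %in% c(0, 1)))
    label_mask(mito) else { storage.mode(mito) <- "integer"; mito }
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!length(ids)) stop("no mitochondria in mask", call. = FALSE)
  er <- er > 0
  if (!any(er)) {
    per <- data.frame(label = ids, min_distance_nm = Inf, contact = FALSE)
    return(list(per_mito = per, percentage = 0, n_mito = length(ids)))
  }
  # distance (px, centre-to-centre) from every pixel to the nearest ER pixel
  dmap <- as.matrix(EBImage::distmap(matrix(as.numeric(!er), nrow(er)),
                                     metric = "euclidean"))
  gap <- vapply(ids, function(id) {
    d <- min(dmap[labels == id])
    max(d - 1, 0) * pixel_size_nm
  }, numeric(1))
  contact <- gap <= band[2] & (if (include_closer) TRUE else gap >= band[1])
  per <- data.frame(label = ids, min_distance_nm = gap, contact = contact)
  list(per_mito = per, percentage = 100 * mean(contact),
       n_mito = length(ids))
}

#' Mask-overlap co-localization percentage
#'
#' Manders-style overlap on binary masks: the percentage of marker pixels
#' that fall inside the reference mask.
#'
#' @param marker,reference Aligned logical masks; the marker must be
#'   non-empty.
#' @return Percentage in [0, 100].
#' @export
coloc_percentage <- function(marker, reference) {
  if (!identical(dim(marker), dim(reference)))
    stop("masks must have the same shape", call. = FALSE)
  marker <- marker > 0; reference <- reference > 0
  if (!any(marker)) stop("empty marker mask", call. = FALSE)
  100 * sum(marker & reference) / sum(marker)
}
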