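#' Track labelled particles across consecutive frames
#'
#' Builds the full overlap table between particles in consecutive frames and
#' a one-to-one identity matching: pairs are matched greedily by descending
#' intersection-over-union above `iou_threshold`, with deterministic
#' tie-breaking (IoU descending, then source and target label ascending).
#' Unmatched particles are flagged.
#'
#' @param stack A [labeled_stack()] with per-frame label masks.
#' @param iou_threshold Minimum IoU for an identity match (default 0.3).
#' @return An object of class `mito_tracking`: list with `overlaps` (data
#'   frame: `frame`, `from`, `to`, `overlap`, `area_from`, `area_to`, `iou`;
#'   one row per overlapping pair between frame and frame + 1), `matches`
#'   (the greedy one-to-one subset), `unmatched` (data frame: `frame`,
#'   `label`, `side`), and the `stack`.
#' @export
track_components <- function(stack, iou_threshold = 0.3) {
  stopifnot(inherits(stack, "labeled_stack"))
  if (is.null(stack$labels)) stop("stack has no label masks", call. = FALSE)
  nT <- dim(stack$labels)[3]
  overlaps <- list(); matches <- list(); unmatched <- list()
  for (f in seq_len(max(nT - 1L, 0L))) {
    a <- stack$labels[, , f]; b <- stack$labels[, , f + 1L]
    la <- setdiff(unique(as.vector(a)), 0L)
    lb <- setdiff(unique(as.vector(b)), 0L)
    area_a <- stats::setNames(tabulate(a[a > 0]), NULL)
    area_b <- stats::setNames(tabulate(b[b > 0]), NULL)
    both <- a > 0 & b > 0
    ov <- NULL
    if (any(both)) {
      tab <- table(a[both], b[both])
      ov <- as.data.frame(tab, stringsAsFactors = FALSE)
      names(ov) <- c("from", "to", "overlap")
      ov <- ov[ov$overlap > 0, , drop = FALSE]
      ov$from <- as.integer(as.character(ov$from))
      ov$to <- as.integer(as.character(ov$to))
      ov$area_from <- area_a[ov$from]
      ov$area_to <- area_b[ov$to]
      ov$iou <- ov$overlap / (ov$area_from + ov$area_to - ov$overlap)
      ov <- cbind(frame = f, ov)
      overlaps[[length(overlaps) + 1L]] <- ov
    }
    # greedy one-to-one matching
    mf <- integer(0); mt <- integer(0)
    if (!is.null(ov) && nrow(ov)) {
      cand <- ov[ov$iou >= iou_threshold, , drop = FALSE]
      cand <- cand[order(-cand$iou, cand$from, cand$to), , drop = FALSE]
      used_f <- integer(0); used_t <- integer(0)
      for (r in seq_len(nrow(cand))) {
        if (cand$from[r] %in% used_f || cand$to[r] %in% used_t) next
        used_f <- c(used_f, cand$from[r]); used_t <- c(used_t, cand$to[r])
        matches[[length(matches) + 1L]] <- cand[r, ]
      }
      mf <- used_f; mt <- used_t
    }
    if (length(setdiff(la, mf)))
      unmatched[[length(unmatched) + 1L]] <- data.frame(
        frame = f, label = setdiff(la, mf), side = "from")
    if (length(setdiff(lb, mt)))
      unmatched[[length(unmatched) + 1L]] <- data.frame(
        frame = f, label = setdiff(lb, mt), side = "to")
  }
  bindr <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  structure(list(
    overlaps = bindr(overlaps, data.frame(frame = integer(), from = integer(),
                                          to = integer(), overlap = integer(),
                                          area_from = integer(),
                                          area_to = integer(),
                                          iou = numeric())),
    matches = bindr(matches, data.frame(frame = integer(), from = integer(),
                                        to = integer(), overlap = integer(),
                                        area_from = integer(),
                                        area_to = integer(), iou = numeric())),
    unmatched = bindr(unmatched, data.frame(frame = integer(),
                                            label = integer(),
                                            side = character())),
    stack = stack), class = "mito_tracking")
}

# labels within `margin` px of the field border, per frame
border_labels <- function(labels, margin) {
  H <- nrow(labels); W <- ncol(labels)
  rim <- labels[c(seq_len(margin), H - seq_len(margin) + 1L), ]
  rim2 <- labels[, c(seq_len(margin), W - seq_len(margin) + 1L)]
  setdiff(unique(c(as.vector(rim), as.vector(rim2))), 0L)
}

#' Detect fission and fusion events from tracked particles
#'
#' A fission is recorded where one particle maps to two or more particles in
#' the next frame, each child having at least `min_frac` of its area
#' overlapping the parent; a fusion is the mirror image (two or more parents
#' each overlapping the child by at least `min_frac` of their own area). The
#' symmetric rule guarantees exact time-reversal duality. Events involving
#' particles within `border_margin` px of the field edge are discarded
#' (objects entering or leaving the field masquerade as events), and an
#' event immediately reversed within one frame is discarded when `debounce`
#' is on.
#'
#' @param tracking A `mito_tracking` from [track_components()].
#' @param min_frac Minimum overlap fraction of the smaller-side particle
#'   (default 0.5).
#' @param border_margin Pixels from the edge within which events are
#'   discarded (default 2).
#' @param debounce Drop events undone within one frame (default TRUE).
#' @return A data frame with columns `type` ("fission"/"fusion"), `frame`
#'   (the earlier frame of the transition), `time` (s, = (frame - 1) *
#'   frame_interval of the later frame), `parents`, `children`
#'   (labels joined with "+").
#' @export
detect_events <- function(tracking, min_frac = 0.5, border_margin = 2,
                          debounce = TRUE) {
  stopifnot(inherits(tracking, "mito_tracking"))
  ov <- tracking$overlaps
  dt <- tracking$stack$frame_interval
  labels <- tracking$stack$labels
  events <- list()
  for (f in sort(unique(ov$frame))) {
    o <- ov[ov$frame == f, , drop = FALSE]
    excl <- union(border_labels(labels[, , f], border_margin),
                  -(border_labels(labels[, , f + 1L], border_margin)))
    # fission: parent at f with >= 2 children at f+1, each child covered
    # >= min_frac of its own area by the parent
    child_edges <- o[o$overlap >= min_frac * o$area_to, , drop = FALSE]
    for (p in unique(child_edges$from)) {
      kids <- child_edges$to[child_edges$from == p]
      if (length(kids) < 2) next
      if (p %in% excl || any(-kids %in% excl)) next
      events[[length(events) + 1L]] <- data.frame(
        type = "fission", frame = f, time = f * dt,
        parents = as.character(p),
        children = paste(sort(kids), collapse = "+"))
    }
    # fusion: child at f+1 with >= 2 parents at f, each parent covered
    # >= min_frac of its own area by the child
    par_edges <- o[o$overlap >= min_frac * o$area_from, , drop = FALSE]
    for (ch in unique(par_edges$to)) {
      pars <- par_edges$from[par_edges$to == ch]
      if (length(pars) < 2) next
      if (any(pars %in% excl) || (-ch) %in% excl) next
      events[[length(events) + 1L]] <- data.frame(
        type = "fusion", frame = f, time = f * dt,
        parents = paste(sort(pars), collapse = "+"),
        children = as.character(ch))
    }
  }
  out <- if (length(events)) do.call(rbind, events)
         else data.frame(type = character(), frame = integer(),
                         time = numeric(), parents = character(),
                         children = character())
  out <- unique(out)
  if (debounce && nrow(out) > 1) {
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(out) - 1L)) {
      j <- which(out$frame == out$frame[i] + 1L &
                 out$type != out$type[i] &
                 out$parents == out$children[i] |
                 (out$frame == out$frame[i] + 1L & out$type != out$type[i] &
                  out$children == out$parents[i]))
      j <- j[j > i]
      if (length(j)) { drop[i] <- TRUE; drop[j[1]] <- TRUE }
    }
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Fission and fusion rates per cell per second
#'
#' @param events Event data frame from [detect_events()].
#' @param n_cells Number of cells observed (>= 1).
#' @param duration_s Observation time in seconds (> 0).
#' @return A list with `fission_rate`, `fusion_rate` (events per cell per
#'   second), `n_fission`, `n_fusion`, `n_cells`, `duration_s`.
#' @export
event_rates <- function(events, n_cells, duration_s) {
  if (duration_s <= 0) stop("duration must be > 0", call. = FALSE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  nf <- sum(events$type == "fission")
  nu <- sum(events$type == "fusion")
  list(fission_rate = nf / (n_cells * duration_s),
       fusion_rate = nu / (n_cells * duration_s),
       n_fission = nf, n_fusion = nu,
       n_cells = n_cells, duration_s = duration_s)
}

#' Marker-mitochondria interaction duration and fate
#'
#' A contact is a run of consecutive frames in which a marker object overlaps
#' a given mitochondrion label by at least `min_overlap_px` pixels. Each
#' contiguous contact gets a duration of `(end - start + 1) * frame_interval`
#' seconds and a fate: `"useful"` if that mitochondrion undergoes fission
#' during the contact or within `fate_window` frames after it ends,
#' `"futile"` otherwise. Mitochondrial labels must be temporally consistent
#' (as produced by the generator, or after track-based relabelling).
#'
#' @param marker_masks Logical or integer array `H x W x T` of the marker
#'   channel (any nonzero pixel is marker; distinct labels are treated as
#'   distinct markers).
#' @param mito_stack A [labeled_stack()] with temporally consistent labels.
#' @param events Event data frame from [detect_events()] (or the generator's
#'   ground-truth log) with `parents` and `frame` columns.
#' @param fate_window Frames after contact end within which a fission still
#'   counts (default 2).
#' @param min_overlap_px Minimum overlap in pixels (default 1).
#' @return A list with `interactions` (data frame: `marker`, `mito`,
#'   `start_frame`, `end_frame`, `duration_s`, `fate`) and `mean_duration_s`.
#' @export
interaction_analysis <- function(marker_masks, mito_stack, events,
                                 fate_window = 2, min_overlap_px = 1) {
  stopifnot(inherits(mito_stack, "labeled_stack"))
  if (length(dim(marker_masks)) == 2)
    dim(marker_masks) <- c(dim(marker_masks), 1L)
  if (!identical(dim(marker_masks), dim(mito_stack$labels)))
    stop("channel shape mismatch between marker and mitochondria stacks",
         call. = FALSE)
  dt <- mito_stack$frame_interval
  nT <- dim(marker_masks)[3]
  # contact table: frame x (marker, mito)
  contacts <- list()
  for (f in seq_len(nT)) {
    mk <- marker_masks[, , f]; mt <- mito_stack$labels[, , f]
    both <- mk > 0 & mt > 0
    if (!any(both)) next
    tab <- table(mk[both], mt[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("marker", "mito", "px")
    df$marker <- as.character(df$marker)
    df$mito <- as.character(df$mito)
    df <- df[df$px >= min_overlap_px, , drop = FALSE]
    if (nrow(df)) contacts[[length(contacts) + 1L]] <-
      cbind(frame = f, df[, c("marker", "mito")])
  }
  if (!length(contacts)) {
    return(list(interactions = data.frame(
      marker = character(), mito = character(), start_frame = integer(),
      end_frame = integer(), duration_s = numeric(), fate = character()),
      mean_duration_s = NaN))
  }
  ct <- do.call(rbind, contacts)
  fission_frames <- function(mito) {
    ev <- events[events$type == "fission", , drop = FALSE]
    ev$frame[vapply(strsplit(ev$parents, "+", fixed = TRUE),
                    function(p) mito %in% p, logical(1))]
  }
  rows <- list()
  for (key in unique(paste(ct$marker, ct$mito, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    fr <- sort(ct$frame[ct$marker == parts[1] & ct$mito == parts[2]])
    runs <- split(fr, cumsum(c(1L, diff(fr) != 1L)))
    ff <- fission_frames(parts[2])
    for (run in runs) {
      s <- min(run); e <- max(run)
      useful <- any(ff >= s & ff <= e + fate_window)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = parts[1], mito = parts[2], start_frame = s, end_frame = e,
        duration_s = (e - s + 1L) * dt,
        fate = if (useful) "useful" else "futile")
    }
  }
  interactions <- do.call(rbind, rows)
  rownames(interactions) <- NULL
  interactions <- interactions[order(interactions$start_frame,
                                     interactions$marker), , drop = FALSE]
  list(interactions = interactions,
       mean_duration_s = mean(interactions$duration_s))
}

#' Propagate persistent track identities through frames
#'
#' Rewrites per-frame labels so that matched particles keep the identity of
#' their first appearance; new (unmatched) particles get fresh ids. Useful
#' before [interaction_analysis()] when labels come from frame-wise
#' thresholding.
#'
#' @param tracking A `mito_tracking` from [track_components()].
#' @return A [labeled_stack()] with persistent labels.
#' @export
propagate_labels <- function(tracking) {
  stopifnot(inherits(tracking, "mito_tracking"))
  labels <- tracking$stack$labels
  nT <- dim(labels)[3]
  out <- labels
  next_id <- 0L
  prev_map <- NULL
  for (f in seq_len(nT)) {
    ids <- setdiff(unique(as.vector(labels[, , f])), 0L)
    map <- integer(0)
    m <- tracking$matches
    for (id in sort(ids)) {
      from <- if (f > 1L) m$from[m$frame == f - 1L & m$to == id] else integer(0)
      if (length(from) == 1L && !is.null(prev_map) &&
          as.character(from) %in% names(prev_map)) {
        map[as.character(id)] <- prev_map[[as.character(from)]]
      } else {
        next_id <- next_id + 1L
        map[as.character(id)] <- next_id
      }
    }
    fr <- labels[, , f]
    nz <- fr > 0
    fr[nz] <- map[as.character(fr[nz])]
    out[, , f] <- fr
    prev_map <- map
  }
  res <- tracking$stack
  res$labels <- out
  res
}
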