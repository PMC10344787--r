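# shared fixtures and independent oracles, built in code

# rasterized disk: pixel centres within radius r of the centre
raster_disk <- function(r, pad = 5) {
  n <- 2 * (r + pad)
  ctr <- (n + 1) / 2
  ii <- matrix(seq_len(n), n, n)
  jj <- t(ii)
  (ii - ctr)^2 + (jj - ctr)^2 <= r^2
}

# brute-force Benjamini-Hochberg step-up, written from the definition:
# adj p_(i) = min over j >= i of min(1, m * p_(j) / j)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force minimum boundary distance: all pairs of object and ER pixel
# centres, minus the one-pixel centre offset
brute_min_gap_px <- function(obj_mask, er_mask) {
  a <- which(obj_mask, arr.ind = TRUE)
  b <- which(er_mask, arr.ind = TRUE)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  max(sqrt(min(d2)) - 1, 0)
}

# small complete phospho table fixture on the log2 scale
toy_log2_table <- function(values, groups) {
  m <- matrix(values, nrow = length(values) / length(groups), byrow = TRUE)
  rownames(m) <- paste0("P1_S", seq_len(nrow(m)))
  colnames(m) <- paste0(groups, "_", seq_along(groups))
  phospho_table(m, protein_id = rep("P1", nrow(m)),
                design = factor(groups, levels = unique(groups)),
                log2 = TRUE)
}

# stack with two static blobs, one fission or fusion scripted via labels
two_frame_stack <- function(labels_t1, labels_t2, frame_interval = 13) {
  labs <- array(0L, c(dim(labels_t1), 2))
  labs[, , 1] <- labels_t1
  labs[, , 2] <- labels_t2
  labeled_stack(frames = (labs > 0) * 200, labels = labs,
                pixel_size = 0.1, frame_interval = frame_interval)
}
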