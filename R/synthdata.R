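#' Configuration for the synthetic phosphoproteomics generator
#'
#' Defines a label-free phosphoproteomics experiment: a set of proteins each
#' carrying one or more quantified phosphopeptides, a group design with a
#' control group and one or more treatment groups, planted group effects on a
#' subset of sites, multiplicative measurement noise, and a mixed
#' MCAR/MNAR missingness mechanism.
#'
#' @param n_proteins Number of phosphoproteins.
#' @param peptides_per_protein Length-2 integer vector `(min, max)`; the
#'   number of phosphopeptides per protein is drawn uniformly in this range.
#' @param n_groups Number of experimental groups (the first is the control).
#' @param n_replicates Samples per group.
#' @param effect_fraction Fraction of sites carrying a planted group effect.
#' @param effect_log2fc Magnitude of the planted |log2 fold change|; each
#'   affected site gets a random sign.
#' @param cv Coefficient of variation of the multiplicative (linear-scale)
#'   measurement noise.
#' @param missing_rate Overall expected fraction of missing intensities.
#' @param mnar_weight Fraction of the missingness that is intensity-dependent
#'   (missing-not-at-random); the remainder is uniform (MCAR).
#' @param base_mean,base_sd Mean and standard deviation (log2 units) of the
#'   site-level base abundance; defaults match a typical LFQ intensity scale.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `phospho_sim_config`.
#' @export
phospho_sim_config <- function(n_proteins = 100, peptides_per_protein = c(1, 5),
                               n_groups = 2, n_replicates = 4,
                               effect_fraction = 0.1, effect_log2fc = 2,
                               cv = 0.2, missing_rate = 0.1, mnar_weight = 0.5,
                               base_mean = 25, base_sd = 2, seed = 1) {
  stopifnot(length(peptides_per_protein) == 2)
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              n_groups = as.integer(n_groups),
              n_replicates = as.integer(n_replicates),
              effect_fraction = effect_fraction, effect_log2fc = effect_log2fc,
              cv = cv, missing_rate = missing_rate, mnar_weight = mnar_weight,
              base_mean = base_mean, base_sd = base_sd, seed = as.integer(seed))
  with(cfg, {
    if (n_proteins < 1 || n_replicates < 1 || n_groups < 2 ||
        any(peptides_per_protein < 1) ||
        peptides_per_protein[1] > peptides_per_protein[2])
      stop("invalid configuration: counts must be >= 1 and n_groups >= 2",
           call. = FALSE)
    for (f in c(effect_fraction, missing_rate, mnar_weight))
      if (f < 0 || f > 1)
        stop("invalid configuration: fractions must lie in [0, 1]",
             call. = FALSE)
    if (cv < 0 || effect_log2fc < 0)
      stop("invalid configuration: cv and effect_log2fc must be >= 0",
           call. = FALSE)
  })
  structure(cfg, class = "phospho_sim_config")
}

#' Simulate a phosphopeptide intensity table with known ground truth
#'
#' Draws site-level base abundances on the log2 scale, plants
#' `effect_log2fc`-sized shifts (random sign) on a random subset of sites in
#' every non-control group, adds multiplicative noise, exponentiates to the
#' linear intensity scale, and knocks out values with a mixed MCAR/MNAR
#' mechanism (the MNAR component preferentially removes low intensities via a
#' logistic weight). Ground truth records the affected sites, their planted
#' effects, and the implied per-protein cumulative phosphorylation change.
#'
#' @param config A [phospho_sim_config()].
#' @return A list with elements `table` (a `phospho_table`: positive
#'   intensities with `NA` for missing) and `truth` (list with
#'   `true_significant_sites`, `effects` named vector of planted signed
#'   log2FCs, and `true_delta_ps` per protein).
#' @export
simulate_phospho_table <- function(config) {
  if (!inherits(config, "phospho_sim_config"))
    stop("config must be a phospho_sim_config", call. = FALSE)
  set.seed(config$seed)
  npep <- sample(seq(config$peptides_per_protein[1],
                     config$peptides_per_protein[2]),
                 config$n_proteins, replace = TRUE)
  protein_id <- rep(sprintf("P%04d", seq_len(config$n_proteins)), npep)
  site_id <- paste0(protein_id, "_S", unlist(lapply(npep, seq_len)))
  n_sites <- length(site_id)
  groups <- c("control", if (config$n_groups == 2) "treatment"
              else paste0("treatment", seq_len(config$n_groups - 1)))
  design <- factor(rep(groups, each = config$n_replicates), levels = groups)
  samples <- paste0(design, "_r", rep(seq_len(config$n_replicates),
                                      config$n_groups))
  n_samp <- length(samples)

  base <- stats::rnorm(n_sites, config$base_mean, config$base_sd)
  n_eff <- round(config$effect_fraction * n_sites)
  eff_idx <- if (n_eff > 0) sort(sample.int(n_sites, n_eff)) else integer(0)
  eff <- numeric(n_sites)
  eff[eff_idx] <- config$effect_log2fc *
    sample(c(-1, 1), n_eff, replace = TRUE)

  sd_log2 <- sqrt(log(1 + config$cv^2)) / log(2)
  m <- matrix(base, n_sites, n_samp)
  m[, design != "control"] <- m[, design != "control"] + eff
  m <- m + matrix(stats::rnorm(n_sites * n_samp, 0, sd_log2), n_sites, n_samp)
  intensity <- 2^m

  # missingness: MCAR uniform + MNAR logistic in the log2 intensity
  if (config$missing_rate > 0) {
    x <- as.vector(m)
    w <- stats::plogis((stats::quantile(x, 0.2) - x) / 1)
    p_mnar <- config$missing_rate * config$mnar_weight * w / mean(w)
    p_mcar <- config$missing_rate * (1 - config$mnar_weight)
    p_miss <- pmin(p_mnar + p_mcar, 1)
    drop <- stats::runif(length(x)) < p_miss
    intensity[matrix(drop, n_sites, n_samp)] <- NA_real_
  }
  dimnames(intensity) <- list(site_id, samples)

  table <- phospho_table(intensity, protein_id = protein_id, design = design)
  true_dps <- tapply(eff, protein_id, sum)
  truth <- list(
    true_significant_sites = site_id[eff_idx],
    effects = stats::setNames(eff, site_id),
    true_delta_ps = true_dps[unique(protein_id)]
  )
  list(table = table, truth = truth)
}

#' Configuration for the synthetic mitochondrial time-lapse generator
#'
#' Describes a single-plane time-lapse field of capsule-shaped mitochondria
#' undergoing scripted fission and fusion, at the acquisition cadence used for
#' live imaging of mitochondrial dynamics (one frame every 13 s single
#' channel, 27 s dual channel, over 10 min).
#'
#' @param field_size `(H, W)` in pixels.
#' @param pixel_size Pixel size in micrometres.
#' @param frame_interval Seconds between frames (default 13).
#' @param duration Total duration in seconds (default 600).
#' @param n_mitochondria Number of capsules placed at t = 0.
#' @param fission_events List of `list(time =, target =)` entries; the capsule
#'   with id `target` splits in two at the first frame at or after `time`.
#' @param fusion_events List of `list(time =, pair = c(a, b))` entries; the
#'   two capsules merge into one spanning capsule.
#' @param psf_sigma Gaussian blur sigma in pixels applied to rendered frames
#'   (0 = no blur).
#' @param noise_sd Standard deviation of additive Gaussian noise (0 = none).
#' @param amplitude Foreground intensity of rendered objects.
#' @param seed Integer seed.
#' @return An object of class `dynamics_sim_config`.
#' @export
dynamics_sim_config <- function(field_size = c(128, 128), pixel_size = 0.1,
                                frame_interval = 13, duration = 600,
                                n_mitochondria = 5, fission_events = list(),
                                fusion_events = list(), psf_sigma = 0,
                                noise_sd = 0, amplitude = 200, seed = 1) {
  cfg <- list(field_size = as.integer(field_size), pixel_size = pixel_size,
              frame_interval = frame_interval, duration = duration,
              n_mitochondria = as.integer(n_mitochondria),
              fission_events = fission_events, fusion_events = fusion_events,
              psf_sigma = psf_sigma, noise_sd = noise_sd,
              amplitude = amplitude, seed = as.integer(seed))
  if (cfg$pixel_size <= 0 || cfg$frame_interval <= 0 || cfg$duration <= 0 ||
      cfg$n_mitochondria < 1 || cfg$noise_sd < 0 || cfg$psf_sigma < 0)
    stop("invalid configuration", call. = FALSE)
  times <- c(vapply(fission_events, `[[`, numeric(1), "time"),
             vapply(fusion_events, `[[`, numeric(1), "time"))
  if (length(times) && (any(times < 0) || any(times > cfg$duration)))
    stop("invalid configuration: event times must lie in [0, duration]",
         call. = FALSE)
  structure(cfg, class = "dynamics_sim_config")
}

# rasterize a capsule (line segment p1-p2 dilated by radius r) into a label
# mask; works on pixel centres
rasterize_capsule <- function(mask, p1, p2, r, id) {
  H <- nrow(mask); W <- ncol(mask)
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  v <- p2 - p1
  len2 <- sum(v^2)
  if (len2 == 0) {
    d2 <- (i - p1[1])^2 + (j - p1[2])^2
  } else {
    t <- ((i - p1[1]) * v[1] + (j - p1[2]) * v[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (i - (p1[1] + t * v[1]))^2 + (j - (p1[2] + t * v[2]))^2
  }
  mask[d2 <= r^2] <- id
  mask
}

#' Simulate a labelled mitochondrial time-lapse stack
#'
#' Capsules (rectangles with semicircular caps, the simplest geometry with a
#' well-defined analytic area) are placed without overlap and kept static
#' except for scripted events. Fission splits a capsule at the midpoint of its
#' axis leaving a 2-px gap; fusion replaces a pair with one capsule spanning
#' their farthest endpoints. Noiseless integer label masks are retained per
#' frame as ground truth; rendered frames optionally get PSF blur and noise.
#'
#' @param config A [dynamics_sim_config()].
#' @return A list with `stack` (a [labeled_stack()]) and `truth` (list with
#'   `true_particle_count_per_frame`, `true_event_log` data frame, and
#'   `capsule_area_um2`, the analytic area of every object ever alive).
#' @export
simulate_timelapse <- function(config) {
  if (!inherits(config, "dynamics_sim_config"))
    stop("config must be a dynamics_sim_config", call. = FALSE)
  set.seed(config$seed)
  H <- config$field_size[1]; W <- config$field_size[2]
  n_frames <- floor(config$duration / config$frame_interval) + 1L
  frame_times <- (seq_len(n_frames) - 1L) * config$frame_interval

  # capsule registry: id -> list(p1, p2, r, alive)
  caps <- list()
  margin <- 18
  for (id in seq_len(config$n_mitochondria)) {
    for (try in 1:200) {
      c0 <- c(stats::runif(1, margin, H - margin),
              stats::runif(1, margin, W - margin))
      ang <- stats::runif(1, 0, pi)
      hl <- stats::runif(1, 6, 12)
      r <- stats::runif(1, 2, 3.5)
      p1 <- c0 + hl * c(cos(ang), sin(ang))
      p2 <- c0 - hl * c(cos(ang), sin(ang))
      ok <- TRUE
      for (cc in caps) {
        if (!cc$alive) next
        # conservative separation: segment midpoints further apart than the
        # sum of half-lengths + radii + gap
        if (sqrt(sum((c0 - (cc$p1 + cc$p2) / 2)^2)) <
            hl + sqrt(sum((cc$p2 - cc$p1)^2)) / 2 + r + cc$r + 3) {
          ok <- FALSE; break
        }
      }
      if (ok) break
      if (try == 200) stop("could not place mitochondria without overlap",
                           call. = FALSE)
    }
    caps[[id]] <- list(p1 = p1, p2 = p2, r = r, alive = TRUE)
  }
  next_id <- length(caps)

  ev <- rbind(
    if (length(config$fission_events))
      do.call(rbind, lapply(config$fission_events, function(e)
        data.frame(type = "fission", time = e$time, a = e$target, b = NA))),
    if (length(config$fusion_events))
      do.call(rbind, lapply(config$fusion_events, function(e)
        data.frame(type = "fusion", time = e$time, a = e$pair[1],
                   b = e$pair[2])))
  )
  if (!is.null(ev)) ev <- ev[order(ev$time), , drop = FALSE]

  labels <- array(0L, c(H, W, n_frames))
  log_rows <- list()
  for (f in seq_len(n_frames)) {
    if (!is.null(ev) && nrow(ev)) {
      due <- ev$time <= frame_times[f]
      for (k in which(due)) {
        e <- ev[k, ]
        if (e$type == "fission") {
          tgt <- if (e$a >= 1 && e$a <= length(caps)) caps[[e$a]] else NULL
          if (is.null(tgt) || !tgt$alive)
            stop(sprintf("fission target %d does not exist at t=%g",
                         e$a, e$time), call. = FALSE)
          mid <- (tgt$p1 + tgt$p2) / 2
          u <- tgt$p2 - tgt$p1
          u <- u / sqrt(sum(u^2))
          gap <- tgt$r + 1.5  # end caps + ~2 px clearance between children
          caps[[e$a]]$alive <- FALSE
          c1 <- list(p1 = tgt$p1, p2 = mid - gap * u, r = tgt$r, alive = TRUE)
          c2 <- list(p1 = mid + gap * u, p2 = tgt$p2, r = tgt$r, alive = TRUE)
          caps[[next_id + 1L]] <- c1
          caps[[next_id + 2L]] <- c2
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            type = "fission", time = e$time, frame = f,
            parents = as.character(e$a),
            children = paste(next_id + 1:2, collapse = "+"))
          next_id <- next_id + 2L
        } else {
          pa <- if (e$a >= 1 && e$a <= length(caps)) caps[[e$a]] else NULL
          pb <- if (e$b >= 1 && e$b <= length(caps)) caps[[e$b]] else NULL
          if (is.null(pa) || is.null(pb) || !pa$alive || !pb$alive)
            stop(sprintf("fusion pair (%d,%d) does not exist at t=%g",
                         e$a, e$b, e$time), call. = FALSE)
          ends <- rbind(pa$p1, pa$p2, pb$p1, pb$p2)
          dm <- as.matrix(stats::dist(ends))
          far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
          caps[[e$a]]$alive <- FALSE
          caps[[e$b]]$alive <- FALSE
          caps[[next_id + 1L]] <- list(p1 = ends[far[1], ], p2 = ends[far[2], ],
                                       r = max(pa$r, pb$r), alive = TRUE)
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            type = "fusion", time = e$time, frame = f,
            parents = paste(c(e$a, e$b), collapse = "+"),
            children = as.character(next_id + 1L))
          next_id <- next_id + 1L
        }
      }
      ev <- ev[!due, , drop = FALSE]
    }
    mask <- matrix(0L, H, W)
    for (id in seq_along(caps))
      if (isTRUE(caps[[id]]$alive))
        mask <- rasterize_capsule(mask, caps[[id]]$p1, caps[[id]]$p2,
                                  caps[[id]]$r, id)
    labels[, , f] <- mask
  }

  frames <- array(0, c(H, W, n_frames))
  for (f in seq_len(n_frames)) {
    img <- config$amplitude * (labels[, , f] > 0)
    if (config$psf_sigma > 0)
      img <- EBImage::gblur(img, sigma = config$psf_sigma)
    if (config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W)
    frames[, , f] <- img
  }

  counts <- apply(labels, 3, function(m) length(setdiff(unique(as.vector(m)),
                                                        0L)))
  # analytic capsule area: L*2r + pi*r^2 (L = axis length), in um^2
  areas <- vapply(seq_along(caps), function(id) {
    cc <- caps[[id]]
    L <- sqrt(sum((cc$p2 - cc$p1)^2))
    (L * 2 * cc$r + pi * cc$r^2) * config$pixel_size^2
  }, numeric(1))
  truth <- list(
    true_particle_count_per_frame = counts,
    true_event_log = if (length(log_rows)) do.call(rbind, log_rows)
                     else data.frame(type = character(), time = numeric(),
                                     frame = integer(), parents = character(),
                                     children = character()),
    capsule_area_um2 = stats::setNames(areas, seq_along(caps))
  )
  stack <- labeled_stack(frames, labels = labels,
                         pixel_size = config$pixel_size,
                         frame_interval = config$frame_interval)
  list(stack = stack, truth = truth)
}

#' Simulate ER-mitochondria boundary geometry at controlled gap distances
#'
#' Places one rectangular mitochondrion per requested distance beside a
#' vertical ER ribbon, at a pixel gap of `round(d / pixel_size_nm)`. Ground
#' truth contact flags are computed from the *requested* distances using the
#' inclusive band rule (default 10-30 nm, the conventional MAM membrane gap).
#'
#' @param distances_nm Numeric vector of requested minimum gap distances (nm).
#' @param pixel_size_nm Pixel size in nm; must resolve the requested gaps
#'   (<= 5 nm/px recommended; a positive distance that rounds to a zero-pixel
#'   gap is an error).
#' @param band Inclusive contact band in nm.
#' @return A list with `mito` (integer label matrix, one label per distance),
#'   `er` (logical mask), and `truth` (list with `true_contact_flags`,
#'   `requested_nm`, `realized_nm`).
#' @export
simulate_contact_geometry <- function(distances_nm, pixel_size_nm,
                                      band = c(10, 30)) {
  if (any(distances_nm < 0) || pixel_size_nm <= 0)
    stop("distances must be >= 0 and pixel_size_nm > 0", call. = FALSE)
  gap_px <- round(distances_nm / pixel_size_nm)
  if (any(distances_nm > 0 & gap_px == 0))
    stop("distance unresolvable at this pixel size", call. = FALSE)
  n <- length(distances_nm)
  mito_w <- 10L; mito_h <- 8L; row_pitch <- mito_h + 8L
  er_col <- 6L
  H <- n * row_pitch + 8L
  W <- er_col + 4L + max(gap_px) + mito_w + 8L
  er <- matrix(FALSE, H, W)
  er[, seq_len(er_col)] <- TRUE
  mito <- matrix(0L, H, W)
  for (k in seq_len(n)) {
    r0 <- (k - 1L) * row_pitch + 5L
    c0 <- er_col + gap_px[k] + 1L
    mito[r0:(r0 + mito_h - 1L), c0:(c0 + mito_w - 1L)] <- k
  }
  flags <- distances_nm >= band[1] & distances_nm <= band[2]
  list(mito = mito, er = er,
       truth = list(true_contact_flags = stats::setNames(flags, seq_len(n)),
                    requested_nm = distances_nm,
                    realized_nm = gap_px * pixel_size_nm))
}
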