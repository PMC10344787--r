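test_that("tracking matches static objects and rejects non-overlaps", {
  m <- matrix(0L, 30, 30)
  m[5:10, 5:10] <- 1L
  m[20:25, 20:25] <- 2L
  st <- two_frame_stack(m, m)
  tr <- track_components(st)
  expect_equal(nrow(tr$matches), 2)
  expect_equal(tr$matches$from, tr$matches$to)
  expect_true(all(tr$matches$iou == 1))

  # identity follows position: swapped label numbers still match by overlap
  sw <- matrix(0L, 30, 30)
  sw[5:10, 5:10] <- 2L
  sw[20:25, 20:25] <- 1L
  trs <- track_components(two_frame_stack(m, sw))
  expect_equal(nrow(trs$matches), 2)
  expect_identical(trs$matches$to[order(trs$matches$from)], c(2L, 1L))

  # objects jumping to disjoint positions share no overlap: no matches
  mv <- matrix(0L, 30, 30)
  mv[12:17, 12:17] <- 1L
  mv[1:4, 24:27] <- 2L
  tr2 <- track_components(two_frame_stack(m, mv))
  expect_equal(nrow(tr2$matches), 0)
  expect_equal(nrow(tr2$unmatched), 4)
})

test_that("tracking reproduces generator lineage on noiseless stacks", {
  cfg <- dynamics_sim_config(field_size = c(200, 200), n_mitochondria = 6,
                             duration = 65, seed = 9)
  sim <- simulate_timelapse(cfg)
  tr <- track_components(sim$stack)
  nT <- dim(sim$stack$labels)[3]
  expect_equal(nrow(tr$matches), 6 * (nT - 1))
  expect_true(all(tr$matches$from == tr$matches$to))
  expect_equal(nrow(tr$unmatched), 0)
})

test_that("scripted events are recovered exactly with no false events", {
  cfg <- dynamics_sim_config(
    field_size = c(240, 240), n_mitochondria = 4, duration = 600, seed = 2,
    fission_events = list(list(time = 100, target = 1),
                          list(time = 300, target = 3)),
    fusion_events = list())
  sim <- simulate_timelapse(cfg)
  tr <- track_components(sim$stack)
  ev <- detect_events(tr)
  expect_equal(sum(ev$type == "fission"), 2)
  expect_equal(sum(ev$type == "fusion"), 0)
  # detected transition frames line up with the scripted log
  expect_setequal(ev$frame + 1L, sim$truth$true_event_log$frame)
  expect_setequal(ev$parents, sim$truth$true_event_log$parents)
  expect_setequal(ev$children, sim$truth$true_event_log$children)
})

test_that("time reversal maps fissions to fusions exactly", {
  cfg <- dynamics_sim_config(
    field_size = c(240, 240), n_mitochondria = 3, duration = 390, seed = 6,
    fission_events = list(list(time = 130, target = 2)))
  sim <- simulate_timelapse(cfg)
  ev <- detect_events(track_components(sim$stack))
  rev_stack <- sim$stack
  nT <- dim(sim$stack$labels)[3]
  rev_stack$labels <- sim$stack$labels[, , nT:1]
  rev_stack$frames <- sim$stack$frames[, , nT:1]
  ev_rev <- detect_events(track_components(rev_stack))
  expect_equal(nrow(ev_rev), nrow(ev))
  expect_identical(sort(ev_rev$type),
                   sort(ifelse(ev$type == "fission", "fusion", "fission")))
  expect_setequal(ev_rev$parents, ev$children)
  expect_setequal(ev_rev$children, ev$parents)
})

test_that("particle-count bookkeeping holds across scripted intervals", {
  cfg <- dynamics_sim_config(
    field_size = c(260, 260), n_mitochondria = 5, duration = 600, seed = 12,
    fission_events = list(list(time = 100, target = 1),
                          list(time = 200, target = 2),
                          list(time = 350, target = 4)),
    fusion_events = list(list(time = 500, pair = c(6, 7))))
  sim <- simulate_timelapse(cfg)
  ev <- detect_events(track_components(sim$stack))
  counts <- sim$truth$true_particle_count_per_frame
  nF <- sum(ev$type == "fission"); nU <- sum(ev$type == "fusion")
  expect_equal(nF, 3); expect_equal(nU, 1)
  expect_equal(counts[length(counts)], counts[1] + nF - nU)
})

test_that("event rates follow the per-cell per-second convention", {
  ev <- data.frame(type = c("fission", "fission", "fission"))
  r <- event_rates(ev, n_cells = 1, duration_s = 600)
  expect_equal(r$fission_rate, 0.005)
  expect_equal(r$fusion_rate, 0)
  expect_equal(event_rates(ev[0, , drop = FALSE], 1, 600)$fission_rate, 0)
  expect_equal(event_rates(ev, 1, 1200)$fission_rate, r$fission_rate / 2)
  expect_error(event_rates(ev, 1, 0), "duration")
})

test_that("mixed scripted events are fully recovered across seeds", {
  for (seed in 1:5) {
    cfg <- dynamics_sim_config(
      field_size = c(360, 360), n_mitochondria = 8, duration = 600,
      seed = seed,
      fission_events = list(list(time = 80, target = 1),
                            list(time = 200, target = 3),
                            list(time = 320, target = 5),
                            list(time = 440, target = 7)),
      # re-fuse the children of the first split well after it
      fusion_events = list(list(time = 560, pair = c(9, 10))))
    sim <- simulate_timelapse(cfg)
    ev <- detect_events(track_components(sim$stack))
    expect_equal(sum(ev$type == "fission"), 4)
    expect_equal(sum(ev$type == "fusion"), 1)
    expect_setequal(ev$frame + 1L, sim$truth$true_event_log$frame)
    r <- event_rates(ev, n_cells = 1, duration_s = 600)
    expect_equal(r$fission_rate, 4 / 600)
    expect_equal(r$fusion_rate, 1 / 600)
  }
})

test_that("interaction durations and fates follow the contact rule", {
  # mito label 1 static; marker overlaps frames 3..9; fission of 1 at frame 10
  H <- 40; nT <- 14
  labs <- array(0L, c(H, H, nT))
  for (f in 1:nT) labs[15:25, 10:30, f] <- 1L
  # fission representation: from frame 11 two children
  for (f in 11:nT) {
    labs[, , f] <- 0L
    labs[15:25, 10:18, f] <- 2L
    labs[15:25, 22:30, f] <- 3L
  }
  mito <- labeled_stack((labs > 0) * 200, labels = labs, pixel_size = 0.1,
                        frame_interval = 13)
  marker <- array(0L, c(H, H, nT))
  for (f in 3:9) marker[18:22, 14:16, f] <- 1L

  ev <- detect_events(track_components(mito))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "fission")
  expect_equal(ev$frame, 10)

  ia <- interaction_analysis(marker, mito, ev, fate_window = 2)
  expect_equal(nrow(ia$interactions), 1)
  expect_equal(ia$interactions$duration_s, 91)  # (9 - 3 + 1) * 13
  expect_identical(ia$interactions$fate, "useful")  # fission 1 frame later
  expect_equal(ia$mean_duration_s, 91)

  # tighter window: the same contact becomes futile
  ia0 <- interaction_analysis(marker, mito, ev, fate_window = 0)
  expect_identical(ia0$interactions$fate, "futile")

  # no events at all: futile by definition
  ia_none <- interaction_analysis(marker, mito, ev[0, ], fate_window = 2)
  expect_identical(ia_none$interactions$fate, "futile")

  expect_error(interaction_analysis(marker[, 1:10, ], mito, ev),
               "shape mismatch")
})

test_that("track propagation assigns persistent identities", {
  # two static blobs with frame-wise scrambled labels, plus a late arrival
  H <- 40; nT <- 4
  labs <- array(0L, c(H, H, nT))
  for (f in 1:nT) {
    a <- if (f %% 2 == 1) 1L else 2L  # swap label numbers every frame
    b <- if (f %% 2 == 1) 2L else 1L
    labs[5:10, 5:10, f] <- a
    labs[20:25, 20:25, f] <- b
  }
  labs[30:34, 30:34, 3:4] <- 3L  # appears at frame 3
  st <- labeled_stack((labs > 0) * 200, labels = labs, pixel_size = 0.1,
                      frame_interval = 13)
  persistent <- propagate_labels(track_components(st))
  # each blob keeps a single id over its lifetime
  idA <- unique(apply(persistent$labels[5:10, 5:10, ], 3, max))
  idB <- unique(apply(persistent$labels[20:25, 20:25, ], 3, max))
  idC <- unique(apply(persistent$labels[30:34, 30:34, 3:4], 3, max))
  expect_length(idA, 1)
  expect_length(idB, 1)
  expect_length(idC, 1)
  expect_length(unique(c(idA, idB, idC)), 3)
})
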