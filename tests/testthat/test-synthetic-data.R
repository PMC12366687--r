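test_that("population sampling respects weights, sides and seeds", {
  pop <- sample_population(1000, class_weights = c(0.21, 0.51, 0.28),
                           side_lengths = c(9, 19, 34), seed = 1)
  frac <- table(factor(vapply(pop, `[[`, "", "class_label"),
                       levels = c("i", "ii", "iii"))) / 1000
  expect_true(all(abs(as.numeric(frac) - c(0.21, 0.51, 0.28)) < 0.04))
  # class side lengths and exact equilateral invariant
  for (p in pop[1:25]) {
    expect_equal(p$side_length,
                 c(i = 9, ii = 19, iii = 34)[[p$class_label]])
    expect_equal(as.numeric(dist(p$vertex_positions_3d)),
                 rep(p$side_length, 3), tolerance = 1e-10)
    expect_true(all(p$dipole_azimuths >= 0 & p$dipole_azimuths < 180))
    expect_equal(p$kinetics$mean_off / p$kinetics$mean_on, 10)
  }
  # degenerate mixture and empty population
  pop_i <- sample_population(20, class_weights = c(1, 0, 0), seed = 2)
  expect_true(all(vapply(pop_i, `[[`, "", "class_label") == "i"))
  expect_identical(sample_population(0, seed = 3), list())
  # seeded runs are bit-reproducible
  expect_identical(sample_population(10, seed = 42),
                   sample_population(10, seed = 42))
})

test_that("invalid population parameters are rejected", {
  expect_error(sample_population(5, class_weights = c(0.5, 0.6, 0.2)),
               "sum to 1")
  expect_error(sample_population(5, class_weights = c(-0.1, 0.6, 0.5)),
               "non-negative")
  expect_error(sample_population(5, side_lengths = c(-1, 19, 34)),
               "positive")
  expect_error(sample_orientation("sideways"))
})

test_that("orientation sampling is uniform or in-plane biased as requested", {
  # extreme concentration collapses to in-plane
  set.seed(4)
  tilts <- replicate(50, {
    o <- sample_orientation("in_plane_biased", concentration = 1e8)
    max(o[2], o[3])
  })
  expect_true(all(tilts < 0.1))
  # finite concentration: mode of the pitch histogram in the 0-degree bin
  pitches <- replicate(2000, sample_orientation("in_plane_biased")[2])
  h <- hist(pitches, breaks = seq(0, 90, by = 5), plot = FALSE)
  expect_equal(which.max(h$counts), 1L)
  # uniform orientations match the view-grid oracle distributionally
  m <- max_side_uniform(2e4, side = 1, seed = 9)
  g <- max_side_view_grid(side = 1, n_theta = 200, n_phi = 400)
  ks <- suppressWarnings(stats::ks.test(m, g))$statistic
  expect_lt(as.numeric(ks), 0.02)
})

test_that("blinking kinetics reproduce the configured dwell and photon rates", {
  p <- sample_population(1, seed = 5)[[1]]
  sched <- simulate_blinking(p, n_frames = 1e5, frame_time = 0.014, seed = 6)
  on_t <- unlist(lapply(sched, attr, "on_times"))
  off_t <- unlist(lapply(sched, attr, "off_times"))
  ratio <- mean(off_t) / mean(on_t)
  expect_lt(abs(ratio - 10) / 10, 0.15)
  photons <- unlist(lapply(sched, `[[`, "photons"))
  expect_lt(abs(mean(photons) - 70) / 70, 0.10)  # 5000/s * 14 ms
})

test_that("polarization channel split follows Malus's law", {
  p <- sample_population(1, seed = 7)[[1]]
  # azimuth 0: all photons in channel 1
  p$dipole_azimuths <- c(0, 45, 90)
  sched <- simulate_blinking(p, n_frames = 5000, seed = 8)
  expect_true(all(sched[[1]]$counts_ch2 == 0))
  frac45 <- sum(sched[[2]]$counts_ch1) / sum(sched[[2]]$photons)
  expect_lt(abs(frac45 - 0.5), 0.05)
  expect_true(all(sched[[3]]$counts_ch1 == 0))
  # conservation: the two channels always sum to the drawn photon total
  for (s in sched)
    expect_identical(s$counts_ch1 + s$counts_ch2, s$photons)
})

test_that("emitted events sit on the schedule with the configured noise", {
  p <- sample_population(1, seed = 10)[[1]]
  sched <- simulate_blinking(p, n_frames = 2000, seed = 11)
  # zero noise: each fluorophore's events collapse onto one point
  ev0 <- emit_events(p, sched, localization_sd = 0, seed = 12)
  for (f in 0:2) {
    sub <- ev0[ev0$fluorophore_index == f, ]
    expect_lt(max(stats::sd(sub$x_nm), stats::sd(sub$y_nm)), 1e-12)
  }
  # events only on scheduled on-frames
  ev <- emit_events(p, sched, localization_sd = 10, seed = 13)
  for (f in 0:2) {
    sub <- ev[ev$fluorophore_index == f, ]
    expect_true(all(sub$frame %in% sched[[f + 1]]$frame))
  }
  # fitted per-axis SD close to the configured 10 nm (chi-square bounds:
  # sd of the SD estimate at n ~ 100 is ~ 7%, so 15% is a 2-sigma band)
  sub <- ev[ev$fluorophore_index == 0, ][seq_len(100), ]
  expect_lt(abs(stats::sd(sub$x_nm) - 10) / 10, 0.15)
  expect_lt(abs(stats::sd(sub$y_nm) - 10) / 10, 0.15)
})

test_that("event tables round-trip through the TSV format", {
  sim <- simulate_experiment(3, seed = 14)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(sim$events, path)
  back <- read_events(path)
  expect_equal(back$x_nm, sim$events$x_nm, tolerance = 1e-9)
  expect_identical(back$counts_ch1, sim$events$counts_ch1)
  truth_path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$particles, truth_path)
  tt <- utils::read.table(truth_path, header = TRUE, sep = "\t")
  expect_equal(nrow(tt), 3)
  expect_equal(tt$side_nm,
               vapply(sim$particles, `[[`, 0, "side_length"))
  # missing columns are rejected
  bad <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(a = 1), bad, sep = "\t", row.names = FALSE)
  expect_error(read_events(bad), "missing columns")
})
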