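test_that("window index arithmetic follows the rounding and clipping rules", {
  tr <- ramp_trial()
  sched <- frame_schedule()
  # constant trial: mean of a constant is the constant, any frame
  ct <- const_trial(7)
  for (k in c(1, 8, 16)) {
    expect_true(all(extract_frame_values(ct, k, sched) == 7))
  }
  # 256 Hz defaults: W = 32, start offset round(0.004 * 256) = 1 (0-based),
  # so frame 1 averages 0-based samples [1, 33) = 1-based 2:33
  expect_equal(unname(extract_frame_values(tr, 1, sched)[1]), mean(2:33))
  # frame 16: 0-based [481, 513) clipped to [481, 512) -> 31 samples
  expect_equal(unname(extract_frame_values(tr, 16, sched)[1]), mean(482:512))
  expect_error(extract_frame_values(tr, 17, sched), "n_frames")
  expect_error(extract_frame_values(tr, 0, sched), "n_frames")
  # a window entirely past the trial end errors
  short <- trial_recording(matrix(1, 15, 100), 256, "x", "s", frontal_subset())
  expect_error(extract_frame_values(short, 16, sched), "frame out of range")
})

test_that("IDW interpolation is node-exact, convex and symmetric", {
  m2d <- frontal_m2d()
  n <- length(m2d$labels)
  # constant field identity
  fld <- interpolate_scalp(rep(3.2, n), m2d, grid_size = 32)
  expect_true(all(abs(fld$grid[fld$mask] - 3.2) < 1e-9))
  # convexity: all masked values within electrode range
  set.seed(11)
  for (rep in 1:3) {
    v <- rnorm(n)
    fld <- interpolate_scalp(v, m2d, grid_size = 32)
    expect_true(all(fld$grid[fld$mask] >= min(v) - 1e-12))
    expect_true(all(fld$grid[fld$mask] <= max(v) + 1e-12))
  }
  # node exactness: electrode placed exactly at a pixel center takes its value
  centers <- -1 + (2 * seq_len(8) - 1) / 8
  m_art <- structure(list(labels = c("a", "b"),
                          positions2d = rbind(c(centers[6], centers[3]),
                                              c(-0.3, -0.3))),
                     class = "montage2d")
  fld2 <- interpolate_scalp(c(42, 7), m_art, grid_size = 8)
  expect_equal(fld2$grid[8 - 3 + 1, 6], 42)
  # mirrored values on the symmetric montage give a mirror-symmetric field
  pairs <- rbind(c("F3", "F4"), c("F5", "F6"), c("F1", "F2"), c("F7", "F8"),
                 c("Fp1", "Fp2"), c("AF3", "AF4"), c("AF7", "AF8"))
  v <- rnorm(n)
  vm <- v
  for (i in seq_len(nrow(pairs))) {
    a <- which(m2d$labels == pairs[i, 1])
    b <- which(m2d$labels == pairs[i, 2])
    vm[c(a, b)] <- v[c(b, a)]
  }
  f1 <- interpolate_scalp(v, m2d, grid_size = 32)
  f2 <- interpolate_scalp(vm, m2d, grid_size = 32)
  mirrored <- f2$grid[, 32:1]
  both <- f1$mask & f2$mask[, 32:1]
  expect_lt(max(abs(f1$grid[both] - mirrored[both])), 1e-6)
  # errors
  expect_error(interpolate_scalp(rep(1, n - 1), m2d), "length")
  m_dup <- structure(list(labels = c("a", "b"),
                          positions2d = rbind(c(0.1, 0.1), c(0.1, 0.1))),
                     class = "montage2d")
  expect_error(interpolate_scalp(c(1, 2), m_dup), "duplicate")
})

test_that("RGB rendering follows the fixed colormap with white background", {
  g <- 16
  grid <- matrix(NA_real_, g, g)
  mask <- matrix(FALSE, g, g)
  mask[4:12, 4:12] <- TRUE
  grid[mask] <- 0
  fld <- structure(list(grid = grid, mask = mask), class = "scalar_field")
  # u = 0.5 at v = 0: colormap gives (0.5, 1, 0.5)
  fr <- render_rgb(fld, vmax = 2)
  expect_equal(fr[8, 8, ], c(0.5, 1, 0.5))
  # v = -vmax -> u = 0 -> (0, 0, 0.5); v = +vmax -> u = 1 -> (0.5, 0, 0)
  grid[mask] <- -2
  fr <- render_rgb(structure(list(grid = grid, mask = mask),
                             class = "scalar_field"), vmax = 2)
  expect_equal(fr[8, 8, ], c(0, 0, 0.5))
  grid[mask] <- 2
  fr <- render_rgb(structure(list(grid = grid, mask = mask),
                             class = "scalar_field"), vmax = 2)
  expect_equal(fr[8, 8, ], c(0.5, 0, 0))
  # outside the head: white
  expect_equal(fr[1, 1, ], c(1, 1, 1))
  expect_error(render_rgb(fld, vmax = 0), "vmax")
})

test_that("trial_to_sequence yields n_frames frames in [0,1] with trial-level scaling", {
  set.seed(5)
  tr <- trial_recording(matrix(rnorm(15 * 512), 15), 256, "hello", "S01",
                        frontal_subset())
  s <- trial_to_sequence(tr)
  expect_s3_class(s, "topomap_sequence")
  expect_equal(dim(s$frames), c(16, 64, 64, 3))
  expect_true(all(s$frames >= 0 & s$frames <= 1))
  expect_identical(s$label, "hello")
  # all-zero trial: every frame identical, mid-scale inside the head
  z <- trial_recording(matrix(0, 15, 512), 256, "x", "s", frontal_subset())
  sz <- trial_to_sequence(z, grid_size = 16)
  for (k in 2:16) expect_equal(sz$frames[k, , , ], sz$frames[1, , , ])
  expect_equal(sz$frames[1, 8, 8, ], c(0.5, 1, 0.5))
  # monotone contrast: scaling the trial by c > 0 leaves frames unchanged
  tr2 <- tr
  tr2$data <- tr$data * 3.7
  s2 <- trial_to_sequence(tr2, grid_size = 16)
  s1 <- trial_to_sequence(tr, grid_size = 16)
  expect_equal(s2$frames, s1$frames, tolerance = 1e-12)
  # determinism: bit-identical repeat
  expect_identical(trial_to_sequence(tr, grid_size = 16)$frames, s1$frames)
  # channel order must not matter (matched by name)
  perm <- sample(15)
  trp <- trial_recording(tr$data[perm, ], 256, "hello", "S01",
                         frontal_subset()[perm])
  expect_equal(trial_to_sequence(trp, grid_size = 16)$frames, s1$frames)
  # missing channel errors
  tr_bad <- trial_recording(tr$data[1:14, ], 256, "x", "s",
                            frontal_subset()[1:14])
  expect_error(trial_to_sequence(tr_bad), "missing montage channel")
})

test_that("quantization roundtrip lands on the 8-bit lattice", {
  set.seed(3)
  tr <- trial_recording(matrix(rnorm(15 * 512), 15), 256, "w", "s",
                        frontal_subset())
  s <- quantize_roundtrip(trial_to_sequence(tr, grid_size = 16))
  expect_true(all(abs(s$frames * 255 - round(s$frames * 255)) < 1e-9))
  expect_true(all(s$frames >= 0 & s$frames <= 1))
  # specific bytes
  sq <- structure(list(frames = array(c(0, 1, 0.5), c(1, 1, 1, 3)),
                       label = "x", subject = "s"), class = "topomap_sequence")
  q <- quantize_roundtrip(sq)
  expect_equal(as.vector(q$frames), c(0, 1, 128 / 255))
})
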