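test_that("code table frequencies and phases follow the arithmetic ladders", {
  tab <- build_code_table(fixation_points())
  one <- tab[tab$fixation == "right", ]
  expect_equal(nrow(one), 40L)
  expect_equal(one$frequency_hz, 8 + 0.2 * (0:39), tolerance = 1e-12)
  expect_lt(max(abs(one$frequency_hz - (8 + 0.2 * (one$flicker_index - 1)))), 1e-9)
  expect_lt(max(abs(one$phase_rad - (0.35 * pi * (one$flicker_index - 1)) %% (2 * pi))), 1e-9)
  # endpoints
  expect_equal(one$frequency_hz[1], 8)
  expect_equal(one$frequency_hz[40], 15.8)
  expect_equal(one$phase_rad[1], 0)
  expect_equal(one$phase_rad[40], 1.65 * pi, tolerance = 1e-9)
  # adjacent flickers differ in phase by 0.35*pi (mod 2*pi)
  dphase <- diff(one$phase_rad) %% (2 * pi)
  expect_true(all(abs(dphase - 0.35 * pi) < 1e-9))
})

test_that("code tables have 40*n unique codes and nested label spaces", {
  for (n in 1:5) {
    for (combo in enumerate_fixation_combos(n)) {
      tab <- build_code_table(combo)
      expect_equal(nrow(tab), 40L * n)
      expect_equal(tab$target_id, seq_len(40L * n))
      key <- paste(tab$frequency_hz, round(tab$phase_rad, 9), tab$fixation)
      expect_equal(anyDuplicated(key), 0L)
      # ids 1..40 are the pure frequency-phase task under the first fixation
      expect_equal(tab$fixation[1:40], rep(combo$members[1], 40))
      expect_equal(tab$flicker_index[1:40], 1:40)
    }
  }
})

test_that("fixation combinations match the published enumeration", {
  counts <- vapply(1:5, function(n) length(enumerate_fixation_combos(n)), 0L)
  expect_equal(counts, c(5L, 10L, 10L, 5L, 1L))
  expect_equal(enumerate_fixation_combos(1)[[1]]$members, "right")
  expect_equal(vapply(enumerate_fixation_combos(1), function(cb) cb$members, ""),
               c("right", "down", "left", "up", "center"))
  expect_equal(enumerate_fixation_combos(2)[[6]]$members, c("down", "up"))
  expect_equal(enumerate_fixation_combos(5)[[1]]$members,
               c("right", "down", "left", "up", "center"))
  expect_error(enumerate_fixation_combos(0), "1..5")
  expect_error(enumerate_fixation_combos(6), "1..5")
})

test_that("invalid fixation names are rejected with the allowed set", {
  expect_error(build_code_table(c("down", "diagonal")), "right, down, left, up, center")
})

test_that("stimulus waveforms follow sampled sinusoidal modulation", {
  c10 <- list(frequency_hz = 10, phase_rad = 0)
  w <- stimulus_waveform(c10, duration = 1, refresh = 240)
  expect_length(w, 240L)
  expect_equal(w[1], 0.5)
  # 24 frames per cycle at 240 Hz
  expect_equal(w[1:100], w[25:124], tolerance = 1e-12)
  w2 <- stimulus_waveform(list(frequency_hz = 10, phase_rad = pi / 2), 0.1, 240)
  expect_equal(w2[1], 1.0)
  # bounded in [0, 1] for every code in the table
  tab <- build_code_table("center")
  for (i in c(1, 20, 40)) {
    wi <- stimulus_waveform(tab[i, ], duration = 0.5, refresh = 240)
    expect_true(all(wi >= 0 & wi <= 1))
  }
  expect_error(stimulus_waveform(list(frequency_hz = 130, phase_rad = 0), 1, 240),
               "twice the stimulus frequency")
  expect_error(stimulus_waveform(c10, duration = -1), "positive")
})

test_that("layout geometry places the 5x8 grid and fixation offsets", {
  lay <- stimulus_layout()
  expect_equal(lay$fixation_offset, round(0.25 * lay$flicker_edge))
  expect_equal(lay$fixation_offset, 36L)
  geo <- layout_geometry(lay)
  expect_equal(nrow(geo$flickers), 40L)
  # column-major traversal: flicker 2 is below flicker 1, flicker 6 starts
  # the next column
  expect_equal(geo$flickers$grid_row[1:6], c(1L, 2L, 3L, 4L, 5L, 1L))
  expect_equal(geo$flickers$grid_col[6], 2L)
  # horizontal pitch = edge + gap
  expect_equal(geo$flickers$center_x[6] - geo$flickers$center_x[1], 194)
  expect_equal(geo$flickers$center_y[2] - geo$flickers$center_y[1], 194)
  off <- geo$fixation_offsets
  expect_equal(off$dx[off$fixation == "up"], 0L)
  expect_equal(off$dy[off$fixation == "up"], -36L)
  expect_equal(off$dy[off$fixation == "down"], 36L)
  expect_equal(unlist(off[off$fixation == "center", c("dx", "dy")],
                      use.names = FALSE), c(0L, 0L))
  # bounding boxes stay on screen
  half <- lay$flicker_edge / 2
  expect_true(all(geo$flickers$center_x - half >= 0))
  expect_true(all(geo$flickers$center_x + half <= lay$screen_px[1]))
  expect_true(all(geo$flickers$center_y + half <= lay$screen_px[2]))
  expect_error(stimulus_layout(flicker_edge = 400), "exceeds the screen")
})

test_that("code table CSV round-trips with the canonical header", {
  tab <- build_code_table(c("right", "left"))
  f <- tempfile(fileext = ".csv")
  write_code_table(tab, f)
  expect_equal(readLines(f, n = 1),
               "target_id,flicker_index,frequency_hz,phase_rad,fixation")
  back <- read_code_table(f)
  expect_equal(back$target_id, tab$target_id)
  expect_equal(back$frequency_hz, tab$frequency_hz, tolerance = 1e-12)
  expect_equal(back$fixation, tab$fixation)
  expect_error(read_code_table(write_montage(load_configuration("9/64"),
                                             tempfile())), "code table")
})
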