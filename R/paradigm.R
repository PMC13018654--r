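#' Fixation point positions of the frequency-phase-space paradigm
#'
#' The spatial code dimension of the paradigm: five cross-shaped fixation
#' markers embedded in each flicker, one on each half-axis plus the center.
#'
#' @return Character vector of the five fixation names, in the canonical
#'   order `right, down, left, up, center`.
#' @export
fixation_points <- function() {
  c("right", "down", "left", "up", "center")
}

check_fixations <- function(fix) {
  fix <- tolower(as.character(fix))
  bad <- setdiff(fix, fixation_points())
  if (length(bad) > 0L) {
    stop("unknown fixation name(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(fixation_points(), collapse = ", "),
         call. = FALSE)
  }
  fix
}

# Fixation combinations for 1..5 fixation points, row by row. Combination
# labels index the rows; members are kept in the listed order.
fixation_combo_rows <- list(
  `1` = list("right", "down", "left", "up", "center"),
  `2` = list(c("right", "down"), c("right", "left"), c("right", "up"),
             c("right", "center"), c("down", "left"), c("down", "up"),
             c("down", "center"), c("left", "up"), c("left", "center"),
             c("up", "center")),
  `3` = list(c("left", "up", "center"), c("down", "up", "center"),
             c("down", "left", "center"), c("down", "left", "up"),
             c("right", "up", "center"), c("right", "left", "center"),
             c("right", "left", "up"), c("right", "down", "center"),
             c("right", "down", "up"), c("right", "down", "left")),
  `4` = list(c("right", "down", "left", "up"),
             c("right", "down", "left", "center"),
             c("right", "down", "up", "center"),
             c("right", "left", "up", "center"),
             c("down", "left", "up", "center")),
  `5` = list(c("right", "down", "left", "up", "center"))
)

#' Enumerate fixation-point combinations
#'
#' Lists every combination of fixation points available for a given number of
#' fixation points per flicker. With 40 flickers, `n_fixations` of 1..5 yields
#' BCI systems with 40, 80, 120, 160 and 200 targets; the number of
#' combinations is 5, 10, 10, 5 and 1 respectively.
#'
#' @param n_fixations Integer in 1..5, the number of fixation points used.
#' @return A list of `fixation_combo` objects, each with elements
#'   `n_fixations`, `members` (ordered character vector) and `combo_label`
#'   (integer row label).
#' @export
enumerate_fixation_combos <- function(n_fixations) {
  if (length(n_fixations) != 1L || is.na(n_fixations) ||
      n_fixations != as.integer(n_fixations) ||
      n_fixations < 1L || n_fixations > 5L) {
    stop("n_fixations must be a single integer in 1..5", call. = FALSE)
  }
  rows <- fixation_combo_rows[[as.character(as.integer(n_fixations))]]
  lapply(seq_along(rows), function(i) {
    structure(list(n_fixations = as.integer(n_fixations),
                   members = rows[[i]],
                   combo_label = as.integer(i)),
              class = "fixation_combo")
  })
}

#' @export
print.fixation_combo <- function(x, ...) {
  cat(sprintf("fixation combo %d/%d: {%s}\n", x$combo_label, x$n_fixations,
              paste(x$members, collapse = ", ")))
  invisible(x)
}

as_fixation_combo <- function(combo) {
  if (inherits(combo, "fixation_combo")) return(combo)
  members <- check_fixations(combo)
  if (anyDuplicated(members)) stop("duplicate fixation names", call. = FALSE)
  n <- length(members)
  combos <- enumerate_fixation_combos(n)
  for (cb in combos) {
    if (setequal(cb$members, members)) {
      cb$members <- members  # keep the caller's ordering
      return(cb)
    }
  }
  stop("no such fixation combination", call. = FALSE)
}

#' Build the frequency-phase-space code table
#'
#' Assigns each of the 40 flickers its stimulation frequency and phase, and
#' crosses them with the requested fixation points. Frequencies run from 8 to
#' 15.8 Hz in 0.2-Hz steps and phases from 0 in 0.35*pi steps (mod 2*pi),
#' following the flicker order (down each column of the 5 x 8 grid, then the
#' next column). Target ids are assigned so that all 40 flickers under the
#' first fixation of the combination occupy ids 1..40, the second fixation
#' 41..80, and so on: the 40-class frequency-phase label space is nested in
#' the larger space.
#'
#' @param combo A `fixation_combo` (see [enumerate_fixation_combos()]) or a
#'   character vector of fixation names.
#' @param n_fixations Optional integer; when given it must equal the size of
#'   `combo`.
#' @return A `ssvep_code_table` data frame with columns `target_id`,
#'   `flicker_index`, `frequency_hz`, `phase_rad`, `fixation`.
#' @examples
#' head(build_code_table(c("down", "up")))
#' @export
build_code_table <- function(combo = fixation_points(), n_fixations = NULL) {
  combo <- as_fixation_combo(combo)
  if (!is.null(n_fixations) && as.integer(n_fixations) != combo$n_fixations) {
    stop("n_fixations does not match the size of the fixation combination",
         call. = FALSE)
  }
  flick <- 1:40
  freq <- 8 + 0.2 * (flick - 1)
  phase <- (0.35 * pi * (flick - 1)) %% (2 * pi)
  tab <- do.call(rbind, lapply(seq_along(combo$members), function(j) {
    data.frame(target_id = (j - 1L) * 40L + flick,
               flicker_index = flick,
               frequency_hz = freq,
               phase_rad = phase,
               fixation = combo$members[j],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(tab, class = c("ssvep_code_table", "data.frame"),
            combo_label = combo$combo_label,
            n_fixations = combo$n_fixations)
}

#' Per-frame stimulus luminance of a coded flicker
#'
#' Sampled sinusoidal stimulation: the luminance of frame `n` (0-based) is
#' `0.5 * (1 + sin(2*pi*f*n/refresh + phase))`, evaluated at the frame start.
#'
#' @param code One row of a code table (or any list with `frequency_hz` and
#'   `phase_rad`).
#' @param duration Stimulus duration in seconds.
#' @param refresh Display refresh rate in Hz; must exceed twice the stimulus
#'   frequency.
#' @return Numeric vector of luminances in \[0, 1\], length
#'   `round(duration * refresh)`.
#' @export
stimulus_waveform <- function(code, duration, refresh = 240) {
  f <- as.numeric(code$frequency_hz)
  phi <- as.numeric(code$phase_rad)
  if (!is.finite(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  if (refresh <= 2 * f) {
    stop(sprintf("refresh rate %g Hz must exceed twice the stimulus frequency (%g Hz)",
                 refresh, f), call. = FALSE)
  }
  n <- seq_len(round(duration * refresh)) - 1
  0.5 * (1 + sin(2 * pi * f * n / refresh + phi))
}

#' Stimulus layout parameters
#'
#' Geometry of the 5 x 8 flicker matrix on the presentation display. Defaults
#' reproduce the study interface: 144-pixel flickers separated by 50-pixel
#' gaps on a 1920 x 1080 screen at 240 Hz, fixation points offset by 25% of
#' the flicker edge (36 px), viewed from 70 cm.
#'
#' @param grid_rows,grid_cols Flicker grid size.
#' @param flicker_edge Flicker edge length in pixels.
#' @param flicker_gap Gap between adjacent flickers in pixels.
#' @param fixation_offset Offset of the lateral fixation points from the
#'   flicker center, in pixels; defaults to `round(0.25 * flicker_edge)`.
#' @param screen_px Screen size `c(width, height)` in pixels.
#' @param refresh Refresh rate in Hz.
#' @param viewing_distance_cm Viewing distance in cm.
#' @param flicker_deg,fixation_deg Visual angles of a flicker and a fixation
#'   point, in degrees (descriptive metadata).
#' @return A `stimulus_layout` list.
#' @export
stimulus_layout <- function(grid_rows = 5L, grid_cols = 8L,
                            flicker_edge = 144L, flicker_gap = 50L,
                            fixation_offset = round(0.25 * flicker_edge),
                            screen_px = c(1920L, 1080L), refresh = 240,
                            viewing_distance_cm = 70,
                            flicker_deg = 3.3, fixation_deg = 0.23) {
  lay <- structure(list(grid_rows = as.integer(grid_rows),
                        grid_cols = as.integer(grid_cols),
                        flicker_edge = as.integer(flicker_edge),
                        flicker_gap = as.integer(flicker_gap),
                        fixation_offset = as.integer(fixation_offset),
                        screen_px = as.integer(screen_px),
                        refresh = refresh,
                        viewing_distance_cm = viewing_distance_cm,
                        flicker_deg = flicker_deg,
                        fixation_deg = fixation_deg),
                   class = "stimulus_layout")
  w <- lay$grid_cols * lay$flicker_edge + (lay$grid_cols - 1L) * lay$flicker_gap
  h <- lay$grid_rows * lay$flicker_edge + (lay$grid_rows - 1L) * lay$flicker_gap
  if (w > lay$screen_px[1] || h > lay$screen_px[2]) {
    stop(sprintf("flicker matrix (%d x %d px) exceeds the screen (%d x %d px)",
                 w, h, lay$screen_px[1], lay$screen_px[2]), call. = FALSE)
  }
  if (lay$flicker_gap < 0L) stop("flicker_gap must be non-negative", call. = FALSE)
  lay
}

#' Pixel geometry of flicker centers and fixation points
#'
#' Places the 40 flickers on the 5 x 8 grid (centered on the screen) and
#' returns the pixel coordinates of each flicker center together with the
#' fixation-point offsets. Flicker indices traverse the grid down each column
#' and then left to right, matching the order in which frequency and phase
#' increase. Screen coordinates have the origin at the top-left corner with y
#' increasing downwards.
#'
#' @param layout A [stimulus_layout()].
#' @return A list with `flickers` (data frame: `flicker_index`, `grid_row`,
#'   `grid_col`, `center_x`, `center_y`) and `fixation_offsets` (data frame:
#'   `fixation`, `dx`, `dy`).
#' @export
layout_geometry <- function(layout = stimulus_layout()) {
  stopifnot(inherits(layout, "stimulus_layout"))
  pitch <- layout$flicker_edge + layout$flicker_gap
  w <- layout$grid_cols * layout$flicker_edge +
    (layout$grid_cols - 1L) * layout$flicker_gap
  h <- layout$grid_rows * layout$flicker_edge +
    (layout$grid_rows - 1L) * layout$flicker_gap
  x0 <- (layout$screen_px[1] - w) / 2 + layout$flicker_edge / 2
  y0 <- (layout$screen_px[2] - h) / 2 + layout$flicker_edge / 2
  idx <- seq_len(layout$grid_rows * layout$grid_cols)
  grid_row <- (idx - 1L) %% layout$grid_rows + 1L
  grid_col <- (idx - 1L) %/% layout$grid_rows + 1L
  flickers <- data.frame(flicker_index = idx,
                         grid_row = grid_row,
                         grid_col = grid_col,
                         center_x = x0 + (grid_col - 1L) * pitch,
                         center_y = y0 + (grid_row - 1L) * pitch)
  off <- layout$fixation_offset
  fixation_offsets <- data.frame(fixation = fixation_points(),
                                 dx = c(off, 0L, -off, 0L, 0L),
                                 dy = c(0L, off, 0L, -off, 0L))
  list(flickers = flickers, fixation_offsets = fixation_offsets)
}

#' Write / read a code table as CSV
#'
#' The CSV has the header `target_id,flicker_index,frequency_hz,phase_rad,fixation`.
#'
#' @param tab A `ssvep_code_table`.
#' @param path File path.
#' @export
write_code_table <- function(tab, path) {
  cols <- c("target_id", "flicker_index", "frequency_hz", "phase_rad", "fixation")
  stopifnot(all(cols %in% names(tab)))
  utils::write.csv(as.data.frame(tab)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_code_table
#' @export
read_code_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("target_id", "flicker_index", "frequency_hz", "phase_rad", "fixation")
  if (!all(cols %in% names(tab))) {
    stop("not a code table CSV: expected columns ",
         paste(cols, collapse = ","), call. = FALSE)
  }
  check_fixations(tab$fixation)
  structure(tab[, cols], class = c("ssvep_code_table", "data.frame"))
}
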