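#' @name montage
#' @title Idealized electrode montages
#'
#' @description
#' Electrode positions are modelled on a spherical head of radius 9.2 cm.
#' Standard caps are laid out after the extended 10-10 / 10-5 nomenclature:
#' sagittal rows run from the frontal pole to the inion in 18-degree (10-10)
#' or 9-degree (10-5) steps of polar angle, and lateral positions within each
#' row sit at fixed fractions of the arc from the midline electrode to the
#' row's endpoint on the 10% circumference circle ("h"-suffixed names mark
#' half-step positions). Cerebellar (CB), mastoid (M) and sub-ring ("9"/"10")
#' sites are placed explicitly. The layout is an idealized stand-in for the
#' commercial cap geometry: adequate for distance summaries and for the
#' spatial-gain and noise-kernel models of the synthetic generator, not
#' claimed to be subject-accurate.
NULL

ideal_head_radius_cm <- 9.2

deg2rad <- function(d) d * pi / 180

# direction of the midline electrode at sagittal angle u (degrees from the
# vertex, posterior positive, anterior negative)
midline_dir <- function(u) {
  u <- deg2rad(u)
  c(0, -sin(u), cos(u))
}

# direction of a point on the circle at `polar` degrees from the vertex, at
# azimuth `phi` degrees from the anterior midline; positive phi is the left
# hemisphere (x negative), mirrored for the right
ring_dir <- function(phi, polar = 72, right = FALSE) {
  phi <- deg2rad(phi); polar <- deg2rad(polar)
  x <- -sin(polar) * sin(phi)
  if (right) x <- -x
  c(x, sin(polar) * cos(phi), cos(polar))
}

# spherical interpolation between two unit vectors
slerp <- function(p, q, t) {
  om <- acos(max(-1, min(1, sum(p * q))))
  if (om < 1e-12) return(p)
  (sin((1 - t) * om) * p + sin(t * om) * q) / sin(om)
}

lateral_dir <- function(u, frac, right = FALSE) {
  slerp(midline_dir(u), ring_dir(90 + u, right = right), frac)
}

# row table: prefix, sagittal angle, lateral suffixes with arc fractions and
# (for positions whose endpoint carries a different prefix, e.g. T7 on the C
# row) an optional name override
cap_row <- function(prefix, u, suffix = character(), frac = numeric(),
                    name_left = NULL, name_right = NULL, midline = TRUE) {
  list(prefix = prefix, u = u, suffix = suffix, frac = frac,
       name_left = name_left, name_right = name_right, midline = midline)
}

row_electrodes <- function(row) {
  out <- list()
  if (row$midline) {
    out[[length(out) + 1L]] <- list(name = paste0(row$prefix, "z"),
                                    dir = midline_dir(row$u), u = row$u)
  }
  for (k in seq_along(row$suffix)) {
    sfx <- row$suffix[k]
    nl <- if (!is.null(row$name_left) && !is.na(row$name_left[k])) {
      row$name_left[k]
    } else {
      paste0(row$prefix, sfx)
    }
    nr <- if (!is.null(row$name_right) && !is.na(row$name_right[k])) {
      row$name_right[k]
    } else {
      # right-hemisphere suffix: odd index -> even index, keep any h marker
      idx <- as.integer(sub("h$", "", sfx))
      paste0(row$prefix, idx + 1L, if (grepl("h$", sfx)) "h" else "")
    }
    out[[length(out) + 1L]] <- list(name = nl,
                                    dir = lateral_dir(row$u, row$frac[k]),
                                    u = row$u)
    out[[length(out) + 1L]] <- list(name = nr,
                                    dir = lateral_dir(row$u, row$frac[k], right = TRUE),
                                    u = row$u)
  }
  out
}

# explicitly placed electrodes: polar angle from vertex, azimuth from the
# anterior midline (pairs are mirrored left/right)
explicit_pair <- function(name_left, name_right, polar, phi, posterior = TRUE) {
  list(list(name = name_left, dir = ring_dir(phi, polar = polar), u = if (posterior) 90 else -90),
       list(name = name_right, dir = ring_dir(phi, polar = polar, right = TRUE), u = if (posterior) 90 else -90))
}

cap64_rows <- function() {
  q <- c(0.25, 0.5, 0.75, 1)
  list(
    cap_row("Fp", -72, "1", 1),
    cap_row("AF", -54, "3", 0.5),
    cap_row("F", -36, c("3", "5", "7"), c(1 / 3, 2 / 3, 1)),
    cap_row("FC", -18, c("1", "3", "5", "7"), q,
            name_left = c(NA, NA, NA, "FT7"), name_right = c(NA, NA, NA, "FT8")),
    cap_row("C", 0, c("1", "3", "5", "7"), q,
            name_left = c(NA, NA, NA, "T7"), name_right = c(NA, NA, NA, "T8")),
    cap_row("CP", 18, c("1", "3", "5", "7"), q,
            name_left = c(NA, NA, NA, "TP7"), name_right = c(NA, NA, NA, "TP8")),
    cap_row("P", 36, c("1", "3", "5", "7"), q),
    cap_row("PO", 54, c("3", "5", "7"), c(1 / 3, 2 / 3, 1)),
    cap_row("O", 72, "1", 1)
  )
}

cap128_extra_rows <- function() {
  tq <- c(0.25, 0.5, 0.75)
  tt <- c(1 / 3, 2 / 3, 1)
  list(
    cap_row("AFp", -63, "1", 0.45, midline = FALSE),
    cap_row("AFF", -45, c("1", "3", "5"), tt),
    cap_row("FFC", -27, c("1", "3", "5"), tq),
    cap_row("FCC", -9, c("1", "3", "5"), tq),
    cap_row("CCP", 9, c("1", "3", "5"), tq),
    cap_row("CPP", 27, c("1", "3", "5"), tq),
    cap_row("PPO", 45, c("1", "3", "5"), tt),
    cap_row("POO", 63, c("1", "3"), c(0.5, 1)),
    cap_row("OI", 81, "1", 0.85)
  )
}

cap256_extra_rows <- function() {
  h3 <- c(1 / 6, 0.5, 5 / 6)
  h4 <- c(0.125, 0.375, 0.625, 0.875)
  list(
    cap_row("Fp", -72, "1h", 0.5, midline = FALSE),
    cap_row("AFp", -63, "3", 0.9, midline = FALSE),
    cap_row("AF", -54, c("1", "5"), c(0.25, 0.75), midline = FALSE),
    cap_row("F", -36, c("1h", "3h", "5h"), h3, midline = FALSE),
    cap_row("AFF", -45, c("1h", "3h", "5h"), h3, midline = FALSE),
    cap_row("FFC", -27, c("1h", "3h", "5h", "7"), c(h4[1:3], 1), midline = FALSE),
    cap_row("FCC", -9, c("1h", "3h", "5h", "7"), c(h4[1:3], 1), midline = FALSE),
    cap_row("CCP", 9, c("1h", "3h", "5h", "7"), c(h4[1:3], 1), midline = FALSE),
    cap_row("CPP", 27, c("1h", "3h", "5h", "7"), c(h4[1:3], 1), midline = FALSE),
    cap_row("FFC", -27, "7h", 0.875, midline = FALSE),
    cap_row("FCC", -9, "7h", 0.875, midline = FALSE),
    cap_row("FC", -18, c("1h", "3h", "5h", "7h"), h4, midline = FALSE),
    cap_row("C", 0, c("1h", "3h", "5h", "7h"), h4, midline = FALSE),
    cap_row("CP", 18, c("1h", "3h", "5h", "7h"), h4, midline = FALSE),
    cap_row("P", 36, c("1h", "3h", "5h", "7h"), h4, midline = FALSE),
    cap_row("PPO", 45, c("1h", "3h", "5h"), h3, midline = FALSE),
    cap_row("PO", 54, c("1h", "3h", "5h"), h3, midline = FALSE),
    cap_row("POO", 63, c("1h", "3h"), c(0.25, 0.75), midline = FALSE),
    cap_row("O", 72, "1h", 0.5, midline = FALSE)
  )
}

assemble_cap <- function(rows, extras = list(), singles = list()) {
  elec <- list()
  for (r in rows) elec <- c(elec, row_electrodes(r))
  for (p in extras) elec <- c(elec, p)
  elec <- c(elec, singles)
  name <- vapply(elec, `[[`, "", "name")
  stopifnot(!anyDuplicated(name))
  dir <- t(vapply(elec, `[[`, numeric(3), "dir"))
  u <- vapply(elec, `[[`, 0, "u")
  data.frame(name = name,
             x_cm = ideal_head_radius_cm * dir[, 1],
             y_cm = ideal_head_radius_cm * dir[, 2],
             z_cm = ideal_head_radius_cm * dir[, 3],
             sagittal_deg = u,
             stringsAsFactors = FALSE)
}

#' Build an idealized standard EEG cap
#'
#' @param cap_total One of 64, 128 or 256: the nominal channel count of the
#'   commercial cap being idealized. The three caps are nested
#'   (64-cap channels are a subset of the 128-cap, which is a subset of the
#'   256-cap).
#' @return Data frame `name, x_cm, y_cm, z_cm, sagittal_deg` on a 9.2-cm
#'   spherical head (x right, y anterior, z up).
#' @export
build_cap <- function(cap_total = 256) {
  cap_total <- as.integer(cap_total)
  iz <- list(list(name = "Iz", dir = midline_dir(90), u = 90))
  cb <- explicit_pair("CB1", "CB2", 87, 168)
  mast <- explicit_pair("M1", "M2", 100, 100, posterior = FALSE)
  cap64 <- assemble_cap(cap64_rows(), extras = list(cb, mast), singles = iz)
  if (cap_total == 64L) return(cap64)

  extras128 <- list(explicit_pair("AF7", "AF8", 72, 36),
                    explicit_pair("P9", "P10", 81, 126),
                    explicit_pair("PO9", "PO10", 81, 144),
                    explicit_pair("FT9", "FT10", 81, 72),
                    explicit_pair("TP9", "TP10", 81, 108),
                    explicit_pair("T9", "T10", 81, 90))
  cap128 <- rbind(cap64,
                  assemble_cap(cap128_extra_rows(),
                               extras = extras128, singles = list()))
  stopifnot(!anyDuplicated(cap128$name))
  if (cap_total == 128L) return(cap128)

  extras256 <- list(explicit_pair("F9", "F10", 81, 54),
                    explicit_pair("AFF9", "AFF10", 81, 45),
                    explicit_pair("FFC9", "FFC10", 81, 63),
                    explicit_pair("FCC9", "FCC10", 81, 81),
                    explicit_pair("CCP9", "CCP10", 81, 99),
                    explicit_pair("CPP9", "CPP10", 81, 117),
                    explicit_pair("PPO9", "PPO10", 81, 135),
                    explicit_pair("POO9", "POO10", 81, 153),
                    explicit_pair("I1", "I2", 90, 162),
                    explicit_pair("I3", "I4", 90, 144),
                    explicit_pair("CB1h", "CB2h", 90, 171))
  cap256 <- rbind(cap128,
                  assemble_cap(cap256_extra_rows(),
                               extras = extras256, singles = list()))
  stopifnot(!anyDuplicated(cap256$name))
  if (cap_total == 256L) return(cap256)
  stop("cap_total must be 64, 128 or 256", call. = FALSE)
}

# posterior (parieto-occipital) pool of a cap: every channel at or behind the
# P row, cerebellar and sub-ring posterior sites included
posterior_pool <- function(cap) {
  post_rows <- cap$sagittal_deg >= 36 & cap$y_cm < 0
  cap$name[post_rows & !(cap$name %in% c("M1", "M2"))]
}

baseline9_channels <- c("Pz", "POz", "Oz", "PO3", "PO4", "PO5", "PO6",
                        "O1", "O2")

dist_from <- function(cap, names, ref = "POz") {
  p <- as.matrix(cap[match(names, cap$name), c("x_cm", "y_cm", "z_cm")])
  r <- as.numeric(cap[cap$name == ref, c("x_cm", "y_cm", "z_cm")])
  sqrt(colSums((t(p) - r)^2))
}

#' Channel lists of the four study electrode configurations
#'
#' Computes the parieto-occipital channel list of a configuration from the
#' idealized caps: the posterior pool (P row and behind) is ranked by
#' distance from POz and trimmed to the configuration's channel count. The
#' 9/64 list is the fixed baseline set; the 66/256 list is forced to contain
#' the 21/64 and 32/128 lists so the reduced configurations are subsets.
#'
#' @param label One of "66/256", "32/128", "21/64", "9/64".
#' @return Character vector of channel names.
#' @export
montage_configuration_channels <- function(label) {
  spec <- switch(label,
                 "9/64" = list(n = 9L, cap = 64L),
                 "21/64" = list(n = 21L, cap = 64L),
                 "32/128" = list(n = 32L, cap = 128L),
                 "66/256" = list(n = 66L, cap = 256L),
                 stop("unknown configuration label '", label,
                      "'; valid labels: 66/256, 32/128, 21/64, 9/64",
                      call. = FALSE))
  if (label == "9/64") return(baseline9_channels)
  cap <- build_cap(spec$cap)
  pool <- posterior_pool(cap)
  keep <- if (label == "66/256") {
    union(montage_configuration_channels("21/64"),
          montage_configuration_channels("32/128"))
  } else {
    baseline9_channels
  }
  stopifnot(all(keep %in% pool))
  rest <- setdiff(pool, keep)
  # rank left/right mirror pairs as units so the selection stays symmetric
  rest_xyz <- cap[match(rest, cap$name), ]
  key <- paste(round(abs(rest_xyz$x_cm), 6), round(rest_xyz$y_cm, 6),
               round(rest_xyz$z_cm, 6))
  groups <- split(rest, key)
  gdist <- vapply(groups, function(g) min(dist_from(cap, g)), 0)
  groups <- groups[order(gdist)]
  sel <- keep
  for (g in groups) {
    rem <- spec$n - length(sel)
    if (length(g) > rem) next
    # keep midline singletons for odd remainders so pairs stay intact
    if (length(g) == 1L && rem %% 2L == 0L) next
    sel <- c(sel, g)
    if (length(sel) == spec$n) break
  }
  stopifnot(length(sel) == spec$n)
  cap$name[cap$name %in% sel]  # cap order
}

new_montage <- function(df, config_label = NULL, cap_total = NA_integer_) {
  stopifnot(is.data.frame(df),
            all(c("name", "x_cm", "y_cm", "z_cm") %in% names(df)),
            !anyDuplicated(df$name),
            all(is.finite(as.matrix(df[, c("x_cm", "y_cm", "z_cm")]))))
  structure(df[, c("name", "x_cm", "y_cm", "z_cm")],
            class = c("eeg_montage", "data.frame"),
            config_label = config_label, cap_total = as.integer(cap_total))
}

#' Load one of the study electrode configurations
#'
#' Returns the montage (channel names + idealized 3-D positions) of one of
#' the four parieto-occipital decoding configurations, where the label
#' `n/cap` gives the number of parieto-occipital electrodes used for decoding
#' over the total channel count of the cap they come from. Channel lists are
#' read from plain-text files shipped in `inst/extdata` (one name per line,
#' editable); positions come from [build_cap()].
#'
#' @param label One of "66/256", "32/128", "21/64", "9/64".
#' @param full_cap If `TRUE`, return the montage of the whole cap rather than
#'   the parieto-occipital selection.
#' @return An `eeg_montage` data frame with attributes `config_label` and
#'   `cap_total`.
#' @export
load_configuration <- function(label, full_cap = FALSE) {
  valid <- c("66/256", "32/128", "21/64", "9/64")
  if (!label %in% valid) {
    stop("unknown configuration label '", label, "'; valid labels: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  cap_total <- as.integer(sub(".*/", "", label))
  cap <- build_cap(cap_total)
  if (full_cap) {
    return(new_montage(cap, config_label = paste0("full-", cap_total),
                       cap_total = cap_total))
  }
  file <- system.file("extdata",
                      paste0("channels_", sub("/", "-", label), ".txt"),
                      package = "hdssvep")
  chans <- if (nzchar(file)) {
    readLines(file)
  } else {
    montage_configuration_channels(label)
  }
  miss <- setdiff(chans, cap$name)
  if (length(miss) > 0L) {
    stop("configuration channel(s) not on the cap: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  new_montage(cap[match(chans, cap$name), ],
              config_label = label, cap_total = cap_total)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("eeg_montage: %d channels (%s)\n", nrow(x),
              attr(x, "config_label") %||% "custom"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean nearest-neighbour interelectrode distance
#'
#' For each channel, the Euclidean distance to its nearest neighbour is
#' computed from the 3-D positions (a chord-length approximation to the
#' geodesic at these spacings); the mean over channels is returned, in cm.
#'
#' @param m An `eeg_montage` (or data frame with `x_cm,y_cm,z_cm`).
#' @return Mean nearest-neighbour distance in cm.
#' @export
mean_interelectrode_distance <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 channels", call. = FALSE)
  p <- as.matrix(m[, c("x_cm", "y_cm", "z_cm")])
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Write / read a montage as CSV (`name,x_cm,y_cm,z_cm`)
#'
#' @param m An `eeg_montage`.
#' @param path File path.
#' @export
write_montage <- function(m, path) {
  utils::write.csv(as.data.frame(m)[, c("name", "x_cm", "y_cm", "z_cm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x_cm", "y_cm", "z_cm") %in% names(df))) {
    stop("not a montage CSV: expected columns name,x_cm,y_cm,z_cm",
         call. = FALSE)
  }
  new_montage(df)
}
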