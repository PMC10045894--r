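#' Aspiration image stack
#'
#' Container for a (possibly binarized) aspiration time-lapse. Frames are
#' stored as a 3D array `rows x cols x time` with row 1 at the image top;
#' the last row corresponds to the channel entrance, so a tongue of length
#' `L` occupies the bottom `round(L / pixel_size_um)` rows of its channel.
#'
#' @param frames 3D numeric array (`rows x cols x frames`), grayscale or
#'   binary.
#' @param pixel_size_um Pixel size in micrometres per pixel (default 1.3:
#'   a 6.5 um camera pixel behind a 5x objective).
#' @param frame_interval_s Time between frames in seconds (default 5).
#' @param centerlines Integer vector of column indices marking the middle
#'   of each aspiration channel (up to 8).
#' @param foreground Binary value that represents tissue (default 1).
#'
#' @return An object of class `"aspiration_stack"`.
#' @export
aspiration_stack <- function(frames, pixel_size_um = 1.3,
                             frame_interval_s = 5, centerlines,
                             foreground = 1) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    abort("`frames` must be a 3D array (rows x cols x frames).")
  }
  if (dim(frames)[3] < 1) abort("The stack contains no frames.")
  if (pixel_size_um <= 0 || frame_interval_s <= 0) {
    abort("`pixel_size_um` and `frame_interval_s` must be positive.")
  }
  centerlines <- as.integer(centerlines)
  if (length(centerlines) < 1 || length(centerlines) > 8) {
    abort("Between 1 and 8 channel centerlines are supported.")
  }
  if (any(centerlines < 1) || any(centerlines > dim(frames)[2])) {
    abort("All centerline columns must lie within the image width.")
  }
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, centerlines = centerlines,
         foreground = foreground),
    class = "aspiration_stack"
  )
}

#' @export
print.aspiration_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Aspiration stack: %d x %d px, %d frames, %d channel(s)\n",
    d[1], d[2], d[3], length(x$centerlines)))
  cat(sprintf("  pixel %.3g um, frame interval %.3g s\n",
              x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Binarize a grayscale frame
#'
#' Thresholds one frame of an aspiration time-lapse. The threshold may be a
#' number (pixels at or above it are foreground) or `"otsu"`, which picks
#' the threshold automatically by Otsu's method as a reproducible
#' replacement for a manually chosen value.
#'
#' @param frame Numeric matrix.
#' @param threshold Numeric intensity or `"otsu"` (default).
#' @param polarity `"bright"` if tissue is brighter than background,
#'   `"dark"` if darker.
#'
#' @return An integer matrix of 0/1 with foreground = 1.
#' @export
#' @examples
#' f <- matrix(10, 20, 20); f[12:20, 8:12] <- 200
#' b <- binarize(f)
#' sum(b)  # 45 foreground pixels
binarize <- function(frame, threshold = "otsu",
                     polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(frame) || length(frame) == 0) {
    abort("`frame` must be a non-empty numeric matrix.")
  }
  if (identical(threshold, "otsu")) {
    rng <- range(frame)
    if (diff(rng) == 0) {
      abort("Cannot apply Otsu thresholding to a constant-intensity frame.")
    }
    threshold <- EBImage::otsu(EBImage::Image(frame), range = rng)
    fg <- frame > threshold
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1) {
      abort("`threshold` must be a single number or \"otsu\".")
    }
    fg <- frame >= threshold
  }
  if (polarity == "dark") fg <- !fg
  out <- matrix(as.integer(fg), nrow(frame), ncol(frame))
  out
}

#' Locate the protrusion front along a channel centerline
#'
#' Scans one column of a binary frame from the top (row 1) downwards and
#' returns the row of the first foreground pixel -- the edge of the
#' aspirated tongue. If the column holds no foreground at all, the sentinel
#' `nrow(frame) + 1` is returned, which corresponds to a creep length of
#' zero.
#'
#' @param binary_frame Binary matrix (foreground coded by `foreground`).
#' @param centerline Column index to scan.
#' @param foreground Foreground value (default 1).
#'
#' @return Integer row index in `1:(nrow + 1)`.
#' @export
find_front <- function(binary_frame, centerline, foreground = 1) {
  if (centerline < 1 || centerline > ncol(binary_frame)) {
    abort("`centerline` must be a valid column index.")
  }
  hit <- which(binary_frame[, centerline] == foreground)
  if (length(hit) == 0) nrow(binary_frame) + 1L else hit[1]
}

front_rows_matrix <- function(stack, cols) {
  n_frames <- dim(stack$frames)[3]
  vapply(seq_len(n_frames), function(k) {
    vapply(cols, function(cc) {
      find_front(stack$frames[, , k], cc, stack$foreground)
    }, integer(1))
  }, integer(length(cols)))
}

#' Extract creep curves from an aspiration stack
#'
#' For every frame and channel, locates the protrusion front on the channel
#' centerline and converts it to a creep length
#' `L = (image_height - front_row + 1) * pixel_size`; frame `k` maps to
#' time `(k - 1) * frame_interval`. Optionally applies the front-stability
#' exclusion rule per channel (see [check_front_stability()]).
#'
#' @param stack An [aspiration_stack()] with binary frames.
#' @param check_stability Apply [check_front_stability()] per channel and
#'   propagate its exclusion flag (default `TRUE`).
#' @param band_halfwidth,max_spread_px,max_retreat_px Passed to
#'   [check_front_stability()].
#'
#' @return A tibble of creep curves: `time_s`, `length_um`, `spheroid_id`
#'   (`"pocket-<k>"`), `pocket`, `excluded`, `reason`.
#' @export
creep_from_stack <- function(stack, check_stability = TRUE,
                             band_halfwidth = 5, max_spread_px = 10,
                             max_retreat_px = 5) {
  stopifnot(inherits(stack, "aspiration_stack"))
  h <- dim(stack$frames)[1]
  n_frames <- dim(stack$frames)[3]
  times <- (seq_len(n_frames) - 1) * stack$frame_interval_s
  curves <- purrr::imap(stack$centerlines, function(cc, k) {
    rows <- front_rows_matrix(stack, cc)
    flag <- if (check_stability) {
      check_front_stability(stack, k, band_halfwidth = band_halfwidth,
                            max_spread_px = max_spread_px,
                            max_retreat_px = max_retreat_px)
    } else {
      tibble(excluded = FALSE, reason = NA_character_)
    }
    tibble(
      time_s = times,
      length_um = (h - as.integer(rows) + 1L) * stack$pixel_size_um,
      spheroid_id = sprintf("pocket-%d", k),
      pocket = as.integer(k),
      excluded = flag$excluded,
      reason = flag$reason
    )
  })
  dplyr::bind_rows(curves)
}

#' Front-stability exclusion check
#'
#' Emulates the manual exclusion of tongues whose thresholded edge changes
#' structure over time (typically because loosely attached cells break off
#' the front). The front row is located in a band of columns around the
#' channel centerline for every frame; the curve is flagged for exclusion
#' when either
#' \itemize{
#'   \item the within-band spread of front rows (among columns where the
#'     tongue is present) exceeds `max_spread_px`, or
#'   \item the centerline front retreats (moves away from the channel, i.e.
#'     the creep length drops) by more than `max_retreat_px` between
#'     consecutive frames.
#' }
#'
#' @param stack An [aspiration_stack()].
#' @param channel Channel index (position in `stack$centerlines`).
#' @param band_halfwidth Half-width of the column band in pixels (default 5).
#' @param max_spread_px Tolerated within-band front spread (default 10).
#' @param max_retreat_px Tolerated single-frame front retreat (default 5).
#'
#' @return A one-row tibble: `excluded` (logical), `reason` (`NA`,
#'   `"front_spread"` or `"front_retreat"`).
#' @export
check_front_stability <- function(stack, channel, band_halfwidth = 5,
                                  max_spread_px = 10, max_retreat_px = 5) {
  stopifnot(inherits(stack, "aspiration_stack"))
  if (channel < 1 || channel > length(stack$centerlines)) {
    abort("`channel` is out of range.")
  }
  cc <- stack$centerlines[channel]
  w <- dim(stack$frames)[2]
  h <- dim(stack$frames)[1]
  band <- (cc - band_halfwidth):(cc + band_halfwidth)
  if (any(band < 1) || any(band > w)) {
    warn("Column band exceeds the image bounds; clipping.")
    band <- band[band >= 1 & band <= w]
  }
  rows <- front_rows_matrix(stack, band)  # band x frames
  center_rows <- front_rows_matrix(stack, cc)
  spread <- apply(rows, 2, function(r) {
    present <- r[r <= h]
    if (length(present) < 2) 0L else diff(range(present))
  })
  if (any(spread > max_spread_px)) {
    return(tibble(excluded = TRUE, reason = "front_spread"))
  }
  retreat <- diff(as.integer(center_rows))
  if (any(retreat > max_retreat_px)) {
    return(tibble(excluded = TRUE, reason = "front_retreat"))
  }
  tibble(excluded = FALSE, reason = NA_character_)
}

mask_area <- function(mask) sum(mask != 0)

# Perimeter of the largest object via its ordered boundary chain
# (horizontal/vertical steps count 1, diagonal steps sqrt(2)).
mask_perimeter <- function(mask) {
  img <- EBImage::Image(matrix(as.numeric(mask != 0), nrow(mask),
                               ncol(mask)))
  oc <- EBImage::ocontour(EBImage::bwlabel(img))
  if (length(oc) == 0) abort("Mask contains no foreground object.")
  xy <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  closed <- rbind(xy, xy[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(closed)^2)))
}

#' Circularity of a binary mask
#'
#' Computes \eqn{4 \pi A / P^2} with the area in pixels and the perimeter
#' measured along the traced boundary chain of the largest connected
#' object. Equals 1 for an ideal disc (slightly less on a pixel grid) and
#' decreases with elongation.
#'
#' @param mask Binary matrix.
#' @return Circularity in (0, 1].
#' @export
mask_circularity <- function(mask) {
  a <- mask_area(mask)
  if (a == 0) abort("Mask contains no foreground object.")
  p <- mask_perimeter(mask)
  4 * pi * a / p^2
}

#' Spheroid shape and volume-constancy exclusion check
#'
#' Spheroids must be round before aspiration and keep a constant projected
#' area during it; this check applies both rules to a series of per-frame
#' spheroid masks. Roundness is judged on the first mask by [mask_circularity()]
#' and volume constancy by the relative drift of the projected area over
#' the series.
#'
#' @param mask_series List of binary matrices (one per sampled frame).
#' @param circularity_min Minimum circularity of the pre-aspiration mask
#'   (default 0.85).
#' @param max_area_drift Maximum tolerated relative change of projected
#'   area over the series (default 0.1).
#'
#' @return A one-row tibble: `excluded`, `reason` (`NA`, `"non_round"` or
#'   `"volume_drift"`), `circularity`, `area_drift`.
#' @export
check_spheroid_shape <- function(mask_series, circularity_min = 0.85,
                                 max_area_drift = 0.1) {
  if (!is.list(mask_series) || length(mask_series) == 0) {
    abort("`mask_series` must be a non-empty list of binary matrices.")
  }
  circ <- mask_circularity(mask_series[[1]])
  areas <- vapply(mask_series, mask_area, numeric(1))
  if (areas[1] == 0) abort("Pre-aspiration mask is empty.")
  drift <- max(abs(areas / areas[1] - 1))
  if (circ < circularity_min) {
    return(tibble(excluded = TRUE, reason = "non_round",
                  circularity = circ, area_drift = drift))
  }
  if (drift > max_area_drift) {
    return(tibble(excluded = TRUE, reason = "volume_drift",
                  circularity = circ, area_drift = drift))
  }
  tibble(excluded = FALSE, reason = NA_character_, circularity = circ,
         area_drift = drift)
}

#' Read and write aspiration stacks as multi-page TIFF
#'
#' Frames are written as one TIFF page per time point with intensities
#' scaled to \[0, 1\]. Pixel size, frame interval and centerlines are not
#' stored in the TIFF and must be supplied again when reading.
#'
#' @param stack An [aspiration_stack()].
#' @param path File path.
#' @inheritParams aspiration_stack
#' @return `read_stack()` returns an [aspiration_stack()]; `write_stack()`
#'   returns `stack` invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "aspiration_stack"))
  mx <- max(stack$frames, 1)
  pages <- purrr::map(seq_len(dim(stack$frames)[3]),
                      ~ stack$frames[, , .x] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(stack)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, pixel_size_um = 1.3, frame_interval_s = 5,
                       centerlines, foreground = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]
  # binary stacks written by write_stack() come back as 0/1 already
  aspiration_stack(frames, pixel_size_um, frame_interval_s, centerlines,
                   foreground)
}
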