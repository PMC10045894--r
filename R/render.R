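#' Render a synthetic multi-channel aspiration stack
#'
#' Builds a binary image time-lapse for up to 8 parallel vertical aspiration
#' channels from the ground-truth creep parameters of a cohort. Each tongue
#' fills its channel from the bottom row (the channel entrance) up to its
#' noiseless creep length, rounded to whole pixels; the renderer uses a flat
#' front, which is all the centerline tracker observes. Alongside the stack
#' the exact per-frame front rows are returned, so trackers can be verified
#' pixel-for-pixel, plus per-spheroid mask series for the shape checks.
#'
#' Artifact modes (per-spheroid column `artifact` in `cohort`):
#' \describe{
#'   \item{`"break_off"`}{a small detached blob appears a few pixels ahead
#'     of the front for a few frames mid-sequence and then disappears,
#'     mimicking cells breaking off the tongue; this violates the
#'     front-stability rule.}
#'   \item{`"non_round"`}{the spheroid mask is a 2:1 ellipse instead of a
#'     disc, violating the roundness rule.}
#'   \item{`"shrinking"`}{the spheroid mask loses 20% of its projected area
#'     over the series, violating volume constancy.}
#' }
#'
#' @param cohort Tibble with one row per spheroid (at most 8), carrying
#'   `delta_true_um`, `beta_true`, `tau_c_true_s`, `l_dot_inf_true_um_s`,
#'   optionally `r0_um`, `spheroid_id` and `artifact`.
#' @param pixel_size_um,frame_interval_s Stack calibration (defaults 1.3 um
#'   and 5 s).
#' @param n_frames Number of frames (default 61).
#' @param channel_width_um Rendered channel width (default 50).
#' @param gap_px Background gap between channels in pixels (default 20).
#' @param margin_um Head-room above the longest tongue (default 30).
#' @param mask_stride Spheroid masks are rendered every `mask_stride`-th
#'   frame (default 10).
#'
#' @return An [aspiration_stack()] with extra elements `truth` (tibble:
#'   `frame`, `time_s`, `pocket`, `spheroid_id`, `length_true_um`,
#'   `front_row`), `masks` (named list of per-spheroid mask series) and
#'   `artifact` (named character vector).
#' @export
#' @examples
#' cohort <- generate_cohort("HEK293T", n_spheroids = 3, seed = 1)
#' stack <- render_stack(cohort, n_frames = 21)
#' stack
render_stack <- function(cohort, pixel_size_um = 1.3, frame_interval_s = 5,
                         n_frames = 61, channel_width_um = 50, gap_px = 20,
                         margin_um = 30, mask_stride = 10) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  if (n < 1) abort("`cohort` must contain at least one spheroid.")
  if (n > 8) abort("At most 8 spheroids fit one stack (one per channel).")
  need <- c("delta_true_um", "beta_true", "tau_c_true_s",
            "l_dot_inf_true_um_s")
  if (!all(need %in% names(cohort))) {
    abort(paste("`cohort` must carry ground-truth columns:",
                paste(need, collapse = ", ")))
  }
  ids <- if ("spheroid_id" %in% names(cohort)) cohort$spheroid_id else
    sprintf("sph-%03d", seq_len(n))
  artifact <- if ("artifact" %in% names(cohort)) cohort$artifact else
    rep(NA_character_, n)
  names(artifact) <- ids

  times <- (seq_len(n_frames) - 1) * frame_interval_s
  lengths_um <- vapply(seq_len(n), function(i) {
    creep_length(times, cohort$delta_true_um[i], cohort$beta_true[i],
                 cohort$tau_c_true_s[i], cohort$l_dot_inf_true_um_s[i])
  }, numeric(n_frames))

  ch_w <- max(3L, round(channel_width_um / pixel_size_um))
  pitch <- ch_w + gap_px
  width <- n * pitch
  centerlines <- (seq_len(n) - 1L) * pitch + gap_px %/% 2L + ch_w %/% 2L + 1L
  height <- ceiling((max(lengths_um) + margin_um) / pixel_size_um)

  frames <- array(0L, c(height, width, n_frames))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    c0 <- centerlines[i] - ch_w %/% 2L
    cols <- c0:(c0 + ch_w - 1L)
    l_px <- pmin(round(lengths_um[, i] / pixel_size_um), height)
    for (k in seq_len(n_frames)) {
      if (l_px[k] >= 1) {
        frames[(height - l_px[k] + 1L):height, cols, k] <- 1L
      }
    }
    front <- ifelse(l_px >= 1, height - l_px + 1L, height + 1L)
    if (identical(artifact[[i]], "break_off")) {
      win <- intersect(seq(n_frames %/% 3, n_frames %/% 3 + 3), seq_len(n_frames))
      bcols <- intersect(centerlines[i] + (-1:1), cols)
      for (k in win) {
        top <- max(front[k] - 14L, 1L)
        frames[top:max(top, front[k] - 11L), bcols, k] <- 1L
      }
    }
    truth[[i]] <- tibble(
      frame = seq_len(n_frames), time_s = times, pocket = i,
      spheroid_id = ids[i], length_true_um = lengths_um[, i],
      front_row = as.integer(front)
    )
  }

  mask_frames <- seq(1, n_frames, by = mask_stride)
  masks <- purrr::map(seq_len(n), function(i) {
    r0 <- if ("r0_um" %in% names(cohort)) cohort$r0_um[i] else 90
    render_spheroid_masks(
      r0_um = r0, pixel_size_um = pixel_size_um,
      n_masks = length(mask_frames),
      mode = if (is.na(artifact[[i]])) "round" else artifact[[i]]
    )
  })
  names(masks) <- ids

  out <- aspiration_stack(frames, pixel_size_um, frame_interval_s,
                          centerlines, foreground = 1)
  out$truth <- dplyr::bind_rows(truth)
  out$masks <- masks
  out$mask_frames <- mask_frames
  out$artifact <- artifact
  out
}

#' Render a series of spheroid masks
#'
#' Disc (or artifact-shaped) binary masks used by the shape and
#' volume-constancy checks.
#'
#' @param r0_um Spheroid radius in micrometres.
#' @param pixel_size_um Pixel size (default 1.3).
#' @param n_masks Number of masks in the series (default 7).
#' @param mode `"round"` (constant disc), `"non_round"` (2:1 ellipse of the
#'   same area) or `"shrinking"` (disc losing 20% area linearly over the
#'   series). `"break_off"` renders a plain disc: that artifact lives in
#'   the channel, not the pocket.
#'
#' @return List of binary matrices.
#' @export
render_spheroid_masks <- function(r0_um, pixel_size_um = 1.3, n_masks = 7,
                                  mode = c("round", "non_round",
                                           "shrinking", "break_off")) {
  mode <- match.arg(mode)
  r_px <- r0_um / pixel_size_um
  half <- ceiling(1.6 * r_px) + 2
  sz <- 2L * half + 1L
  cx <- half + 1
  xx <- matrix(seq_len(sz), sz, sz)
  yy <- t(xx)
  purrr::map(seq_len(n_masks), function(k) {
    scale <- if (mode == "shrinking") {
      sqrt(1 - 0.2 * (k - 1) / max(n_masks - 1, 1))
    } else 1
    if (mode == "non_round") {
      a <- r_px * sqrt(2)   # 2:1 ellipse, area preserved
      b <- r_px / sqrt(2)
      m <- ((xx - cx) / a)^2 + ((yy - cx) / b)^2 <= 1
    } else {
      m <- (xx - cx)^2 + (yy - cx)^2 <= (scale * r_px)^2
    }
    matrix(as.integer(m), sz, sz)
  })
}
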