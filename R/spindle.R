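# Spindle coordinate-frame estimation and per-chromosome metaphase metrics.

# Positions array accessor: smoothed if present, else raw.
rec_positions <- function(recording) {
  if (!is.null(recording$spos)) recording$spos else recording$pos
}

# Indices of sister 0 / sister 1 slices, aligned by chromosome order.
sister_slices <- function(recording) {
  ch <- recording$chromatids
  ord <- order(ch$chromosome_id, ch$sister_index)
  chromosomes <- unique(ch$chromosome_id[ord])
  s0 <- match(paste(chromosomes, 0), paste(ch$chromosome_id, ch$sister_index))
  s1 <- match(paste(chromosomes, 1), paste(ch$chromosome_id, ch$sister_index))
  if (anyNA(s0) || anyNA(s1)) {
    stop("analysis requires both sister tracks for every chromosome; ",
         "missing sister for chromosome(s) ",
         paste(chromosomes[is.na(s0) | is.na(s1)], collapse = ", "))
  }
  list(chromosomes = chromosomes, s0 = s0, s1 = s1)
}

#' Estimate the spindle coordinate frame at one timepoint
#'
#' The centroid is the mean of all centromere positions at the timepoint.
#' The axis is the principal eigenvector of the orientation tensor
#' `sum(u_i %o% u_i)` over included chromosomes, where `u_i` is the unit
#' sister-connection vector (sign-insensitive orientation averaging).
#' Inclusion is iterated: starting from all chromosomes, the axis is refit
#' and chromosomes whose midpoint lies farther than `alignment_radius_um`
#' from the current equator plane are dropped, until the included set is
#' stable (at most 10 iterations). The equator plane is the plane through
#' the centroid normal to the axis.
#'
#' The returned axis sign points into the +z hemisphere by default; callers
#' tracking frames over time should enforce temporal sign consistency
#' (see [estimate_frames()]).
#'
#' @param recording an [oocyte_recording()] (smoothed positions are used
#'   when available).
#' @param time_index frame index to analyse.
#' @param alignment_radius_um equator-distance trim radius, micrometres.
#' @return object of class `spindle_frame`: list with `time`, `centroid`
#'   (length-3), `axis` (unit length-3), `included` (chromosome ids used
#'   for the axis fit).
#' @export
estimate_frame <- function(recording, time_index, alignment_radius_um = 3) {
  P <- rec_positions(recording)
  ss <- sister_slices(recording)
  nchr <- length(ss$chromosomes)
  if (nchr < 3) stop("estimate_frame: need >= 3 chromosomes")
  X <- P[time_index, , ]                      # 3 x n_chromatid
  centroid <- rowMeans(X)
  S0 <- X[, ss$s0, drop = FALSE]
  S1 <- X[, ss$s1, drop = FALSE]
  U <- S1 - S0
  len <- sqrt(colSums(U^2))
  if (any(len == 0)) stop("estimate_frame: coincident sister centromeres")
  U <- sweep(U, 2, len, "/")
  M <- (S0 + S1) / 2

  include <- rep(TRUE, nchr)
  axis <- NULL
  for (iter in seq_len(10)) {
    Ui <- U[, include, drop = FALSE]
    tensor <- tcrossprod(Ui)                  # 3 x 3 orientation tensor
    eig <- eigen(tensor, symmetric = TRUE)
    if (eig$values[1] - eig$values[2] < 1e-10) {
      stop("estimate_frame: degenerate orientation tensor (no dominant ",
           "spindle direction)")
    }
    axis <- eig$vectors[, 1]
    dist_eq <- abs(colSums((M - centroid) * axis))
    new_include <- dist_eq <= alignment_radius_um
    if (sum(new_include) < 3) break           # keep last viable set
    if (identical(new_include, include)) {
      include <- new_include
      break
    }
    include <- new_include
  }
  if (axis[3] < 0 || (axis[3] == 0 && axis[1] < 0)) axis <- -axis
  structure(list(time = recording$times[time_index],
                 centroid = centroid,
                 axis = axis,
                 included = ss$chromosomes[include]),
            class = "spindle_frame")
}

#' Estimate spindle frames over a set of timepoints
#'
#' Per-timepoint [estimate_frame()] with temporal sign consistency: each
#' frame's axis is flipped to maximise its dot product with the previous
#' frame's axis (there is no temporal smoothing of the axis itself).
#'
#' @inheritParams estimate_frame
#' @param time_indices integer frame indices (default: all frames).
#' @param egg_direction optional length-3 vector; when given, the first
#'   frame's axis is oriented so the axis points toward the egg side.
#' @return list of `spindle_frame` objects, named by frame index.
#' @export
estimate_frames <- function(recording, time_indices = NULL,
                            alignment_radius_um = 3, egg_direction = NULL) {
  time_indices <- time_indices %||% seq_along(recording$times)
  frames <- vector("list", length(time_indices))
  prev_axis <- NULL
  for (j in seq_along(time_indices)) {
    fr <- estimate_frame(recording, time_indices[j], alignment_radius_um)
    ref <- prev_axis %||% egg_direction
    if (!is.null(ref) && sum(fr$axis * ref) < 0) fr$axis <- -fr$axis
    frames[[j]] <- fr
    prev_axis <- fr$axis
  }
  names(frames) <- as.character(time_indices)
  frames
}

#' Per-chromosome metaphase-II metrics over the pre-onset window
#'
#' For every frame in `[onset_min - window_min, onset_min)` computes, in
#' the per-frame spindle frame: the chromosome midpoint
#' `m = (s0 + s1) / 2`, its distance to the equator plane
#' `|(m - centroid) . axis|` and to the spindle axis (norm of the component
#' of `m - centroid` orthogonal to the axis), the chromosome-axis angle
#' `acos(|u . axis|)` folded to [0, 90] degrees, the inter-centromere
#' distance `|s0 - s1|`, and the midpoint speed from smoothed positions.
#' Window summaries follow the published table rows: maxima for the two
#' distances, means for angle, speed and inter-centromere distance.
#'
#' @param recording a [smooth_recording()] output (smoothed positions are
#'   required for speeds).
#' @param frames list of `spindle_frame` objects named by frame index
#'   (see [estimate_frames()]); must cover the window.
#' @param onset_min anaphase-II onset time, minutes.
#' @param window_min averaging window length before onset, minutes.
#' @return data.frame with one row per chromosome: `chromosome_id`,
#'   `window_start`, `window_end`, `max_dist_to_equator_um`,
#'   `max_dist_to_axis_um`, `mean_angle_deg`, `mean_speed_um_per_min`,
#'   `mean_icd_um`; the per-frame series are attached as attribute
#'   `"series"` (long data.frame).
#' @export
compute_metrics <- function(recording, frames, onset_min, window_min = 40) {
  times <- recording$times
  idx <- which(times >= onset_min - window_min & times < onset_min)
  if (length(idx) < 2) {
    stop("compute_metrics: fewer than 2 frames in the pre-onset window")
  }
  have <- as.character(idx) %in% names(frames)
  if (!all(have)) {
    stop("compute_metrics: spindle frames missing for window frame(s) ",
         paste(idx[!have], collapse = ", "))
  }
  P <- rec_positions(recording)
  ss <- sister_slices(recording)
  nchr <- length(ss$chromosomes)

  # midpoint positions over the window for speed computation
  mid <- (P[, , ss$s0, drop = FALSE] + P[, , ss$s1, drop = FALSE]) / 2

  series <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    k <- idx[j]
    fr <- frames[[as.character(k)]]
    X <- P[k, , ]
    S0 <- X[, ss$s0, drop = FALSE]
    S1 <- X[, ss$s1, drop = FALSE]
    M <- (S0 + S1) / 2
    D <- S1 - S0
    icd <- sqrt(colSums(D^2))
    u_dot <- abs(colSums(D * fr$axis)) / icd
    angle <- acos(pmin(1, u_dot)) * 180 / pi
    rel <- M - fr$centroid
    d_eq <- abs(colSums(rel * fr$axis))
    d_ax <- sqrt(pmax(0, colSums(rel^2) - d_eq^2))
    series[[j]] <- data.frame(
      chromosome_id = ss$chromosomes, time_min = times[k],
      dist_to_equator_um = d_eq, dist_to_axis_um = d_ax,
      angle_deg = angle, icd_um = icd
    )
  }
  series <- do.call(rbind, series)

  # midpoint speeds on window frames (first window frame copies second)
  spd <- matrix(NA_real_, length(idx), nchr)
  for (c in seq_len(nchr)) {
    spd[, c] <- speeds_from_positions(times[idx], mid[idx, , c])
  }
  series$speed_um_per_min <- NA_real_
  for (j in seq_along(idx)) {
    series$speed_um_per_min[series$time_min == times[idx[j]]] <- spd[j, ]
  }

  agg <- function(v, f) tapply(v, series$chromosome_id, f)
  out <- data.frame(
    chromosome_id = as.integer(names(agg(series$icd_um, mean))),
    window_start = onset_min - window_min,
    window_end = onset_min,
    max_dist_to_equator_um = as.numeric(agg(series$dist_to_equator_um, max)),
    max_dist_to_axis_um = as.numeric(agg(series$dist_to_axis_um, max)),
    mean_angle_deg = as.numeric(agg(series$angle_deg, mean)),
    mean_speed_um_per_min = as.numeric(agg(series$speed_um_per_min, mean)),
    mean_icd_um = as.numeric(agg(series$icd_um, mean))
  )
  out <- out[match(ss$chromosomes, out$chromosome_id), ]
  rownames(out) <- NULL
  stopifnot(all(out$mean_icd_um > 0),
            all(out$mean_angle_deg >= 0 & out$mean_angle_deg <= 90))
  attr(out, "series") <- series
  out
}
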