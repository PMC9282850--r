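# Anaphase-II event detection: onset, pole assignment, laggards,
# segregation-pattern classification and ploidy calling.

onset_not_found <- function(msg) {
  stop(structure(class = c("miiseg_onset_not_found", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Inter-centromere distance matrix (n_time x n_chromosome).
# Event detection runs on raw positions: the global smoothing spline
# spreads the sharp anaphase rise backward in time, which would bias the
# detected onset early; thresholds here are large relative to noise.
icd_matrix <- function(recording) {
  P <- recording$pos
  ss <- sister_slices(recording)
  D <- P[, , ss$s1, drop = FALSE] - P[, , ss$s0, drop = FALSE]
  icd <- sqrt(apply(D^2, c(1, 3), sum))
  colnames(icd) <- as.character(ss$chromosomes)
  icd
}

#' Detect anaphase-II onset
#'
#' Onset is the first time-frame at which the inter-centromere distance
#' starts to increase, operationalised robustly across chromosomes: the
#' earliest frame whose median (across chromosomes) inter-centromere
#' distance exceeds the trailing baseline (mean of the preceding
#' `baseline_frames` frames) by `baseline_sd_mult` baseline standard
#' deviations, and from which the median increases monotonically over the
#' next `rise_frames` frames.
#'
#' @param recording an [oocyte_recording()]; raw positions are used (the
#'   global smoothing spline spreads the anaphase rise backward in time
#'   and would bias the detected onset early).
#' @param params an [analysis_params()] list.
#' @return list with `onset_min` (time of the onset frame) and `index`
#'   (frame index).
#' @section Errors: signals a condition of class `miiseg_onset_not_found`
#'   when no frame satisfies the criterion (metaphase-arrested recording).
#' @export
detect_anaphase_onset <- function(recording, params = analysis_params()) {
  icd <- icd_matrix(recording)
  med <- apply(icd, 1, stats::median)
  n <- length(med)
  b <- params$baseline_frames
  r <- params$rise_frames
  first <- b + 1
  last <- n - r
  if (first > last) {
    onset_not_found("recording too short to evaluate the onset criterion")
  }
  for (k in first:last) {
    base <- med[(k - b):(k - 1)]
    thr <- mean(base) + params$baseline_sd_mult * stats::sd(base)
    if (med[k] > thr) {
      seg <- med[k:(k + r)]
      # sustained-rise guard: besides monotone growth, the rise over the
      # look-ahead window must itself be substantive (anaphase separation
      # moves micrometres per frame; correlated noise wiggles do not),
      # and -- since sister separation is irreversible -- the median must
      # never fall back below the trigger threshold afterwards
      sustained <- r == 0 ||
        (all(diff(seg) > 0) &&
           seg[r + 1] - seg[1] > params$baseline_sd_mult * stats::sd(base))
      if (sustained && all(med[k:n] > thr)) {
        return(list(onset_min = recording$times[k], index = k))
      }
    }
  }
  onset_not_found("no sustained inter-centromere distance rise found")
}

#' Assign chromatids to spindle poles over post-onset frames
#'
#' At each frame from onset onward, a chromatid is assigned to a pole when
#' the absolute axial projection of its position (relative to the spindle
#' centroid) exceeds the midzone half-width; otherwise it is labelled
#' midzone. Pole identity follows the axis sign convention: the `+axis`
#' side is the egg side when `egg_direction` agrees with the axis (the
#' egg/polar-body side cannot be inferred from centromere tracks alone).
#'
#' @param recording an [oocyte_recording()] (raw positions are used; the
#'   2-um midzone half-width dwarfs localization noise).
#' @param onset output of [detect_anaphase_onset()] (or a list with
#'   `index`).
#' @param frame the `spindle_frame` used for post-onset geometry (the
#'   onset-frame estimate; the spindle frame is not re-estimated while
#'   chromosomes leave the plate).
#' @param params an [analysis_params()] list.
#' @param egg_direction optional length-3 vector marking the egg side.
#' @return object of class `pole_assignments`: integer matrix
#'   (`n_post_frames x n_chromatid`) with values +1 (axis-positive pole),
#'   -1 (axis-negative pole), 0 (midzone); attributes `time_indices`,
#'   `frame`, `egg_sign`.
#' @export
assign_poles <- function(recording, onset, frame,
                         params = analysis_params(), egg_direction = NULL) {
  P <- recording$pos
  idx <- which(seq_along(recording$times) >= onset$index)
  proj <- sapply(seq_len(dim(P)[3]), function(k) {
    colSums((t(P[idx, , k]) - frame$centroid) * frame$axis)
  })
  proj <- matrix(proj, nrow = length(idx))
  lab <- matrix(0L, nrow(proj), ncol(proj))
  lab[proj > params$midzone_halfwidth_um] <- 1L
  lab[proj < -params$midzone_halfwidth_um] <- -1L
  egg_sign <- 1L
  if (!is.null(egg_direction)) {
    egg_sign <- if (sum(egg_direction * frame$axis) >= 0) 1L else -1L
  }
  structure(lab, time_indices = idx, frame = frame, egg_sign = egg_sign,
            class = "pole_assignments")
}

#' Detect lagging-chromatid episodes and their merge times
#'
#' A chromatid is a laggard when it remains in the spindle midzone
#' continuously from onset for at least `lag_min_duration_min` minutes
#' while its sister reaches a pole before the dwell ends. The merge time of a
#' laggard is the time from onset to the first frame at which it stays
#' within `merge_radius_um` of the centroid of its destination pole's
#' chromatid cluster (excluding itself) for at least 2 consecutive frames.
#' A laggard that never merges before the recording ends is reported as an
#' open episode with `merge_time_min = NA`.
#'
#' @param recording the recording the assignments came from.
#' @param assignments output of [assign_poles()].
#' @param onset output of [detect_anaphase_onset()].
#' @param params an [analysis_params()] list.
#' @return data.frame with one row per chromatid: `chromosome_id`,
#'   `sister_index`, `final_side` (+1/-1/0), `is_laggard`,
#'   `merge_time_min`, `resolved`.
#' @export
detect_laggards <- function(recording, assignments, onset,
                            params = analysis_params()) {
  P <- recording$pos
  idx <- attr(assignments, "time_indices")
  times <- recording$times[idx]
  onset_time <- recording$times[onset$index]
  nf <- length(idx)
  ss <- sister_slices(recording)
  nchtd <- dim(P)[3]

  # pole cluster centroids per frame and side (including all assigned)
  sums <- array(0, c(nf, 3, 2))    # side 1 -> +1, side 2 -> -1
  counts <- matrix(0L, nf, 2)
  for (k in seq_len(nchtd)) {
    for (s in 1:2) {
      sgn <- c(1L, -1L)[s]
      in_side <- assignments[, k] == sgn
      if (any(in_side)) {
        sums[in_side, , s] <- sums[in_side, , s] + P[idx[in_side], , k]
        counts[in_side, s] <- counts[in_side, s] + 1L
      }
    }
  }

  sister_of <- integer(nchtd)
  sister_of[ss$s0] <- ss$s1
  sister_of[ss$s1] <- ss$s0

  out <- recording$chromatids
  out$final_side <- assignments[nf, seq_len(nchtd)]
  out$is_laggard <- FALSE
  out$merge_time_min <- NA_real_
  out$resolved <- out$final_side != 0L

  dt <- recording$frame_interval_min
  for (k in seq_len(nchtd)) {
    lab <- assignments[, k]
    exit_idx <- which(lab != 0L)[1]
    if (is.na(exit_idx)) exit_idx <- nf + 1L        # never leaves midzone
    if (exit_idx == 1L) next                        # assigned from onset
    sis <- sister_of[k]
    sis_assigned <- which(assignments[, sis] != 0L)[1]
    if (is.na(sis_assigned) || sis_assigned >= exit_idx) next
    exit_time <- if (exit_idx <= nf) times[exit_idx] else times[nf] + dt
    dwell <- exit_time - onset_time
    if (dwell < params$lag_min_duration_min) next
    out$is_laggard[k] <- TRUE

    side <- out$final_side[k]
    if (side == 0L) next                            # open episode
    s <- if (side == 1L) 1L else 2L
    # cluster centroid excluding the laggard itself
    cnt <- counts[, s] - as.integer(lab == side)
    ctr_ok <- cnt > 0
    dist_to_cluster <- rep(Inf, nf)
    for (j in which(ctr_ok)) {
      ctr <- (sums[j, , s] - if (lab[j] == side) P[idx[j], , k] else 0) / cnt[j]
      dist_to_cluster[j] <- sqrt(sum((P[idx[j], , k] - ctr)^2))
    }
    near <- dist_to_cluster <= params$merge_radius_um
    sustained <- which(near & c(near[-1], FALSE))
    if (length(sustained)) {
      out$merge_time_min[k] <- times[sustained[1]] - onset_time
    }
  }
  rownames(out) <- NULL
  out
}

SEGREGATION_PATTERNS <- c("normal", "equational_laggard",
                          "coseg_with_laggard", "coseg_without_laggard",
                          "misaligned_at_onset", "unresolved")

ANEUPLOIDY_PATTERNS <- c("coseg_with_laggard", "coseg_without_laggard",
                         "misaligned_at_onset")

#' Classify the segregation pattern of every chromosome
#'
#' Decision rules, applied in order per chromosome: (1) misaligned at
#' onset when the chromosome midpoint lies at least
#' `misalign_threshold_um` from the equator plane at onset -- measured on
#' the last pre-onset frame, since by definition the detected onset frame
#' already shows sister separation and co-segregating pairs have moved
#' off the plate by then; (2) otherwise, when the sisters' final pole
#' destinations differ:
#' normal without a laggard episode, equational laggard with one;
#' (3) otherwise (same destination): co-segregation with or without a
#' laggard episode. Chromatids unassigned at the recording end yield an
#' `unresolved` call, excluded from summaries. A chromosome contributes to
#' aneuploidy iff its pattern is one of the co-segregation/misaligned
#' classes.
#'
#' @param recording the recording (smoothed positions used when available).
#' @param onset output of [detect_anaphase_onset()].
#' @param frame the onset `spindle_frame`.
#' @param assignments output of [assign_poles()].
#' @param laggards output of [detect_laggards()].
#' @param params an [analysis_params()] list.
#' @return data.frame with one row per chromosome: `chromosome_id`,
#'   `pattern`, `merge_time_min` (NA unless a laggard episode exists),
#'   `contributes_to_aneuploidy`, `resolved`.
#' @export
classify_segregation <- function(recording, onset, frame, assignments,
                                 laggards, params = analysis_params()) {
  P <- recording$pos
  ss <- sister_slices(recording)
  X <- P[max(onset$index - 1L, 1L), , ]
  M <- (X[, ss$s0, drop = FALSE] + X[, ss$s1, drop = FALSE]) / 2
  d_eq <- abs(colSums((M - frame$centroid) * frame$axis))

  n <- length(ss$chromosomes)
  pattern <- character(n)
  merge_time <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    l0 <- laggards[ss$s0[i], ]
    l1 <- laggards[ss$s1[i], ]
    has_laggard <- l0$is_laggard || l1$is_laggard
    mt <- c(l0$merge_time_min, l1$merge_time_min)
    if (has_laggard) merge_time[i] <- suppressWarnings(min(mt, na.rm = TRUE))
    if (!is.finite(merge_time[i])) merge_time[i] <- NA_real_
    if (d_eq[i] >= params$misalign_threshold_um) {
      pattern[i] <- "misaligned_at_onset"
    } else if (l0$final_side == 0L || l1$final_side == 0L) {
      pattern[i] <- "unresolved"
    } else if (l0$final_side != l1$final_side) {
      pattern[i] <- if (has_laggard) "equational_laggard" else "normal"
    } else {
      pattern[i] <- if (has_laggard) "coseg_with_laggard"
                    else "coseg_without_laggard"
    }
  }
  data.frame(
    chromosome_id = ss$chromosomes,
    pattern = factor(pattern, levels = SEGREGATION_PATTERNS),
    merge_time_min = merge_time,
    contributes_to_aneuploidy = pattern %in% ANEUPLOIDY_PATTERNS,
    resolved = pattern != "unresolved"
  )
}

#' Call ploidy of the egg and polar body
#'
#' Counts chromatids at the egg-side pole at the final frame; the egg is
#' aneuploid iff that count differs from the oocyte's chromosome number.
#' The metaphase-II chromosome count is taken from the recording itself.
#' Unresolved (midzone-at-end) chromatids make the pole counts lower
#' bounds, flagged via `counts_are_lower_bounds`.
#'
#' @param recording the recording.
#' @param calls output of [classify_segregation()] (used for consistency
#'   checking; may be NULL for metaphase-only recordings).
#' @param assignments output of [assign_poles()]; NULL for metaphase-only
#'   recordings, in which case only the metaphase fields are filled.
#' @param expected_n euploid chromosome number (mouse: 20).
#' @return data.frame (one row): `oocyte_id`, `chromatids_at_egg_pole`,
#'   `chromatids_at_pb_pole`, `unresolved_chromatids`, `aneuploid_egg`,
#'   `mII_chromosome_count`, `aneuploid_mII`, `counts_are_lower_bounds`.
#' @export
call_ploidy <- function(recording, calls = NULL, assignments = NULL,
                        expected_n = 20L) {
  n_chr <- n_chromosomes(recording)
  if (is.null(assignments)) {
    return(data.frame(
      oocyte_id = recording$oocyte_id,
      chromatids_at_egg_pole = NA_integer_,
      chromatids_at_pb_pole = NA_integer_,
      unresolved_chromatids = NA_integer_,
      aneuploid_egg = NA,
      mII_chromosome_count = n_chr,
      aneuploid_mII = n_chr != expected_n,
      counts_are_lower_bounds = NA
    ))
  }
  egg_sign <- attr(assignments, "egg_sign")
  final <- assignments[nrow(assignments), ]
  egg <- sum(final == egg_sign)
  pb <- sum(final == -egg_sign)
  unres <- sum(final == 0L)
  stopifnot(egg + pb + unres == 2L * n_chr)
  data.frame(
    oocyte_id = recording$oocyte_id,
    chromatids_at_egg_pole = egg,
    chromatids_at_pb_pole = pb,
    unresolved_chromatids = unres,
    aneuploid_egg = egg != expected_n,
    mII_chromosome_count = n_chr,
    aneuploid_mII = n_chr != expected_n,
    counts_are_lower_bounds = unres > 0
  )
}
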