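# Track containers, CSV I/O and cubic smoothing-spline denoising.

TRACK_COLUMNS <- c("oocyte_id", "chromosome_id", "sister_index",
                   "time_min", "x_um", "y_um", "z_um")

#' Construct a single centromere track
#'
#' One sister chromatid's centromere positions over time.
#'
#' @param oocyte_id character label of the parent oocyte.
#' @param chromosome_id integer chromosome identifier.
#' @param sister_index 0 or 1.
#' @param times strictly increasing numeric vector, minutes.
#' @param positions numeric matrix `length(times)` x 3 of x/y/z in
#'   micrometres.
#' @return object of class `centromere_track`.
#' @export
centromere_track <- function(oocyte_id, chromosome_id, sister_index,
                             times, positions) {
  positions <- as.matrix(positions)
  tr <- structure(list(
    oocyte_id = as.character(oocyte_id),
    chromosome_id = as.integer(chromosome_id),
    sister_index = as.integer(sister_index),
    times = as.numeric(times),
    positions = positions
  ), class = "centromere_track")
  validate_centromere_track(tr)
  tr
}

validate_centromere_track <- function(tr) {
  if (length(tr$times) < 2) stop("centromere_track: need >= 2 timepoints")
  if (nrow(tr$positions) != length(tr$times) || ncol(tr$positions) != 3) {
    stop("centromere_track: positions must be length(times) x 3")
  }
  if (any(diff(tr$times) <= 0)) {
    stop("centromere_track: times must be strictly increasing")
  }
  if (!all(is.finite(tr$positions))) {
    stop("centromere_track: non-finite coordinates")
  }
  if (!tr$sister_index %in% c(0L, 1L)) {
    stop("centromere_track: sister_index must be 0 or 1")
  }
  invisible(tr)
}

#' Construct an oocyte recording
#'
#' The pipeline's unit of analysis: all centromere tracks of one oocyte on
#' a shared acquisition time grid. Internally positions are held as a
#' `n_time x 3 x n_chromatid` array for vectorised processing; the
#' `chromatids` table maps array slices to (chromosome, sister) pairs.
#'
#' @param oocyte_id character label.
#' @param age_group `"young"` or `"aged"` (or other label).
#' @param frame_interval_min nominal frame interval, minutes.
#' @param times shared strictly increasing time grid, minutes.
#' @param chromatids data.frame with columns `chromosome_id`,
#'   `sister_index`; one row per array slice.
#' @param pos numeric array `length(times) x 3 x nrow(chromatids)`.
#' @param batch optional experiment/batch label.
#' @return object of class `oocyte_recording`.
#' @export
oocyte_recording <- function(oocyte_id, age_group, frame_interval_min,
                             times, chromatids, pos, batch = NA_character_) {
  rec <- structure(list(
    oocyte_id = as.character(oocyte_id),
    age_group = as.character(age_group),
    batch = as.character(batch),
    frame_interval_min = frame_interval_min,
    times = as.numeric(times),
    chromatids = chromatids,
    pos = pos
  ), class = "oocyte_recording")
  validate_oocyte_recording(rec)
  rec
}

validate_oocyte_recording <- function(rec) {
  nt <- length(rec$times)
  if (nt < 2 || any(diff(rec$times) <= 0)) {
    stop("oocyte_recording: times must be strictly increasing, length >= 2")
  }
  d <- dim(rec$pos)
  if (length(d) != 3 || d[1] != nt || d[2] != 3 ||
      d[3] != nrow(rec$chromatids)) {
    stop("oocyte_recording: pos must be n_time x 3 x n_chromatid")
  }
  if (!all(is.finite(rec$pos))) stop("oocyte_recording: non-finite positions")
  key <- paste(rec$chromatids$chromosome_id, rec$chromatids$sister_index)
  if (anyDuplicated(key)) {
    stop("oocyte_recording: duplicated (chromosome, sister) pair")
  }
  if (!all(rec$chromatids$sister_index %in% c(0L, 1L))) {
    stop("oocyte_recording: sister_index must be 0 or 1")
  }
  # incomplete sister pairs are tolerated at the container level (partial
  # track files); analysis operations require complete pairs
  invisible(rec)
}

#' @export
print.oocyte_recording <- function(x, ...) {
  cat("<oocyte_recording>", x$oocyte_id, sprintf("(%s)", x$age_group),
      "-", nrow(x$chromatids) / 2, "chromosomes,",
      length(x$times), "frames,",
      sprintf("%.1f-%.1f min\n", min(x$times), max(x$times)))
  invisible(x)
}

#' Number of chromosomes in a recording
#' @param recording an `oocyte_recording`.
#' @return integer count of sister pairs.
#' @export
n_chromosomes <- function(recording) {
  length(unique(recording$chromatids$chromosome_id))
}

# Extract one centromere_track from a recording (by array slice index).
track_from_recording <- function(recording, slice) {
  ch <- recording$chromatids[slice, ]
  centromere_track(recording$oocyte_id, ch$chromosome_id, ch$sister_index,
                   recording$times, recording$pos[, , slice])
}

#' Read track tables from CSV/TSV
#'
#' Parses a track table with columns `oocyte_id, chromosome_id,
#' sister_index, time_min, x_um, y_um, z_um` (header required; comma or tab
#' separated, '.' decimal) into a list of validated [oocyte_recording()]
#' objects, one per oocyte, rows sorted by time within track.
#'
#' @param path file path.
#' @return named list of `oocyte_recording` objects.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("read_tracks: no such file: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character", dec = ".")
  missing <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing)) {
    stop("read_tracks: missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[TRACK_COLUMNS]
  for (col in c("chromosome_id", "sister_index", "time_min",
                "x_um", "y_um", "z_um")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("read_tracks: non-numeric value in column '", col,
           "' at data row ", bad[1])
    }
    if (anyNA(v)) stop("read_tracks: missing value in column '", col, "'")
    df[[col]] <- v
  }
  key <- paste(df$oocyte_id, df$chromosome_id, df$sister_index, df$time_min)
  if (anyDuplicated(key)) {
    stop("read_tracks: duplicate (oocyte, chromosome, sister, time) row: ",
         key[which(duplicated(key))[1]])
  }
  df <- df[order(df$oocyte_id, df$chromosome_id, df$sister_index,
                 df$time_min), ]
  recs <- lapply(split(df, df$oocyte_id), function(o) {
    times <- sort(unique(o$time_min))
    ch <- unique(o[c("chromosome_id", "sister_index")])
    ch <- ch[order(ch$chromosome_id, ch$sister_index), ]
    rownames(ch) <- NULL
    ch$chromosome_id <- as.integer(ch$chromosome_id)
    ch$sister_index <- as.integer(ch$sister_index)
    pos <- array(NA_real_, c(length(times), 3, nrow(ch)))
    for (i in seq_len(nrow(ch))) {
      tri <- o[o$chromosome_id == ch$chromosome_id[i] &
                 o$sister_index == ch$sister_index[i], ]
      if (nrow(tri) != length(times) || any(tri$time_min != times)) {
        stop("read_tracks: track (", o$oocyte_id[1], ", ",
             ch$chromosome_id[i], ", ", ch$sister_index[i],
             ") does not share the oocyte time grid")
      }
      pos[, , i] <- as.matrix(tri[c("x_um", "y_um", "z_um")])
    }
    oocyte_recording(o$oocyte_id[1], age_group = "unknown",
                     frame_interval_min = if (length(times) > 1)
                       stats::median(diff(times)) else NA_real_,
                     times = times, chromatids = ch, pos = pos)
  })
  recs
}

#' Write recordings as a track CSV
#'
#' Canonical column order, full double precision (`%.17g`), deterministic
#' row order (oocyte, chromosome, sister, time); two writes of the same
#' data are byte-identical.
#'
#' @param recordings one `oocyte_recording` or a list of them.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_tracks <- function(recordings, path) {
  if (inherits(recordings, "oocyte_recording")) recordings <- list(recordings)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(TRACK_COLUMNS, collapse = ","), con)
  ids <- vapply(recordings, function(r) r$oocyte_id, character(1))
  for (rec in recordings[order(ids)]) {
    ch <- rec$chromatids
    ord <- order(ch$chromosome_id, ch$sister_index)
    for (i in ord) {
      lines <- sprintf("%s,%d,%d,%s,%s,%s,%s",
                       rec$oocyte_id, ch$chromosome_id[i], ch$sister_index[i],
                       sprintf("%.17g", rec$times),
                       sprintf("%.17g", rec$pos[, 1, i]),
                       sprintf("%.17g", rec$pos[, 2, i]),
                       sprintf("%.17g", rec$pos[, 3, i]))
      writeLines(lines, con)
    }
  }
  invisible(path)
}

# ---- cubic smoothing spline (Green & Silverman penalized form) ----------

# Natural cubic smoothing spline fitted values for each column of Y on grid
# `times`, minimizing p * sum((y - f)^2) + (1 - p) * integral(f'')^2.
# Solved from the penalized normal equations (I + lambda * K) f = y with
# K = t(D) C^-1 D, lambda = (1 - p) / p. Exact interpolation at p = 1.
fit_smoothing_spline <- function(times, Y, p) {
  stopifnot(p > 0, p <= 1)
  Y <- as.matrix(Y)
  n <- length(times)
  if (n < 4) {
    warning("smoothing spline under-determined (< 4 timepoints); ",
            "returning input unsmoothed")
    return(Y)
  }
  if (p == 1) return(Y)
  h <- diff(times)
  D <- matrix(0, n - 2, n)
  C <- matrix(0, n - 2, n - 2)
  for (i in seq_len(n - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    C[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < n - 2) {
      C[i, i + 1] <- h[i + 1] / 6
      C[i + 1, i] <- h[i + 1] / 6
    }
  }
  K <- crossprod(D, solve(C, D))
  lambda <- (1 - p) / p
  A <- diag(n) + lambda * K
  solve(A, Y)
}

# Per-frame speeds from smoothed positions: |delta position| / delta t
# between frames i-1 and i; the first frame copies the second.
speeds_from_positions <- function(times, positions) {
  d <- diff(positions)
  sp <- c(NA_real_, sqrt(rowSums(d^2)) / diff(times))
  sp[1] <- sp[2]
  sp
}

#' Smooth a centromere track
#'
#' Fits an independent cubic smoothing spline to each coordinate of the
#' track, minimizing `p * sum((y - f(t))^2) + (1 - p) * integral(f'')^2`
#' with `p = smoothing`, evaluated on the original time grid (the published
#' analysis used p = 0.35). Per-frame speeds are the norm of the smoothed
#' displacement divided by the frame interval, with the first frame copying
#' the second.
#'
#' Tracks with fewer than 4 timepoints are returned unsmoothed with a
#' warning (the natural-spline system is under-determined).
#'
#' @param track a [centromere_track()].
#' @param smoothing spline parameter `p` in (0, 1]; `p = 1` reproduces the
#'   input exactly (pure interpolation limit).
#' @return object of class `smoothed_track`: the input track plus
#'   `smoothed` positions and `speeds` (micrometres/minute).
#' @export
smooth_track <- function(track, smoothing = 0.35) {
  validate_centromere_track(track)
  sm <- fit_smoothing_spline(track$times, track$positions, smoothing)
  out <- track
  out$smoothed <- sm
  out$speeds <- speeds_from_positions(track$times, sm)
  out$smoothing <- smoothing
  class(out) <- c("smoothed_track", "centromere_track")
  out
}

#' Restrict a recording to a subset of frames
#'
#' @param recording an [oocyte_recording()].
#' @param idx increasing frame indices to keep (at least 2).
#' @return the restricted recording.
#' @export
subset_recording <- function(recording, idx) {
  recording$times <- recording$times[idx]
  recording$pos <- recording$pos[idx, , , drop = FALSE]
  if (!is.null(recording$spos)) {
    recording$spos <- recording$spos[idx, , , drop = FALSE]
  }
  if (!is.null(recording$speeds)) {
    recording$speeds <- recording$speeds[idx, , drop = FALSE]
  }
  validate_oocyte_recording(recording)
  recording
}

#' Smooth every track of a recording
#'
#' Batched equivalent of [smooth_track()]: all chromatids of the recording
#' share one time grid, so one penalized solve handles all coordinates.
#'
#' @param recording an [oocyte_recording()].
#' @param smoothing spline parameter `p` in (0, 1].
#' @return the recording with added `spos` array (smoothed positions, same
#'   shape as `pos`) and `speeds` matrix (`n_time x n_chromatid`), class
#'   `smoothed_recording`.
#' @export
smooth_recording <- function(recording, smoothing = 0.35) {
  nt <- length(recording$times)
  nc <- dim(recording$pos)[3]
  flat <- matrix(recording$pos, nrow = nt)      # columns: coord-major slices
  sm <- fit_smoothing_spline(recording$times, flat, smoothing)
  spos <- array(sm, dim = dim(recording$pos))
  dt <- diff(recording$times)
  speeds <- matrix(NA_real_, nt, nc)
  for (k in seq_len(nc)) {
    speeds[, k] <- speeds_from_positions(recording$times, spos[, , k])
  }
  out <- recording
  out$spos <- spos
  out$speeds <- speeds
  out$smoothing <- smoothing
  class(out) <- c("smoothed_recording", "oocyte_recording")
  out
}
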