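# Cohort-level analysis: the per-oocyte pipeline driver, summaries,
# the per-1000-chromosome extrapolation, and report output.

#' Analyse one oocyte recording end-to-end
#'
#' Runs smoothing, onset detection, spindle-frame estimation over the
#' pre-onset window, metaphase metrics, pole assignment, laggard
#' detection, segregation classification and ploidy calling. A recording
#' in which no onset is found (metaphase-arrested) yields metaphase
#' fields only.
#'
#' @param recording an [oocyte_recording()].
#' @param params an [analysis_params()] list.
#' @param egg_direction optional length-3 vector marking the egg side
#'   (for synthetic data, the ground-truth axis; not inferable from
#'   centromere tracks alone).
#' @return list with `onset` (or NULL), `onset_found`, `metrics`,
#'   `calls`, `laggards`, `ploidy`, `frame_at_onset`.
#' @export
analyze_oocyte <- function(recording, params = analysis_params(),
                           egg_direction = NULL) {
  onset <- tryCatch(detect_anaphase_onset(recording, params),
                    miiseg_onset_not_found = function(e) NULL)
  if (is.null(onset)) {
    return(list(onset = NULL, onset_found = FALSE, metrics = NULL,
                calls = NULL, laggards = NULL,
                ploidy = call_ploidy(recording, NULL, NULL),
                frame_at_onset = NULL))
  }
  times <- recording$times
  # metaphase metrics come from a spline fitted to the pre-onset segment
  # only: a global fit would leak the (much larger) anaphase excursions
  # backward into the last window frames
  sm <- smooth_recording(subset_recording(recording,
                                          seq_len(onset$index - 1L)),
                         params$smoothing)
  idx_window <- which(times >= onset$onset_min - params$window_min &
                        times < onset$onset_min)
  frames <- estimate_frames(sm, idx_window,
                            params$alignment_radius_um, egg_direction)
  metrics <- compute_metrics(sm, frames, onset$onset_min, params$window_min)
  frame_at_onset <- estimate_frame(recording, onset$index,
                                   params$alignment_radius_um)
  ref <- egg_direction %||% frames[[length(frames)]]$axis
  if (sum(frame_at_onset$axis * ref) < 0) {
    frame_at_onset$axis <- -frame_at_onset$axis
  }
  assignments <- assign_poles(recording, onset, frame_at_onset, params,
                              egg_direction)
  laggards <- detect_laggards(recording, assignments, onset, params)
  calls <- classify_segregation(recording, onset, frame_at_onset,
                                assignments, laggards, params)
  ploidy <- call_ploidy(recording, calls, assignments)
  list(onset = onset, onset_found = TRUE, metrics = metrics, calls = calls,
       laggards = laggards, ploidy = ploidy, frame_at_onset = frame_at_onset)
}

#' Analyse a cohort of recordings
#'
#' Applies [analyze_oocyte()] to every recording and assembles tidy
#' cohort-level tables. When ground truth is available (synthetic
#' cohorts) the true class and parameters are merged into the call and
#' metric tables (columns prefixed `true_`) for validation; classification
#' itself never sees them.
#'
#' @param cohort a `miiseg_cohort` (list of `list(recording, truth)`)
#'   or a plain list of recordings.
#' @param params an [analysis_params()] list.
#' @param use_true_egg_direction orient the egg side from ground truth
#'   when available (default TRUE); otherwise the +hemisphere of the
#'   estimated axis is used.
#' @return list of data.frames: `calls`, `metrics`, `laggards`, `ploidy`,
#'   `onsets`.
#' @export
analyze_cohort <- function(cohort, params = analysis_params(),
                           use_true_egg_direction = TRUE) {
  res <- lapply(cohort, function(el) {
    if (inherits(el, "oocyte_recording")) el <- list(recording = el)
    rec <- el$recording
    truth <- el$truth
    egg_dir <- if (use_true_egg_direction && !is.null(truth))
      truth$true_axis else NULL
    a <- analyze_oocyte(rec, params, egg_dir)

    meta <- data.frame(oocyte_id = rec$oocyte_id, age_group = rec$age_group,
                       batch = rec$batch)
    calls <- if (!is.null(a$calls)) cbind(meta, a$calls) else NULL
    metrics <- if (!is.null(a$metrics)) cbind(meta, a$metrics) else NULL
    laggards <- if (!is.null(a$laggards)) cbind(meta, a$laggards) else NULL
    if (!is.null(truth)) {
      tc <- truth$per_chromosome
      if (!is.null(calls)) {
        m <- match(calls$chromosome_id, tc$chromosome_id)
        calls$true_class <- tc$true_class[m]
        calls$true_merge_time_min <- tc$true_merge_time_min[m]
      }
      if (!is.null(metrics)) {
        m <- match(metrics$chromosome_id, tc$chromosome_id)
        metrics$true_class <- tc$true_class[m]
        metrics$true_icd_um <- tc$true_icd_um[m]
        metrics$true_angle_deg <- tc$true_angle_deg[m]
        metrics$true_speed_um_per_min <- tc$true_speed_um_per_min[m]
      }
    }
    onsets <- cbind(meta, data.frame(
      onset_found = a$onset_found,
      onset_min = if (a$onset_found) a$onset$onset_min else NA_real_,
      true_onset_min = if (!is.null(truth)) truth$true_onset_min
                       else NA_real_
    ))
    list(calls = calls, metrics = metrics, laggards = laggards,
         ploidy = cbind(data.frame(age_group = rec$age_group,
                                   batch = rec$batch), a$ploidy),
         onsets = onsets)
  })
  bind <- function(name) {
    parts <- Filter(Negate(is.null), lapply(res, `[[`, name))
    if (!length(parts)) return(NULL)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  }
  list(calls = bind("calls"), metrics = bind("metrics"),
       laggards = bind("laggards"), ploidy = bind("ploidy"),
       onsets = bind("onsets"))
}

batch_mean_sd <- function(values, batches) {
  per <- tapply(values, batches, mean)
  if (length(per) < 2) {
    message("single batch: across-batch SD unavailable")
    return(c(mean = unname(per[1]), sd = NA_real_))
  }
  c(mean = mean(per), sd = stats::sd(per))
}

#' Summarise a cohort's calls, ploidy and metrics
#'
#' Fractions (aberrant oocytes, aneuploid eggs/oocytes) are computed per
#' batch and reported as mean +/- SD across batches, mirroring the
#' mean-over-independent-experiments presentation; chromosome-level rates
#' are pooled. Metric summaries are split by segregation outcome
#' (normal vs aberrant call).
#'
#' @param calls cohort call table ([analyze_cohort()] `$calls`).
#' @param ploidy cohort ploidy table.
#' @param metrics cohort metric table (optional).
#' @param batch_labels optional replacement batch labels keyed by
#'   `oocyte_id` (defaults to the `batch` column).
#' @return object of class `cohort_summary` (a list).
#' @export
summarize_cohort <- function(calls, ploidy, metrics = NULL,
                             batch_labels = NULL) {
  if (is.null(calls) || !nrow(calls)) stop("summarize_cohort: empty cohort")
  if (!is.null(batch_labels)) {
    calls$batch <- batch_labels[calls$oocyte_id]
    ploidy$batch <- batch_labels[ploidy$oocyte_id]
  }
  resolved <- calls[calls$pattern != "unresolved", ]
  per_oocyte <- tapply(resolved$pattern != "normal", resolved$oocyte_id, any)
  oocyte_batch <- tapply(as.character(resolved$batch), resolved$oocyte_id,
                         `[`, 1)
  n_oocytes <- length(per_oocyte)

  frac_oocytes_aberrant <- batch_mean_sd(as.numeric(per_oocyte),
                                         oocyte_batch[names(per_oocyte)])
  aneuploid_known <- !is.na(ploidy$aneuploid_egg)
  frac_eggs_aneuploid <- if (any(aneuploid_known)) {
    batch_mean_sd(as.numeric(ploidy$aneuploid_egg[aneuploid_known]),
                  ploidy$batch[aneuploid_known])
  } else c(mean = NA_real_, sd = NA_real_)
  frac_mII_aneuploid <- batch_mean_sd(as.numeric(ploidy$aneuploid_mII),
                                      ploidy$batch)

  n_aberrant <- sum(resolved$pattern != "normal")
  class_counts <- table(resolved$pattern)
  merge_times <- resolved$merge_time_min[!is.na(resolved$merge_time_min)]

  metric_summary <- NULL
  if (!is.null(metrics) && nrow(metrics)) {
    m <- merge(metrics,
               resolved[c("oocyte_id", "chromosome_id", "pattern")],
               by = c("oocyte_id", "chromosome_id"))
    m$outcome <- ifelse(m$pattern == "normal", "normal", "aberrant")
    cols <- c("max_dist_to_equator_um", "max_dist_to_axis_um",
              "mean_angle_deg", "mean_speed_um_per_min", "mean_icd_um")
    metric_summary <- do.call(rbind, lapply(cols, function(cl) {
      data.frame(
        metric = cl,
        normal_mean = mean(m[[cl]][m$outcome == "normal"]),
        normal_sd = stats::sd(m[[cl]][m$outcome == "normal"]),
        aberrant_mean = if (any(m$outcome == "aberrant"))
          mean(m[[cl]][m$outcome == "aberrant"]) else NA_real_,
        aberrant_sd = if (sum(m$outcome == "aberrant") > 1)
          stats::sd(m[[cl]][m$outcome == "aberrant"]) else NA_real_
      )
    }))
  }

  structure(list(
    age_group = calls$age_group[1],
    n_oocytes = n_oocytes,
    n_batches = length(unique(calls$batch)),
    frac_oocytes_aberrant = unname(frac_oocytes_aberrant["mean"]),
    frac_oocytes_aberrant_sd = unname(frac_oocytes_aberrant["sd"]),
    frac_oocytes_aberrant_pooled = mean(per_oocyte),
    frac_eggs_aneuploid = unname(frac_eggs_aneuploid["mean"]),
    frac_eggs_aneuploid_sd = unname(frac_eggs_aneuploid["sd"]),
    frac_eggs_aneuploid_pooled =
      mean(ploidy$aneuploid_egg[aneuploid_known]),
    frac_mII_aneuploid = unname(frac_mII_aneuploid["mean"]),
    frac_chromosomes_aberrant = n_aberrant / nrow(resolved),
    mean_aberrant_per_oocyte = n_aberrant / n_oocytes,
    class_counts = class_counts,
    n_unresolved = sum(calls$pattern == "unresolved"),
    mean_merge_time_min = if (length(merge_times)) mean(merge_times)
                          else NA_real_,
    sd_merge_time_min = if (length(merge_times) > 1) stats::sd(merge_times)
                        else NA_real_,
    n_laggard_episodes = length(merge_times),
    metric_summary = metric_summary
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s: %d oocytes in %d batches\n",
              x$age_group, x$n_oocytes, x$n_batches))
  cat(sprintf("  aberrant oocytes: %.1f%% (batch mean %.1f +/- %.1f%%)\n",
              100 * x$frac_oocytes_aberrant_pooled,
              100 * x$frac_oocytes_aberrant,
              100 * x$frac_oocytes_aberrant_sd))
  cat(sprintf("  aneuploid eggs:   %.1f%% (batch mean %.1f +/- %.1f%%)\n",
              100 * x$frac_eggs_aneuploid_pooled,
              100 * x$frac_eggs_aneuploid, 100 * x$frac_eggs_aneuploid_sd))
  cat(sprintf("  aberrant chromosomes: %.2f%%, %.2f per oocyte\n",
              100 * x$frac_chromosomes_aberrant,
              x$mean_aberrant_per_oocyte))
  if (is.finite(x$mean_merge_time_min)) {
    cat(sprintf("  laggard merge time: %.1f +/- %.1f min (%d episodes)\n",
                x$mean_merge_time_min, x$sd_merge_time_min,
                x$n_laggard_episodes))
  }
  invisible(x)
}

#' Summarise kinetochore-attachment tables
#'
#' @param attachments output of [simulate_attachments()] (or a table with
#'   the same columns).
#' @return list with the merotelic fraction, per-class counts and
#'   inter-centromere-distance summaries, and the Mann-Whitney comparison
#'   of merotelic vs amphitelic distances.
#' @export
summarize_attachments <- function(attachments) {
  stopifnot(all(c("attachment", "icd_um") %in% names(attachments)))
  mero <- attachments$attachment == "merotelic"
  list(
    n_chromosomes = nrow(attachments),
    n_merotelic = sum(mero),
    frac_merotelic = mean(mero),
    merotelic_per_oocyte = sum(mero) /
      length(unique(attachments$oocyte_id)),
    icd_amphitelic_mean = mean(attachments$icd_um[!mero]),
    icd_amphitelic_sd = stats::sd(attachments$icd_um[!mero]),
    icd_merotelic_mean = mean(attachments$icd_um[mero]),
    icd_merotelic_sd = stats::sd(attachments$icd_um[mero]),
    icd_test = mann_whitney(attachments$icd_um[mero],
                            attachments$icd_um[!mero])
  )
}

EXTRAPOLATION_CATEGORIES <- c("amphitelic_normal", "merotelic_normal",
                              "merotelic_equational",
                              "merotelic_aneuploidy")

#' Extrapolate chromosome fates to a standard 1000 chromosomes
#'
#' Normalises the observed fractions to an initial pool of 1000
#' chromosomes per group: merotelic attachments are a subset of all
#' chromosomes, aberrantly segregating chromosomes a subset of the
#' merotelic ones, and aneuploidy-causing chromosomes a subset of the
#' aberrant ones. Counts are `1000 * f` rounded with a largest-remainder
#' correction so the four categories sum to exactly 1000. Each category
#' is assigned an inter-centromere-distance sample resampled (with
#' replacement) from the supplied empirical distributions, scaled to the
#' category count.
#'
#' @param f_merotelic fraction of chromosomes with merotelic attachments
#'   (~0.13 in both age groups).
#' @param f_aberrant fraction showing an aberrant anaphase-II pattern
#'   (aged midpoint 0.045; young 0.015).
#' @param f_aneuploidy fraction contributing to aneuploidy (aged midpoint
#'   0.015; young 0.0015).
#' @param icd_samples_by_category optional named list of empirical
#'   inter-centromere-distance vectors (names in
#'   `c("amphitelic_normal", "merotelic_normal", "merotelic_equational",
#'   "merotelic_aneuploidy")`).
#' @return object of class `extrapolation_result`: list with `counts`
#'   (named, summing to 1000) and `icd_samples`.
#' @export
extrapolate_per_1000 <- function(f_merotelic, f_aberrant, f_aneuploidy,
                                 icd_samples_by_category = NULL) {
  if (!(f_aneuploidy >= 0 && f_aneuploidy <= f_aberrant &&
        f_aberrant <= f_merotelic && f_merotelic <= 1)) {
    stop("extrapolate_per_1000: need 0 <= f_aneuploidy <= f_aberrant <= ",
         "f_merotelic <= 1")
  }
  fractions <- c(
    amphitelic_normal = 1 - f_merotelic,
    merotelic_normal = f_merotelic - f_aberrant,
    merotelic_equational = f_aberrant - f_aneuploidy,
    merotelic_aneuploidy = f_aneuploidy
  )
  raw <- 1000 * fractions
  counts <- floor(raw)
  short <- 1000 - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  stopifnot(sum(counts) == 1000)

  icd_samples <- NULL
  if (!is.null(icd_samples_by_category)) {
    icd_samples <- lapply(EXTRAPOLATION_CATEGORIES, function(cat) {
      src <- icd_samples_by_category[[cat]]
      if (is.null(src) || !length(src) || counts[cat] == 0) {
        return(numeric(0))
      }
      sample(src, counts[cat], replace = TRUE)
    })
    names(icd_samples) <- EXTRAPOLATION_CATEGORIES
  }
  structure(list(counts = counts, fractions = fractions,
                 icd_samples = icd_samples),
            class = "extrapolation_result")
}

#' @export
print.extrapolation_result <- function(x, ...) {
  cat("<extrapolation_result> per 1000 chromosomes:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %4d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> smooth -> spindle frame -> metrics -> onset
#' -> classification -> ploidy -> summaries -> statistics ->
#' extrapolation, optionally writing all tables, a JSON summary and a run
#' log to `out_dir`. Reruns with the same config and seed produce an
#' identical summary.
#'
#' @param input either a `miiseg_cohort`, a path to a track CSV (see
#'   [read_tracks()]), or the string `"simulate"`.
#' @param config a [generator_config()] (required when simulating; also
#'   supplies the extrapolation defaults).
#' @param out_dir output directory (created); NULL returns results
#'   without writing.
#' @param seed integer seed for simulation and resampling.
#' @param params an [analysis_params()] list.
#' @param n_oocytes,n_batches cohort size when `input = "simulate"`.
#' @param write_track_csv also write the (large) simulated track table.
#' @return list with `analysis`, `summary`, `extrapolation`, `config`.
#' @export
run_pipeline <- function(input, config = NULL, out_dir = NULL, seed = 1L,
                         params = analysis_params(), n_oocytes = 50L,
                         n_batches = 5L, write_track_csv = FALSE) {
  if (is.character(input) && length(input) == 1 && input != "simulate") {
    if (dir.exists(input)) {
      files <- list.files(input, pattern = "\\.(csv|tsv)$",
                          full.names = TRUE)
      if (!length(files)) {
        stop("run_pipeline: no track CSV/TSV files in ", input)
      }
      cohort <- unlist(lapply(files, function(f) {
        lapply(read_tracks(f), function(r) list(recording = r, truth = NULL))
      }), recursive = FALSE)
    } else {
      cohort <- lapply(read_tracks(input),
                       function(r) list(recording = r, truth = NULL))
    }
    class(cohort) <- "miiseg_cohort"
  } else if (identical(input, "simulate")) {
    if (is.null(config)) stop("run_pipeline: simulation requires a config")
    cohort <- simulate_cohort(config, n_oocytes, seed, n_batches)
  } else if (inherits(input, "miiseg_cohort") || is.list(input)) {
    cohort <- input
  } else {
    stop("run_pipeline: unrecognised input")
  }

  analysis <- analyze_cohort(cohort, params)
  if (is.null(analysis$calls)) {
    stop("run_pipeline: no anaphase onset found in any recording")
  }
  summary <- summarize_cohort(analysis$calls, analysis$ploidy,
                              analysis$metrics)

  aged <- !is.null(config) && config$age_group == "aged"
  f_ab <- if (aged) 0.045 else 0.015
  f_an <- if (aged) 0.015 else 0.0015
  f_mero <- if (!is.null(config)) config$p_merotelic else 0.13
  m <- analysis$metrics
  calls_key <- paste(analysis$calls$oocyte_id, analysis$calls$chromosome_id)
  pat <- analysis$calls$pattern[match(paste(m$oocyte_id, m$chromosome_id),
                                      calls_key)]
  set.seed(child_seed(seed, 999L))
  mero_icd <- if (!is.null(config)) {
    simulate_attachments(config, 50L, seed = child_seed(seed, 998L))
  } else NULL
  mero_pool <- if (!is.null(mero_icd)) {
    mero_icd$icd_um[mero_icd$attachment == "merotelic"]
  } else m$mean_icd_um[pat != "normal"]
  pick <- function(p) {
    v <- m$mean_icd_um[!is.na(pat) & pat %in% p]
    if (length(v) >= 5) v else mero_pool
  }
  extrapolation <- extrapolate_per_1000(
    f_mero, f_ab, f_an,
    icd_samples_by_category = list(
      amphitelic_normal = m$mean_icd_um[!is.na(pat) & pat == "normal"],
      merotelic_normal = mero_pool,
      merotelic_equational = pick("equational_laggard"),
      merotelic_aneuploidy = pick(ANEUPLOIDY_PATTERNS)
    )
  )

  result <- list(analysis = analysis, summary = summary,
                 extrapolation = extrapolation, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    wr(analysis$calls, "calls.csv")
    wr(analysis$metrics, "metrics.csv")
    wr(analysis$ploidy, "ploidy.csv")
    wr(analysis$laggards, "laggards.csv")
    wr(analysis$onsets, "onsets.csv")
    wr(data.frame(category = names(extrapolation$counts),
                  count_per_1000 = as.integer(extrapolation$counts)),
       "extrapolation.csv")
    if (write_track_csv) {
      write_tracks(lapply(cohort, `[[`, "recording"),
                   file.path(out_dir, "tracks.csv"))
    }
    summary_json <- summary[!vapply(summary, is.data.frame, logical(1))]
    summary_json$class_counts <- as.list(summary_json$class_counts)
    jsonlite::write_json(summary_json,
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         na = "null")
    writeLines(c(
      paste("miiseg", as.character(utils::packageVersion("miiseg"))),
      paste("R", paste(R.version$major, R.version$minor, sep = ".")),
      paste("seed", seed),
      paste("n_oocytes", length(cohort)),
      paste("age_group", if (!is.null(config)) config$age_group else "NA"),
      paste("smoothing", params$smoothing)
    ), file.path(out_dir, "run_log.txt"))
  }
  result
}

#' Write a simulated cohort to disk
#'
#' Track tables as CSV plus a ground-truth JSON sidecar.
#'
#' @param cohort a `miiseg_cohort`.
#' @param dir output directory (created).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks(lapply(cohort, `[[`, "recording"),
               file.path(dir, "tracks.csv"))
  truths <- lapply(cohort, function(el) {
    tr <- el$truth
    tr$per_chromosome <- as.list(tr$per_chromosome)
    tr
  })
  jsonlite::write_json(truths, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 10, na = "null")
  invisible(dir)
}
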