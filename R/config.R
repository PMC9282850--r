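#' Build a synthetic-cohort generator configuration
#'
#' Assembles every distributional parameter of the synthetic meiosis-II
#' oocyte generator. Defaults encode the published statistical structure of
#' the two mouse cohorts: chromosome-level metaphase-II metrics (inter-
#' centromere distance, chromosome--axis angle, speed) for normally versus
#' aberrantly segregating chromosomes, aberrancy rates at anaphase II,
#' laggard merge-time distributions, the monastrol (monopolar) tension-free
#' inter-centromere distances, and the metaphase-II attachment-class mix.
#'
#' Two-component numeric parameters are `c(mean, sd)` pairs in the stated
#' units. `class_mix` gives the conditional probabilities of the four
#' aberrant segregation patterns given that a chromosome is aberrant; the
#' aged default puts 2/3 on the equational-laggard class (18 of 27 aberrant
#' chromosomes segregated equationally) and splits the remaining 1/3 over
#' the three aneuploidy-causing classes. The young default puts 0.9 on the
#' equational class (one tenth of aberrant chromosomes contribute to
#' aneuploidy in young adults).
#'
#' @param age_group `"aged"` (47--50-week cohort) or `"young"`
#'   (11--13-week cohort); selects all group-specific defaults.
#' @param n_chromosomes chromosomes per oocyte (mouse: 20).
#' @param frame_interval_min acquisition interval in minutes (legal
#'   range 1.5--3).
#' @param metaphase_duration_min imaged metaphase-II span before anaphase
#'   onset, minutes.
#' @param post_onset_duration_min imaged span after anaphase onset, minutes.
#' @param plate_radius_um metaphase-plate radius: chromosome midpoints stay
#'   within this distance of the spindle axis.
#' @param icd_normal_um,icd_aberrant_um `c(mean, sd)` inter-centromere
#'   distance, micrometres, for normally / aberrantly segregating
#'   chromosomes.
#' @param angle_normal_deg,angle_aberrant_deg `c(mean, sd)` chromosome-axis
#'   angle, degrees.
#' @param speed_um_per_min,speed_aberrant_um_per_min `c(mean, sd)` mean
#'   chromosome (midpoint) speed, micrometres per minute.
#' @param p_oocyte_aberrant probability an oocyte contains at least one
#'   aberrant chromosome.
#' @param class_mix named probability vector over
#'   `c("equational_laggard", "coseg_with_laggard", "coseg_without_laggard",
#'   "misaligned_at_onset")`; must sum to 1.
#' @param merge_time_min `c(mean, sd)` laggard merge time, minutes from
#'   anaphase onset. Drawn from a truncated normal on
#'   `[merge_time_lower_min, post-onset span - 2 frames]` whose location is
#'   calibrated so the truncated mean equals the configured mean.
#' @param merge_time_lower_min lower truncation bound for merge times;
#'   merge times below ~10 min are unresolvable under the 5-min laggard
#'   dwell criterion.
#' @param positional_noise_sd_um isotropic Gaussian localization noise per
#'   coordinate, micrometres.
#' @param pole_separation_um spindle half-length at anaphase end: poles sit
#'   at centroid +/- this distance along the axis.
#' @param anaphase_speed_um_per_min poleward speed of immediately
#'   segregating chromatids.
#' @param laggard_speed_um_per_min poleward transit speed of a resolved
#'   lagging chromatid (its release time is back-computed from the drawn
#'   merge time).
#' @param p_mII_aneuploid probability the oocyte enters metaphase II already
#'   aneuploid (default 0: no aneuploidy increase is seen at MI completion).
#' @param icd_monopolar_um `c(mean, sd)` tension-free inter-centromere
#'   distance on a monastrol-induced monopolar spindle.
#' @param p_merotelic probability a chromosome carries a merotelic
#'   kinetochore-microtubule attachment at metaphase II (~13%).
#' @param icd_amphitelic_um,icd_merotelic_um `c(mean, sd)` inter-centromere
#'   distance for amphitelically / merotelically attached chromosomes in
#'   fixed metaphase-II oocytes.
#' @param seed optional integer seed stored with the config.
#'
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config("aged")
#' cfg$icd_aberrant_um
#' @export
generator_config <- function(age_group = c("aged", "young"),
                             n_chromosomes = 20L,
                             frame_interval_min = 2,
                             metaphase_duration_min = 60,
                             post_onset_duration_min = 40,
                             plate_radius_um = 4.5,
                             icd_normal_um = NULL,
                             icd_aberrant_um = NULL,
                             angle_normal_deg = NULL,
                             angle_aberrant_deg = NULL,
                             speed_um_per_min = NULL,
                             speed_aberrant_um_per_min = NULL,
                             p_oocyte_aberrant = NULL,
                             class_mix = NULL,
                             merge_time_min = NULL,
                             merge_time_lower_min = 10,
                             positional_noise_sd_um = 0.1,
                             pole_separation_um = 12,
                             anaphase_speed_um_per_min = 1.0,
                             laggard_speed_um_per_min = 3.0,
                             p_mII_aneuploid = 0,
                             icd_monopolar_um = NULL,
                             p_merotelic = 0.13,
                             icd_amphitelic_um = NULL,
                             icd_merotelic_um = NULL,
                             seed = NULL) {
  age_group <- match.arg(age_group)
  aged <- age_group == "aged"

  icd_normal_um <- icd_normal_um %||% if (aged) c(1.6, 0.3) else c(1.7, 0.2)
  icd_aberrant_um <- icd_aberrant_um %||% if (aged) c(0.8, 0.3) else c(1.3, 0.7)
  angle_normal_deg <- angle_normal_deg %||% if (aged) c(7.5, 2) else c(6, 2)
  angle_aberrant_deg <- angle_aberrant_deg %||% if (aged) c(24, 12) else c(17, 10)
  speed_um_per_min <- speed_um_per_min %||% if (aged) c(0.18, 0.03) else c(0.2, 0.03)
  speed_aberrant_um_per_min <-
    speed_aberrant_um_per_min %||% if (aged) c(0.22, 0.07) else c(0.2, 0.04)
  p_oocyte_aberrant <- p_oocyte_aberrant %||% if (aged) 0.55 else 0.15
  class_mix <- class_mix %||% if (aged) {
    c(equational_laggard = 18 / 27, coseg_with_laggard = 3 / 27,
      coseg_without_laggard = 3 / 27, misaligned_at_onset = 3 / 27)
  } else {
    c(equational_laggard = 0.9, coseg_with_laggard = 0.1 / 3,
      coseg_without_laggard = 0.1 / 3, misaligned_at_onset = 0.1 / 3)
  }
  merge_time_min <- merge_time_min %||% if (aged) c(20, 8) else c(15, 3)
  icd_monopolar_um <- icd_monopolar_um %||% if (aged) c(0.8, 0.3) else c(0.7, 0.2)
  icd_amphitelic_um <- icd_amphitelic_um %||% if (aged) c(1.4, 0.2) else c(1.3, 0.2)
  icd_merotelic_um <- icd_merotelic_um %||% if (aged) c(1.0, 0.3) else c(1.1, 0.3)

  cfg <- list(
    age_group = age_group,
    n_chromosomes = as.integer(n_chromosomes),
    frame_interval_min = frame_interval_min,
    metaphase_duration_min = metaphase_duration_min,
    post_onset_duration_min = post_onset_duration_min,
    plate_radius_um = plate_radius_um,
    icd_normal_um = icd_normal_um,
    icd_aberrant_um = icd_aberrant_um,
    angle_normal_deg = angle_normal_deg,
    angle_aberrant_deg = angle_aberrant_deg,
    speed_um_per_min = speed_um_per_min,
    speed_aberrant_um_per_min = speed_aberrant_um_per_min,
    p_oocyte_aberrant = p_oocyte_aberrant,
    class_mix = class_mix,
    merge_time_min = merge_time_min,
    merge_time_lower_min = merge_time_lower_min,
    positional_noise_sd_um = positional_noise_sd_um,
    pole_separation_um = pole_separation_um,
    anaphase_speed_um_per_min = anaphase_speed_um_per_min,
    laggard_speed_um_per_min = laggard_speed_um_per_min,
    p_mII_aneuploid = p_mII_aneuploid,
    icd_monopolar_um = icd_monopolar_um,
    p_merotelic = p_merotelic,
    icd_amphitelic_um = icd_amphitelic_um,
    icd_merotelic_um = icd_merotelic_um,
    seed = if (!is.null(seed)) as.integer(seed) else NULL
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)

  # Merge-time truncation bounds and calibrated location (see vignette):
  # the upper bound keeps every merge observable before the recording ends.
  upper <- post_onset_duration_min - 2 * frame_interval_min
  if (merge_time_min[1] >= upper) {
    stop("merge_time_min mean must lie below the observable post-onset span")
  }
  cfg$merge_time_bounds <- c(merge_time_lower_min, upper)
  cfg$merge_time_location <- truncnorm_location_for_mean(
    merge_time_min[1], merge_time_min[2], merge_time_lower_min, upper
  )
  cfg
}

validate_generator_config <- function(cfg) {
  num <- vapply(cfg[!vapply(cfg, is.null, logical(1)) &
                      !(names(cfg) %in% c("age_group", "class_mix"))],
                function(x) all(is.finite(x)), logical(1))
  if (!all(num)) {
    stop("generator_config: non-finite parameter(s): ",
         paste(names(num)[!num], collapse = ", "))
  }
  probs <- c(p_oocyte_aberrant = cfg$p_oocyte_aberrant,
             p_mII_aneuploid = cfg$p_mII_aneuploid,
             p_merotelic = cfg$p_merotelic)
  if (any(probs < 0 | probs > 1)) {
    stop("generator_config: probabilities must lie in [0, 1]")
  }
  cm <- cfg$class_mix
  need <- c("equational_laggard", "coseg_with_laggard",
            "coseg_without_laggard", "misaligned_at_onset")
  if (!setequal(names(cm), need) || any(cm < 0) ||
      abs(sum(cm) - 1) > 1e-8) {
    stop("generator_config: class_mix must be a probability vector over the ",
         "four aberrant classes summing to 1")
  }
  pairs <- c("icd_normal_um", "icd_aberrant_um", "angle_normal_deg",
             "angle_aberrant_deg", "speed_um_per_min",
             "speed_aberrant_um_per_min", "merge_time_min",
             "icd_monopolar_um", "icd_amphitelic_um", "icd_merotelic_um")
  for (p in pairs) {
    v <- cfg[[p]]
    if (length(v) != 2 || v[2] < 0) {
      stop("generator_config: ", p, " must be c(mean, sd) with sd >= 0")
    }
  }
  if (cfg$n_chromosomes < 1) stop("generator_config: n_chromosomes >= 1 required")
  if (cfg$frame_interval_min <= 0) {
    stop("generator_config: frame_interval_min must be positive")
  }
  if (cfg$positional_noise_sd_um < 0) {
    stop("generator_config: positional_noise_sd_um must be >= 0")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>", x$age_group, "cohort;",
      x$n_chromosomes, "chromosomes;",
      x$frame_interval_min, "min frames;",
      "P(oocyte aberrant) =", x$p_oocyte_aberrant, "\n")
  cat("  icd normal/aberrant (um):",
      sprintf("%.2f+/-%.2f", x$icd_normal_um[1], x$icd_normal_um[2]), "/",
      sprintf("%.2f+/-%.2f", x$icd_aberrant_um[1], x$icd_aberrant_um[2]), "\n")
  cat("  angle normal/aberrant (deg):",
      sprintf("%.1f+/-%.1f", x$angle_normal_deg[1], x$angle_normal_deg[2]), "/",
      sprintf("%.1f+/-%.1f", x$angle_aberrant_deg[1], x$angle_aberrant_deg[2]),
      "\n")
  invisible(x)
}

#' Analysis parameters for the track-to-call pipeline
#'
#' Tunable thresholds of the measurement pipeline, all in physical units.
#' None of these is quantified by the source data beyond the smoothing
#' parameter; defaults are documented modelling choices.
#'
#' @param smoothing cubic smoothing-spline parameter `p` in (0, 1] of the
#'   criterion `p * sum((y - f)^2) + (1 - p) * integral(f'')^2`.
#' @param alignment_radius_um equator-distance trim radius used when
#'   iteratively selecting aligned chromosomes for spindle-axis fitting.
#' @param window_min pre-onset averaging window for metaphase metrics.
#' @param midzone_halfwidth_um half-width of the spindle-midzone band; a
#'   chromatid farther than this from the equator plane is pole-assigned.
#' @param lag_min_duration_min minimum time a chromatid must remain in the
#'   midzone (while its sister is pole-assigned) to count as a laggard.
#' @param merge_radius_um distance to the destination pole's chromatid
#'   cluster centroid below which a laggard has merged.
#' @param misalign_threshold_um midpoint-to-equator distance at onset above
#'   which a chromosome is called misaligned.
#' @param baseline_frames trailing frames used for the onset-detection
#'   inter-centromere-distance baseline.
#' @param baseline_sd_mult baseline standard-deviation multiplier for the
#'   onset threshold.
#' @param rise_frames number of subsequent frames over which the median
#'   inter-centromere distance must increase monotonically at onset.
#' @return A named list of class `analysis_params`.
#' @export
analysis_params <- function(smoothing = 0.35,
                            alignment_radius_um = 3,
                            window_min = 40,
                            midzone_halfwidth_um = 2,
                            lag_min_duration_min = 5,
                            merge_radius_um = 2,
                            misalign_threshold_um = 3,
                            baseline_frames = 10,
                            baseline_sd_mult = 2,
                            rise_frames = 2) {
  stopifnot(smoothing > 0, smoothing <= 1,
            alignment_radius_um > 0, window_min > 0,
            midzone_halfwidth_um > 0, lag_min_duration_min >= 0,
            merge_radius_um > 0, misalign_threshold_um > 0,
            baseline_frames >= 2, baseline_sd_mult >= 0, rise_frames >= 0)
  structure(list(
    smoothing = smoothing,
    alignment_radius_um = alignment_radius_um,
    window_min = window_min,
    midzone_halfwidth_um = midzone_halfwidth_um,
    lag_min_duration_min = lag_min_duration_min,
    merge_radius_um = merge_radius_um,
    misalign_threshold_um = misalign_threshold_um,
    baseline_frames = baseline_frames,
    baseline_sd_mult = baseline_sd_mult,
    rise_frames = rise_frames
  ), class = "analysis_params")
}
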