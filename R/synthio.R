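# Synthetic meiosis-II oocyte recordings with known ground truth.
#
# Geometry is built in a canonical frame (spindle axis = +z, egg pole on
# the +z side, plate centred at the origin) and then rigidly rotated and
# translated per oocyte, so the analysis pipeline must re-estimate the
# spindle frame from the data.

ABERRANT_CLASSES <- c("equational_laggard", "coseg_with_laggard",
                      "coseg_without_laggard", "misaligned_at_onset")

# Sister-pair orientation unit vector from polar angle (deg) and azimuth.
orientation_vector <- function(theta_deg, phi) {
  th <- theta_deg * pi / 180
  c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
}

# Smooth bounded in-plane path with exact frame-to-frame speed.
# Persistent walk: heading rotates by a small Gaussian angle per frame;
# the in-plane step length is chosen so the total 3D step (including the
# axial component dz) equals speed * dt; reflected at the plate boundary.
persistent_walk_xy <- function(n_frames, start_xy, speed, dt, dz,
                               plate_radius, turn_sd = 0.35) {
  xy <- matrix(NA_real_, n_frames, 2)
  xy[1, ] <- start_xy
  heading <- stats::runif(1, 0, 2 * pi)
  step3 <- speed * dt
  for (k in 2:n_frames) {
    heading <- heading + stats::rnorm(1, 0, turn_sd)
    l <- sqrt(max(0, step3^2 - dz[k - 1]^2))
    cand <- xy[k - 1, ] + l * c(cos(heading), sin(heading))
    if (sqrt(sum(cand^2)) > plate_radius) {
      # reflect: head back toward the plate centre with jitter
      heading <- atan2(-xy[k - 1, 2], -xy[k - 1, 1]) +
        stats::rnorm(1, 0, 0.2)
      cand <- xy[k - 1, ] + l * c(cos(heading), sin(heading))
      r <- sqrt(sum(cand^2))
      if (r > plate_radius) cand <- cand * (plate_radius / r)
    }
    xy[k, ] <- cand
  }
  xy
}

# Draw per-chromosome ground-truth classes for one oocyte.
draw_classes <- function(config, n, forced_classes = NULL) {
  classes <- rep("normal", n)
  if (!is.null(forced_classes)) {
    stopifnot(all(forced_classes %in% c("normal", ABERRANT_CLASSES)))
    k <- length(forced_classes)
    if (k > n) stop("make_fixture_cohort: class counts exceed n_chromosomes")
    classes[sample.int(n, k)] <- forced_classes
    return(classes)
  }
  if (stats::runif(1) < config$p_oocyte_aberrant) {
    # 1 + Bernoulli(0.5): mean 1.5 aberrant chromosomes per aberrant oocyte
    n_ab <- min(n, 1L + stats::rbinom(1, 1, 0.5))
    which_ab <- sample.int(n, n_ab)
    classes[which_ab] <- sample(names(config$class_mix), n_ab,
                                replace = TRUE, prob = config$class_mix)
  }
  classes
}

#' Simulate one metaphase-II / anaphase-II oocyte recording
#'
#' Generates the 4D centromere tracks of a single oocyte together with its
#' ground truth. During metaphase, sister-pair midpoints follow a smooth
#' bounded persistent walk within the metaphase plate with exact
#' frame-to-frame speed; sister connection vectors hold a fixed
#' class-appropriate angle to the spindle axis at the class-appropriate
#' inter-centromere distance. After anaphase onset, normally segregating
#' sisters move to opposite poles at constant speed; equational laggards
#' hold near the midzone and then segregate opposite their sister, merging
#' with the destination pole's chromatin cluster at the drawn merge time;
#' co-segregating classes deliver both sisters to one pole (with or
#' without a laggard episode); misaligned chromosomes sit more than 3 um
#' from the equator plane at onset and co-segregate toward the nearer
#' pole. Isotropic Gaussian localisation noise is added everywhere, and
#' the whole oocyte receives a random rigid rotation + translation.
#'
#' @param config a [generator_config()].
#' @param seed optional integer seed (falls back to `config$seed`; if both
#'   are NULL the current RNG state is used).
#' @param oocyte_id label for the oocyte.
#' @param batch batch/experiment label.
#' @param forced_classes optional character vector of ground-truth classes
#'   to impose (used by [make_fixture_cohort()]).
#' @return list with elements `recording` ([oocyte_recording()]) and
#'   `truth` (ground-truth list, see Details).
#' @details The ground truth contains `per_chromosome` (class, true
#'   inter-centromere distance, angle, merge time, per-sister pole
#'   destination), `true_onset_min` (first frame showing sister
#'   separation), `true_axis` (unit vector toward the egg pole),
#'   `true_centroid` (plate centre) and `egg_chromatid_count`.
#' @export
simulate_oocyte <- function(config, seed = NULL, oocyte_id = "oocyte_1",
                            batch = "batch_1", forced_classes = NULL) {
  validate_generator_config(config)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  dt <- config$frame_interval_min
  t_meta <- config$metaphase_duration_min
  times <- seq(0, t_meta + config$post_onset_duration_min, by = dt)
  n_meta <- sum(times <= t_meta)          # frames up to metaphase end
  n_time <- length(times)
  true_onset <- times[n_meta] + dt        # first frame with separation
  n <- config$n_chromosomes
  noise <- config$positional_noise_sd_um
  pole_z <- config$pole_separation_um
  v_ana <- config$anaphase_speed_um_per_min
  v_lag <- config$laggard_speed_um_per_min

  # MI-derived aneuploidy: drop or duplicate one chromosome pair
  chromosomes <- seq_len(n)
  if (config$p_mII_aneuploid > 0 &&
      stats::runif(1) < config$p_mII_aneuploid) {
    if (stats::runif(1) < 0.5 && n > 1) {
      chromosomes <- chromosomes[-sample.int(n, 1)]
    } else {
      chromosomes <- c(chromosomes, n + 1L)
    }
  }
  n_eff <- length(chromosomes)

  classes <- draw_classes(config, n_eff, forced_classes)
  aberrant <- classes != "normal"
  needs_midzone <- classes %in% c("equational_laggard", "coseg_with_laggard")

  icd <- ifelse(aberrant,
                rtruncnorm(n_eff, config$icd_aberrant_um[1],
                           config$icd_aberrant_um[2], lower = 0.1),
                rtruncnorm(n_eff, config$icd_normal_um[1],
                           config$icd_normal_um[2], lower = 0.1))
  angle <- ifelse(aberrant,
                  abs(stats::rnorm(n_eff, config$angle_aberrant_deg[1],
                                   config$angle_aberrant_deg[2])),
                  abs(stats::rnorm(n_eff, config$angle_normal_deg[1],
                                   config$angle_normal_deg[2])))
  angle <- pmin(angle, 89)
  speed <- ifelse(aberrant,
                  rtruncnorm(n_eff, config$speed_aberrant_um_per_min[1],
                             config$speed_aberrant_um_per_min[2],
                             lower = 0.02),
                  rtruncnorm(n_eff, config$speed_um_per_min[1],
                             config$speed_um_per_min[2], lower = 0.02))

  # equally spaced azimuths (random offset): the orientation tensor of the
  # plate is then exactly axis-aligned in the noise-free limit
  phi <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(n_eff) / n_eff

  merge_times <- rep(NA_real_, n_eff)
  has_laggard_cls <- needs_midzone
  mb <- config$merge_time_bounds
  merge_times[has_laggard_cls] <- round(
    rtruncnorm(sum(has_laggard_cls), config$merge_time_location,
               config$merge_time_min[2], mb[1], mb[2]) / dt
  ) * dt

  pos <- array(NA_real_, c(n_time, 3, 2 * n_eff))
  dest <- matrix(NA_character_, n_eff, 2)   # columns: sister 0, sister 1

  for (i in seq_len(n_eff)) {
    u <- orientation_vector(angle[i], phi[i])
    cls <- classes[i]

    # ---- metaphase midpoint path (canonical frame) ----
    if (cls == "misaligned_at_onset") {
      z_sign <- sample(c(-1, 1), 1)
      z0 <- z_sign * stats::runif(1, 3.6, 4.6)
      amp <- stats::runif(1, 0.05, 0.15)
    } else {
      z0 <- max(-2.1, min(2.1, stats::rnorm(1, 0, 1.3)))
      amp <- stats::runif(1, 0.2, 0.7)
    }
    period <- stats::runif(1, 40, 80)
    phase <- stats::runif(1, 0, 2 * pi)
    z_path <- z0 + amp * sin(2 * pi * times[1:n_meta] / period + phase)
    if (cls != "misaligned_at_onset") {
      # keep laggard-destined and co-segregating chromosomes in the
      # midzone; the lagging CHROMATID (midpoint + sister offset) must
      # stay within 2 um of the equator plane, with noise margin
      cap <- if (needs_midzone[i] || cls == "coseg_without_laggard") {
        max(0.3, min(1.2, 1.75 - (icd[i] / 2) * cos(angle[i] * pi / 180)))
      } else 2.8
      mx <- max(abs(z_path))
      if (mx > cap) z_path <- z_path * (cap / mx)
    }
    r0 <- sqrt(stats::runif(1)) * config$plate_radius_um
    a0 <- stats::runif(1, 0, 2 * pi)
    xy <- persistent_walk_xy(n_meta, r0 * c(cos(a0), sin(a0)), speed[i], dt,
                             diff(z_path), config$plate_radius_um)
    mid_meta <- cbind(xy, z_path)

    half <- (icd[i] / 2) * u
    up_is_s1 <- stats::runif(1) < 0.5      # which sister sits on the +u side
    s_meta <- list(`0` = mid_meta + matrix(if (up_is_s1) -half else half,
                                           n_meta, 3, byrow = TRUE),
                   `1` = mid_meta + matrix(if (up_is_s1) half else -half,
                                           n_meta, 3, byrow = TRUE))

    # ---- destinations ----
    sis_z <- c(s_meta$`0`[n_meta, 3], s_meta$`1`[n_meta, 3])
    if (cls == "normal" || cls == "equational_laggard") {
      upper <- which.max(sis_z)
      d <- c("pb", "pb"); d[upper] <- "egg"
    } else if (cls == "misaligned_at_onset") {
      side <- if (mid_meta[n_meta, 3] > 0) "egg" else "pb"
      d <- c(side, side)
    } else {
      side <- sample(c("egg", "pb"), 1)
      d <- c(side, side)
    }
    dest[i, ] <- d

    # ---- anaphase paths ----
    laggard_sister <- if (needs_midzone[i]) sample(1:2, 1) else 0L
    q0 <- rbind(s_meta$`0`[n_meta, ], s_meta$`1`[n_meta, ])
    eps <- times[(n_meta + 1):n_time] - true_onset   # 0, dt, ..., span-dt
    for (s in 1:2) {
      pole <- c(0, 0, if (dest[i, s] == "egg") pole_z else -pole_z)
      dir_vec <- pole - q0[s, ]
      dist_pole <- sqrt(sum(dir_vec^2))
      dir_vec <- dir_vec / dist_pole
      if (s == laggard_sister) {
        m <- merge_times[i]
        travel_to_merge <- dist_pole - 1.7   # just inside the merge radius
        t_rel <- m - travel_to_merge / v_lag
        adv <- pmax(0, (eps - t_rel)) * v_lag
      } else {
        adv <- (eps + dt) * v_ana
      }
      adv <- pmin(adv, dist_pole)
      path <- matrix(q0[s, ], length(eps), 3, byrow = TRUE) +
        outer(adv, dir_vec)
      pos[(n_meta + 1):n_time, , 2 * (i - 1) + s] <- path
    }
    pos[1:n_meta, , 2 * i - 1] <- s_meta$`0`
    pos[1:n_meta, , 2 * i] <- s_meta$`1`
  }

  # localisation noise, then a random rigid transform
  if (noise > 0) {
    pos <- pos + array(stats::rnorm(length(pos), 0, noise), dim(pos))
  }
  rot <- random_rotation()
  shift <- stats::runif(3, -20, 20)
  flat <- matrix(aperm(pos, c(2, 1, 3)), nrow = 3)
  flat <- rot %*% flat + shift
  pos <- aperm(array(flat, c(3, n_time, 2 * n_eff)), c(2, 1, 3))

  chromatids <- data.frame(
    chromosome_id = rep(chromosomes, each = 2),
    sister_index = rep(0:1, n_eff)
  )
  recording <- oocyte_recording(oocyte_id, config$age_group, dt, times,
                                chromatids, pos, batch = batch)

  per_chromosome <- data.frame(
    chromosome_id = chromosomes,
    true_class = classes,
    true_icd_um = icd,
    true_angle_deg = angle,
    true_speed_um_per_min = speed,
    true_merge_time_min = merge_times,
    dest_sister0 = dest[, 1],
    dest_sister1 = dest[, 2]
  )
  truth <- list(
    oocyte_id = oocyte_id,
    per_chromosome = per_chromosome,
    true_onset_min = true_onset,
    true_axis = as.numeric(rot %*% c(0, 0, 1)),
    true_centroid = as.numeric(shift),
    egg_chromatid_count = sum(dest == "egg")
  )
  list(recording = recording, truth = truth)
}

#' Simulate a cohort of oocytes
#'
#' Independent oocytes drawn from per-oocyte child seeds (documented
#' stream order), so a cohort is reproducible given `(config, seed)` and
#' any oocyte can be regenerated in isolation.
#'
#' @param config a [generator_config()].
#' @param n_oocytes number of oocytes (>= 1).
#' @param seed integer master seed.
#' @param n_batches number of experiment batches; oocytes are assigned to
#'   batches in contiguous blocks (mimicking independent experiments).
#' @return list of `list(recording, truth)` pairs, class `miiseg_cohort`.
#' @export
simulate_cohort <- function(config, n_oocytes, seed = 1L, n_batches = 1L) {
  if (n_oocytes < 1) stop("simulate_cohort: n_oocytes must be >= 1")
  batch_of <- sort(rep_len(seq_len(n_batches), n_oocytes))
  out <- lapply(seq_len(n_oocytes), function(i) {
    simulate_oocyte(config, seed = child_seed(seed, i),
                    oocyte_id = sprintf("%s_%03d", config$age_group, i),
                    batch = sprintf("batch_%02d", batch_of[i]))
  })
  class(out) <- "miiseg_cohort"
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}

#' Packaged deterministic fixture composition
#'
#' Twenty aged oocytes of twenty chromosomes containing exactly thirty
#' aberrant chromosomes (on average 1.5 per oocyte: ten oocytes carry one,
#' ten carry two), ten of which co-segregate their sisters (four with a
#' laggard, three without, three misaligned at onset) -- the published
#' aged-cohort composition.
#'
#' @return data.frame with one row per oocyte and one column per
#'   segregation class giving chromosome counts.
#' @export
fixture_spec_default <- function() {
  spec <- data.frame(
    oocyte = seq_len(20),
    equational_laggard = c(rep(1L, 7), rep(0L, 3), rep(2L, 3), rep(1L, 7)),
    coseg_with_laggard = c(rep(0L, 7), 1L, 0L, 0L, rep(0L, 3),
                           1L, 1L, 1L, 0L, 0L, 0L, 0L),
    coseg_without_laggard = c(rep(0L, 8), 1L, 0L, rep(0L, 3),
                              0L, 0L, 0L, 1L, 1L, 0L, 0L),
    misaligned_at_onset = c(rep(0L, 9), 1L, rep(0L, 3),
                            0L, 0L, 0L, 0L, 0L, 1L, 1L)
  )
  stopifnot(sum(spec[-1]) == 30,
            sum(spec[c("coseg_with_laggard", "coseg_without_laggard",
                       "misaligned_at_onset")]) == 10)
  spec
}

#' Build a deterministic fixture cohort with exact class counts
#'
#' Simulates a cohort whose ground-truth segregation-class counts equal
#' the supplied per-oocyte specification exactly (classes are placed on
#' randomly chosen chromosomes; all other draws follow the config).
#'
#' @param spec data.frame like [fixture_spec_default()]: one row per
#'   oocyte, columns named after aberrant classes giving counts.
#' @param config a [generator_config()] (default: aged defaults).
#' @param seed integer seed.
#' @return a `miiseg_cohort` (list of `list(recording, truth)`).
#' @export
make_fixture_cohort <- function(spec = fixture_spec_default(),
                                config = generator_config("aged"),
                                seed = 20L) {
  cls_cols <- intersect(ABERRANT_CLASSES, names(spec))
  out <- lapply(seq_len(nrow(spec)), function(i) {
    forced <- rep(cls_cols, times = as.integer(spec[i, cls_cols]))
    if (length(forced) > config$n_chromosomes) {
      stop("make_fixture_cohort: class counts exceed n_chromosomes")
    }
    simulate_oocyte(config, seed = child_seed(seed, i),
                    oocyte_id = sprintf("fixture_%03d", i),
                    batch = sprintf("batch_%02d", ((i - 1) %/% 5) + 1),
                    forced_classes = forced)
  })
  class(out) <- "miiseg_cohort"
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}

#' Simulate tension-free inter-centromere distances on monopolar spindles
#'
#' Emulates the monastrol (Eg5-inhibited) experiment: no bipolar tension,
#' no anaphase; per-chromosome inter-centromere distances are drawn from
#' the group's monopolar distribution.
#'
#' @param config a [generator_config()].
#' @param n_oocytes number of oocytes.
#' @param seed integer seed.
#' @return data.frame: `oocyte_id`, `chromosome_id`, `icd_um`.
#' @export
simulate_monopolar <- function(config, n_oocytes, seed = 1L) {
  validate_generator_config(config)
  set.seed(child_seed(seed, 0L))
  n <- config$n_chromosomes
  data.frame(
    oocyte_id = rep(sprintf("%s_mono_%03d", config$age_group,
                            seq_len(n_oocytes)), each = n),
    chromosome_id = rep(seq_len(n), n_oocytes),
    icd_um = rtruncnorm(n_oocytes * n, config$icd_monopolar_um[1],
                        config$icd_monopolar_um[2], lower = 0.05)
  )
}

#' Simulate metaphase-II kinetochore-attachment tables
#'
#' Emulates the fixed-oocyte super-resolution attachment scoring: each
#' chromosome independently carries a merotelic attachment with
#' probability `p_merotelic` (both age groups show ~13%), and its
#' inter-centromere distance is drawn from the attachment-class
#' distribution.
#'
#' @param config a [generator_config()].
#' @param n_oocytes number of fixed oocytes.
#' @param seed integer seed.
#' @return data.frame: `oocyte_id`, `chromosome_id`, `attachment`
#'   (`"amphitelic"`/`"merotelic"`), `icd_um`.
#' @export
simulate_attachments <- function(config, n_oocytes, seed = 1L) {
  validate_generator_config(config)
  set.seed(child_seed(seed, 0L))
  n <- config$n_chromosomes
  total <- n_oocytes * n
  mero <- stats::runif(total) < config$p_merotelic
  icd <- numeric(total)
  icd[mero] <- rtruncnorm(sum(mero), config$icd_merotelic_um[1],
                          config$icd_merotelic_um[2], lower = 0.05)
  icd[!mero] <- rtruncnorm(sum(!mero), config$icd_amphitelic_um[1],
                           config$icd_amphitelic_um[2], lower = 0.05)
  data.frame(
    oocyte_id = rep(sprintf("%s_fix_%03d", config$age_group,
                            seq_len(n_oocytes)), each = n),
    chromosome_id = rep(seq_len(n), n_oocytes),
    attachment = ifelse(mero, "merotelic", "amphitelic"),
    icd_um = icd
  )
}
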