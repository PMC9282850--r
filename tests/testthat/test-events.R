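test_that("noise-free onset is detected at the exact frame", {
  cfg <- clean_config(p_oocyte_aberrant = 0)
  sim <- simulate_oocyte(cfg, seed = 8)
  onset <- detect_anaphase_onset(sim$recording)
  expect_equal(onset$onset_min, sim$truth$true_onset_min)
})

test_that("metaphase-only recordings raise onset-not-found", {
  rec <- static_plate_recording(20, n_time = 30)
  expect_error(detect_anaphase_onset(rec),
               class = "miiseg_onset_not_found")
  # analysis degrades gracefully to metaphase-only output
  a <- analyze_oocyte(rec)
  expect_false(a$onset_found)
  expect_true(is.na(a$ploidy$chromatids_at_egg_pole))
  expect_equal(a$ploidy$mII_chromosome_count, 20)
})

test_that("pole assignment follows the axial projection sign", {
  cfg <- clean_config(p_oocyte_aberrant = 0)
  sim <- simulate_oocyte(cfg, seed = 9)
  rec <- sim$recording
  onset <- detect_anaphase_onset(rec)
  sm <- smooth_recording(rec)
  fr <- estimate_frames(sm, onset$index,
                        egg_direction = sim$truth$true_axis)[[1]]
  asg <- assign_poles(rec, onset, fr, egg_direction = sim$truth$true_axis)
  expect_equal(attr(asg, "egg_sign"), 1L)
  # mid-anaphase: every chromatid beyond 2 um is labelled, none midzone
  # at the final frame; noise-free destinations match ground truth
  final <- asg[nrow(asg), ]
  expect_true(all(final != 0L))
  ss <- sister_slices(rec)
  truth_dest <- sim$truth$per_chromosome[, c("dest_sister0", "dest_sister1")]
  got_egg <- ifelse(final == 1L, "egg", "pb")
  expect_equal(got_egg[ss$s0], truth_dest$dest_sister0)
  expect_equal(got_egg[ss$s1], truth_dest$dest_sister1)
})

test_that("scripted laggard dwell yields the scripted merge time", {
  # all-equational oocyte, dispersion-free: every laggard merges at
  # exactly 12 min after onset
  cfg <- clean_config(merge_time_min = c(12, 0))
  sim <- simulate_oocyte(cfg, seed = 10,
                         forced_classes = rep("equational_laggard", 20))
  a <- analyze_oocyte(sim$recording)
  expect_true(all(a$calls$pattern == "equational_laggard"))
  expect_equal(a$calls$merge_time_min, rep(12, 20))
  # one laggard per chromosome, the sister is never a laggard
  lg <- a$laggards
  expect_equal(sum(lg$is_laggard), 20)
  expect_true(all(tapply(lg$is_laggard, lg$chromosome_id, sum) == 1))
})

test_that("no midzone dwell means no laggard episode", {
  cfg <- clean_config(p_oocyte_aberrant = 0)
  sim <- simulate_oocyte(cfg, seed = 12)
  a <- analyze_oocyte(sim$recording)
  expect_equal(sum(a$laggards$is_laggard), 0)
  expect_true(all(is.na(a$calls$merge_time_min)))
})

test_that("noise-free classification matches ground truth for all classes", {
  cfg <- clean_config()
  forced <- c(rep("normal", 15), "equational_laggard", "equational_laggard",
              "coseg_with_laggard", "coseg_without_laggard",
              "misaligned_at_onset")
  sim <- simulate_oocyte(cfg, seed = 13, forced_classes = forced)
  a <- analyze_oocyte(sim$recording)
  truth <- sim$truth$per_chromosome
  m <- match(a$calls$chromosome_id, truth$chromosome_id)
  expect_equal(as.character(a$calls$pattern), truth$true_class[m])
  expect_equal(a$calls$contributes_to_aneuploidy,
               truth$true_class[m] %in%
                 c("coseg_with_laggard", "coseg_without_laggard",
                   "misaligned_at_onset"))
})

test_that("ploidy arithmetic is forced by co-segregation", {
  cfg <- clean_config()
  sim <- simulate_oocyte(cfg, seed = 16,
                         forced_classes = c(rep("normal", 19),
                                            "coseg_without_laggard"))
  a <- analyze_oocyte(sim$recording, egg_direction = sim$truth$true_axis)
  p <- a$ploidy
  expect_true(p$chromatids_at_egg_pole %in% c(19L, 21L))
  expect_equal(p$chromatids_at_egg_pole + p$chromatids_at_pb_pole, 40L)
  expect_true(p$aneuploid_egg)
  expect_equal(p$chromatids_at_egg_pole, sim$truth$egg_chromatid_count)

  # all-normal oocyte: 20 chromatids at each pole, euploid
  sim0 <- simulate_oocyte(clean_config(p_oocyte_aberrant = 0), seed = 17)
  p0 <- analyze_oocyte(sim0$recording)$ploidy
  expect_equal(p0$chromatids_at_egg_pole, 20L)
  expect_equal(p0$chromatids_at_pb_pole, 20L)
  expect_false(p0$aneuploid_egg)
})

test_that("classification is invariant to sister relabeling", {
  cfg <- generator_config("aged")
  sim <- simulate_oocyte(cfg, seed = 19,
                         forced_classes = c(rep("normal", 17),
                                            "equational_laggard",
                                            "coseg_with_laggard",
                                            "misaligned_at_onset"))
  a1 <- analyze_oocyte(sim$recording)
  a2 <- analyze_oocyte(relabel_sisters(sim$recording))
  expect_equal(as.character(a1$calls$pattern),
               as.character(a2$calls$pattern))
  expect_equal(a1$calls$merge_time_min, a2$calls$merge_time_min)
})

test_that("onset detection tracks ground truth within one frame at noise", {
  cfg <- generator_config("aged")
  coh <- simulate_cohort(cfg, 100, seed = 23)
  hits <- vapply(coh, function(el) {
    onset <- tryCatch(detect_anaphase_onset(el$recording),
                      miiseg_onset_not_found = function(e) NULL)
    !is.null(onset) &&
      abs(onset$onset_min - el$truth$true_onset_min) <=
        cfg$frame_interval_min
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("conservation: egg + polar-body chromatids = 2 x chromosomes", {
  cfg <- generator_config("aged")
  coh <- simulate_cohort(cfg, 12, seed = 27)
  an <- analyze_cohort(coh)
  expect_true(all(an$ploidy$chromatids_at_egg_pole +
                    an$ploidy$chromatids_at_pb_pole +
                    an$ploidy$unresolved_chromatids ==
                    2 * an$ploidy$mII_chromosome_count))
})

test_that("aneuploid egg calls are consistent with contributing calls", {
  cfg <- generator_config("aged", positional_noise_sd_um = 0)
  coh <- simulate_cohort(cfg, 40, seed = 29)
  an <- analyze_cohort(coh)
  contributing <- tapply(an$calls$contributes_to_aneuploidy,
                         an$calls$oocyte_id, sum)
  resolved <- tapply(an$calls$pattern != "unresolved",
                     an$calls$oocyte_id, all)
  ploidy <- an$ploidy[match(names(contributing), an$ploidy$oocyte_id), ]
  ok <- resolved
  # aneuploidy requires at least one contributing chromosome ...
  expect_true(all(contributing[ok & ploidy$aneuploid_egg] >= 1))
  # ... and is equivalent when at most one chromosome contributes
  # (two co-segregations toward opposite poles can cancel)
  single <- ok & contributing <= 1
  expect_equal(ploidy$aneuploid_egg[single],
               as.vector(contributing[single] == 1))
})
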