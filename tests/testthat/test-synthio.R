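test_that("generation is deterministic given config and seed", {
  cfg <- generator_config("aged")
  a <- simulate_oocyte(cfg, seed = 77)
  b <- simulate_oocyte(cfg, seed = 77)
  expect_identical(a$recording$pos, b$recording$pos)
  expect_identical(a$truth, b$truth)
  ca <- simulate_cohort(generator_config("young"), 3, seed = 5)
  cb <- simulate_cohort(generator_config("young"), 3, seed = 5)
  expect_identical(lapply(ca, function(x) x$truth$per_chromosome),
                   lapply(cb, function(x) x$truth$per_chromosome))
})

test_that("chromatid conservation and shared-grid invariants hold", {
  cfg <- generator_config("aged")
  sim <- simulate_oocyte(cfg, seed = 41)
  rec <- sim$recording
  expect_equal(dim(rec$pos)[3], 2L * cfg$n_chromosomes)
  expect_true(all(is.finite(rec$pos)))
  expect_equal(length(rec$times),
               (cfg$metaphase_duration_min + cfg$post_onset_duration_min) /
                 cfg$frame_interval_min + 1)
  expect_true(all(table(rec$chromatids$chromosome_id) == 2))
})

test_that("the degenerate error-free oocyte has 20 normal chromosomes", {
  cfg <- clean_config(p_oocyte_aberrant = 0)
  sim <- simulate_oocyte(cfg, seed = 43)
  truth <- sim$truth
  expect_true(all(truth$per_chromosome$true_class == "normal"))
  expect_equal(truth$egg_chromatid_count, 20)
  # sisters end at opposite poles: terminal positions straddle the
  # equator plane along the true axis
  rec <- sim$recording
  ss <- sister_slices(rec)
  last <- rec$pos[length(rec$times), , ]
  proj <- colSums((last - truth$true_centroid) * truth$true_axis)
  expect_true(all(proj[ss$s0] * proj[ss$s1] < 0))
})

test_that("ground-truth destinations respect class semantics", {
  cfg <- generator_config("aged")
  coh <- simulate_cohort(cfg, 30, seed = 47)
  for (el in coh) {
    tc <- el$truth$per_chromosome
    same <- tc$dest_sister0 == tc$dest_sister1
    expect_true(all(!same[tc$true_class %in%
                            c("normal", "equational_laggard")]))
    expect_true(all(same[tc$true_class %in%
                           c("coseg_with_laggard", "coseg_without_laggard",
                             "misaligned_at_onset")]))
    expect_equal(el$truth$egg_chromatid_count,
                 sum(c(tc$dest_sister0, tc$dest_sister1) == "egg"))
    has_lag <- tc$true_class %in% c("equational_laggard",
                                    "coseg_with_laggard")
    expect_true(all(is.na(tc$true_merge_time_min[!has_lag])))
    expect_true(all(tc$true_merge_time_min[has_lag] > 0))
  }
})

test_that("cohort class frequencies concentrate on configured rates", {
  cfg <- generator_config("aged")
  coh <- simulate_cohort(cfg, 400, seed = 53)
  ab_oocyte <- vapply(coh, function(el) {
    any(el$truth$per_chromosome$true_class != "normal")
  }, logical(1))
  p <- mean(ab_oocyte)
  expect_lt(abs(p - 0.55), 2 * sqrt(0.55 * 0.45 / 400) + 1e-9)
  n_ab <- vapply(coh, function(el) {
    sum(el$truth$per_chromosome$true_class != "normal")
  }, numeric(1))
  mean_ab <- mean(n_ab[n_ab > 0])
  expect_lt(abs(mean_ab - 1.5), 2 * 0.5 / sqrt(sum(n_ab > 0)))
  classes <- unlist(lapply(coh, function(el) {
    tc <- el$truth$per_chromosome
    tc$true_class[tc$true_class != "normal"]
  }))
  expect_lt(abs(mean(classes == "equational_laggard") - 2 / 3),
            2 * sqrt(2 / 9 / length(classes)) + 0.02)
})

test_that("young cohort aberrancy matches its configured rate", {
  coh <- simulate_cohort(generator_config("young"), 200, seed = 1)
  p <- mean(vapply(coh, function(el) {
    any(el$truth$per_chromosome$true_class != "normal")
  }, logical(1)))
  expect_lt(abs(p - 0.15), 2 * sqrt(0.15 * 0.85 / 200) + 1e-9)
  expect_length(simulate_cohort(generator_config("young"), 1, seed = 2), 1)
  expect_error(simulate_cohort(generator_config("young"), 0, seed = 2),
               "n_oocytes")
})

test_that("fixture cohort reproduces the published composition exactly", {
  fx <- make_fixture_cohort()
  expect_length(fx, 20)
  classes <- unlist(lapply(fx, function(el) {
    el$truth$per_chromosome$true_class
  }))
  expect_equal(sum(classes != "normal"), 30)
  expect_equal(sum(classes %in% c("coseg_with_laggard",
                                  "coseg_without_laggard",
                                  "misaligned_at_onset")), 10)
  per <- vapply(fx, function(el) {
    sum(el$truth$per_chromosome$true_class != "normal")
  }, numeric(1))
  expect_true(all(per %in% c(1, 2)))
  expect_equal(mean(per), 1.5)

  # explicit spec control: all-normal and single-misaligned
  spec0 <- data.frame(oocyte = 1:2, equational_laggard = 0L,
                      coseg_with_laggard = 0L, coseg_without_laggard = 0L,
                      misaligned_at_onset = 0L)
  fx0 <- make_fixture_cohort(spec0, seed = 3)
  expect_true(all(unlist(lapply(fx0, function(el) {
    el$truth$per_chromosome$true_class
  })) == "normal"))
  spec1 <- spec0[1, ]
  spec1$misaligned_at_onset <- 1L
  fx1 <- make_fixture_cohort(spec1, seed = 4)
  expect_equal(sum(fx1[[1]]$truth$per_chromosome$true_class ==
                     "misaligned_at_onset"), 1)
  spec_bad <- spec0[1, ]
  spec_bad$equational_laggard <- 21L
  expect_error(make_fixture_cohort(spec_bad, seed = 5),
               "exceed n_chromosomes")
})

test_that("monopolar tables draw from the tension-free distribution", {
  cfg <- generator_config("aged")
  tab <- simulate_monopolar(cfg, 30, seed = 61)
  expect_equal(nrow(tab), 600)
  expect_lt(abs(mean(tab$icd_um) - 0.8), 2 * 0.3 / sqrt(600))
  cfg0 <- generator_config("aged", icd_monopolar_um = c(0.8, 0))
  tab0 <- simulate_monopolar(cfg0, 3, seed = 62)
  expect_true(all(tab0$icd_um == 0.8))
  expect_identical(simulate_monopolar(cfg, 5, seed = 63),
                   simulate_monopolar(cfg, 5, seed = 63))
})

test_that("attachment tables carry ~13% merotelic chromosomes", {
  cfg <- generator_config("young")
  att <- simulate_attachments(cfg, 150, seed = 67)
  s <- summarize_attachments(att)
  expect_lt(abs(s$frac_merotelic - 0.13),
            2 * sqrt(0.13 * 0.87 / nrow(att)))
  # merotelic chromosomes sit at shorter inter-centromere distances
  expect_lt(s$icd_merotelic_mean, s$icd_amphitelic_mean)
  expect_lt(s$icd_test$p_value, 0.01)
})

test_that("aberrant chromosomes show reduced tension in any aged cohort", {
  coh <- simulate_cohort(generator_config("aged"), 40, seed = 71)
  an <- analyze_cohort(coh)
  m <- an$metrics
  ab <- m$true_class != "normal"
  expect_gt(sum(ab), 5)
  p <- stats::wilcox.test(m$mean_icd_um[ab], m$mean_icd_um[!ab],
                          alternative = "less")$p.value
  expect_lt(p, 1e-6)
})
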