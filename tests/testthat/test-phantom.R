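test_that("phantom geometry invariants are enforced", {
  g <- small_geometry()
  masks <- mibiquant:::phantom_masks(g)
  expect_false(any(masks$left_lobe & masks$right_lobe))
  expect_true(all(masks$nodule[masks$nodule] &
                    masks$right_lobe[masks$nodule]))
  # nodule spilling out of the lobe is rejected
  expect_error(small_geometry(nodule_center = c(47.5, 70)), "contained")
  # background mirror landing on the thyroid is rejected
  expect_error(small_geometry(bg_mirror_axis_col = 50), "thyroid|outside")
})

test_that("truth ROIs sit in the intended compartments", {
  ph <- build_phantom(small_geometry(), kinetic_params(), noise = "none")
  masks <- ph$truth
  in_mask <- function(roi, m) all(roi_to_raster(roi) <= m)
  expect_true(in_mask(ph$study$rois$nodule, masks$nodule))
  expect_true(in_mask(ph$study$rois$contralateral, masks$left_lobe))
  expect_false(any(roi_to_raster(ph$study$rois$mirror_background) &
                     masks$thyroid))
  expect_false(any(roi_to_raster(ph$study$rois$thorax_background) &
                     masks$thyroid))
  # mirrored masks preserve pixel count
  expect_equal(nrow(ph$study$rois$mirror_background$pixels),
               nrow(ph$study$rois$nodule$pixels))
})

test_that("noiseless ROI means equal the closed-form compartment intensities", {
  kin <- kinetic_params()
  ph <- build_phantom(small_geometry(), kin, noise = "none")
  s <- roi_mean_counts(ph$study$early, ph$study$rois$nodule)
  expect_equal(s$mean_counts_per_pixel,
               (kin$a0_body_background + kin$a0_nodule) * 600,
               tolerance = 1e-12)
  s_bg <- roi_mean_counts(ph$study$late, ph$study$rois$thorax_background)
  expect_equal(s_bg$mean_counts_per_pixel,
               kin$a0_body_background * kin$f_background * 600,
               tolerance = 1e-12)
})

test_that("the noiseless pipeline matches analytic_index for random kinetics", {
  set.seed(55)
  geom <- small_geometry()
  for (i in 1:25) {
    kin <- suppressWarnings(kinetic_params(
      a0_nodule = runif(1, 0.05, 0.5),
      a0_parenchyma = runif(1, 0.05, 0.4),
      a0_body_background = runif(1, 0.005, 0.05),
      f_nodule = runif(1, 0.3, 1),
      f_parenchyma = runif(1, 0.2, 1),
      f_background = runif(1, 0.2, 1),
      apply_physical_decay = sample(c(TRUE, FALSE), 1)
    ))
    ph <- build_phantom(geom, kin, noise = "none")
    q <- quantify_study(ph$study)
    expect_equal(q$woind$value, analytic_index(kin, "WOind"),
                 tolerance = 1e-9)
    expect_equal(q$ri$value, analytic_index(kin, "RI"), tolerance = 1e-9)
  }
})

test_that("analytic_index reproduces hand-derived special cases", {
  # every compartment retains 80%: pure common-factor wash-out
  kin <- suppressWarnings(kinetic_params(f_nodule = 0.8, f_parenchyma = 0.8,
                                         f_background = 0.8))
  expect_equal(analytic_index(kin, "WOind"), -20, tolerance = 1e-12)
  # no body background, nodule retains 90%
  kin2 <- suppressWarnings(kinetic_params(a0_body_background = 0,
                                          f_nodule = 0.9,
                                          f_parenchyma = 0.9))
  expect_equal(analytic_index(kin2, "WOind"), -10, tolerance = 1e-12)
  # equal initial densities, parenchyma retains 50% vs nodule 70%
  kin3 <- kinetic_params(a0_nodule = 0.15, a0_parenchyma = 0.15,
                         a0_body_background = 0, f_nodule = 0.7,
                         f_parenchyma = 0.5)
  expect_equal(analytic_index(kin3, "RI"), 100 * (0.7 / 0.5 - 1),
               tolerance = 1e-12)
  # degenerate contrast
  expect_error(analytic_index(kinetic_params(a0_nodule = 0), "WOind"),
               class = "mibiquant_non_positive_net_uptake")
})

test_that("a zero-uptake nodule propagates to NonPositiveNetUptake", {
  ph <- build_phantom(small_geometry(), kinetic_params(a0_nodule = 0),
                      noise = "none")
  expect_error(quantify_study(ph$study, methods = "WOind"),
               class = "mibiquant_non_positive_net_uptake")
})

test_that("R.I. from the phantom is unchanged by physical decay toggling", {
  geom <- small_geometry()
  for (decay_on in c(FALSE, TRUE)) {
    kin <- kinetic_params(apply_physical_decay = decay_on)
    q <- quantify_study(build_phantom(geom, kin, noise = "none")$study)
    expect_equal(q$ri$value, 100 * (0.7 / 0.5 - 1), tolerance = 1e-9)
  }
})

test_that("WOind under physical decay shifts by the closed-form factor", {
  geom <- small_geometry()
  raw <- quantify_study(
    build_phantom(geom, kinetic_params(), noise = "none")$study
  )$woind$value
  dec <- quantify_study(
    build_phantom(geom, kinetic_params(apply_physical_decay = TRUE),
                  noise = "none")$study
  )$woind$value
  expect_equal(dec / 100 + 1, (raw / 100 + 1) * 2 ^ (-(60 - 10) / 360.4),
               tolerance = 1e-9)
  # and decay correction in the pipeline undoes the physical decay
  corr <- quantify_study(
    build_phantom(geom, kinetic_params(apply_physical_decay = TRUE),
                  noise = "none")$study,
    decay = decay_spec(enabled = TRUE)
  )$woind$value
  expect_equal(corr, raw, tolerance = 1e-9)
})

test_that("Poisson WOind bias shrinks as the count scale grows", {
  geom <- small_geometry()
  truth <- analytic_index(kinetic_params(), "WOind")
  bias <- vapply(c(0.5, 5, 50), function(scale) {
    est <- vapply(1:40, function(r) {
      kin <- kinetic_params(a0_nodule = 0.2 * scale,
                            a0_parenchyma = 0.15 * scale,
                            a0_body_background = 0.02 * scale)
      ph <- build_phantom(geom, kin, noise = "poisson", seed = 1000 + r)
      quantify_study(ph$study, methods = "WOind")$woind$value
    }, numeric(1))
    abs(mean(est) - truth)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 0.5)
})

test_that("cohort simulation is reproducible and label counts are exact", {
  cfg <- cohort_sim_config(n_patients = 8, seed = 77,
                           geometry = small_geometry())
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$patients[[3]]$study$early$counts,
                   b$patients[[3]]$study$early$counts)
  expect_equal(sum(a$truth$truth_label == "malignant"),
               round(8 * 0.2))
  cfg20 <- cohort_sim_config(n_patients = 20, seed = 5,
                             geometry = small_geometry())
  expect_equal(sum(simulate_cohort(cfg20)$truth$truth_label == "malignant"), 4)
})

test_that("simulated retention fractions respect class ordering and bounds", {
  co <- simulate_cohort(cohort_sim_config(n_patients = 40, seed = 19,
                                          geometry = small_geometry()))
  t <- co$truth
  expect_true(all(t$f_nodule > 0 & t$f_nodule <= 1))
  expect_true(all(t$f_parenchyma > 0 & t$f_parenchyma <= 1))
  expect_gt(mean(t$f_nodule[t$truth_label == "malignant"]),
            mean(t$f_nodule[t$truth_label == "benign"]))
  expect_gt(mean(t$f_nodule), mean(t$f_parenchyma))
})

test_that("each patient's kinetics come from their own class distribution", {
  # malignant mean close to 1 forces truncation rejections; any
  # patient-to-class misalignment would cross the wide gap between classes
  co <- suppressWarnings(simulate_cohort(cohort_sim_config(
    n_patients = 50, malignant_fraction = 0.5,
    f_nodule_malignant = 0.995, f_nodule_benign = 0.2, f_sd = 0.01,
    geometry = small_geometry(), seed = 4
  )))
  t <- co$truth
  expect_true(all(t$f_nodule[t$truth_label == "malignant"] > 0.9))
  expect_true(all(t$f_nodule[t$truth_label == "benign"] < 0.3))
})
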