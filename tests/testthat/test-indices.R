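woind_from_means <- function(ne, be, nl, bl, decay = decay_spec()) {
  washout_index(make_stats(ne, t = 10), make_stats(be, t = 10,
                                                   label = "mirror_background"),
                make_stats(nl, t = 60), make_stats(bl, t = 60,
                                                   label = "mirror_background"),
                decay)
}

ri_from_means <- function(ne, ce, te, nl, cl, tl, decay = decay_spec()) {
  retention_index(
    make_stats(ne, t = 10),
    make_stats(ce, t = 10, label = "contralateral"),
    make_stats(te, t = 10, label = "thorax_background"),
    make_stats(nl, t = 60),
    make_stats(cl, t = 60, label = "contralateral"),
    make_stats(tl, t = 60, label = "thorax_background"),
    decay
  )
}

test_that("the wash-out index follows the printed formula chain", {
  r <- woind_from_means(200, 100, 180, 100)
  expect_equal(r$early_ratio_ER, 100)
  expect_equal(r$late_term, 80)
  expect_equal(r$value, -20)
  expect_length(r$flags, 0)

  # no net change between scans is the fixed point
  expect_equal(woind_from_means(150, 50, 130, 30)$value, 0)

  expect_error(woind_from_means(100, 100, 90, 80),
               class = "mibiquant_non_positive_net_uptake")
  expect_error(woind_from_means(90, 100, 90, 80),
               class = "mibiquant_non_positive_net_uptake")

  # late nodule below late background: deep wash-out, flagged not fatal
  deep <- woind_from_means(200, 100, 90, 100)
  expect_lt(deep$value, -100)
  expect_true("deep_washout_late_below_background" %in% deep$flags)
})

test_that("the retention index follows the printed ratio chain", {
  expect_equal(ri_from_means(30, 20, 10, 22, 18, 10)$value,
               oracle_ri(30, 20, 10, 22, 18, 10))
  # DR = ER fixed point
  expect_equal(ri_from_means(30, 20, 10, 30, 20, 10)$value, 0)
  # ER 1.0 -> DR 1.5 and ER 2.0 -> DR 1.0
  expect_equal(ri_from_means(20, 20, 10, 25, 20, 10)$value, 50)
  expect_equal(ri_from_means(30, 20, 10, 20, 20, 10)$value, -50)

  expect_error(ri_from_means(30, 10, 10, 22, 18, 10),
               class = "mibiquant_degenerate_ratio")
  expect_error(ri_from_means(10, 20, 10, 22, 18, 10),
               class = "mibiquant_degenerate_ratio")
})

test_that("mismatched labels or timepoints are refused", {
  expect_error(
    washout_index(make_stats(2, t = 10), make_stats(1, t = 10),
                  make_stats(2, t = 60),
                  make_stats(1, t = 60, label = "mirror_background")),
    "label"
  )
  expect_error(woind_from_means_bad <- washout_index(
    make_stats(2, t = 60), make_stats(1, t = 60, label = "mirror_background"),
    make_stats(2, t = 10), make_stats(1, t = 10, label = "mirror_background")
  ), "precede")
})

test_that("both indices agree with the spreadsheet oracle on random inputs", {
  set.seed(99)
  for (i in 1:1000) {
    be <- runif(1, 1, 200); ne <- be + runif(1, 1, 300)
    bl <- runif(1, 0, 200); nl <- runif(1, 0, 400)
    w <- woind_from_means(ne, be, nl, bl)
    expect_equal(w$value, oracle_woind(ne, be, nl, bl), tolerance = 1e-9)

    te <- runif(1, 0, 50)
    ne2 <- te + runif(1, 1, 300); ce <- te + runif(1, 1, 300)
    nl2 <- te + runif(1, 0.5, 300); cl <- te + runif(1, 1, 300)
    r <- ri_from_means(ne2, ce, te, nl2, cl, te)
    expect_equal(r$value, oracle_ri(ne2, ce, te, nl2, cl, te),
                 tolerance = 1e-9)
  }
})

test_that("R.I. is exactly invariant to decay correction", {
  set.seed(7)
  for (i in 1:50) {
    m <- runif(4, 10, 400)
    ne <- m[1] + m[4] + 1; ce <- m[2] + m[4] + 1; te <- m[4]
    nl <- m[3] + m[4] + 1; cl <- m[2] * 0.7 + m[4] + 1; tl <- m[4]
    off <- ri_from_means(ne, ce, te, nl, cl, tl)
    on <- ri_from_means(ne, ce, te, nl, cl, tl,
                        decay_spec(enabled = TRUE))
    expect_equal(on$value, off$value, tolerance = 1e-12)
  }
})

test_that("WOind shifts by the closed-form factor under decay correction", {
  set.seed(17)
  hl <- 360.4
  for (i in 1:50) {
    ne <- runif(1, 100, 300); be <- runif(1, 10, 90)
    nl <- runif(1, 50, 250); bl <- runif(1, 10, 45)
    raw <- woind_from_means(ne, be, nl, bl)$value
    corr <- woind_from_means(ne, be, nl, bl,
                             decay_spec(half_life_min = hl,
                                        enabled = TRUE))$value
    expect_equal(corr / 100 + 1, (raw / 100 + 1) * 2 ^ ((60 - 10) / hl),
                 tolerance = 1e-9)
  }
})

test_that("WOind is strictly increasing in late nodular counts, R.I. in DR", {
  vals_w <- vapply(seq(60, 140, by = 10),
                   function(nl) woind_from_means(200, 100, nl, 50)$value,
                   numeric(1))
  expect_true(all(diff(vals_w) > 0))
  vals_r <- vapply(seq(15, 40, by = 5),
                   function(nl) ri_from_means(30, 20, 10, nl, 18, 10)$value,
                   numeric(1))
  expect_true(all(diff(vals_r) > 0))
})

test_that("quantify_study names any missing ROI", {
  ph <- build_phantom(small_geometry(), kinetic_params(), noise = "none")
  study <- ph$study
  study$rois$thorax_background <- NULL
  err <- tryCatch(quantify_study(study), error = identity)
  expect_match(conditionMessage(err), "thorax_background")
  expect_silent(quantify_study(study, methods = "WOind"))
})

test_that("a static tracer distribution gives WOind 0 and R.I. 0", {
  kin <- suppressWarnings(kinetic_params(f_nodule = 1, f_parenchyma = 1,
                                         f_background = 1))
  ph <- build_phantom(small_geometry(), kin, noise = "none")
  q <- quantify_study(ph$study)
  expect_equal(q$woind$value, 0, tolerance = 1e-9)
  expect_equal(q$ri$value, 0, tolerance = 1e-9)
})

test_that("parenchyma clearing faster than the nodule gives RI > 0, WOind < 0", {
  kin <- kinetic_params(f_nodule = 0.7, f_parenchyma = 0.5)
  ph <- build_phantom(small_geometry(), kin, noise = "none")
  q <- quantify_study(ph$study)
  expect_lt(q$woind$value, 0)
  expect_gt(q$ri$value, 0)
})
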