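test_that("thermal time accumulates clamped daily means over (t0, t]", {
  temps <- data.frame(date = as.Date("2017-06-01") + 0:4,
                      tmin = 20, tmax = 20)
  expect_equal(compute_thermal_time(temps, as.Date("2017-05-31"),
                                    as.Date("2017-06-05")), 100)
  expect_equal(compute_thermal_time(temps, as.Date("2017-06-03"),
                                    as.Date("2017-06-03")), 0)

  mixed <- data.frame(date = as.Date("2018-07-01") + 0:2,
                      tmin = c(5, 10, -4), tmax = c(15, 20, 0))
  expect_equal(compute_thermal_time(mixed, as.Date("2018-06-30"),
                                    as.Date("2018-07-03")), 25)

  gappy <- temps[-3, ]
  expect_error(compute_thermal_time(gappy, as.Date("2017-05-31"),
                                    as.Date("2017-06-05")), "missing days")
})

test_that("onset/termination crossing uses the first strictly-above record", {
  tc <- data.frame(thermal_time = c(100, 150, 200), score = c(5, 10, 15))
  expect_equal(find_crossing(tc, 10), 200)  # score 10 itself does not trigger
  expect_true(is.na(find_crossing(tc, 90)))
  tc100 <- data.frame(thermal_time = c(50, 80), score = c(100, 100))
  expect_equal(find_crossing(tc100, 90), 50)
  expect_error(find_crossing(tc[0, ], 10), "empty")
})

test_that("TT-score interpolation is linear between scoring points", {
  tc <- data.frame(thermal_time = c(300, 340), score = c(60, 80))
  expect_equal(interpolate_tt_score(tc, 70), 320)
  hit <- data.frame(thermal_time = c(310, 350), score = c(70, 90))
  expect_equal(interpolate_tt_score(hit, 70), 310)
  low <- data.frame(thermal_time = c(300, 340), score = c(60, 65))
  expect_true(is.na(interpolate_tt_score(low, 70)))
  # non-monotone course: first upward crossing wins
  wiggle <- data.frame(thermal_time = c(100, 200, 300, 400),
                       score = c(60, 75, 65, 80))
  expect_equal(interpolate_tt_score(wiggle, 70),
               100 + (70 - 60) / (75 - 60) * 100)
  expect_error(interpolate_tt_score(tc, 0), "target")
})

test_that("the metric panel is complete and internally consistent", {
  ramp <- data.frame(thermal_time = seq(0, 1000, by = 100),
                     score = seq(0, 100, by = 10))
  m <- derive_metrics(ramp)
  expect_equal(unname(m$tt_scores["TT50"]), 500)
  expect_equal(m$mean_senescence, 50)
  expect_equal(m$onset, 200)           # first recorded score > 10
  expect_equal(m$termination, 1000)    # first recorded score > 90
  expect_equal(m$duration_from_onset, m$termination - m$onset)
  flat <- data.frame(thermal_time = c(0, 100, 200), score = 0)
  mf <- derive_metrics(flat)
  expect_true(is.na(mf$onset))
  expect_equal(mf$mean_senescence, 0)
  expect_true(all(is.na(mf$tt_scores)))
})

test_that("TT scores are monotone in the target over simulated courses", {
  cfg <- fast_config()
  temps <- data.frame(date = as.Date("2017-06-02") + 0:79,
                      tmin = 12, tmax = 20)
  set.seed(21)
  tc <- simulate_senescence_timecourse(
    stats::setNames(sample(0:2, 30, replace = TRUE), sprintf("P%02d", 1:30)),
    NULL, cfg, temps)
  for (p in unique(tc$plot)) {
    m <- derive_metrics(tc[tc$plot == p, ])
    tts <- m$tt_scores[!is.na(m$tt_scores)]
    if (length(tts) > 1) expect_false(is.unsorted(tts))
  }
})

test_that("simulated mutant-vs-wild-type metric gap recovers the onset delay", {
  cfg <- fast_config()   # delay 8 d, noise SD 15 day degC
  temps <- data.frame(date = as.Date("2017-06-02") + 0:79,
                      tmin = 12, tmax = 20)
  delay_tt <- 8 * 16     # constant 16 degC daily mean
  set.seed(22)
  dos <- stats::setNames(rep(c(0L, 2L), each = 100), sprintf("P%03d", 1:200))
  tc <- simulate_senescence_timecourse(dos, NULL, cfg, temps)
  tt50 <- vapply(split(tc, tc$plot), function(d) interpolate_tt_score(d, 50),
                 numeric(1))
  gap <- mean(tt50[names(dos)[dos == 2L]]) - mean(tt50[names(dos)[dos == 0L]])
  expect_lt(abs(gap - delay_tt), 10)
})

test_that("RIL classification votes metrics toward the closer parent", {
  mk <- function(shift) {
    tc <- data.frame(thermal_time = seq(0, 1000, by = 100) + shift,
                     score = seq(0, 100, by = 10))
    derive_metrics(tc)
  }
  wt <- mk(0); sg <- mk(200)
  expect_equal(classify_ril(mk(0), wt, sg)$class, "non_staygreen")
  expect_equal(classify_ril(mk(200), wt, sg)$class, "staygreen")
  expect_equal(classify_ril(mk(180), wt, sg)$class, "staygreen")
  # conflicting votes under a unanimity rule -> ambiguous
  conflicted <- wt
  conflicted$tt_scores["TT70"] <- (wt$tt_scores["TT70"] + sg$tt_scores["TT70"]) / 2
  conflicted$duration_from_ee <- sg$duration_from_ee
  res <- classify_ril(conflicted, wt, sg,
                      rule = list(metrics = c("mean_senescence",
                                              "duration_from_ee", "tt70"),
                                  min_votes = 3))
  expect_equal(res$class, "ambiguous")
  broken <- wt; broken$mean_senescence <- NA
  expect_error(classify_ril(mk(0), broken, sg), "missing")
})

test_that("classification recovers simulated truth for homozygotes", {
  cfg <- fast_config()   # onset delay 8 d ~ 128 day degC >> 4 x 15 noise SD
  temps <- data.frame(date = as.Date("2017-06-02") + 0:79,
                      tmin = 12, tmax = 20)
  cfg0 <- cfg; cfg0$t50_noise_sd <- 0
  ptc <- simulate_senescence_timecourse(c(wt = 0L, mut = 2L), NULL, cfg0, temps)
  wt_m <- derive_metrics(ptc[ptc$plot == "wt", ])
  sg_m <- derive_metrics(ptc[ptc$plot == "mut", ])
  correct <- total <- 0
  for (s in 1:100) {
    set.seed(s)
    dos <- stats::setNames(rep(c(0L, 2L), each = 10), sprintf("R%02d", 1:20))
    tc <- simulate_senescence_timecourse(dos, NULL, cfg, temps)
    for (r in names(dos)) {
      cl <- classify_ril(derive_metrics(tc[tc$plot == r, ]), wt_m, sg_m)$class
      want <- if (dos[r] == 2L) "staygreen" else "non_staygreen"
      correct <- correct + (cl == want)
      total <- total + 1
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("bulk selection demands multi-year concordance and caps by TT70", {
  cl <- data.frame(
    ril = rep(c("R1", "R2", "R3", "R4"), each = 2),
    year = rep(c(2017, 2018), 4),
    class = c("staygreen", "staygreen",          # concordant SG
              "staygreen", "non_staygreen",      # discordant
              "non_staygreen", "non_staygreen",  # concordant NSG
              "staygreen", "ambiguous"),         # only one usable year
    tt70 = c(900, 910, 800, 700, 600, 610, 880, 870))
  sel <- suppressWarnings(select_bulks(cl, min_years = 2,
                                       bulk_caps = c(sg = 17, nsg = 17),
                                       midparent_tt70 = 750))
  expect_equal(sel$sg, "R1")
  expect_equal(sel$nsg, "R3")
  expect_false("R2" %in% c(sel$sg, sel$nsg))
  expect_false("R4" %in% c(sel$sg, sel$nsg))
  expect_match(sel$status, "warning")

  # cap: 20 eligible, keep the 17 with the largest |TT70 - midparent|
  many <- data.frame(ril = sprintf("S%02d", 1:20), year = 2017,
                     class = "staygreen", tt70 = 800 + 1:20)
  many2 <- transform(many, year = 2018)
  sel2 <- suppressWarnings(select_bulks(rbind(many, many2), min_years = 2,
                                        bulk_caps = c(sg = 17, nsg = 17),
                                        midparent_tt70 = 750))
  expect_length(sel2$sg, 17)
  expect_setequal(sel2$sg, sprintf("S%02d", 4:20))
})

test_that("grain moisture follows the water-fraction formula", {
  expect_equal(moisture_percent(1000, 550), 45)
  expect_equal(moisture_percent(800, 800), 0)
  expect_equal(moisture_percent(800, 200), 75)
  expect_equal(moisture_percent(1000, 550, literal = TRUE), 55)
  expect_error(moisture_percent(500, 600), "exceeds")
})

test_that("time-point group tests behave at the null and at separation", {
  same <- rep(c(10, 11, 12), 2)
  res0 <- timepoint_group_test(same, rep(c("a", "b"), each = 3))
  expect_gt(res0$f_p, 0.9)
  const <- timepoint_group_test(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(const$f_p, 1)
  expect_equal(const$pairwise$p, 1)

  set.seed(30)
  x <- c(rnorm(10, 10, 1), rnorm(10, 20, 1))  # |t| ~ 22
  res1 <- timepoint_group_test(x, rep(c("a", "b"), each = 10))
  expect_lt(res1$pairwise$p, 1e-6)

  y <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 8))
  res3 <- timepoint_group_test(y, rep(c("a", "b", "c"), each = 10))
  shifted <- res3$pairwise$g1 == "a" & res3$pairwise$g2 == "b"
  expect_gt(res3$pairwise$p[shifted], 0.01)
  expect_true(all(res3$pairwise$p[!shifted] < 1e-4))
  expect_error(timepoint_group_test(1:4, rep("a", 4)), "two groups")
})
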