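test_that("stature from foot length reproduces printed values and is linear", {
  expect_equal(round_half_up(stature_from_foot_length(13.0)), 84.36)
  expect_equal(round_half_up(stature_from_foot_length(26.2)), 170.02)
  expect_equal(round_half_up(stature_from_foot_length(15.41)), 100.00)
  expect_equal(stature_from_foot_length(2 * 17.3),
               2 * stature_from_foot_length(17.3))
  expect_error(stature_from_foot_length(-1), "positive")
  expect_error(stature_from_foot_length(13, ratio = 0), "positive")
})

test_that("tibia regressions give the published stature check", {
  m <- stature_from_tibia(35, "male")
  expect_equal(m$stature, 165.2, tolerance = 1e-9)
  expect_equal(m$band, 3.73)
  f <- stature_from_tibia(35, "female")
  expect_equal(f$stature, 77.86 + 2.36 * 35)   # 160.46
  expect_equal(f$band, 2.94)
  expect_equal(stature_from_tibia(1e-9, "male")$stature, 101.85,
               tolerance = 1e-6)
  expect_error(stature_from_tibia(35, "other"))
  expect_error(stature_from_tibia(0, "male"), "positive")
})

test_that("body-mass models reproduce printed cells and their functional form", {
  expect_equal(round_half_up(body_mass(13.0, "a")), 11.78)
  expect_equal(round_half_up(body_mass(25.3, "b")), 50.76)
  expect_equal(round_half_up(body_mass(22.5, "c")), 47.19)
  # model a is log-linear with rate exactly 0.126
  fl <- c(14, 17, 21, 25)
  expect_equal(diff(log(body_mass(fl, "a"))) / diff(fl),
               rep(0.126, 3), tolerance = 1e-12)
  expect_true(all(diff(body_mass(fl, "a")) > 0))
  expect_error(body_mass(13, "c"), "non-positive")
  expect_error(body_mass(13, "z"))
})

test_that("mass-model routing follows the size-class rule", {
  expect_setequal(select_mass_models(147.96, "adult"), c("b", "c"))
  expect_equal(select_mass_models(166.99, "adult"), "b")
  expect_equal(select_mass_models(87.93, "child"), "a")
  expect_equal(select_mass_models(135.19, "adolescent"), "a")
  expect_error(select_mass_models(-5, "adult"), "positive")
})

test_that("age classes bracket the growth anchors as printed", {
  expect_equal(age_class(17.0)$class, "5-6")
  a1 <- age_class(13.07)
  expect_equal(a1$age, 1.0, tolerance = 1e-12)
  expect_equal(a1$class, "<3")
  expect_false(a1$extrapolated)
  expect_equal(age_class(20.83)$class, "8-11")
  expect_equal(age_class(13.55)$class, "<3")
  expect_equal(age_class(25.73)$class, ">14 - adult")
  # adult morphology overrides the interpolated class
  expect_equal(age_class(22.8)$class, "8-11")
  expect_equal(age_class(22.8, adult_morphology = TRUE)$class, ">14 - adult")
  # extrapolation below the first anchor is clamped and flagged
  lo <- age_class(12.5)
  expect_true(lo$extrapolated)
  expect_equal(lo$age, 1.0)
  expect_match(age_class(20.83, Aa = 40)$note, "within")
  expect_match(age_class(20.83, Aa = 55)$note, "outside")
})

test_that("sex inference is conservative and rule driven", {
  morph5 <- list(mean_FI = 0.41, mean_Aa = 52, size_class = "adult",
                 largest = TRUE, n = 3)
  call5 <- infer_sex(morph5)
  expect_equal(call5$sex, "probable_male")
  expect_true(call5$low_confidence)
  expect_match(call5$rationale, "stout")

  morph1 <- list(mean_FI = 0.48, mean_Aa = 22, size_class = "child",
                 largest = FALSE, n = 4)
  expect_equal(infer_sex(morph1)$sex, "indeterminate")

  lone <- list(mean_FI = 0.4, mean_Aa = NA, size_class = "adult",
               largest = TRUE, n = 1)
  expect_equal(infer_sex(lone)$sex, "indeterminate")

  morph4 <- list(mean_FI = 0.38, mean_Aa = 44, size_class = "adult",
                 largest = FALSE, n = 7)
  expect_equal(infer_sex(morph4)$sex, "indeterminate")
  expect_equal(infer_sex(morph4, sex_rules(adult_gracile_female = TRUE))$sex,
               "probable_female")

  expect_error(infer_sex(list(n = 0)), "empty")
})

test_that("group summaries use mean and sample SD (n-1)", {
  s <- summarize_group(c(84.36, 87.61, 87.61, 92.15))
  expect_equal(round_half_up(s[["mean"]]), 87.93)
  expect_equal(round_half_up(s[["sd"]]), 3.20)   # requires n-1 denominator

  two_pass <- function(v) {
    m <- sum(v) / length(v)
    c(mean = m, sd = sqrt(sum((v - m)^2) / (length(v) - 1)))
  }
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(sample(2:30, 1), sd = runif(1, 0.1, 50))
    s <- summarize_group(v)
    expect_equal(s[c("mean", "sd")], two_pass(v), tolerance = 1e-12)
  }
  single <- summarize_group(5.5)
  expect_true(is.na(single[["sd"]]))
  expect_error(summarize_group(numeric(0)), "empty")
})

test_that("fixture profiles reproduce every printed elaboration", {
  t3 <- load_basura_fixtures("table3")
  prof <- profile_individuals(t3, published_morphotypes(t3))
  expect_equal(nrow(prof), 5)

  # group summary rows, exactly as printed (2 decimals, half-up);
  # published cells that are blank (e.g. single-model groups) are skipped
  pub <- load_basura_fixtures("table3_summary")
  cols <- c(max_FL_mean = "FL_mean", max_FL_sd = "FL_sd",
            FI_mean = "FI_mean", FI_sd = "FI_sd",
            stature_mean = "stature_mean", stature_sd = "stature_sd",
            mass_a_mean = "mass_a_mean", mass_a_sd = "mass_a_sd",
            mass_b_mean = "mass_b_mean", mass_b_sd = "mass_b_sd",
            mass_c_mean = "mass_c_mean", mass_c_sd = "mass_c_sd")
  for (pubcol in names(cols)) {
    got <- round_half_up(prof[[cols[[pubcol]]]])
    want <- pub[[pubcol]]
    ok <- !is.na(want)
    expect_equal(got[ok], want[ok], info = pubcol)
  }
  expect_equal(prof$age_class, pub$age)
  expect_equal(prof$sex,
               c(rep("indeterminate", 4), "probable_male"))

  # per-footprint stature and mass cells; the two cells printed 30.30 are
  # arithmetically 30.31 under the stated exponential model (source slip)
  per <- attr(prof, "footprints")
  t3d <- as.data.frame(t3)
  expected_mass_a <- t3d$mass_a
  expected_mass_a[t3d$id %in% c("C10", "SM15")] <- 30.31
  expect_equal(round_half_up(per$stature), t3d$stature)
  expect_equal(round_half_up(per$mass_a), expected_mass_a)
  expect_equal(round_half_up(per$mass_b), t3d$mass_b)
  expect_equal(round_half_up(per$mass_c), t3d$mass_c)
  expect_equal(round_half_up(per$FI), t3d$FI)

  # the tibia check agrees with the foot-length stature of the tallest group
  tib <- stature_from_tibia(35, "male")
  expect_lte(abs(tib$stature - prof$stature_mean[5]), tib$band)
})

test_that("profiling requires full assignment and some foot lengths", {
  t3 <- load_basura_fixtures("table3")
  asg <- published_morphotypes(t3)
  short <- t3[t3$id != "SM3", ]
  expect_s3_class(profile_individuals(short, asg), "biometric_profile")
  one <- t3[t3$id == "SM3", ]
  p1 <- profile_individuals(one, asg)
  expect_equal(nrow(p1), 1)
  expect_true(is.na(p1$stature_sd))
  asg2 <- asg
  asg2$assignment <- asg2$assignment[-1]
  missing_id <- setdiff(t3$id, names(asg2$assignment))
  expect_error(profile_individuals(t3, asg2), missing_id)
})
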