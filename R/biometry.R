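#' Stature model coefficients
#'
#' Calibrations used for stature inference: the foot-length/stature ratio
#' (0.1541, fitted on terminal Upper Palaeolithic adults from the Italian
#' peninsula) and the sex-specific percutaneous-tibia regressions with their
#' published error bands.
#'
#' @return list with `foot_ratio` and per-sex tibia coefficients
#'   (`intercept` cm, `slope` cm per cm of tibia, `band` cm).
#' @export
stature_model <- function() {
  list(
    foot_ratio = 0.1541,
    tibia = list(
      male   = c(intercept = 101.85, slope = 1.81, band = 3.73),
      female = c(intercept = 77.86,  slope = 2.36, band = 2.94)
    )
  )
}

#' Body-mass model coefficients
#'
#' Three closed-form calibrations of body mass on maximum foot length:
#' \describe{
#'   \item{a}{child exponential, `2.2897 * exp(0.126 * FL)` kg, fitted on
#'     extant children of stature 118.6-145.7 cm.}
#'   \item{b}{adult linear, `4.71 + 1.82 * FL` kg, fitted on mature
#'     individuals 154-185 cm tall.}
#'   \item{c}{child/adolescent linear, `-71.142 + 5.259 * FL` kg, fitted on
#'     children averaging 147.44 cm; positive only for FL > 13.53 cm.}
#' }
#' Routing: adult-class groups get model b, plus model c when the group
#' mean stature does not exceed `c_stature_max` (152 cm, near the c-model
#' calibration height); smaller size classes get model a. The adult class
#' starts above `adult_stature_min` (147 cm).
#'
#' @return list of coefficients and routing thresholds.
#' @export
mass_models <- function() {
  list(
    a = c(coef = 2.2897, rate = 0.126),
    b = c(intercept = 4.71, slope = 1.82),
    c = c(intercept = -71.142, slope = 5.259),
    c_min_FL = 13.53,
    adult_stature_min = 147,
    c_stature_max = 152
  )
}

#' Juvenile foot-growth reference
#'
#' Anchor points of foot length against age in extant juveniles (age 1 yr:
#' 13.07 ± 1.59 cm; age 13 yr: 24.4 ± 2.96 cm), the arch-angle development
#' bands (21-43 degrees in young males and 26-47 degrees in young females
#' between ages 3-4 and 9-11), and the age-class vocabulary used in
#' reports.
#'
#' @return list with `anchors` (data frame age/FL/sd), `arch_bands`, and
#'   `age_classes`.
#' @export
growth_reference <- function() {
  list(
    anchors = data.frame(age = c(1, 13), FL = c(13.07, 24.4),
                         sd = c(1.59, 2.96)),
    arch_bands = list(male = c(21, 43), female = c(26, 47),
                      ages = c(3.5, 10)),
    age_classes = c("<3", "5-6", "8-11", ">14 - adult")
  )
}

#' Sex-inference rule table
#'
#' Transparent defaults for the (explicitly speculative) sex call: only the
#' largest adult-class group with a stout profile (mean foot index at least
#' `stout_fi`) and an observed arch angle is called probable male; all
#' other groups are indeterminate. Setting `adult_gracile_female = TRUE`
#' additionally calls adult-class gracile groups probable female (the
#' reading applied to the second-largest producer in the source study's
#' results text).
#'
#' @param stout_fi foot-index threshold separating stout from gracile adult
#'   footprints (default 0.40).
#' @param adult_gracile_female enable the probable-female call for gracile
#'   adult groups (default `FALSE`).
#' @return list of rule parameters.
#' @export
sex_rules <- function(stout_fi = 0.40, adult_gracile_female = FALSE) {
  list(stout_fi = stout_fi, adult_gracile_female = adult_gracile_female)
}

#' Stature from maximum foot length
#'
#' `stature = max_FL / R` with `R` the foot-length/stature ratio.
#'
#' @param max_FL maximum foot length, cm (vectorised).
#' @param ratio foot-length/stature ratio (default 0.1541).
#' @return stature in cm, unrounded (reports round half-up to 2 decimals).
#' @examples
#' round_half_up(stature_from_foot_length(13))    # 84.36
#' @export
stature_from_foot_length <- function(max_FL, ratio = stature_model()$foot_ratio) {
  if (any(!is.na(max_FL) & max_FL <= 0)) stop("max_FL must be positive")
  if (!is.finite(ratio) || ratio <= 0) stop("ratio must be positive")
  max_FL / ratio
}

#' Stature from percutaneous tibial length
#'
#' Sex-specific linear regressions of stature on percutaneous tibial
#' length: `101.85 + 1.81 * PCTL` (± 3.73 cm) for males and
#' `77.86 + 2.36 * PCTL` (± 2.94 cm) for females.
#'
#' @param PCTL percutaneous tibial length, cm.
#' @param sex `"male"` or `"female"`.
#' @return list with `stature` (cm) and `band` (± cm).
#' @examples
#' stature_from_tibia(35, "male")   # 165.2 +/- 3.73
#' @export
stature_from_tibia <- function(PCTL, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (any(!is.finite(PCTL) | PCTL <= 0)) stop("PCTL must be positive")
  cf <- stature_model()$tibia[[sex]]
  list(stature = unname(cf["intercept"] + cf["slope"] * PCTL),
       band = unname(cf["band"]), sex = sex)
}

#' Body mass from maximum foot length
#'
#' Applies one of the three closed-form mass calibrations (see
#' [mass_models()]). Model c is only admissible where it yields positive
#' mass (FL > 13.53 cm).
#'
#' @param max_FL maximum foot length, cm (vectorised).
#' @param model `"a"` (child exponential), `"b"` (adult linear) or `"c"`
#'   (child/adolescent linear).
#' @return mass in kg, unrounded (reports round half-up to 2 decimals).
#' @examples
#' round_half_up(body_mass(13, "a"))     # 11.78
#' round_half_up(body_mass(25.3, "b"))   # 50.76
#' @export
body_mass <- function(max_FL, model = c("a", "b", "c")) {
  model <- match.arg(model)
  if (any(!is.na(max_FL) & max_FL <= 0)) stop("max_FL must be positive")
  mm <- mass_models()
  out <- switch(model,
    a = mm$a["coef"] * exp(mm$a["rate"] * max_FL),
    b = mm$b["intercept"] + mm$b["slope"] * max_FL,
    c = mm$c["intercept"] + mm$c["slope"] * max_FL
  )
  if (model == "c" && any(!is.na(out) & out <= 0))
    stop("model c yields non-positive mass for FL <= 13.53 cm")
  unname(out)
}

#' Select applicable body-mass models for a group
#'
#' Adult-class groups get the adult linear model b, plus the
#' child/adolescent linear model c when the group stature is within the
#' c-model calibration range (<= 152 cm); child and adolescent classes get
#' the child exponential model a.
#'
#' @param stature group mean stature, cm.
#' @param size_class `"child"`, `"adolescent"` or `"adult"`.
#' @return character vector of model tokens.
#' @export
select_mass_models <- function(stature,
                               size_class = c("child", "adolescent", "adult")) {
  size_class <- match.arg(size_class)
  if (!is.finite(stature) || stature <= 0) stop("stature must be positive")
  mm <- mass_models()
  if (size_class == "adult") {
    if (stature <= mm$c_stature_max) c("b", "c") else "b"
  } else "a"
}

#' Age class from foot length
#'
#' A point age is obtained by linear interpolation between the two
#' foot-growth anchors (age 1 yr, 13.07 cm; age 13 yr, 24.4 cm);
#' extrapolation beyond the anchor ages is clamped and flagged. The
#' returned class is the report vocabulary bin containing the point age
#' (< 4.5 yr: "<3"; < 7 yr: "5-6"; < 12 yr: "8-11"; otherwise
#' ">14 - adult"); `adult_morphology = TRUE` forces the adult class
#' regardless of foot length. When an arch angle is supplied, a note
#' records whether it falls within the juvenile development band.
#'
#' @param max_FL maximum foot length, cm.
#' @param Aa arch angle in degrees, or `NA`.
#' @param adult_morphology force the adult class (used for groups whose
#'   stature or morphology marks an adult producer).
#' @return list with `age` (interpolated point age, yr), `class`,
#'   `extrapolated` flag and `note`.
#' @export
age_class <- function(max_FL, Aa = NA, adult_morphology = FALSE) {
  if (!is.finite(max_FL) || max_FL <= 0) stop("max_FL must be positive")
  gr <- growth_reference()$anchors
  slope <- diff(gr$age) / diff(gr$FL)
  age <- gr$age[1] + (max_FL - gr$FL[1]) * slope
  extrapolated <- age < gr$age[1] || age > gr$age[2]
  age_clamped <- min(max(age, gr$age[1]), gr$age[2] + 5)
  cls <- if (adult_morphology) ">14 - adult"
         else if (age_clamped < 4.5) "<3"
         else if (age_clamped < 7) "5-6"
         else if (age_clamped < 12) "8-11"
         else ">14 - adult"
  note <- NA_character_
  if (!is.na(Aa)) {
    bands <- growth_reference()$arch_bands
    lo <- min(bands$male[1], bands$female[1])
    hi <- max(bands$male[2], bands$female[2])
    note <- if (Aa >= lo && Aa <= hi)
      sprintf("arch angle %.0f within juvenile development band (%d-%d)",
              Aa, lo, hi)
    else
      sprintf("arch angle %.0f outside juvenile development band (%d-%d)",
              Aa, lo, hi)
  }
  list(age = age_clamped, class = cls, extrapolated = extrapolated,
       note = note)
}

#' Sex call for a morphotype group
#'
#' Rule-based, deliberately conservative sex inference (the underlying
#' method is speculative and every call carries a low-confidence marker).
#' See [sex_rules()] for the default rule table.
#'
#' @param group_stats list with `mean_FI`, `mean_Aa` (may be `NA`),
#'   `size_class`, `largest` (logical: largest group of the assemblage),
#'   `n` (number of footprints).
#' @param rules rule table from [sex_rules()].
#' @return list with `sex` (`"probable_male"`, `"probable_female"`,
#'   `"indeterminate"`), `rationale`, `low_confidence = TRUE`.
#' @export
infer_sex <- function(group_stats, rules = sex_rules()) {
  gs <- group_stats
  if (is.null(gs$n) || gs$n < 1) stop("empty group")
  call <- "indeterminate"
  why <- "insufficient evidence for a sex call"
  adult <- identical(gs$size_class, "adult")
  enough <- gs$n >= 2 && !is.na(gs$mean_Aa %||% NA) && !is.na(gs$mean_FI %||% NA)
  if (adult && enough) {
    if (isTRUE(gs$largest) && gs$mean_FI >= rules$stout_fi) {
      call <- "probable_male"
      why <- sprintf(paste0("largest adult group with stout morphology ",
                            "(mean FI %.2f >= %.2f) and arch angle %.0f"),
                     gs$mean_FI, rules$stout_fi, gs$mean_Aa)
    } else if (rules$adult_gracile_female && gs$mean_FI < rules$stout_fi) {
      call <- "probable_female"
      why <- sprintf("adult group with gracile morphology (mean FI %.2f < %.2f)",
                     gs$mean_FI, rules$stout_fi)
    }
  } else if (adult) {
    why <- "adult group but too few footprints or missing arch angle/foot index"
  } else {
    why <- "juvenile size class: no sex call attempted"
  }
  list(sex = call, rationale = why, low_confidence = TRUE)
}

#' Mean and sample standard deviation of a group of values
#'
#' The dispersion convention of the published summary rows: arithmetic mean
#' and sample SD (n-1 denominator); a single value yields `sd = NA`
#' (reported as "n/a").
#'
#' @param values numeric vector, `NA` dropped.
#' @return named numeric: `mean`, `sd`, `n`.
#' @export
summarize_group <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("empty value list")
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
    n = length(v))
}

# summarize_group tolerant of all-missing input (returns NA summaries)
.summarize_or_na <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
  summarize_group(v)
}

# size class of a group from its mean stature and interpolated age
.size_class <- function(stature_mean, point_age, adult_min) {
  if (!is.na(stature_mean) && stature_mean > adult_min) "adult"
  else if (!is.na(point_age) && point_age >= 7) "adolescent"
  else "child"
}

#' Per-individual biometric profiles from a grouped footprint table
#'
#' Composes the full biometric inference for each morphotype group: stature
#' from foot length per footprint, body mass under the models selected for
#' the group's size class, foot index, then group summaries (mean ± sample
#' SD of the unrounded per-footprint values), age class from the group mean
#' foot length, and the rule-based sex call. When the table carries a
#' `summary_subset` column (the published summary-row subsets of the source
#' tables) and `use_summary_subset` is `TRUE`, group summaries are computed
#' over the flagged rows only, while per-footprint estimates still cover
#' every measured footprint.
#'
#' @param x a [footprint_table()] with `max_FL` (or `Dt1`) present.
#' @param assignment a `morphotype_assignment` covering every footprint.
#' @param ratio foot-length/stature ratio.
#' @param rules sex rule table, see [sex_rules()].
#' @param use_summary_subset honour a `summary_subset` column if present.
#' @return data frame of class `biometric_profile`, one row per group, with
#'   attribute `footprints` holding the per-footprint estimate table.
#' @export
profile_individuals <- function(x, assignment,
                                ratio = stature_model()$foot_ratio,
                                rules = sex_rules(),
                                use_summary_subset = TRUE) {
  stopifnot(inherits(x, "footprint_table"),
            inherits(assignment, "morphotype_assignment"))
  grp <- assignment$assignment
  if (!all(x$id %in% names(grp)))
    stop("unassigned footprint(s): ",
         paste(setdiff(x$id, names(grp)), collapse = ", "))
  FL <- if ("max_FL" %in% names(x)) x$max_FL else x$Dt1
  if (all(is.na(FL))) stop("no foot-length measurements")
  FW <- if ("max_FW" %in% names(x)) x$max_FW
        else if ("mtm_horiz" %in% names(x)) x$mtm_horiz
        else rep(NA_real_, nrow(x))
  Aa <- if ("Aa" %in% names(x)) x$Aa else rep(NA_real_, nrow(x))
  mm <- mass_models()

  # per-footprint estimates (masses filled once group models are known)
  per <- data.frame(
    id = x$id,
    group = unname(grp[x$id]),
    max_FL = FL,
    FI = ifelse(is.na(FW) | is.na(FL), NA_real_, FW / FL),
    stature = ifelse(is.na(FL), NA_real_, FL / ratio),
    mass_a = NA_real_, mass_b = NA_real_, mass_c = NA_real_,
    stringsAsFactors = FALSE
  )

  subset_flag <- if (use_summary_subset && "summary_subset" %in% names(x))
    x$summary_subset else rep(TRUE, nrow(x))
  subset_flag[is.na(subset_flag)] <- TRUE

  groups <- sort(unique(per$group))
  # group mean foot length decides the largest group
  gFL <- vapply(groups, function(g) {
    v <- per$max_FL[per$group == g & subset_flag]
    if (all(is.na(v))) v <- per$max_FL[per$group == g]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  largest <- groups[which.max(gFL)]

  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    in_g <- per$group == g
    in_s <- in_g & subset_flag
    if (!any(in_s & !is.na(per$max_FL))) in_s <- in_g
    sFL <- summarize_group(per$max_FL[in_s])
    sFI <- .summarize_or_na(per$FI[in_s])
    sSt <- summarize_group(per$stature[in_s])
    ac0 <- age_class(sFL["mean"])
    size_class <- .size_class(sSt["mean"], ac0$age, mm$adult_stature_min)
    models <- select_mass_models(sSt["mean"], size_class)
    for (m in models) {
      ok <- in_g & !is.na(per$max_FL)
      if (m == "c") ok <- ok & per$max_FL > mm$c_min_FL
      per[ok, paste0("mass_", m)] <<- body_mass(per$max_FL[ok], m)
    }
    sm <- lapply(c(a = "a", b = "b", c = "c"), function(m)
      if (m %in% models) .summarize_or_na(per[[paste0("mass_", m)]][in_s])
      else c(mean = NA_real_, sd = NA_real_, n = 0))
    mAa <- mean(Aa[in_g], na.rm = TRUE); if (is.nan(mAa)) mAa <- NA_real_
    ac <- age_class(sFL["mean"], mAa,
                    adult_morphology = size_class == "adult")
    sx <- infer_sex(list(mean_FI = unname(sFI["mean"]), mean_Aa = mAa,
                         size_class = size_class, largest = g == largest,
                         n = sum(in_g)), rules)
    data.frame(
      group = g, n = sum(in_g), n_summarized = sum(in_s),
      FL_mean = unname(sFL["mean"]), FL_sd = unname(sFL["sd"]),
      FI_mean = unname(sFI["mean"]), FI_sd = unname(sFI["sd"]),
      stature_mean = unname(sSt["mean"]), stature_sd = unname(sSt["sd"]),
      mass_a_mean = unname(sm$a["mean"]), mass_a_sd = unname(sm$a["sd"]),
      mass_b_mean = unname(sm$b["mean"]), mass_b_sd = unname(sm$b["sd"]),
      mass_c_mean = unname(sm$c["mean"]), mass_c_sd = unname(sm$c["sd"]),
      mean_Aa = mAa, size_class = size_class,
      age = unname(ac$age), age_class = ac$class,
      sex = sx$sex, sex_rationale = sx$rationale,
      stringsAsFactors = FALSE
    )
  })
  prof <- do.call(rbind, rows)
  attr(prof, "footprints") <- per
  attr(prof, "ratio") <- ratio
  class(prof) <- c("biometric_profile", "data.frame")
  prof
}

#' @export
print.biometric_profile <- function(x, ...) {
  cat("Biometric profile: ", nrow(x), " producer group(s)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  group %d (n=%d): stature %s cm, age %s, sex %s\n",
                x$group[i], x$n[i],
                fmt_pm(x$stature_mean[i], x$stature_sd[i]),
                x$age_class[i], x$sex[i]))
  }
  invisible(x)
}
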