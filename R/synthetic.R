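#' Mean foot-proportion template of the measurement fixture
#'
#' Column-mean proportions of the nine PCA measurement variables relative
#' to each footprint's largest measurement, computed from the packaged
#' 23-footprint measurement fixture and rescaled so the largest component
#' (the Dt1 foot length) equals 1. Used as the default anatomy of
#' synthetic individuals, so simulated tables are realistic without
#' inventing proportions.
#'
#' @return named numeric vector of length 9, values in (0, 1].
#' @export
default_foot_template <- function() {
  t4 <- load_basura_fixtures("table4")
  M <- measurement_matrix(t4)
  P <- M / apply(M, 1, max, na.rm = TRUE)
  tpl <- colMeans(P, na.rm = TRUE)
  tpl / max(tpl)
}

#' Generate a synthetic population of trackmakers
#'
#' Ages are drawn uniformly in `age_range`; the expected foot length comes
#' from the juvenile growth reference (linear between the anchors at ages
#' 1 and 13, continued to age 15 and constant thereafter), multiplied by
#' lognormal individual variation with coefficient of variation
#' `stature_cv`. True stature is the foot length divided by the
#' foot-length/stature ratio, so the package's stature estimator is the
#' exact inverse of the generator; true mass applies the mass model the
#' pipeline itself would select.
#'
#' @param n number of individuals.
#' @param age_range ages in years, `c(min, max)`.
#' @param seed integer seed (same seed, same population).
#' @param stature_cv lognormal CV of individual foot length about the
#'   growth-reference mean (default 0.05).
#' @param ratio foot-length/stature ratio.
#' @param ages optional fixed ages (length `n`), bypassing the uniform
#'   draw — used to construct cohorts with a prescribed size structure.
#' @return data frame of class `synthetic_population`: `id`, `true_age`,
#'   `true_FL`, `true_stature`, `true_mass`, `sex`.
#' @export
generate_population <- function(n, age_range = c(3, 30), seed = 1,
                                stature_cv = 0.05,
                                ratio = stature_model()$foot_ratio,
                                ages = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (length(age_range) != 2 || age_range[1] > age_range[2] ||
      age_range[1] <= 0)
    stop("invalid age range")
  set.seed(seed)
  age <- if (is.null(ages)) sort(runif(n, age_range[1], age_range[2]))
         else { stopifnot(length(ages) == n, all(ages > 0)); sort(ages) }
  mu <- .growth_FL(age)
  sdlog <- sqrt(log(1 + stature_cv^2))
  FL <- mu * exp(rnorm(n, 0, sdlog))
  stature <- FL / ratio
  mm <- mass_models()
  mass <- ifelse(stature > mm$adult_stature_min,
                 body_mass(FL, "b"), body_mass(FL, "a"))
  structure(data.frame(
    id = sprintf("IND%02d", seq_len(n)),
    true_age = age, true_FL = FL, true_stature = stature, true_mass = mass,
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ), class = c("synthetic_population", "data.frame"), ratio = ratio)
}

# expected foot length at a given age: linear between the growth anchors,
# continued to age 15, constant (adult) beyond
.growth_FL <- function(age) {
  gr <- growth_reference()$anchors
  slope <- diff(gr$FL) / diff(gr$age)
  eff <- pmin(pmax(age, gr$age[1]), 15)
  gr$FL[1] + (eff - gr$age[1]) * slope
}

#' Define a synthetic trackway scenario
#'
#' @param footprints_per_individual footprints left by each individual.
#' @param noise_cv per-cell multiplicative lognormal measurement noise
#'   (coefficient of variation), emulating substrate plasticity; default
#'   0.03, within the ±0.5 cm landmark-reliability bound at the fixture's
#'   foot lengths.
#' @param missing_rate probability that a measurement cell is lost
#'   (missing completely at random), as in the partially preserved
#'   footprints of the fixture.
#' @param digit_block if `TRUE`, missingness hits the three digit-length
#'   cells of a footprint together, mirroring the blank digit blocks of
#'   the fixture, instead of independent cells.
#' @param seed integer seed.
#' @return list of class `track_scenario`.
#' @export
track_scenario <- function(footprints_per_individual = 5, noise_cv = 0.03,
                           missing_rate = 0, digit_block = FALSE, seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  structure(list(footprints_per_individual = footprints_per_individual,
                 noise_cv = noise_cv, missing_rate = missing_rate,
                 digit_block = digit_block, seed = as.integer(seed)),
            class = "track_scenario")
}

#' Simulate a footprint measurement table
#'
#' Each footprint is the individual's proportion template scaled by its
#' true foot length, perturbed cell-wise by multiplicative lognormal noise
#' (positive lengths stay positive), with cells masked missing at the
#' scenario's rate. The output is structurally identical to the packaged
#' nine-variable measurement table (plus `max_FL`/`max_FW` derived from
#' the simulated cells) and passes table validation and CSV round-trip.
#'
#' @param pop a [generate_population()] result.
#' @param scenario a [track_scenario()].
#' @param template foot-proportion template (default
#'   [default_foot_template()]).
#' @return a [footprint_table()] with attribute `truth` mapping footprint
#'   ids to individual ids.
#' @export
simulate_footprints <- function(pop, scenario,
                                template = default_foot_template()) {
  stopifnot(inherits(pop, "synthetic_population"),
            inherits(scenario, "track_scenario"))
  set.seed(scenario$seed)
  m <- scenario$footprints_per_individual
  sdlog <- if (scenario$noise_cv > 0)
    sqrt(log(1 + scenario$noise_cv^2)) else 0
  p <- length(template)
  rows <- lapply(seq_len(nrow(pop)), function(i) {
    vals <- t(vapply(seq_len(m), function(j)
      template * pop$true_FL[i] * exp(rnorm(p, 0, sdlog)),
      numeric(p)))
    colnames(vals) <- names(template)
    vals
  })
  X <- do.call(rbind, rows)
  ids <- unlist(lapply(seq_len(nrow(pop)), function(i)
    sprintf("%s_F%02d", pop$id[i], seq_len(m))))
  if (scenario$missing_rate > 0) {
    if (scenario$digit_block) {
      digits <- grep("^Dt", colnames(X))
      other <- setdiff(seq_len(ncol(X)), digits)
      drop_rows <- runif(nrow(X)) < scenario$missing_rate
      X[drop_rows, digits] <- NA
      X[, other][runif(length(X[, other])) < scenario$missing_rate] <- NA
    } else {
      X[runif(length(X)) < scenario$missing_rate] <- NA
    }
  }
  df <- data.frame(id = ids, X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$side <- rep(c("left", "right"), length.out = nrow(df))
  df$max_FL <- apply(df[, grep("^Dt", colnames(X), value = TRUE)], 1,
                     function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  df$max_FW <- df$mtm_horiz
  out <- footprint_table(df, validate = FALSE)
  attr(out, "truth") <- stats::setNames(rep(pop$id, each = m), ids)
  out
}

#' Parameter-recovery experiment over replicated synthetic trackways
#'
#' Generates one ground-truth population, then, per replicate, simulates a
#' measurement table with fresh noise (replicate r uses seed
#' `seed + r`, a documented counter scheme), runs the grouping and
#' biometric pipeline, and scores recovery: fraction of replicates whose
#' estimated minimum number of individuals equals the true count, and,
#' over replicates with the correct count (groups matched to individuals
#' by size rank), stature bias and RMSE, per-model mass RMSE, and the
#' age-class confusion table.
#'
#' @param n_individuals true number of trackmakers.
#' @param age_range ages, years.
#' @param scenario a [track_scenario()]; its `seed` field is ignored in
#'   favour of the per-replicate counter.
#' @param n_reps number of replicates.
#' @param seed master seed.
#' @param stature_cv individual foot-length CV for the population.
#' @param cut,linkage grouping parameters, see [group_morphotypes()].
#' @param ages optional fixed ages passed to [generate_population()].
#' @return list of class `recovery_report`: `mni_accuracy`, `k_table`,
#'   `stature_bias`, `stature_rmse`, `mass_rmse`, `age_confusion`,
#'   `n_reps`, `truth`.
#' @export
recovery_experiment <- function(n_individuals = 5, age_range = c(3, 30),
                                scenario = track_scenario(), n_reps = 20,
                                seed = 1, stature_cv = 0.05,
                                cut = 0.166, linkage = "ward.D2",
                                ages = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  pop <- generate_population(n_individuals, age_range, seed = seed,
                             stature_cv = stature_cv, ages = ages)
  truthFL <- sort(pop$true_FL)
  truth_stat <- sort(pop$true_stature)
  truth_age_class <- vapply(sort(pop$true_age), function(a) {
    if (a < 4.5) "<3" else if (a < 7) "5-6"
    else if (a < 12) "8-11" else ">14 - adult"
  }, character(1))
  ks <- integer(n_reps)
  st_err <- list(); mass_err <- list(a = c(), b = c(), c = c())
  conf <- table(factor(character(), levels = growth_reference()$age_classes),
                factor(character(), levels = growth_reference()$age_classes))
  for (r in seq_len(n_reps)) {
    sc <- scenario
    sc$seed <- (seed + r) %% .Machine$integer.max
    tab <- simulate_footprints(pop, sc)
    asg <- group_morphotypes(tab, cut = cut, linkage = linkage)
    ks[r] <- minimum_individuals(asg)
    if (ks[r] == n_individuals) {
      prof <- profile_individuals(tab, asg)
      prof <- prof[order(prof$FL_mean), ]
      st_err[[length(st_err) + 1L]] <- prof$stature_mean - truth_stat
      for (m in c("a", "b", "c")) {
        est <- prof[[paste0("mass_", m, "_mean")]]
        ok <- !is.na(est)
        if (any(ok)) {
          tm <- .true_mass(truthFL[ok], m)
          mass_err[[m]] <- c(mass_err[[m]], est[ok] - tm)
        }
      }
      conf <- conf + table(
        factor(truth_age_class, levels = growth_reference()$age_classes),
        factor(prof$age_class, levels = growth_reference()$age_classes))
    }
  }
  errs <- unlist(st_err)
  structure(list(
    mni_accuracy = mean(ks == n_individuals),
    k_table = table(ks),
    stature_bias = if (length(errs)) mean(errs) else NA_real_,
    stature_rmse = if (length(errs)) sqrt(mean(errs^2)) else NA_real_,
    mass_rmse = vapply(mass_err, function(e)
      if (length(e)) sqrt(mean(e^2)) else NA_real_, numeric(1)),
    age_confusion = conf,
    n_reps = n_reps,
    truth = pop
  ), class = "recovery_report")
}

.true_mass <- function(FL, model) {
  mm <- mass_models()
  switch(model,
    a = unname(mm$a["coef"] * exp(mm$a["rate"] * FL)),
    b = unname(mm$b["intercept"] + mm$b["slope"] * FL),
    c = unname(mm$c["intercept"] + mm$c["slope"] * FL))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery experiment over ", x$n_reps, " replicate(s)\n", sep = "")
  cat(sprintf("  MNI accuracy: %.2f\n", x$mni_accuracy))
  cat(sprintf("  stature bias %.3f cm, RMSE %.3f cm\n",
              x$stature_bias, x$stature_rmse))
  invisible(x)
}

#' @importFrom stats runif rnorm setNames hclust cutree as.dist
NULL
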