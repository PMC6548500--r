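#' Render a biometric report
#'
#' Deterministic human-readable rendering of a biometric profile in the
#' layout of the published elaboration table: per-footprint rows (foot
#' length, foot index, stature, applicable body masses) followed by
#' per-morphotype summary rows (mean ± sample SD, "± n/a" for
#' single-member groups). All numbers are rounded half-up to 2 decimals.
#' Re-rendering the same estimates yields byte-identical output.
#'
#' @param profile a [profile_individuals()] result.
#' @param style `"text"` (character vector of lines) or `"csv"` (list of
#'   two data frames, `footprints` and `groups`, with rounded cells).
#' @return see `style`.
#' @export
render_report <- function(profile, style = c("text", "csv")) {
  style <- match.arg(style)
  stopifnot(inherits(profile, "biometric_profile"))
  per <- attr(profile, "footprints")
  if (is.null(per) || nrow(per) == 0) stop("profile has no estimates")

  per_out <- data.frame(
    id = per$id, group = per$group,
    max_FL = round_half_up(per$max_FL),
    FI = round_half_up(per$FI),
    stature = round_half_up(per$stature),
    mass_a = round_half_up(per$mass_a),
    mass_b = round_half_up(per$mass_b),
    mass_c = round_half_up(per$mass_c),
    stringsAsFactors = FALSE
  )
  grp_out <- data.frame(
    group = profile$group, n = profile$n, n_summarized = profile$n_summarized,
    FL_mean = round_half_up(profile$FL_mean),
    FL_sd = round_half_up(profile$FL_sd),
    FI_mean = round_half_up(profile$FI_mean),
    FI_sd = round_half_up(profile$FI_sd),
    stature_mean = round_half_up(profile$stature_mean),
    stature_sd = round_half_up(profile$stature_sd),
    mass_a_mean = round_half_up(profile$mass_a_mean),
    mass_a_sd = round_half_up(profile$mass_a_sd),
    mass_b_mean = round_half_up(profile$mass_b_mean),
    mass_b_sd = round_half_up(profile$mass_b_sd),
    mass_c_mean = round_half_up(profile$mass_c_mean),
    mass_c_sd = round_half_up(profile$mass_c_sd),
    age_class = profile$age_class,
    sex = profile$sex,
    stringsAsFactors = FALSE
  )
  if (style == "csv") return(list(footprints = per_out, groups = grp_out))

  lines <- c("Footprint biometric report",
             "==========================", "")
  lines <- c(lines, sprintf("%-8s %5s %6s %8s %8s %8s %8s",
                            "id", "grp", "FL", "FI", "stature",
                            "mass(a)", "mass(b/c)"))
  for (i in seq_len(nrow(per_out))) {
    bc <- if (!is.na(per_out$mass_b[i]) || !is.na(per_out$mass_c[i]))
      paste(fmt2(per_out$mass_b[i]), fmt2(per_out$mass_c[i]), sep = "/")
    else "-"
    lines <- c(lines, sprintf("%-8s %5d %6s %8s %8s %8s %8s",
                              per_out$id[i], per_out$group[i],
                              fmt2(per$max_FL[i]), fmt2(per$FI[i]),
                              fmt2(per$stature[i]), fmt2(per$mass_a[i]), bc))
  }
  if (nrow(profile) > 1 || profile$n[1] > 1) {
    lines <- c(lines, "", "Group summaries (mean ± sample SD)",
               "----------------------------------")
    for (i in seq_len(nrow(profile))) {
      mass <- if (!is.na(profile$mass_a_mean[i]))
        paste0("mass(a) ", fmt_pm(profile$mass_a_mean[i], profile$mass_a_sd[i]))
      else paste0("mass(b) ",
                  fmt_pm(profile$mass_b_mean[i], profile$mass_b_sd[i]),
                  if (!is.na(profile$mass_c_mean[i]))
                    paste0(" / mass(c) ",
                           fmt_pm(profile$mass_c_mean[i], profile$mass_c_sd[i]))
                  else "")
      lines <- c(lines, sprintf(
        "group %d (n=%d): FL %s cm, FI %s, stature %s cm, %s kg, age %s, sex %s",
        profile$group[i], profile$n[i],
        fmt_pm(profile$FL_mean[i], profile$FL_sd[i]),
        fmt_pm(profile$FI_mean[i], profile$FI_sd[i]),
        fmt_pm(profile$stature_mean[i], profile$stature_sd[i]),
        mass, profile$age_class[i], profile$sex[i]))
    }
  }
  lines
}

#' Write a biometric report to disk
#'
#' Writes `<base>_footprints.csv` (per-footprint estimates),
#' `<base>_groups.csv` (per-morphotype summaries) and `<base>.txt` (the
#' text rendering). Written CSVs re-read to the rendered values exactly
#' (cells are rounded half-up to 2 decimals before writing).
#'
#' @param profile a [profile_individuals()] result.
#' @param base output path prefix (directories must exist).
#' @return named character vector of the written paths, invisibly.
#' @export
write_report <- function(profile, base) {
  parts <- render_report(profile, style = "csv")
  paths <- c(footprints = paste0(base, "_footprints.csv"),
             groups = paste0(base, "_groups.csv"),
             text = paste0(base, ".txt"))
  write.csv(parts$footprints, paths["footprints"], row.names = FALSE, na = "")
  write.csv(parts$groups, paths["groups"], row.names = FALSE, na = "")
  writeLines(render_report(profile, "text"), paths["text"])
  invisible(paths)
}

#' Run the full ichnometric pipeline
#'
#' Composes the pipeline in the study's order: read and validate the
#' measurement table; build the nine-variable log matrix; impute missing
#' cells and run the principal component analysis (when at least three
#' footprints carry PCA variables); group footprints into morphotypes
#' (published labels when the table carries them and
#' `config$use_published` is not `FALSE`, otherwise clustering); infer
#' per-group biometrics; and write the report files, PCA exports and a
#' JSON run manifest.
#'
#' @param input `"basura-fixture"` (the packaged measurement table) or a
#'   CSV path readable by [read_footprint_table()].
#' @param config list of overrides: `ratio`, `pca_k`, `impute_tol`,
#'   `impute_max_iter`, `group_cut`, `group_linkage`, `use_published`,
#'   `use_summary_subset`, `sex_rules`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `table`, `assignment`, `profile`, `pca`,
#'   `manifest`, `paths`.
#' @export
run_pipeline <- function(input = "basura-fixture", config = list(),
                         out_dir = tempfile("ichnometry_run_")) {
  cfg <- list(ratio = stature_model()$foot_ratio, pca_k = 3,
              impute_tol = 1e-6, impute_max_iter = 200,
              group_cut = 0.166, group_linkage = "ward.D2",
              use_published = TRUE, use_summary_subset = TRUE,
              sex_rules = sex_rules())
  bad <- setdiff(names(config), names(cfg))
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "))
  cfg[names(config)] <- config

  tab <- if (identical(input, "basura-fixture"))
    load_basura_fixtures("table3") else read_footprint_table(input)
  if (nrow(tab) == 0) stop("input table has no records")

  pca <- NULL
  pvars <- intersect(PCA_VARIABLES, names(tab))
  if (length(pvars) >= 2 && nrow(tab) >= 3) {
    M <- measurement_matrix(tab, pvars)
    keep <- rowSums(!is.na(M)) > 0
    L <- log_transform(M[keep, , drop = FALSE])
    Lc <- if (anyNA(L))
      impute_missing(L, k = min(cfg$pca_k, min(dim(L)) - 1),
                     tol = cfg$impute_tol, max_iter = cfg$impute_max_iter)
    else L
    pca <- footprint_pca(Lc)
  }

  asg <- if (cfg$use_published && "morphotype" %in% names(tab))
    published_morphotypes(tab)
  else group_morphotypes(tab, cut = cfg$group_cut,
                         linkage = cfg$group_linkage)

  prof <- profile_individuals(tab, asg, ratio = cfg$ratio,
                              rules = cfg$sex_rules,
                              use_summary_subset = cfg$use_summary_subset)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_report(prof, file.path(out_dir, "report"))
  if (!is.null(pca)) {
    sc <- data.frame(id = rownames(pca$scores), round(pca$scores, 6))
    write.csv(sc, file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    ld <- data.frame(variable = rownames(pca$loadings),
                     round(pca$loadings, 6))
    write.csv(ld, file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
    paths <- c(paths, pca_scores = file.path(out_dir, "pca_scores.csv"),
               pca_loadings = file.path(out_dir, "pca_loadings.csv"))
  }

  manifest <- list(
    package = "ichnometry",
    version = as.character(utils::packageVersion("ichnometry")),
    input = input,
    config = cfg[setdiff(names(cfg), "sex_rules")],
    sex_rules = cfg$sex_rules,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_records = nrow(tab),
    n_groups = asg$n_groups,
    provenance = asg$provenance
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, manifest = mpath)

  invisible(list(table = tab, assignment = asg, profile = prof, pca = pca,
                 manifest = manifest, paths = paths))
}
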