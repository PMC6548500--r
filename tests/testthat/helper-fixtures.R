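# small in-code fixtures shared across test files

# complete three-footprint table with plausible proportions
tiny_table <- function() {
  footprint_table(data.frame(
    id = c("A1", "A2", "A3"),
    side = c("left", "right", "left"),
    Dt1 = c(20, 21, 19.5), Dt2 = c(19, 20.2, 18.8), Dt3 = c(18, 19, 17.7),
    mtm_BL = c(15, 15.8, 14.6), mtl_BL = c(13, 13.5, 12.8),
    ccm_BL = c(3, 3.2, 2.9), ctul_BL = c(2.5, 2.6, 2.4),
    mtm_horiz = c(7.5, 7.8, 7.2), ctul_horiz = c(5.5, 5.7, 5.3),
    max_FL = c(20, 21, 19.5), max_FW = c(7.5, 7.8, 7.2),
    Aa = c(40, 42, 38),
    stringsAsFactors = FALSE
  ))
}

# rank-1 matrix: rows are scalar multiples of one positive profile
rank1_matrix <- function(nr = 6, profile = c(1, 0.9, 0.7, 0.35, 0.2)) {
  scale <- seq(10, 20, length.out = nr)
  outer(scale, profile)
}

# scale a table's measurement columns by a constant (e.g. cm -> mm)
scale_table <- function(tab, f) {
  df <- as.data.frame(tab)
  for (v in intersect(ichnometry:::MEASUREMENT_COLUMNS, names(df))) {
    if (!v %in% c("T1_T5", "Aa")) df[[v]] <- df[[v]] * f
  }
  footprint_table(df)
}
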