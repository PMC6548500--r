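#' Foot index
#'
#' Ratio of maximum foot width to maximum foot length. The published
#' measurement tables report the plain ratio (e.g. 0.46); the percentage
#' form used in parts of the ichnological literature is available via
#' `scale100`.
#'
#' @param max_FW maximum foot width, cm.
#' @param max_FL maximum foot length, cm.
#' @param scale100 if `TRUE`, return the index as a percentage.
#' @return numeric ratio (or percentage), unrounded; reports round half-up
#'   to 2 decimals.
#' @examples
#' round_half_up(foot_index(6, 13))   # 0.46
#' @export
foot_index <- function(max_FW, max_FL, scale100 = FALSE) {
  if (any(!is.finite(max_FW) | max_FW <= 0) ||
      any(!is.finite(max_FL) | max_FL <= 0))
    stop("foot_index needs positive max_FW and max_FL")
  r <- max_FW / max_FL
  if (scale100) r * 100 else r
}

#' Arch angle from landmark points
#'
#' Angle between the footprint medial border line and the line connecting
#' the most medial point of the metatarsal region to the apex of the arch
#' concavity. The second row of `border` is taken as the medial metatarsal
#' point where the two lines meet. The angle is reported as the acute angle
#' in (0, 90) degrees and is invariant under rigid motion and uniform
#' scaling of the landmark configuration.
#'
#' @param border 2x2 matrix; rows are two points on the medial border line
#'   (heel-side point first, medial metatarsal point second), planar
#'   footprint coordinates.
#' @param apex length-2 numeric, apex of the arch concavity.
#' @return angle in degrees.
#' @export
arch_angle <- function(border, apex) {
  border <- matrix(as.numeric(border), ncol = 2)
  apex <- as.numeric(apex)
  if (nrow(border) != 2 || length(apex) != 2)
    stop("border must be two points, apex one point")
  u <- border[2, ] - border[1, ]
  v <- apex - border[2, ]
  if (all(abs(u) < 1e-12) || all(abs(v) < 1e-12))
    stop("duplicate landmark points")
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  ct <- min(1, max(-1, ct))
  ang <- acos(ct) * 180 / pi
  if (ang > 90) ang <- 180 - ang     # acute representation
  if (ang < 1e-9) stop("collinear landmark points: arch angle undefined")
  ang
}

#' Extract the nine-variable measurement matrix
#'
#' Builds the rows-by-variables matrix of the nine anatomical lengths and
#' widths used for the principal component analysis (digit lengths Dt1-Dt3,
#' medial/lateral ball and heel lengths, ball and heel widths), with row
#' names from footprint ids and `NA` marking missing cells.
#'
#' @param x a [footprint_table()].
#' @param variables measurement columns to extract (default the nine PCA
#'   variables).
#' @return numeric matrix with attribute `mask` (logical, `TRUE` = missing).
#' @export
measurement_matrix <- function(x, variables = PCA_VARIABLES) {
  stopifnot(inherits(x, "footprint_table"))
  have <- intersect(variables, names(x))
  if (!length(have)) stop("none of the requested variables are present")
  M <- as.matrix(as.data.frame(x)[have])
  mode(M) <- "numeric"
  rownames(M) <- x$id
  attr(M, "mask") <- is.na(M)
  M
}

#' Natural-log transform of a measurement matrix
#'
#' Entrywise natural logarithm; the missingness mask is unchanged. Log
#' transformation linearises allometric relations and makes isometric size
#' variation a common additive shift of all variables.
#'
#' @param M numeric matrix of positive measurements (NA allowed).
#' @return log-transformed matrix, mask preserved.
#' @export
log_transform <- function(M) {
  if (any(!is.na(M) & M <= 0)) stop("log_transform needs positive entries")
  L <- log(M)
  attr(L, "mask") <- is.na(M)
  L
}

#' Iterative PCA imputation of missing cells
#'
#' Standard iterative-imputation scheme: missing cells are initialised with
#' column means, then the matrix is column-centred, reconstructed from its
#' leading `k` singular components, and the reconstruction overwrites the
#' missing cells only; iteration stops when the largest absolute change of
#' any imputed cell falls below `tol` or after `max_iter` sweeps. Observed
#' cells are never altered, and a complete matrix is returned unchanged.
#'
#' @param M numeric matrix with `NA` for missing cells (typically
#'   log-transformed measurements).
#' @param k number of components used for the reconstruction (default 3:
#'   the dominant size axis plus two shape axes).
#' @param tol convergence threshold on imputed-cell change (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @return completed matrix with attributes `iterations` and `converged`.
#' @export
impute_missing <- function(M, k = 3, tol = 1e-6, max_iter = 200) {
  M <- as.matrix(M)
  if (k < 1 || k >= min(dim(M)))
    stop("k must satisfy 1 <= k < min(rows, columns)")
  npres <- colSums(!is.na(M))
  if (any(npres == 0))
    stop("all-missing column(s): ", paste(colnames(M)[npres == 0], collapse = ", "))
  if (any(npres < 2))
    stop("column(s) with fewer than 2 observed values: ",
         paste(colnames(M)[npres < 2], collapse = ", "))
  mask <- is.na(M)
  if (!any(mask)) {
    attr(M, "iterations") <- 0L
    attr(M, "converged") <- TRUE
    return(M)
  }
  X <- M
  mu0 <- colMeans(M, na.rm = TRUE)
  X[mask] <- mu0[col(M)[mask]]
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- colMeans(X)
    C <- sweep(X, 2, mu)
    s <- svd(C, nu = k, nv = k)
    R <- s$u %*% (diag(s$d[seq_len(k)], k, k) %*% t(s$v))
    R <- sweep(R, 2, mu, "+")
    delta <- max(abs(R[mask] - X[mask]))
    X[mask] <- R[mask]
    if (delta < tol) { converged <- TRUE; break }
  }
  attr(X, "mask") <- mask
  attr(X, "iterations") <- it
  attr(X, "converged") <- converged
  X
}

#' Principal component analysis of a completed measurement matrix
#'
#' PCA on the covariance matrix of the column-centred data (variables share
#' units, log-cm, so covariance preserves the allometric reading of the
#' loadings). Components are ordered by decreasing variance; each loading
#' column is sign-fixed so that its largest-magnitude entry is positive.
#'
#' @param M complete numeric matrix (no `NA`), at least 3 rows.
#' @return object of class `footprint_pca` with elements `scores`
#'   (rows x components), `loadings` (variables x components),
#'   `explained_variance` (fraction per component), `sdev`, and
#'   `transform_log` flag (taken from the input's provenance, informational).
#' @export
footprint_pca <- function(M) {
  M <- as.matrix(M)
  if (anyNA(M)) stop("matrix has missing cells; impute first")
  if (nrow(M) < 3) stop("need at least 3 rows")
  p <- prcomp(M, center = TRUE, scale. = FALSE)
  if (all(p$sdev < 1e-12)) stop("constant matrix: zero variance")
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2, flip, "*")
  sc <- sweep(p$x, 2, flip, "*")
  structure(list(
    scores = sc,
    loadings = rot,
    explained_variance = p$sdev^2 / sum(p$sdev^2),
    sdev = p$sdev,
    center = p$center
  ), class = "footprint_pca")
}

#' @importFrom stats prcomp
#' @export
print.footprint_pca <- function(x, ...) {
  k <- min(3, length(x$explained_variance))
  cat("Footprint PCA: ", nrow(x$scores), " footprints, ",
      nrow(x$loadings), " variables\n", sep = "")
  cat("explained variance: ",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$explained_variance[seq_len(k)]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# pairwise mean absolute log difference over shared-present variables:
# a unit-free relative-difference distance between footprint rows
.log_shape_dist <- function(L) {
  n <- nrow(L)
  D <- matrix(0, n, n, dimnames = list(rownames(L), rownames(L)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(L[i, ]) & !is.na(L[j, ])
      if (!any(ok))
        stop("footprints ", rownames(L)[i], " and ", rownames(L)[j],
             " share no measured variable")
      D[i, j] <- D[j, i] <- mean(abs(L[i, ok] - L[j, ok]))
    }
  }
  as.dist(D)
}

#' Group footprints into morphotypes
#'
#' Hierarchical agglomerative clustering of the log-measurement rows, with
#' a unit-free distance (mean absolute difference of log measurements over
#' variables present in both rows, i.e. a relative-difference metric) and
#' Ward linkage. The tree is cut at `cut` times the maximum merge height;
#' the default 0.166 is calibrated so the Bàsura measurement fixture yields
#' the published five-morphotype partition. Rows are ordered
#' lexicographically by id before clustering, making the assignment
#' deterministic and invariant to input row order; group labels are
#' renumbered by increasing group mean size so label 1 is the smallest
#' size class.
#'
#' @param x a [footprint_table()] with at least one measured record.
#' @param cut fraction of the maximum merge height at which the tree is cut
#'   (default 0.166).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @param variables measurement columns used (default the nine PCA
#'   variables; columns entirely absent from `x` are dropped).
#' @return object of class `morphotype_assignment`: list with `assignment`
#'   (named integer vector footprint id -> group), `n_groups`, `provenance`
#'   (`"clustered"`), `spread` (per-group relative range of the size
#'   variable, the "<2 percent" diagnostic of the overlap rule), `cut`,
#'   `linkage`.
#' @export
group_morphotypes <- function(x, cut = 0.166, linkage = "ward.D2",
                              variables = PCA_VARIABLES) {
  stopifnot(inherits(x, "footprint_table"))
  if (nrow(x) == 0) stop("empty footprint table")
  have <- intersect(variables, names(x))
  have <- have[vapply(have, function(v) any(!is.na(x[[v]])), logical(1))]
  if (!length(have)) stop("no usable measurement columns")
  x <- x[order(x$id), , drop = FALSE]
  M <- measurement_matrix(footprint_table(as.data.frame(x)), have)
  keep <- rowSums(!is.na(M)) > 0
  if (!all(keep)) stop("record(s) with no measurements: ",
                       paste(rownames(M)[!keep], collapse = ", "))
  L <- log_transform(M)
  n <- nrow(L)
  if (n == 1L) {
    grp <- stats::setNames(1L, rownames(L))
  } else {
    D <- .log_shape_dist(L)
    h <- stats::hclust(D, method = linkage)
    hmax <- max(h$height)
    grp <- if (hmax <= 0) stats::setNames(rep(1L, n), rownames(L))
           else stats::cutree(h, h = cut * hmax)
  }
  # renumber groups by increasing mean size (row mean of log measurements)
  size <- tapply(rowMeans(L, na.rm = TRUE), grp, mean)
  relab <- match(names(sort(size)), names(size))
  grp <- stats::setNames(match(grp, as.integer(names(size))[relab]),
                         names(grp))
  new_morphotype_assignment(grp, "clustered", x,
                            cut = cut, linkage = linkage)
}

new_morphotype_assignment <- function(grp, provenance, tab,
                                      cut = NA_real_, linkage = NA_character_) {
  sizevar <- if ("max_FL" %in% names(tab)) tab$max_FL[match(names(grp), tab$id)]
             else if ("Dt1" %in% names(tab)) tab$Dt1[match(names(grp), tab$id)]
             else rep(NA_real_, length(grp))
  spread <- vapply(split(sizevar, grp), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    (max(v) - min(v)) / mean(v)
  }, numeric(1))
  structure(list(
    assignment = grp,
    n_groups = length(unique(grp)),
    provenance = provenance,
    spread = spread,
    cut = cut,
    linkage = linkage
  ), class = "morphotype_assignment")
}

#' Published morphotype assignment
#'
#' Wraps the morphotype labels printed in the source tables (descriptor or
#' measurement fixture) as a `morphotype_assignment` with provenance
#' `"published"`.
#'
#' @param x a [footprint_table()] with a `morphotype` column.
#' @return a `morphotype_assignment`.
#' @export
published_morphotypes <- function(x) {
  stopifnot(inherits(x, "footprint_table"))
  if (!"morphotype" %in% names(x)) stop("no 'morphotype' column")
  grp <- stats::setNames(as.integer(x$morphotype), x$id)
  if (anyNA(grp)) stop("unlabelled footprint(s): ",
                       paste(x$id[is.na(grp)], collapse = ", "))
  new_morphotype_assignment(grp, "published", x)
}

#' @export
print.morphotype_assignment <- function(x, ...) {
  cat("Morphotype assignment (", x$provenance, "): ",
      length(x$assignment), " footprints in ", x$n_groups, " group(s)\n",
      sep = "")
  for (g in sort(unique(x$assignment))) {
    sp <- x$spread[as.character(g)]
    cat(sprintf("  group %d (n=%d%s): %s\n", g, sum(x$assignment == g),
                if (is.na(sp)) "" else sprintf(", size spread %.1f%%", 100 * sp),
                paste(names(x$assignment)[x$assignment == g], collapse = ", ")))
  }
  invisible(x)
}

#' Minimum number of individuals
#'
#' Under the one-producer-per-morphotype reading of a trace assemblage, the
#' minimum number of individuals is the number of morphotype groups.
#'
#' @param a a `morphotype_assignment`.
#' @return integer count.
#' @export
minimum_individuals <- function(a) {
  stopifnot(inherits(a, "morphotype_assignment"))
  a$n_groups
}
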