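#' Electrode montages on a spherical head model
#'
#' A montage holds electrode labels and 3-D positions (cm) on a sphere of
#' radius `sphere_radius`. Positions are used for two things only: the
#' fixed-distance neighbourhood rule that defines cluster connectivity, and
#' the spherical-spline surface Laplacian. The default montage places 64
#' extended 10/20 labels by the standard proportional arc construction:
#' electrodes sit at equal angular steps along the sagittal midline arc, the
#' ear-to-ear coronal arc, the 10% outer ring, and the circles through the
#' lateral/midline anchor triplets of each row.
#'
#' @name montage
NULL

# point on the sphere: incl = inclination from the vertex (deg),
# az = azimuth from anterior midline (deg), positive toward the left
.sph_point <- function(r, incl, az) {
  ti <- incl * pi / 180
  ta <- az * pi / 180
  c(x = -r * sin(ti) * sin(ta), y = r * sin(ti) * cos(ta), z = r * cos(ti))
}

# circle on the sphere through three points, parameterised by arc angle;
# returns points at given fractions of the arc from a to b (through mid)
.arc_points <- function(a, mid, b, fractions) {
  ## circle centre: intersection of the plane through a, mid, b with the
  ## perpendicular bisector planes of (a,b) and (a,mid)
  n <- .cross3(mid - a, b - a)
  n <- n / sqrt(sum(n^2))
  A <- rbind(a - b, a - mid, n)
  rhs <- c(sum(a^2) - sum(b^2), sum(a^2) - sum(mid^2), 2 * sum(n * a)) / 2
  ctr <- solve(A, rhs)
  r <- sqrt(sum((a - ctr)^2))
  e1 <- (a - ctr) / r
  e2 <- .cross3(n, e1)
  ang <- function(p) atan2(sum(e2 * (p - ctr)), sum(e1 * (p - ctr)))
  am <- ang(mid)
  if (am < 0) { e2 <- -e2; am <- -am }
  ab <- ang(b)
  if (ab < am) ab <- ab + 2 * pi
  t(vapply(fractions * ab, function(th) ctr + r * (cos(th) * e1 + sin(th) * e2),
           numeric(3)))
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Default 64-channel extended 10/20 montage
#'
#' @param sphere_radius head radius in cm (default 9.2).
#' @return An object of class `eeg_montage`: list with `names` (64 labels),
#'   `coords` (64 x 3 matrix, cm, rows named) and `sphere_radius`.
#' @examples
#' m <- default_montage()
#' nrow(m$coords)
#' @export
default_montage <- function(sphere_radius = 9.2) {
  R <- sphere_radius
  pts <- list()
  add <- function(lab, p) pts[[lab]] <<- p

  ## outer 10% ring, inclination 72 deg, 18-deg steps around the ring
  ring <- c(Fpz = 0, Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
            TP7 = 108, P7 = 126, PO7 = 144, O1 = 162, Oz = 180)
  for (lab in names(ring)) add(lab, .sph_point(R, 72, ring[[lab]]))
  right_ring <- c(Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
                  TP8 = 108, P8 = 126, PO8 = 144, O2 = 162)
  for (lab in names(right_ring)) add(lab, .sph_point(R, 72, -right_ring[[lab]]))

  ## sagittal midline
  add("AFz", .sph_point(R, 54, 0)); add("Fz", .sph_point(R, 36, 0))
  add("Cz", .sph_point(R, 0, 0))
  add("CPz", .sph_point(R, 18, 180)); add("Pz", .sph_point(R, 36, 180))
  add("POz", .sph_point(R, 54, 180))

  ## coronal ear-to-ear arc
  cor_left <- c(C1 = 18, C3 = 36, C5 = 54)
  for (lab in names(cor_left)) add(lab, .sph_point(R, cor_left[[lab]], 90))
  cor_right <- c(C2 = 18, C4 = 36, C6 = 54)
  for (lab in names(cor_right)) add(lab, .sph_point(R, cor_right[[lab]], -90))

  ## interpolated rows: equal arc steps between lateral and midline anchors
  row4 <- function(left_anchor, mid_anchor, right_anchor, left_labs, right_labs) {
    a <- pts[[left_anchor]]; b <- pts[[right_anchor]]
    mid <- if (is.character(mid_anchor)) pts[[mid_anchor]] else mid_anchor
    nseg <- length(left_labs) + 1L
    fr_left <- seq_len(length(left_labs)) / (2 * nseg)
    fr_right <- 1 - rev(fr_left)
    pl <- .arc_points(a, mid, b, fr_left)
    pr <- .arc_points(a, mid, b, fr_right)
    for (i in seq_along(left_labs)) add(left_labs[i], pl[i, ])
    for (i in seq_along(right_labs)) add(right_labs[i], pr[i, ])
  }
  row4("F7", "Fz", "F8", c("F5", "F3", "F1"), c("F2", "F4", "F6"))
  ## FC row interpolates through the (unrecorded) vertex-adjacent midline point
  row4("FT7", .sph_point(R, 18, 0), "FT8", c("FC5", "FC3", "FC1"), c("FC2", "FC4", "FC6"))
  row4("TP7", "CPz", "TP8", c("CP5", "CP3", "CP1"), c("CP2", "CP4", "CP6"))
  row4("P7", "Pz", "P8", c("P5", "P3", "P1"), c("P2", "P4", "P6"))
  row4("AF7", "AFz", "AF8", "AF3", "AF4")
  row4("PO7", "POz", "PO8", "PO3", "PO4")

  ## inferior temporal sites on the equator
  add("FT9", .sph_point(R, 90, 72));  add("FT10", .sph_point(R, 90, -72))
  add("TP9", .sph_point(R, 90, 108)); add("TP10", .sph_point(R, 90, -108))

  coords <- do.call(rbind, pts)
  rownames(coords) <- names(pts)
  colnames(coords) <- c("x", "y", "z")
  ## snap interpolated points back onto the sphere (they are on it already up
  ## to round-off; normalisation keeps the radius invariant exact)
  coords <- coords * (R / sqrt(rowSums(coords^2)))
  new_montage(names(pts), coords, R)
}

#' Construct a montage object
#'
#' @param names character vector of unique electrode labels.
#' @param coords numeric matrix, one row per electrode, columns x, y, z (cm).
#' @param sphere_radius sphere radius in cm; all coordinates must lie on it.
#' @export
new_montage <- function(names, coords, sphere_radius) {
  stopifnot(is.character(names), !anyDuplicated(names),
            is.matrix(coords), nrow(coords) == length(names), ncol(coords) == 3)
  r <- sqrt(rowSums(coords^2))
  if (any(abs(r - sphere_radius) > 1e-6 * sphere_radius))
    stop("all electrode coordinates must lie at distance sphere_radius from the origin")
  rownames(coords) <- names
  structure(list(names = names, coords = coords, sphere_radius = sphere_radius),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes on a %.1f cm sphere\n",
              length(x$names), x$sphere_radius))
  cat(" ", paste(utils::head(x$names, 10), collapse = " "),
      if (length(x$names) > 10) "..." else "", "\n")
  invisible(x)
}

#' Subset a montage by electrode label
#'
#' @param montage an `eeg_montage`.
#' @param labels labels to keep (order preserved as given).
#' @export
montage_subset <- function(montage, labels) {
  missing <- setdiff(labels, montage$names)
  if (length(missing))
    stop("labels not in montage: ", paste(missing, collapse = ", "))
  new_montage(labels, montage$coords[labels, , drop = FALSE], montage$sphere_radius)
}

#' A 16-channel fronto-central/parietal reduction of the default montage
#'
#' Used for calibration experiments where the full 64-channel grid is not
#' needed; keeps the midfrontal (Fz, F1, F2) and left sensorimotor/parietal
#' sites so planted effects remain representable.
#' @param sphere_radius head radius in cm.
#' @export
reduced_montage <- function(sphere_radius = 9.2) {
  keep <- c("F3", "F1", "Fz", "F2", "F4", "FC1", "FC2", "C3", "C1", "Cz",
            "C2", "CP3", "CP1", "CPz", "P1", "Pz")
  montage_subset(default_montage(sphere_radius), keep)
}

#' Write / read a montage as plain text
#'
#' Format: one electrode per line, `label<TAB>x<TAB>y<TAB>z` in cm, no header.
#' @param montage an `eeg_montage`.
#' @param path file path.
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(label = montage$names, montage$coords, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @param sphere_radius radius of the sphere the coordinates lie on; if `NULL`
#'   it is taken as the mean distance of the electrodes from the origin.
#' @export
read_montage <- function(path, sphere_radius = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("label", "x", "y", "z"),
                          colClasses = c("character", rep("numeric", 3)))
  co <- as.matrix(df[, c("x", "y", "z")])
  if (is.null(sphere_radius)) sphere_radius <- mean(sqrt(rowSums(co^2)))
  new_montage(df$label, co, sphere_radius)
}

#' Electrode neighbourhood graph
#'
#' Two electrodes are neighbours when their 3-D Euclidean distance is
#' strictly below `threshold_cm`. The graph is symmetric and irreflexive.
#' Electrodes with no neighbour are allowed (a message notes them).
#'
#' @param montage an `eeg_montage`.
#' @param threshold_cm distance threshold in cm (default 4).
#' @return object of class `neighbor_graph`: `adj` (logical matrix),
#'   `names`, `threshold_cm`.
#' @export
build_neighbors <- function(montage, threshold_cm = 4) {
  d <- as.matrix(stats::dist(montage$coords))
  adj <- d < threshold_cm
  diag(adj) <- FALSE
  lonely <- montage$names[rowSums(adj) == 0]
  if (length(lonely))
    message("electrodes with no neighbours: ", paste(lonely, collapse = ", "))
  structure(list(adj = adj, names = montage$names, threshold_cm = threshold_cm),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d electrodes, %d edges, threshold %.1f cm\n",
              length(x$names), sum(x$adj) / 2, x$threshold_cm))
  invisible(x)
}
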