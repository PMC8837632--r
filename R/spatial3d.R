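#' Aggregate segmented cells into spot windows
#'
#' Assigns each segmented cell to the spot whose axis-aligned square window
#' (side `window`, centered on the spot) contains its centroid, and reports
#' per-spot cell counts and mean morphological features. Cells exactly on a
#' window boundary are included. Spots with no cells are flagged for removal
#' (spots without detected nuclei carry no usable morphology).
#'
#' @param cells data.frame with columns x, y, area, section_id, in the same
#'   coordinate frame as the spots.
#' @param spots spot table (barcode, x, y, section_id).
#' @param window window side length in the shared coordinate units
#'   (200 for the original pixel frame of 100-um spots).
#' @return data.frame per spot: barcode, section_id, cell_count, mean_area,
#'   remove (TRUE when no cells fell in the window).
#' @export
aggregate_cells_to_spots <- function(cells, spots, window = 200) {
  need <- c("x", "y", "area", "section_id")
  stopifnot(all(need %in% names(cells)),
            all(c("barcode", "x", "y", "section_id") %in% names(spots)))
  extra <- setdiff(unique(cells$section_id), unique(spots$section_id))
  if (length(extra))
    stop_spatlo(paste0("cell table has sections unknown to the spot table: ",
                       paste(extra, collapse = ", ")), "spatlo_validation_error")
  h <- window / 2
  out <- spots[, c("barcode", "section_id")]
  out$cell_count <- 0L
  out$mean_area <- NA_real_
  for (s in unique(spots$section_id)) {
    si <- which(spots$section_id == s)
    ci <- which(cells$section_id == s)
    if (!length(ci)) next
    cx <- cells$x[ci]; cy <- cells$y[ci]; ca <- cells$area[ci]
    for (i in si) {
      inwin <- abs(cx - spots$x[i]) <= h & abs(cy - spots$y[i]) <= h
      out$cell_count[i] <- sum(inwin)
      if (any(inwin)) out$mean_area[i] <- mean(ca[inwin])
    }
  }
  out$remove <- out$cell_count == 0L
  out
}

#' Percentile cell-density score and TLO call
#'
#' Converts per-spot cell counts into a within-section percentile rank in
#' `[0, 100]` (average ranks for ties; a single spot scores 50 by
#' convention) and flags spots whose score strictly exceeds the threshold as
#' TLO candidates. The default threshold of 70 flags roughly the densest
#' 30% of spots.
#'
#' @param counts per-spot cell counts.
#' @param section_id per-spot section identifiers (percentiles are computed
#'   within section); a single section is assumed when omitted.
#' @param threshold percentile above which a spot is called TLO (strict).
#' @return data.frame: cell_count, density_score, is_tlo (input order
#'   preserved).
#' @export
density_score <- function(counts, section_id = NULL, threshold = 70) {
  if (is.null(section_id)) section_id <- rep("all", length(counts))
  stopifnot(length(counts) == length(section_id))
  score <- numeric(length(counts))
  for (s in unique(section_id)) {
    i <- which(section_id == s)
    n <- length(i)
    score[i] <- if (n == 1) 50 else 100 * (rank(counts[i]) - 1) / (n - 1)
  }
  data.frame(cell_count = counts, density_score = score,
             is_tlo = score > threshold)
}

#' Fraction of annotated spots captured by the TLO call
#'
#' @param d a [density_score()] result.
#' @param annotations per-spot annotation labels (same order).
#' @param label the annotation of interest (e.g. `"infiltrate"`).
#' @return fraction of `label`-annotated spots with `is_tlo = TRUE`.
#' @export
annotation_overlap <- function(d, annotations, label = "infiltrate") {
  stopifnot(nrow(d) == length(annotations))
  sel <- annotations == label
  if (!any(sel))
    stop_spatlo("no spots carry the requested annotation", "spatlo_validation_error")
  mean(d$is_tlo[sel])
}

# closed-form least-squares similarity (Umeyama): maps X onto Y
fit_similarity <- function(X, Y, scale = TRUE) {
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- sum(Xc^2) / nrow(X)
  if (varx < 1e-12)
    stop_spatlo("degenerate landmark configuration", "spatlo_degenerate_error")
  s <- if (scale) sum(diag(D %*% diag(sv$d))) / varx else 1
  t <- my - s * as.vector(R %*% mx)
  list(theta = atan2(R[2, 1], R[1, 1]), scale = s, tx = t[1], ty = t[2],
       R = R)
}

apply_similarity <- function(P, tr) {
  sweep(tr$scale * P %*% t(tr$R), 2, c(tr$tx, tr$ty), `+`)
}

#' Register serial sections by point-set alignment
#'
#' Aligns every section's spot coordinates onto a reference section with a
#' least-squares similarity transform (rotation, isotropic scale,
#' translation; `"rigid"` fixes scale to 1). When two sections share spot
#' barcodes, correspondences are taken from the barcodes and the closed-form
#' (Umeyama) solution is exact; otherwise correspondences are established by
#' nearest-neighbour matching after centroid/principal-axis pre-alignment
#' and refined by a few ICP iterations.
#'
#' @param spots spot table (barcode, x, y, section_id, z); >= 3 spots per
#'   section.
#' @param mode `"scaled_rotation"` or `"rigid"`.
#' @param reference section id to hold fixed (default: first section).
#' @param max_icp_iter ICP iterations when no barcode correspondence exists.
#' @return list of class `spatlo_volume`: `transforms` (per section: theta,
#'   scale, tx, ty; identity for the reference), `spots` (table with
#'   registered `x_reg`, `y_reg`), `z` (per section), `reference`, `mode`.
#' @export
register_sections <- function(spots, mode = c("scaled_rotation", "rigid"),
                              reference = NULL, max_icp_iter = 30) {
  mode <- match.arg(mode)
  stopifnot(all(c("barcode", "x", "y", "section_id") %in% names(spots)))
  secs <- unique(spots$section_id)
  if (length(secs) < 2)
    stop_spatlo("need at least two sections to register", "spatlo_validation_error")
  if (any(table(spots$section_id) < 3))
    stop_spatlo("each section needs at least 3 spots", "spatlo_validation_error")
  reference <- reference %||% secs[1]
  if (!reference %in% secs)
    stop_spatlo("reference section not present", "spatlo_validation_error")
  ref <- spots[spots$section_id == reference, ]
  refP <- as.matrix(ref[, c("x", "y")])
  with_scale <- mode == "scaled_rotation"
  transforms <- list()
  spots$x_reg <- spots$x
  spots$y_reg <- spots$y
  for (s in secs) {
    if (s == reference) {
      transforms[[s]] <- list(theta = 0, scale = 1, tx = 0, ty = 0)
      next
    }
    mv <- spots[spots$section_id == s, ]
    P <- as.matrix(mv[, c("x", "y")])
    common <- intersect(mv$barcode, ref$barcode)
    if (length(common) >= 3) {
      tr <- fit_similarity(P[match(common, mv$barcode), , drop = FALSE],
                           refP[match(common, ref$barcode), , drop = FALSE],
                           scale = with_scale)
    } else {
      # pre-align by centroid and principal axis, then ICP
      pre_axis <- function(M) {
        e <- eigen(cov(M))
        ang <- atan2(e$vectors[2, 1], e$vectors[1, 1])
        ang
      }
      rot <- pre_axis(refP) - pre_axis(P)
      R0 <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
      cur <- sweep(sweep(P, 2, colMeans(P)) %*% t(R0), 2, colMeans(refP), `+`)
      tr <- NULL
      for (it in seq_len(max_icp_iter)) {
        nn <- apply(cur, 1, function(p)
          which.min((refP[, 1] - p[1])^2 + (refP[, 2] - p[2])^2))
        tr <- fit_similarity(P, refP[nn, , drop = FALSE], scale = with_scale)
        new <- apply_similarity(P, tr)
        if (max(abs(new - cur)) < 1e-10) { cur <- new; break }
        cur <- new
      }
    }
    reg <- apply_similarity(P, tr)
    spots$x_reg[spots$section_id == s] <- reg[, 1]
    spots$y_reg[spots$section_id == s] <- reg[, 2]
    transforms[[s]] <- tr[c("theta", "scale", "tx", "ty")]
  }
  z <- if ("z" %in% names(spots))
    vapply(secs, function(s) spots$z[spots$section_id == s][1], 1) else
      setNames(seq_along(secs) - 1, secs)
  structure(list(transforms = transforms, spots = spots,
                 z = setNames(as.numeric(z), secs),
                 reference = reference, mode = mode),
            class = "spatlo_volume")
}

#' @export
print.spatlo_volume <- function(x, ...) {
  cat(sprintf("<spatlo_volume> %d sections (%s registration), reference = %s\n",
              length(x$transforms), x$mode, x$reference))
  invisible(x)
}

#' Interpolate a per-spot scalar onto a regular grid
#'
#' Piecewise-linear interpolation on the Delaunay triangulation of the spot
#' positions, evaluated on a regular grid; grid nodes outside the spots'
#' convex hull are masked (NA). Linear fields are reproduced exactly and
#' spot values are recovered at the spot locations.
#'
#' @param values per-spot scalar.
#' @param x,y spot coordinates (same length as `values`).
#' @param grid_step grid spacing in coordinate units.
#' @return list `(x, y, z)` where `z` is a length(x)-by-length(y) matrix
#'   with NA outside the hull.
#' @export
interpolate_grid <- function(values, x, y, grid_step = 1) {
  stopifnot(length(values) == length(x), length(x) == length(y))
  if (length(x) < 4)
    stop_spatlo("need at least 4 spots to interpolate", "spatlo_validation_error")
  if (sd(x) == 0 || sd(y) == 0 || abs(cor(x, y)) > 1 - 1e-12)
    stop_spatlo("spots are collinear; cannot triangulate", "spatlo_degenerate_error")
  gx <- seq(min(x), max(x), by = grid_step)
  gy <- seq(min(y), max(y), by = grid_step)
  out <- interp::interp(x = x, y = y, z = values, xo = gx, yo = gy,
                        method = "linear", extrap = FALSE,
                        duplicate = "mean")
  list(x = out$x, y = out$y, z = out$z)
}

#' Interpolate one scalar per section of a registered volume
#'
#' Applies [interpolate_grid()] to each section of a registered volume using
#' the registered coordinates; stacking the returned grids by `z` gives the
#' interpolated volume (no smoothing across sections).
#'
#' @param volume a `spatlo_volume` from [register_sections()].
#' @param values named per-spot vector (names = barcodes) or unnamed in spot
#'   table order.
#' @param grid_step grid spacing.
#' @return the volume with a `grids` element (one grid per section, ordered
#'   by z).
#' @export
interpolate_volume <- function(volume, values, grid_step = 1) {
  stopifnot(inherits(volume, "spatlo_volume"))
  sp <- volume$spots
  v <- if (!is.null(names(values))) values[sp$barcode] else values
  stopifnot(length(v) == nrow(sp))
  secs <- names(sort(volume$z))
  volume$grids <- setNames(lapply(secs, function(s) {
    i <- sp$section_id == s
    interpolate_grid(v[i], sp$x_reg[i], sp$y_reg[i], grid_step)
  }), secs)
  volume
}
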