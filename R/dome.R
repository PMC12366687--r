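## Membrane dome geometry: interblade distance -> in-plane radius ->
## spherical-cap curvature radius, plus the generic rigid-body
## blade-rotation scan for labeled atomic coordinate sets.
##
## The in-plane radius is the circumradius of the equilateral fluorophore
## triangle, r = d / sqrt(3), with a fixed 1.5-nm offset from the labeled
## residue to the blade edge added to d first:
##     r = (d + 1.5) / sqrt(3).
## A spherical cap of in-plane radius r and height h has curvature radius
##     R = (r^2 + h^2) / (2 h).

#' In-plane radius from the interblade distance
#'
#' `r = (d + offset) / sqrt(3)`; the default 1.5-nm offset is the distance
#' from the labeled blade residue to the blade edge. The returned
#' uncertainty propagates the measured distance error through the same
#' affine map.
#'
#' @param d Interblade distance(s) in nm (>= 0).
#' @param offset Label-to-blade-edge offset in nm.
#' @param d_error Distance error in nm (default 2.3, the median propagated
#'   localization error of the standard conditions).
#' @return List with `r` (nm) and `r_error` (nm); both vectorized over `d`.
#' @export
#' @examples
#' radius_from_distance(19)$r  # ~ 11.8 nm
radius_from_distance <- function(d, offset = 1.5, d_error = 2.3) {
  if (any(!is.finite(d)) || any(d < 0)) stop("d must be non-negative")
  list(r = (d + offset) / sqrt(3), r_error = d_error / sqrt(3))
}

#' Spherical-cap curvature radius
#'
#' `R = (r^2 + h^2) / (2 h)` for a spherical cap of in-plane radius `r`
#' reaching height `h` above the flat membrane. `h = 0` corresponds to a
#' flat membrane with `R = Inf` and is rejected here; use
#' [median_curvature()] to integrate over a height range excluding 0.
#'
#' @param r In-plane radius in nm.
#' @param h Dome height in nm (> 0).
#' @return Curvature radius in nm (vectorized over `r` and `h`).
#' @export
#' @examples
#' curvature_radius(6, 5.5)   # ~ 6 nm: highly curved
#' curvature_radius(20, 1)    # ~ 200 nm: nearly flat
curvature_radius <- function(r, h) {
  if (any(!is.finite(h)) || any(h <= 0))
    stop("h must be positive (h = 0 gives a flat membrane, R = Inf)")
  (r^2 + h^2) / (2 * h)
}

#' Median curvature radius over a dome-height range
#'
#' Samples the dome height uniformly on the half-open interval
#' `(h_range[1], h_range[2]]` (the lower end, usually 0, is excluded since
#' R diverges there), computes `R` per sample and returns the median with
#' a 2.5--97.5 percentile interval. When `r_sd` is given, `r` is also
#' drawn as `N(r, r_sd^2)` per sample, propagating the radius uncertainty.
#'
#' @param r In-plane radius in nm (> 0).
#' @param h_range Height range in nm, lower bound excluded.
#' @param n_samples Monte Carlo sample count.
#' @param r_sd Optional SD of `r` in nm (0 = fixed r).
#' @param seed Optional RNG seed.
#' @return List with `median` (nm), `interval` (2.5 and 97.5 percentiles)
#'   and `samples` count.
#' @export
#' @examples
#' median_curvature(12, seed = 1)$median  # ~ 30 nm
median_curvature <- function(r, h_range = c(0, 5), n_samples = 1e5,
                             r_sd = 0, seed = NULL) {
  stopifnot(r > 0, length(h_range) == 2, h_range[2] > h_range[1],
            h_range[2] > 0, n_samples >= 1)
  .with_seed(seed, {
    ## uniform on (lo, hi]: flip runif's [0, 1) to (0, 1]
    u <- 1 - stats::runif(n_samples)
    h <- h_range[1] + u * (h_range[2] - h_range[1])
    rs <- if (r_sd > 0) stats::rnorm(n_samples, r, r_sd) else r
    R <- curvature_radius(rs, h)
    list(median = stats::median(R),
         interval = stats::quantile(R, c(0.025, 0.975), names = FALSE),
         samples = n_samples)
  })
}

#' Dome geometry summary for a class
#'
#' Convenience wrapper chaining [radius_from_distance()],
#' [curvature_radius()] (at a fixed height, if given) and
#' [median_curvature()] (over a height range).
#'
#' @param d Interblade distance in nm.
#' @param h Fixed dome height in nm (optional).
#' @param h_range Height range for the median (optional).
#' @param seed Optional RNG seed for the median sampling.
#' @return List with `d`, `r`, `r_error`, and `R` (at `h`) and/or
#'   `R_median` + `R_interval` (over `h_range`).
#' @export
dome_geometry <- function(d, h = NULL, h_range = NULL, seed = NULL) {
  rr <- radius_from_distance(d)
  out <- list(d = d, r = rr$r, r_error = rr$r_error)
  if (!is.null(h)) out$R <- curvature_radius(rr$r, h)
  if (!is.null(h_range)) {
    mc <- median_curvature(rr$r, h_range, seed = seed)
    out$R_median <- mc$median
    out$R_interval <- mc$interval
  }
  out
}

#' Rigid-body blade rotation scan
#'
#' Generic scan for trimeric blade models: all points of one protomer from
#' the N-terminal side up to (and excluding) the pivot are rotated rigidly
#' about the pivot point, the trimer is rebuilt by three-fold replication
#' about the z axis, and the interblade distance between the probe sites
#' of neighboring protomers is reported per grid angle.
#'
#' Axes: `"in_plane"` rotates about the z axis through the pivot (blades
#' sweep in the membrane plane); `"out_of_plane"` rotates about the
#' in-plane axis through the pivot perpendicular to the pivot's radial
#' direction (blades swing up out of the plane).
#'
#' @param coords Nx3 numeric matrix: one protomer's labeled points, ordered
#'   from the N terminus, in the declared unit, with the trimer axis at the
#'   origin along z.
#' @param pivot Row index of the pivot point (the elbow).
#' @param probe Row index of the probe site (the labeled residue analogue);
#'   must be on the N-terminal side of the pivot.
#' @param axis `"in_plane"` or `"out_of_plane"`.
#' @param angles Rotation grid in degrees.
#' @param unit `"nm"` or `"angstrom"` (converted to nm).
#' @return A `blade_scan` data.frame with columns `angle` (degrees) and
#'   `interblade_nm`, plus attribute `coords_at` (function returning the
#'   rotated protomer for a given angle, in nm).
#' @export
rigid_body_scan <- function(coords, pivot, probe = 1,
                            axis = c("in_plane", "out_of_plane"),
                            angles = seq(0, 180, by = 5),
                            unit = c("nm", "angstrom")) {
  axis <- match.arg(axis)
  unit <- match.arg(unit)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an Nx3 matrix")
  if (!is.numeric(coords) || any(!is.finite(coords)))
    stop("coords must be finite numeric values in the declared unit")
  if (unit == "angstrom") coords <- coords / 10
  n <- nrow(coords)
  if (pivot < 1 || pivot > n) stop("pivot index outside the coordinate set")
  if (probe >= pivot) stop("probe must lie on the N-terminal side of the pivot")
  pv <- coords[pivot, ]

  ## rotation axis through the pivot
  u <- if (axis == "in_plane") c(0, 0, 1) else {
    radial <- c(pv[1], pv[2], 0)
    if (sum(radial^2) < 1e-12)
      stop("out-of-plane axis undefined: pivot lies on the trimer axis")
    radial <- radial / sqrt(sum(radial^2))
    c(-radial[2], radial[1], 0)  # in-plane, perpendicular to radial
  }

  rotate_about <- function(pts, phi_deg) {
    phi <- phi_deg * .deg2rad
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)  # Rodrigues
    sweep(sweep(pts, 2, pv) %*% t(R), 2, pv, `+`)
  }

  rot120 <- rotation_matrix(120, 0, 0)
  coords_at <- function(phi_deg) {
    out <- coords
    out[seq_len(pivot - 1), ] <- rotate_about(coords[seq_len(pivot - 1), ,
                                                     drop = FALSE], phi_deg)
    out
  }
  dist_at <- function(phi_deg) {
    pr <- coords_at(phi_deg)[probe, ]
    pr2 <- as.numeric(pr %*% t(rot120))  # neighboring protomer's probe
    sqrt(sum((pr - pr2)^2))
  }
  out <- data.frame(angle = angles,
                    interblade_nm = vapply(angles, dist_at, 0))
  attr(out, "coords_at") <- coords_at
  class(out) <- c("blade_scan", "data.frame")
  out
}

#' Load a blade model from a PDB file
#'
#' Reads C-alpha coordinates of one chain with bio3d and returns them (in
#' nm) together with the row indices of the pivot and probe residues, ready
#' for [rigid_body_scan()].
#'
#' @param file PDB file path.
#' @param chain Chain identifier.
#' @param pivot_resno,probe_resno Residue numbers of pivot and probe.
#' @return List with `coords` (Nx3, nm), `pivot`, `probe`.
#' @export
blade_from_pdb <- function(file, chain, pivot_resno, probe_resno) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(file)
  sel <- bio3d::atom.select(pdb, chain = chain, elety = "CA")
  at <- pdb$atom[sel$atom, ]
  coords <- as.matrix(at[, c("x", "y", "z")]) / 10  # Angstrom -> nm
  list(coords = coords,
       pivot = match(pivot_resno, at$resno),
       probe = match(probe_resno, at$resno))
}
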