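## Rotational alignment and template classification.
##
## Particle maps are mixtures of isotropic Gaussians, so the Pearson
## cross-correlation between two maps over a finite window can be written in
## closed form from pairwise Gaussian overlap integrals:
##   integral(A * B) = sum_ij w_i w_j N(mu_i - nu_j; 0, (s_i^2 + s_j^2) I).
## Working on the mixture representation makes the rotation scan exact (no
## image resampling) and fast; map-valued inputs are compared with the same
## statistic via map_correlation().

## Overlap integral of two isotropic Gaussian mixtures in 2D.
## a, b: lists with positions (n x 2), sds (length n), weights (length n).
.mix_overlap <- function(ax, ay, as2, aw, bx, by, bs2, bw) {
  tot <- 0
  for (i in seq_along(ax)) {
    s2 <- as2[i] + bs2
    tot <- tot + sum(aw[i] * bw / (2 * pi * s2) *
                       exp(-((ax[i] - bx)^2 + (ay[i] - by)^2) / (2 * s2)))
  }
  tot
}

## Windowed Pearson correlation of two unit-mass mixtures: the continuous
## limit of the pixelwise correlation over a window of area W containing
## essentially all mass.
.mix_correlation <- function(a, b, window_area) {
  iab <- .mix_overlap(a$x, a$y, a$s2, a$w, b$x, b$y, b$s2, b$w)
  iaa <- .mix_overlap(a$x, a$y, a$s2, a$w, a$x, a$y, a$s2, a$w)
  ibb <- .mix_overlap(b$x, b$y, b$s2, b$w, b$x, b$y, b$s2, b$w)
  m <- 1 / window_area
  (iab - m) / sqrt((iaa - m) * (ibb - m))
}

## Mixture view of a particle_projection or template (positions centered).
.as_mixture <- function(p, width = NULL) {
  if (inherits(p, "triangle_template")) {
    pos <- p$positions; s <- rep(p$width, nrow(pos))
  } else if (inherits(p, "particle_projection")) {
    pos <- sweep(p$positions, 2, colMeans(p$positions))
    s <- if (is.null(width)) p$precisions else rep(width, 3)
  } else stop("unsupported input for mixture correlation")
  n <- nrow(pos)
  list(x = pos[, 1], y = pos[, 2], s2 = s^2, w = rep(1 / n, n))
}

#' Equilateral triangle template
#'
#' A template is an equilateral triangle of the given side length, centered
#' at the origin, each vertex rendered as a unit-mass Gaussian of SD
#' `width` (default 1.4 nm, the population-median localization precision of
#' the standard conditions).
#'
#' @param side Side length in nm.
#' @param width Rendering Gaussian SD in nm.
#' @return A `triangle_template` with fields `side`, `width`, `positions`.
#' @export
triangle_template <- function(side, width = 1.4) {
  structure(list(side = side, width = width,
                 positions = equilateral_vertices(side)[, 1:2]),
            class = "triangle_template")
}

#' Pearson correlation of two rendered maps
#'
#' Plain normalized cross-correlation of two same-sized matrices (no
#' shift); uncorrelated noise maps score near 0, identical maps score 1.
#'
#' @param a,b Numeric matrices of identical dimension.
#' @return Correlation in \[-1, 1\].
#' @export
map_correlation <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("maps must share a grid")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant map")
  stats::cor(as.vector(a), as.vector(b))
}

#' Best in-plane rotation of a particle against a template
#'
#' Scans the in-plane rotation angle at `step`-degree resolution, computing
#' the windowed Pearson correlation between the rotated particle mixture
#' and the template, then refines the best angle by golden-section search.
#' Templates are three-fold symmetric, so the correlation has period 120
#' degrees and the angle is reported modulo 120.
#'
#' @param p A `particle_projection`.
#' @param template A `triangle_template`.
#' @param step Scan step in degrees.
#' @param window Side length (nm) of the correlation window.
#' @return List with `angle` (degrees, in \[0, 120)) and `correlation`.
#' @export
align_rotation <- function(p, template, step = 1, window = 80) {
  b <- .as_mixture(template)
  W <- window^2
  corr_at <- function(theta) {
    a <- .rotated_mixture(p, theta)
    .mix_correlation(a, b, W)
  }
  angles <- seq(0, 120 - step, by = step)
  cors <- .rotation_scan(p, template, angles, W)
  i <- which.max(cors)
  ## golden-section refinement on the bracketing interval
  lo <- angles[i] - step; hi <- angles[i] + step
  opt <- stats::optimize(corr_at, c(lo, hi), maximum = TRUE, tol = 1e-3)
  ang <- opt$maximum %% 120
  if (opt$objective >= cors[i]) list(angle = ang, correlation = opt$objective)
  else list(angle = angles[i] %% 120, correlation = cors[i])
}

## Rotate a particle's centered positions by theta degrees (about the
## centroid) and return its mixture view.
.rotated_mixture <- function(p, theta) {
  m <- .as_mixture(p)
  ct <- cos(theta * .deg2rad); st <- sin(theta * .deg2rad)
  list(x = ct * m$x - st * m$y, y = st * m$x + ct * m$y, s2 = m$s2, w = m$w)
}

## Vectorized correlation over a vector of scan angles. Uses
## |R(theta) p_i - q_j|^2 = |p_i|^2 + |q_j|^2 - 2 (p_i . R(theta)^T q_j),
## which is a + b cos(theta) + c sin(theta) per pair, so the full scan
## costs one exp() per (pair, angle).
.rotation_scan <- function(p, template, angles, window_area) {
  a <- .as_mixture(p); b <- .as_mixture(template)
  th <- angles * .deg2rad
  iab <- numeric(length(th))
  for (i in seq_along(a$x)) for (j in seq_along(b$x)) {
    s2 <- a$s2[i] + b$s2[j]
    const <- a$x[i]^2 + a$y[i]^2 + b$x[j]^2 + b$y[j]^2
    ## (R p_i) . q_j = cos*(xi xj + yi yj) + sin*(xi yj - yi xj)
    cc <- a$x[i] * b$x[j] + a$y[i] * b$y[j]
    cs <- a$x[i] * b$y[j] - a$y[i] * b$x[j]
    d2 <- const - 2 * (cc * cos(th) + cs * sin(th))
    iab <- iab + a$w[i] * b$w[j] / (2 * pi * s2) * exp(-d2 / (2 * s2))
  }
  iaa <- .mix_overlap(a$x, a$y, a$s2, a$w, a$x, a$y, a$s2, a$w)
  ibb <- .mix_overlap(b$x, b$y, b$s2, b$w, b$x, b$y, b$s2, b$w)
  m <- 1 / window_area
  (iab - m) / sqrt((iaa - m) * (ibb - m))
}

#' Classify a particle by template matching
#'
#' A particle whose maximum side exceeds `cutoff` (default 43 nm, beyond
#' the protein dimension) is unclassified. Otherwise the label is the
#' template (side 9 / 19 / 34 nm by default) with the highest
#' rotation-maximized correlation; the score is that maximum, clamped to
#' \[0, 1\]. An optional `score_floor` additionally unclassifies particles
#' whose best score falls below it (off by default).
#'
#' @param p A `particle_projection`.
#' @param templates List of `triangle_template` objects, one per class.
#' @param cutoff Maximum-side cutoff in nm.
#' @param score_floor Minimum acceptable score (0 disables).
#' @param step Rotation scan step in degrees.
#' @return A `class_assignment`: list with `particle_id`, `class_label`
#'   (`"i"`, `"ii"`, `"iii"` or `"unclassified"`), `score`, `angle`
#'   (best in-plane rotation, degrees mod 120) and `d_max`.
#' @export
classify_template <- function(p, templates = default_templates(),
                              cutoff = 43, score_floor = 0, step = 1) {
  d_max <- max(.tri_dists(p$positions))
  labels <- c("i", "ii", "iii")[seq_along(templates)]
  if (d_max > cutoff) {
    return(structure(list(particle_id = p$particle_id,
                          class_label = "unclassified", score = NA_real_,
                          angle = NA_real_, d_max = d_max),
                     class = "class_assignment"))
  }
  best <- lapply(templates, function(tem) align_rotation(p, tem, step = step))
  scores <- vapply(best, `[[`, 0, "correlation")
  k <- which.max(scores)
  score <- min(max(scores[k], 0), 1)
  label <- if (score < score_floor) "unclassified" else labels[k]
  structure(list(particle_id = p$particle_id, class_label = label,
                 score = score, angle = best[[k]]$angle, d_max = d_max),
            class = "class_assignment")
}

#' Default class templates (sides 9, 19, 34 nm)
#'
#' @param width Rendering Gaussian SD in nm.
#' @param sides Template side lengths in nm.
#' @return List of `triangle_template` objects.
#' @export
default_templates <- function(width = 1.4, sides = c(9, 19, 34)) {
  lapply(sides, triangle_template, width = width)
}

#' Classify a particle set
#'
#' @param particles List of `particle_projection` objects.
#' @inheritParams classify_template
#' @return Data.frame with `particle_id`, `class_label`, `score`, `angle`,
#'   `d_max`.
#' @export
classify_particles <- function(particles, templates = default_templates(),
                               cutoff = 43, score_floor = 0, step = 1) {
  rows <- lapply(particles, function(p) {
    a <- classify_template(p, templates, cutoff, score_floor, step)
    data.frame(particle_id = a$particle_id, class_label = a$class_label,
               score = a$score, angle = a$angle, d_max = a$d_max)
  })
  do.call(rbind, rows)
}

#' Class fractions over classified particles
#'
#' @param assignments Data.frame from [classify_particles()] (or a vector
#'   of labels).
#' @return List with `fractions` (over `i`, `ii`, `iii`; sums to 1) and
#'   `n_unclassified`.
#' @export
class_fractions <- function(assignments) {
  labels <- if (is.data.frame(assignments)) assignments$class_label
  else as.character(assignments)
  if (!length(labels)) stop("no assignments given")
  n_un <- sum(labels == "unclassified")
  cl <- labels[labels != "unclassified"]
  if (!length(cl)) stop("no classified particles")
  fr <- table(factor(cl, levels = c("i", "ii", "iii"))) / length(cl)
  list(fractions = as.numeric(fr), n_unclassified = n_un)
}

#' Sum aligned particle maps of one class
#'
#' Rotates each particle to its best template angle (about its centroid),
#' renders all on a common centered grid, averages and renormalizes. For
#' display, pixels below `outlier_floor` times the composite maximum are
#' suppressed, matching the treatment of low-probability outlier
#' projections in class-average images.
#'
#' @param particles List of `particle_projection` objects (one class).
#' @param assignments Matching rows of [classify_particles()] (angles are
#'   recomputed when absent).
#' @param template The class template (used when angles must be computed).
#' @param grid_size,pixel_nm Rendering grid (see [render_particle()]).
#' @param outlier_floor Display suppression threshold (fraction of max).
#' @return Composite map matrix (unit sum before suppression) with
#'   attribute `raw` holding the unsuppressed average.
#' @export
sum_aligned <- function(particles, assignments = NULL, template = NULL,
                        grid_size = 128, pixel_nm = 0.75,
                        outlier_floor = 0.5) {
  if (!length(particles)) stop("empty class: nothing to sum")
  angles <- if (!is.null(assignments)) assignments$angle
  else vapply(particles, function(p)
    align_rotation(p, template)$angle, 0)
  acc <- NULL
  for (i in seq_along(particles)) {
    p <- particles[[i]]
    th <- angles[i] * .deg2rad  # the rotation that maximized template correlation
    ct <- cos(th); st <- sin(th)
    pos <- sweep(p$positions, 2, colMeans(p$positions))
    rot <- cbind(ct * pos[, 1] - st * pos[, 2],
                 st * pos[, 1] + ct * pos[, 2])
    q <- particle_projection(lapply(1:3, function(k) {
      f <- p$fluorophores[[k]]
      f$x <- rot[k, 1]; f$y <- rot[k, 2]
      f
    }), particle_id = p$particle_id)
    m <- render_particle(q, grid_size, pixel_nm, center = c(0, 0))
    acc <- if (is.null(acc)) m else acc + m
  }
  avg <- acc / sum(acc)
  shown <- avg
  shown[shown < outlier_floor * max(shown)] <- 0
  attr(shown, "raw") <- avg
  attr(shown, "pixel_nm") <- pixel_nm
  shown
}
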