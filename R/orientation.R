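## 3D orientation estimation by penalized simulated annealing.
##
## A model equilateral triangle of the particle's class side is rotated
## through (yaw, pitch, roll), projected, rendered with the particle's
## Gaussian widths, and compared with the particle map by windowed Pearson
## correlation. The objective
##     objective = -correlation + theta * (pitch + roll)
## (theta in correlation units per degree; pitch/roll folded into [0, 90])
## prefers in-plane solutions when the data cannot distinguish, matching
## the physical prior that transmembrane particles lie in the plane.

#' Orientation objective for a candidate rotation
#'
#' @param p A `particle_projection`.
#' @param model_side Side length (nm) of the model triangle.
#' @param yaw,pitch,roll Candidate Euler angles (degrees).
#' @param theta Penalty weight per degree of out-of-plane angle.
#' @param width Gaussian width (nm) of the model's rendered vertices
#'   (default: the particle's mean precision).
#' @param window Correlation window side (nm).
#' @return List with `objective`, `correlation`, `pitch`, `roll` (folded).
#' @export
orientation_objective <- function(p, model_side, yaw, pitch, roll,
                                  theta = 0.005, width = NULL,
                                  window = 80) {
  ctx <- .orientation_context(p, model_side, width, window)
  .obj_eval(ctx, yaw, pitch, roll, theta)
}

## Precompute everything reusable across objective evaluations.
.orientation_context <- function(p, model_side, width = NULL, window = 80) {
  a <- .as_mixture(p)
  v <- equilateral_vertices(model_side)
  w <- if (is.null(width)) p$mean_precision else width
  W <- window^2
  m <- 1 / W
  iaa <- .mix_overlap(a$x, a$y, a$s2, a$w, a$x, a$y, a$s2, a$w)
  ## model self-overlap is rotation invariant (rigid body, equal widths)
  bs2 <- rep(w^2, 3)
  bw <- rep(1 / 3, 3)
  ibb <- .mix_overlap(v[, 1], v[, 2], bs2, bw, v[, 1], v[, 2], bs2, bw)
  list(ax = a$x, ay = a$y, as2 = a$s2, aw = a$w, v = v,
       bs2 = bs2, bw = bw, denom = sqrt((iaa - m) * (ibb - m)), m = m)
}

.obj_eval <- function(ctx, yaw, pitch, roll, theta) {
  R <- rotation_matrix(yaw, pitch, roll)
  bx <- ctx$v %*% R[1, ]
  by <- ctx$v %*% R[2, ]
  iab <- .mix_overlap(ctx$ax, ctx$ay, ctx$as2, ctx$aw,
                      bx, by, ctx$bs2, ctx$bw)
  corr <- (iab - ctx$m) / ctx$denom
  fp <- fold_angle(pitch); fr <- fold_angle(roll)
  list(objective = -corr + theta * (fp + fr), correlation = corr,
       pitch = fp, roll = fr)
}

#' Projection-equivalent orientations of a trimer model
#'
#' The orthographic projection of a C3-symmetric planar triangle does not
#' change under the triangle's in-plane symmetries (rotations by 120
#' degrees and mirror flips) or under view inversion. These generate a
#' 12-element group of rotations with identical projections but different
#' Euler angles -- e.g. a pure 30-degree pitch projects identically to a
#' (14.4, 26.5) pitch/roll combination. Orientation estimates are therefore
#' only defined modulo this group; this function enumerates the copies.
#'
#' @param yaw,pitch,roll Euler angles in degrees.
#' @return A 12x3 matrix of equivalent (yaw, pitch, roll) triples (signed
#'   pitch/roll; apply [fold_angle()] for reporting).
#' @export
equivalent_orientations <- function(yaw, pitch, roll) {
  R0 <- rotation_matrix(yaw, pitch, roll)
  out <- matrix(NA_real_, 12, 3,
                dimnames = list(NULL, c("yaw", "pitch", "roll")))
  i <- 0
  for (k in 0:2) for (mx in c(1, -1)) for (mz in c(1, -1)) {
    S <- rotation_matrix(120 * k, 0, 0) %*% diag(c(mx, 1, mz))
    A <- (R0 %*% S)[1:2, ]
    r3 <- c(A[1, 2] * A[2, 3] - A[1, 3] * A[2, 2],
            A[1, 3] * A[2, 1] - A[1, 1] * A[2, 3],
            A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])  # proper completion
    i <- i + 1
    out[i, ] <- .euler_from_matrix(rbind(A, r3))
  }
  out[, 1] <- out[, 1] %% 360
  out
}

## Canonical representative: the projection-equivalent copy with the least
## total out-of-plane angle (ties toward smaller |pitch|, then pitch >= 0).
## Angles stay signed -- they define the actual rotation; folding is a
## reporting convention only.
.canonical_orientation <- function(yaw, pitch, roll) {
  eq <- equivalent_orientations(yaw, pitch, roll)
  tot <- fold_angle(eq[, 2]) + fold_angle(eq[, 3])
  best <- eq[order(tot, fold_angle(eq[, 2]), -sign(eq[, 2]))[1], ]
  c(yaw = unname(best[1]), pitch = unname(best[2]), roll = unname(best[3]))
}

#' Estimate a particle's 3D orientation by simulated annealing
#'
#' Minimizes `-correlation + theta * (pitch + roll)` over (yaw, pitch,
#' roll) with restarts of a geometric-cooling Metropolis annealer
#' (start temperature 1.0, factor 0.95, 200 steps per restart, Gaussian
#' angle proposals annealed from 10 to 1 degrees). Reproducible for a
#' fixed seed.
#'
#' @param p A `particle_projection`.
#' @param model_side Model triangle side (nm), normally the class side.
#' @param theta Out-of-plane penalty weight per degree (>= 0; default
#'   0.005, so a 10-degree excursion costs 0.1 correlation units).
#' @param restarts Number of annealing restarts.
#' @param n_steps Annealing steps per restart.
#' @param t_start,cooling Start temperature and geometric cooling factor.
#' @param width,window See [orientation_objective()].
#' @param seed Optional RNG seed.
#' @param keep_trace If TRUE, records (temperature, objective) per step of
#'   the best restart.
#' @return An `orientation_estimate`: list with `yaw`, `pitch`, `roll`
#'   (degrees; pitch/roll folded into \[0, 90\] and reported for the
#'   canonical, least out-of-plane member of the projection-equivalent
#'   class -- see [equivalent_orientations()]), `objective`,
#'   `correlation`, `theta`, `low_confidence` (TRUE for degenerate,
#'   all-overlapping particles) and optionally `annealing_trace`.
#' @export
estimate_orientation <- function(p, model_side, theta = 0.005,
                                 restarts = 20, n_steps = 200,
                                 t_start = 1, cooling = 0.95,
                                 width = NULL, window = 80, seed = NULL,
                                 keep_trace = FALSE) {
  stopifnot(theta >= 0)
  ctx <- .orientation_context(p, model_side, width, window)
  ## degenerate particle: all three fluorophores overlapping within precision
  spread <- max(.tri_dists(p$positions))
  low_conf <- spread < 2 * p$mean_precision
  .with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      ang <- c(stats::runif(1, 0, 360), stats::runif(1, 0, 90),
               stats::runif(1, 0, 90))
      cur <- .obj_eval(ctx, ang[1], ang[2], ang[3], theta)
      best_r <- list(ang = ang, val = cur$objective)
      temp <- t_start
      trace <- if (keep_trace) matrix(NA_real_, n_steps, 2) else NULL
      for (s in seq_len(n_steps)) {
        prop_sd <- 10 * (1 / 10)^((s - 1) / (n_steps - 1))  # 10 -> 1 deg
        cand <- ang + stats::rnorm(3, 0, prop_sd)
        cand[1] <- cand[1] %% 360
        cand[2] <- fold_angle(cand[2]); cand[3] <- fold_angle(cand[3])
        new <- .obj_eval(ctx, cand[1], cand[2], cand[3], theta)
        if (new$objective < cur$objective ||
            stats::runif(1) < exp((cur$objective - new$objective) / temp)) {
          ang <- cand; cur <- new
        }
        if (cur$objective < best_r$val) best_r <- list(ang = ang, val = cur$objective)
        if (keep_trace) trace[s, ] <- c(temp, cur$objective)
        temp <- temp * cooling
      }
      if (is.null(best) || best_r$val < best$val) {
        best <- best_r
        best$trace <- trace
      }
    }
    ## report the canonical (least out-of-plane) projection-equivalent copy;
    ## its correlation is identical and its penalty can only be lower. A
    ## Nelder-Mead polish then refines the annealer's discrete endpoint.
    can <- .canonical_orientation(best$ang[1], best$ang[2], best$ang[3])
    pol <- stats::optim(can, function(a)
      .obj_eval(ctx, a[1], a[2], a[3], theta)$objective,
      method = "Nelder-Mead",
      control = list(maxit = 200, reltol = 1e-10))
    can <- .canonical_orientation(pol$par[1], pol$par[2], pol$par[3])
    fin <- .obj_eval(ctx, can[1], can[2], can[3], theta)
    structure(list(
      yaw = can[1], pitch = fin$pitch, roll = fin$roll,
      objective = fin$objective, correlation = fin$correlation,
      theta = theta, low_confidence = low_conf,
      annealing_trace = if (keep_trace) best$trace else NULL
    ), class = "orientation_estimate")
  })
}

#' @export
print.orientation_estimate <- function(x, ...) {
  cat(sprintf("<orientation_estimate> yaw %.1f, pitch %.1f, roll %.1f deg; corr %.3f, objective %.3f%s\n",
              x$yaw, x$pitch, x$roll, x$correlation, x$objective,
              if (isTRUE(x$low_confidence)) " (low confidence)" else ""))
  invisible(x)
}

#' Exhaustive grid search over orientations
#'
#' Brute-force minimizer of the same objective on a regular
#' (yaw, pitch, roll) grid; serves as the independent oracle for the
#' annealer.
#'
#' @inheritParams estimate_orientation
#' @param step Grid step in degrees.
#' @return List with `yaw`, `pitch`, `roll`, `objective`, `correlation`.
#' @export
orientation_grid_search <- function(p, model_side, theta = 0.005,
                                    step = 10, width = NULL, window = 80) {
  ctx <- .orientation_context(p, model_side, width, window)
  yaws <- seq(0, 360 - step, by = step)
  tilts <- seq(0, 90, by = step)
  best <- list(objective = Inf)
  for (yv in yaws) for (pv in tilts) for (rv in tilts) {
    o <- .obj_eval(ctx, yv, pv, rv, theta)
    if (o$objective < best$objective)
      best <- list(yaw = yv, pitch = pv, roll = rv,
                   objective = o$objective, correlation = o$correlation)
  }
  best
}

#' Out-of-plane orientation distributions
#'
#' Normalized histograms of pitch and roll over \[0, 90\] degrees.
#'
#' @param estimates List of `orientation_estimate` objects.
#' @param bin_width Bin width in degrees.
#' @return List with `breaks`, `pitch` and `roll` (probabilities per bin,
#'   each summing to 1).
#' @export
orientation_distribution <- function(estimates, bin_width = 5) {
  if (!length(estimates)) stop("no estimates given")
  breaks <- seq(0, 90, by = bin_width)
  pit <- vapply(estimates, `[[`, 0, "pitch")
  rol <- vapply(estimates, `[[`, 0, "roll")
  hp <- graphics::hist(pmin(pit, 90 - 1e-9), breaks = breaks, plot = FALSE)
  hr <- graphics::hist(pmin(rol, 90 - 1e-9), breaks = breaks, plot = FALSE)
  list(breaks = breaks,
       pitch = hp$counts / sum(hp$counts),
       roll = hr$counts / sum(hr$counts))
}

#' Accumulate a naive 3D density map
#'
#' Diagnostic only: back-rotates each particle's three Gaussians into a
#' common 3D frame using its estimated orientation and sums isotropic 3D
#' Gaussians on a voxel grid. No symmetry is imposed and no resolution
#' claim is made; the proper maximum-likelihood 3D reconstruction is out
#' of scope.
#'
#' @param particles List of `particle_projection` objects.
#' @param estimates Matching list of `orientation_estimate` objects.
#' @param voxel Voxel edge in nm.
#' @param half_size Half-extent of the cubic grid in nm.
#' @return 3D array (unit sum) with attribute `voxel_nm`.
#' @export
accumulate_density <- function(particles, estimates, voxel = 1,
                               half_size = 24) {
  if (!length(particles)) stop("no particles to accumulate")
  stopifnot(length(particles) == length(estimates))
  ax <- seq(-half_size, half_size, by = voxel)
  n <- length(ax)
  acc <- array(0, c(n, n, n))
  for (i in seq_along(particles)) {
    p <- particles[[i]]; e <- estimates[[i]]
    R <- rotation_matrix(e$yaw, e$pitch, e$roll)
    pos <- sweep(p$positions, 2, colMeans(p$positions))
    p3 <- cbind(pos, 0) %*% R  # R^T applied: back into the common frame
    for (k in 1:3) {
      s <- p$precisions[k]
      gx <- stats::dnorm(ax, p3[k, 1], s)
      gy <- stats::dnorm(ax, p3[k, 2], s)
      gz <- stats::dnorm(ax, p3[k, 3], s)
      acc <- acc + outer(outer(gx, gy), gz) / 3
    }
  }
  acc <- acc / sum(acc)
  attr(acc, "voxel_nm") <- voxel
  acc
}
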