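## Projected-triangle statistics: pairwise distances, the maximum-side
## statistic and its propagated error, and class discovery by 1D Gaussian
## mixture modelling of the max-side distribution.
##
## For a randomly oriented equilateral triangle of side d, the maximum
## projected side always lies in [sqrt(3)/2 * d, d]: taking the per-particle
## maximum side therefore sharpens class peaks against projection smearing.

#' Pairwise distances and the maximum-side statistic
#'
#' @param p A `particle_projection` (or a 3x2 position matrix).
#' @return A `triangle_geometry`: list with `d12`, `d13`, `d23`, `d_max`
#'   (all nm), `d_max_error` (propagated error of the maximal pair, nm, NA
#'   when precisions are unavailable) and `particle_id`.
#' @export
pairwise_distances <- function(p) {
  if (inherits(p, "particle_projection")) {
    pos <- p$positions; prec <- p$precisions; id <- p$particle_id
  } else {
    pos <- matrix(p, ncol = 2); prec <- NULL; id <- NA
  }
  d <- .tri_dists(pos)
  imax <- which.max(d)
  err <- NA_real_
  if (!is.null(prec)) {
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))[[imax]]
    err <- distance_error(prec[pairs[1]], prec[pairs[2]])
  }
  structure(list(d12 = d[1], d13 = d[2], d23 = d[3],
                 d_max = d[imax], d_max_error = err, particle_id = id),
            class = "triangle_geometry")
}

#' @export
print.triangle_geometry <- function(x, ...) {
  cat(sprintf("<triangle_geometry #%s> sides %.2f / %.2f / %.2f nm, d_max %.2f +/- %.2f nm\n",
              x$particle_id, x$d12, x$d13, x$d23, x$d_max, x$d_max_error))
  invisible(x)
}

#' Propagated error of a pairwise distance
#'
#' Quadrature sum of the two localization precisions:
#' `sqrt(p1^2 + p2^2)`. Accepts precisions or `localized_fluorophore`
#' objects.
#'
#' @param f1,f2 Precisions (nm) or `localized_fluorophore` objects.
#' @return Distance error in nm.
#' @export
#' @examples
#' distance_error(1, 1)  # sqrt(2)
distance_error <- function(f1, f2) {
  s1 <- if (inherits(f1, "localized_fluorophore")) f1$precision else f1
  s2 <- if (inherits(f2, "localized_fluorophore")) f2$precision else f2
  sqrt(s1^2 + s2^2)
}

#' Triangle geometry table for a particle set
#'
#' @param particles List of `particle_projection` objects.
#' @return Data.frame with one row per particle: `particle_id`, `d12`,
#'   `d13`, `d23`, `d_max`, `d_max_error`, `mean_precision`.
#' @export
triangle_table <- function(particles) {
  do.call(rbind, lapply(particles, function(p) {
    g <- pairwise_distances(p)
    data.frame(particle_id = g$particle_id, d12 = g$d12, d13 = g$d13,
               d23 = g$d23, d_max = g$d_max, d_max_error = g$d_max_error,
               mean_precision = p$mean_precision)
  }))
}

#' Filter particles by maximum-side distance error
#'
#' Keeps particles whose `d_max` error is below `cutoff` (default 2.2 nm).
#'
#' @param particles List of `particle_projection` objects.
#' @param cutoff Error cutoff in nm.
#' @return The filtered list.
#' @export
filter_distance_error <- function(particles, cutoff = 2.2) {
  keep <- vapply(particles, function(p) {
    pairwise_distances(p)$d_max_error < cutoff
  }, logical(1))
  particles[keep]
}

#' Check the projection bound of the max-side statistic
#'
#' For noise-free projections of an equilateral triangle of side `d`, the
#' maximum projected side must lie in `[sqrt(3)/2 * d, d]`. Returns the
#' orientations violating the bound beyond tolerance `eps` (none, for a
#' correct projection).
#'
#' @param side Triangle side length (nm).
#' @param orientations Matrix with columns yaw, pitch, roll (degrees), one
#'   row per orientation.
#' @param eps Numerical tolerance (nm).
#' @return Data.frame of violating rows (with the offending `d_max`);
#'   zero rows when the bound holds.
#' @export
max_side_bound_check <- function(side, orientations, eps = 1e-9) {
  orientations <- matrix(orientations, ncol = 3)
  v <- equilateral_vertices(side)
  lo <- sqrt(3) / 2 * side - eps
  hi <- side + eps
  dm <- apply(orientations, 1, function(o) {
    max(.tri_dists(project_vertices(v, o[1], o[2], o[3])))
  })
  bad <- dm < lo | dm > hi
  data.frame(yaw = orientations[bad, 1], pitch = orientations[bad, 2],
             roll = orientations[bad, 3], d_max = dm[bad])
}

#' Fit a Gaussian mixture to max-side values
#'
#' Fits 1D Gaussian mixtures (unequal variances) for each component count in
#' `k_range` to the raw `d_max` values -- never to binned counts; the
#' display bin size is carried only for plotting -- and selects the count by
#' the chosen information criterion (ties broken toward fewer components).
#'
#' @param d_max Numeric vector of maximum side lengths (nm), or a
#'   data.frame with a `d_max` column.
#' @param k_range Candidate component counts.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param bin_size_display Display-only histogram bin size in nm.
#' @return A `dmax_gmm`: list with `n_components`, `means`, `sds`, `weights`
#'   (components sorted by ascending mean), `criterion`, `scores` (per-k
#'   criterion values), `loglik`, `converged` and the input `d_max`.
#' @export
#' @examples
#' fit <- fit_gmm(c(rnorm(60, 19, 1.4)), k_range = 1:3)
#' fit$n_components
fit_gmm <- function(d_max, k_range = 1:5, criterion = c("BIC", "AIC"),
                    bin_size_display = 1.5) {
  criterion <- match.arg(criterion)
  if (is.data.frame(d_max)) d_max <- d_max$d_max
  d_max <- as.numeric(d_max)
  if (length(d_max) < 10) stop("fit_gmm needs at least 10 values")
  n <- length(d_max)
  fits <- lapply(k_range, function(k) {
    if (k == 1) {
      mu <- mean(d_max); s <- stats::sd(d_max)
      return(list(k = 1, loglik = sum(stats::dnorm(d_max, mu, s, log = TRUE)),
                  df = 2, means = mu, sds = s, weights = 1, ok = TRUE))
    }
    fit <- tryCatch(
      suppressWarnings(Mclust(d_max, G = k, modelNames = "V",
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$loglik)) return(list(k = k, ok = FALSE))
    list(k = k, loglik = fit$loglik, df = fit$df,
         means = as.numeric(fit$parameters$mean),
         sds = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
         weights = as.numeric(fit$parameters$pro), ok = TRUE)
  })
  ok <- vapply(fits, `[[`, logical(1), "ok")
  if (!any(ok)) stop("mixture fitting failed for every component count")
  fits <- fits[ok]
  score <- vapply(fits, function(f) {
    pen <- if (criterion == "AIC") 2 * f$df else f$df * log(n)
    -2 * f$loglik + pen
  }, 0)
  best <- fits[[which.min(score)]]
  ord <- order(best$means)
  if (length(best$sds) == 1) best$sds <- rep(best$sds, best$k)
  structure(list(
    n_components = best$k,
    means = best$means[ord],
    sds = best$sds[ord],
    weights = best$weights[ord],
    criterion = criterion,
    scores = stats::setNames(score, paste0("k", vapply(fits, `[[`, 0, "k"))),
    loglik = best$loglik,
    converged = all(ok),
    bin_size_display = bin_size_display,
    d_max = d_max
  ), class = "dmax_gmm")
}

#' @export
print.dmax_gmm <- function(x, ...) {
  cat(sprintf("<dmax_gmm> %d component(s) selected by %s from %d particles\n",
              x$n_components, x$criterion, length(x$d_max)))
  tab <- cbind(mean_nm = x$means, sd_nm = x$sds, weight = x$weights)
  print(round(tab, 3))
  invisible(x)
}

#' @export
summary.dmax_gmm <- function(object, ...) {
  print(object)
  cat("criterion scores:\n")
  print(round(object$scores, 2))
  invisible(object)
}

#' @export
plot.dmax_gmm <- function(x, ...) {
  h <- graphics::hist(x$d_max,
                      breaks = seq(min(x$d_max) - x$bin_size_display,
                                   max(x$d_max) + x$bin_size_display,
                                   by = x$bin_size_display),
                      freq = FALSE, xlab = "max side length (nm)",
                      main = "max-side distribution with GMM fit", ...)
  xs <- seq(min(x$d_max), max(x$d_max), length.out = 400)
  dens <- rowSums(vapply(seq_len(x$n_components), function(k)
    x$weights[k] * stats::dnorm(xs, x$means[k], x$sds[k]), xs))
  graphics::lines(xs, dens, col = "red", lwd = 2)
  invisible(h)
}
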