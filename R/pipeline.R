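## End-to-end convenience driver over the module functions.

#' Run the projection-analysis pipeline on an event table
#'
#' Localizes particles, applies the precision and distance-error filters,
#' computes triangle statistics, discovers classes with a Gaussian mixture
#' on the max-side statistic and classifies particles against the
#' equilateral templates.
#'
#' @param events Combined fluorophore event table (see
#'   [simulate_experiment()] or [read_events()]).
#' @param by How to group events into fluorophores (see
#'   [localize_particles()]).
#' @param precision_cutoff Mean-precision filter in nm.
#' @param error_cutoff Max-side distance-error filter in nm.
#' @param template_sides Template side lengths in nm.
#' @param criterion Model-selection criterion for the mixture fit.
#' @param cutoff Unclassified cutoff on `d_max` in nm.
#' @return List with `particles` (filtered projections), `geometry`
#'   (triangle table), `gmm` (`dmax_gmm` fit), `assignments`
#'   (classification table) and `fractions` (class fractions).
#' @export
#' @examples
#' sim <- simulate_experiment(40, seed = 1)
#' res <- analyze_projections(sim$events, by = "fluorophore")
#' res$gmm
analyze_projections <- function(events, by = c("fluorophore", "decompose"),
                                precision_cutoff = 2, error_cutoff = 2.2,
                                template_sides = c(9, 19, 34),
                                criterion = "BIC", cutoff = 43) {
  by <- match.arg(by)
  particles <- localize_particles(events, by = by)
  particles <- filter_by_precision(particles, precision_cutoff)
  particles <- filter_distance_error(particles, error_cutoff)
  if (!length(particles)) stop("no particles survive the filters")
  geometry <- triangle_table(particles)
  gmm <- fit_gmm(geometry$d_max, criterion = criterion)
  templates <- default_templates(width = stats::median(geometry$mean_precision),
                                 sides = template_sides)
  assignments <- classify_particles(particles, templates, cutoff = cutoff)
  list(particles = particles, geometry = geometry, gmm = gmm,
       assignments = assignments, fractions = class_fractions(assignments))
}
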