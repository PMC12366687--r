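# Fixture builders shared across the suite. Everything is generated in code;
# no stored data.

# A particle projection with known vertex positions: equilateral triangle of
# `side`, optionally rotated in-plane by `rot` degrees or tilted via full
# Euler angles, plus iid Gaussian vertex noise.
make_projection <- function(side, rot = 0, yaw = NULL, pitch = 0, roll = 0,
                            noise = 0, precision = 1.4, n_loc = 51,
                            id = 1) {
  if (is.null(yaw)) {
    pos <- equilateral_vertices(side)[, 1:2]
    th <- rot * pi / 180
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    pos <- pos %*% t(Rm)
  } else {
    pos <- project_vertices(equilateral_vertices(side), yaw, pitch, roll)
  }
  if (noise > 0) pos <- pos + stats::rnorm(6, 0, noise)
  particle_projection(lapply(1:3, function(k) structure(list(
    x = pos[k, 1], y = pos[k, 2], sigma_x = precision * sqrt(n_loc),
    sigma_y = precision * sqrt(n_loc), n_loc = n_loc,
    precision = precision), class = "localized_fluorophore")),
    particle_id = id)
}

# Best label-matching accuracy of a 3-state assignment against truth.
match_accuracy <- function(assignment, truth) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  truth <- as.integer(factor(truth))
  max(vapply(perms, function(pm) mean(pm[assignment] == truth), 0))
}

# Minimum pairwise separation of dipole azimuths in the polarization
# observable: a two-channel splitter measures cos^2(az), so the effective
# coordinate is the fold |90 - (az mod 180)|.
folded_azimuth_sep <- function(az) {
  zf <- abs(90 - (az %% 180))
  min(dist(zf))
}

# Sample one particle whose dipoles are polarization-distinguishable.
sample_separable_particle <- function(class_weights, min_sep = 15) {
  repeat {
    p <- sample_population(1, class_weights = class_weights)[[1]]
    if (folded_azimuth_sep(p$dipole_azimuths) >= min_sep) return(p)
  }
}

# Simulate one particle end to end and localize it from ground-truth
# fluorophore indices.
simulate_and_localize <- function(p, n_frames = trimer_defaults()$n_frames) {
  ev <- emit_events(p, simulate_blinking(p, n_frames = n_frames))
  localize_particles(ev, by = "fluorophore")[[1]]
}
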