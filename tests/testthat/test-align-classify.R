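test_that("rotational alignment recovers known in-plane rotations", {
  tem <- triangle_template(19)
  # self-alignment: angle 0 (mod 120), perfect correlation
  a0 <- align_rotation(make_projection(19), tem)
  expect_lt(min(a0$angle %% 120, 120 - a0$angle %% 120), 1)
  expect_equal(a0$correlation, 1, tolerance = 1e-6)
  # a particle rotated by 40 degrees aligns back with the inverse rotation
  a40 <- align_rotation(make_projection(19, rot = 40), tem)
  expect_lt(min(abs(((a40$angle + 40) %% 120) - c(0, 120))), 1.1)
  expect_equal(a40$correlation, 1, tolerance = 1e-6)
})

test_that("map correlation behaves like Pearson correlation", {
  p <- make_projection(19)
  m <- render_particle(p, grid_size = 64, pixel_nm = 1)
  expect_equal(map_correlation(m, m), 1)
  # uncorrelated noise maps: correlation indistinguishable from 0
  set.seed(61)
  cors <- replicate(30, map_correlation(matrix(runif(4096), 64),
                                        matrix(runif(4096), 64)))
  expect_lt(abs(mean(cors)), 3 / sqrt(30 * 4096))
  expect_error(map_correlation(m, matrix(0, 64, 64)), "constant")
  expect_error(map_correlation(m, matrix(1, 10, 10)), "grid")
})

test_that("template classification labels particles by side length", {
  # clean in-plane particles go to their own class with score ~ 1
  for (side in c(9, 19, 34)) {
    a <- classify_template(make_projection(side, rot = 25))
    expect_equal(a$class_label, c("i", "ii", "iii")[which(c(9, 19, 34) == side)])
    expect_gt(a$score, 0.98)
  }
  # beyond the protein dimension: unclassified
  a50 <- classify_template(make_projection(50))
  expect_equal(a50$class_label, "unclassified")
  expect_gt(a50$d_max, 43)
  # optional score floor
  noisy <- make_projection(14, noise = 3)
  afloor <- classify_template(noisy, score_floor = 0.999)
  expect_equal(afloor$class_label, "unclassified")
})

test_that("classification is invariant to rotation and translation", {
  set.seed(62)
  p0 <- make_projection(19, noise = 1.4)
  a0 <- classify_template(p0)
  th <- 77 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pos <- p0$positions %*% t(Rm) + matrix(c(40, -25), 3, 2, byrow = TRUE)
  p1 <- particle_projection(lapply(1:3, function(k) {
    f <- p0$fluorophores[[k]]; f$x <- pos[k, 1]; f$y <- pos[k, 2]; f
  }), particle_id = 1)
  a1 <- classify_template(p1)
  expect_equal(a1$class_label, a0$class_label)
  expect_equal(a1$score, a0$score, tolerance = 1e-5)
})

test_that("population classification recovers classes and fractions", {
  sim <- simulate_experiment(150, seed = 63)
  parts <- localize_particles(sim$events, by = "fluorophore")
  asg <- classify_particles(parts)
  truth <- vapply(sim$particles, `[[`, "", "class_label")[asg$particle_id]
  expect_gte(mean(asg$class_label == truth), 0.8)
  fr <- class_fractions(asg)
  expect_equal(sum(fr$fractions), 1)
  true_fr <- as.numeric(table(factor(truth, c("i", "ii", "iii"))) / length(truth))
  expect_true(all(abs(fr$fractions - true_fr) < 0.10))
  # degenerate and empty inputs
  expect_equal(class_fractions(c("i", "i"))$fractions, c(1, 0, 0))
  expect_error(class_fractions(character(0)), "no assignments")
  expect_error(class_fractions("unclassified"), "no classified")
})

test_that("aligned class averages show the class geometry with C3 symmetry", {
  set.seed(64)
  tem <- triangle_template(19)
  parts <- lapply(1:120, function(i)
    make_projection(19, rot = runif(1, 0, 360), noise = 1.4, id = i))
  asg <- data.frame(angle = vapply(parts, function(p)
    align_rotation(p, tem)$angle, 0))
  comp <- sum_aligned(parts, assignments = asg, grid_size = 96,
                      pixel_nm = 0.75)
  raw <- attr(comp, "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  # three intensity maxima at the class side length +/- the distance error
  idx <- which(comp > 0.5 * max(comp), arr.ind = TRUE)
  km <- stats::kmeans(idx, 3, nstart = 10)
  d <- as.numeric(dist((km$centers - (96 + 1) / 2) * 0.75))
  expect_true(all(abs(d - 19) < 2.3))
  # composite C3 symmetry: rotating every aligned particle by an extra 120
  # degrees rotates the composite exactly (no image resampling needed)
  comp120 <- sum_aligned(parts, assignments = data.frame(angle = asg$angle + 120),
                         grid_size = 96, pixel_nm = 0.75)
  expect_gte(map_correlation(raw, attr(comp120, "raw")), 0.9)
  # a single particle's composite is its own rotated map
  single <- sum_aligned(parts[1], template = tem, grid_size = 96,
                        pixel_nm = 0.75)
  expect_equal(sum(attr(single, "raw")), 1, tolerance = 1e-9)
  expect_error(sum_aligned(list(), template = tem), "empty")
})
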