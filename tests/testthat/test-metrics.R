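# Placement metrics: MLD, deviations, perforation detection, report assembly.

axis_frame <- function() {
  build_frame(landmark_set(c(-120, 0, 0), c(120, 0, 0), c(0, 0, -90)))
}

test_that("MLD trivial cases localise to the right endpoint", {
  planned <- trajectory(c(0, 0, 0), c(0, 0, 100), depth = 100)
  expect_equal(mld(planned, planned)$mld, 0)
  drilled <- trajectory(c(0, 0, 0), c(10, 0, 100), depth = sqrt(10100))
  m <- mld(planned, drilled)
  expect_equal(m$mld, 10, tolerance = 1e-9)
  expect_equal(m$location, "tip")
  drilled_base <- trajectory(c(8, 0, 0), c(0, 0, 100),
                             depth = sqrt(64 + 10000))
  m2 <- mld(planned, drilled_base)
  expect_equal(m2$mld, 8, tolerance = 1e-9)
  expect_equal(m2$location, "base")
})

test_that("endpoint MLD equals the dense-sampling maximum on random pairs", {
  set.seed(31)
  for (i in 1:50) {
    planned <- rand_trajectory(); drilled <- rand_trajectory()
    m <- mld(planned, drilled)
    o <- mld_dense(planned, drilled, n = 1e5)
    expect_equal(m$mld, o$mld, tolerance = 1e-3)
    expect_equal(m$location, o$location)
  }
})

test_that("entry deviation is the 3-4-5 distance and rigid-motion invariant", {
  a <- trajectory(c(0, 0, 0), c(0, 0, 100))
  b <- trajectory(c(3, 4, 0), c(0, 0, 100))
  expect_equal(entry_deviation(a, a), 0)
  expect_equal(entry_deviation(a, b), 5)
  set.seed(13)
  Q <- similarity_transform(rand_rotation(), rand_point(), 1)
  expect_equal(entry_deviation(transform_trajectory(Q, a),
                               transform_trajectory(Q, b)), 5,
               tolerance = 1e-9)
})

test_that("central-aim deviation is measured to the drilled tip (depth-aware)", {
  planned <- trajectory(c(0, 0, 0), c(0, 0, 90), depth = 90)
  expect_equal(central_aim_deviation(planned, planned), 0)
  short <- trajectory(c(0, 0, 0), c(0, 0, 90), depth = 80)
  expect_equal(central_aim_deviation(planned, short), 10)
  set.seed(37)
  for (i in 1:20) {
    p <- rand_trajectory(); d <- rand_trajectory()
    tip <- d$entry + d$depth * (d$central_aim - d$entry) /
      sqrt(sum((d$central_aim - d$entry)^2))
    expect_equal(central_aim_deviation(p, d),
                 sqrt(sum((tip - p$central_aim)^2)), tolerance = 1e-9)
  }
})

test_that("angular deviation covers parallel, 5-degree and antiparallel cases", {
  base <- trajectory(c(0, 0, 0), c(0, 0, 100))
  expect_equal(angular_deviation(base, base), 0)
  tilted <- trajectory(c(0, 0, 0), c(sin(5 * pi / 180) * 100, 0,
                                     cos(5 * pi / 180) * 100))
  expect_equal(angular_deviation(base, tilted), 5, tolerance = 1e-9)
  reversed <- trajectory(c(0, 0, 100), c(0, 0, 0))
  expect_equal(angular_deviation(base, reversed), 180)
})

test_that("perforation arithmetic matches the stated capsule rule", {
  frame <- axis_frame()
  co <- list(label = "S1_right", axis_entry = c(95, -80, -40),
             axis_end = c(-15, -80, -40), radius = 7.5,
             forbidden_regions = c(anterior = "small pelvis",
                                   superior = "neuroforamina",
                                   inferior = "neuroforamina",
                                   posterior = "spinal canal"))
  # coaxial screw: 3.75 + 0 < 7.5 -> safe
  drilled <- trajectory(c(95, -80, -40), c(0, -80, -40), diameter = 7.5)
  f <- detect_perforation(drilled, co, frame)
  expect_false(f$perforated)
  expect_length(f$directions, 0)
  expect_equal(f$breach_depth, 0)
  # parallel, offset 4 mm anterior (+y): 4 + 3.75 - 7.5 = 0.25 mm breach
  drilled2 <- trajectory(c(95, -76, -40), c(0, -76, -40), diameter = 7.5)
  f2 <- detect_perforation(drilled2, co, frame)
  expect_true(f2$perforated)
  expect_equal(f2$directions, "anterior")
  expect_equal(f2$breach_depth, 0.25, tolerance = 1e-9)
  expect_equal(f2$regions, "small pelvis")
})

test_that("combined direction labels follow the 8-sector compass rule", {
  frame <- axis_frame()
  co <- list(label = "S2_right", axis_entry = c(90, -85, -70),
             axis_end = c(-10, -85, -70), radius = 5.5,
             forbidden_regions = c(anterior = "small pelvis",
                                   superior = "neuroforamina",
                                   inferior = "neuroforamina",
                                   posterior = "spinal canal"))
  mk <- function(dy, dz) {
    trajectory(c(90, -85 + dy, -70 + dz), c(0, -85 + dy, -70 + dz),
               diameter = 7.5)
  }
  f_diag <- detect_perforation(mk(4, 4), co, frame)
  expect_setequal(f_diag$directions, c("anterior", "superior"))
  f_pure <- detect_perforation(mk(6, 0.5), co, frame)
  expect_equal(f_pure$directions, "anterior")
  f_inf <- detect_perforation(mk(0.5, -6), co, frame)
  expect_equal(f_inf$directions, "inferior")
  f_post <- detect_perforation(mk(-6, 0), co, frame)
  expect_equal(f_post$directions, "posterior")
  expect_equal(f_post$regions, "spinal canal")
})

test_that("analytic perforation verdicts agree with capsule-surface sampling", {
  set.seed(41)
  n_cases <- 200
  agree <- 0
  for (i in seq_len(n_cases)) {
    repeat {
      a <- rand_point(40); b <- rand_point(40)
      if (sqrt(sum((b - a)^2)) > 20) break
    }
    co <- list(label = "test", axis_entry = a, axis_end = b,
               radius = runif(1, 4, 10),
               forbidden_regions = c(anterior = "small pelvis",
                                     superior = "neuroforamina",
                                     inferior = "neuroforamina",
                                     posterior = "spinal canal"))
    drilled <- trajectory(co$axis_entry + rnorm(3, sd = 3),
                          co$axis_end + rnorm(3, sd = 3),
                          diameter = runif(1, 4, 9))
    verdict <- detect_perforation(drilled, co, axis_frame())$perforated
    oracle <- perforation_sampled(drilled, co, n = 5e3)
    if (verdict == oracle$perforated ||
        abs(oracle$max_excess) < 1e-2) agree <- agree + 1
  }
  expect_gte(agree, n_cases - 2)
})

test_that("perforation verdict is monotone in screw radius and offset", {
  frame <- axis_frame()
  co <- list(label = "S1_right", axis_entry = c(95, -80, -40),
             axis_end = c(-15, -80, -40), radius = 7.5,
             forbidden_regions = c(anterior = "small pelvis",
                                   superior = "neuroforamina",
                                   inferior = "neuroforamina",
                                   posterior = "spinal canal"))
  set.seed(43)
  for (i in 1:50) {
    off <- runif(1, 0, 6)
    dia <- runif(1, 3, 9)
    mk <- function(off, dia) {
      trajectory(c(95, -80 + off, -40), c(0, -80 + off, -40), diameter = dia)
    }
    base_perf <- detect_perforation(mk(off, dia), co, frame)$perforated
    wider <- detect_perforation(mk(off, dia + 1), co, frame)$perforated
    further <- detect_perforation(mk(off + 1, dia), co, frame)$perforated
    if (base_perf) {
      expect_true(wider)
      expect_true(further)
    }
  }
})

test_that("mesh-based containment agrees with the analytic capsule verdict", {
  ph <- make_phantom(mesh = TRUE)
  frame <- ph$frame
  co <- ph$corridors$S1_right
  safe <- ph$planned$S1_right
  expect_false(detect_perforation(safe, co, frame)$perforated)
  set.seed(47)
  # a single-corridor mesh so the union of capsules does not mask breaches
  mesh1 <- pelvnav:::capsule_mesh(co$axis_entry, co$axis_end, co$radius, 48, 12)
  offs <- c(0, 1, 2, 3, 5, 6)
  for (off in offs) {
    drilled <- trajectory(co$axis_entry + c(0, off, 0),
                          co$axis_end + c(0, off, 0), diameter = 7.5)
    analytic <- detect_perforation(drilled, co, frame)$perforated
    meshres <- detect_perforation_mesh(drilled, mesh1, frame, density = 2)
    if (abs(off + 3.75 - co$radius) > 0.5) {  # away from the decision boundary
      expect_equal(meshres$perforated, analytic)
    }
  }
})

test_that("placement reports assemble all metrics with the correct verdict", {
  ph <- make_phantom()
  frame <- ph$frame
  planned <- ph$planned$S1_right
  co <- ph$corridors$S1_right
  rep0 <- evaluate_placement(planned, planned, co, frame)
  expect_true(rep0$correct)
  expect_equal(rep0$mld_mm, 0)
  expect_equal(rep0$entry_dev_mm, 0)
  expect_equal(rep0$angular_dev_deg, 0)
  expect_equal(rep0$directions, "")
  drilled <- trajectory(planned$entry + c(0, 4, 0),
                        planned$central_aim + c(0, 4, 0),
                        diameter = planned$diameter)
  rep1 <- evaluate_placement(planned, drilled, co, frame)
  expect_false(rep1$correct)
  expect_true(rep1$perforated)
  expect_match(rep1$directions, "anterior")
  expect_equal(rep1$entry_dev_mm, 4, tolerance = 1e-9)
})

test_that("all metrics are invariant under a common rigid motion", {
  ph <- make_phantom()
  set.seed(53)
  planned <- ph$planned$S2_right
  co <- ph$corridors$S2_right
  drilled <- trajectory(planned$entry + c(1, 3, -2),
                        planned$central_aim + c(-2, 4, 1),
                        diameter = planned$diameter, depth = planned$depth)
  r0 <- evaluate_placement(planned, drilled, co, ph$frame)
  for (i in 1:5) {
    Q <- similarity_transform(rand_rotation(), rand_point(), 1)
    r1 <- evaluate_placement(
      transform_trajectory(Q, planned), transform_trajectory(Q, drilled),
      transform_corridor(Q, co), build_frame(transform_landmarks(Q, ph$landmarks))
    )
    expect_equal(r1$mld_mm, r0$mld_mm, tolerance = 1e-9)
    expect_equal(r1$entry_dev_mm, r0$entry_dev_mm, tolerance = 1e-9)
    expect_equal(r1$central_aim_dev_mm, r0$central_aim_dev_mm, tolerance = 1e-9)
    expect_equal(r1$angular_dev_deg, r0$angular_dev_deg, tolerance = 1e-7)
    expect_equal(r1$perforated, r0$perforated)
    expect_equal(r1$directions, r0$directions)
  }
})

test_that("pure orthogonal translation error: MLD equals entry deviation, no tilt", {
  planned <- trajectory(c(0, 0, 0), c(0, 0, 100), depth = 100)
  drilled <- trajectory(c(0, 6, 0), c(0, 6, 100), depth = 100)
  m <- mld(planned, drilled)
  expect_equal(m$mld, entry_deviation(planned, drilled), tolerance = 1e-9)
  expect_equal(angular_deviation(planned, drilled), 0, tolerance = 1e-9)
})
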