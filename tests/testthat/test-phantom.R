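# Parametric phantom, landmark probing and drilling simulation.

test_that("phantom generation is deterministic and satisfies its invariants", {
  p1 <- make_phantom(phantom_params(anatomy_jitter_sigma = 1), seed = 42)
  p2 <- make_phantom(phantom_params(anatomy_jitter_sigma = 1), seed = 42)
  expect_identical(p1, p2)
  ph <- make_phantom()
  expect_setequal(names(ph$corridors),
                  c("S1_right", "S1_left", "S2_right", "S2_left"))
  expect_gt(ph$corridors$S1_left$radius, ph$corridors$S2_left$radius)
  expect_equal(ph$corridors$S1_left$radius, 7.5)
  expect_equal(ph$corridors$S2_left$radius, 5.5)
  expect_equal(ph$planned$S1_right$diameter, 7.5)
  for (label in names(ph$planned)) {
    tr <- ph$planned[[label]]
    co <- ph$corridors[[label]]
    dir <- (co$axis_end - co$axis_entry)
    dir <- dir / sqrt(sum(dir^2))
    expect_lt(point_line_distance(tr$entry, co$axis_entry, dir), 1e-9)
    expect_lt(point_line_distance(tr$central_aim, co$axis_entry, dir), 1e-9)
  }
})

test_that("out-of-range phantom parameters are rejected", {
  expect_error(phantom_params(s1_radius = 5, s2_radius = 5.5), "wider")
  expect_error(phantom_params(asis_span = 1000), "plausible")
  expect_error(phantom_params(screw_diameter = -1), "positive")
  expect_error(noise_model(landmark_sigma = -1), ">= 0")
})

test_that("noise-free probing reproduces the transformed landmarks exactly", {
  ph <- make_phantom()
  tf <- rand_similarity(c(1, 1))
  probed <- probe_landmarks(ph, tf, zero_noise())
  truth <- transform_landmarks(tf, ph$landmarks)
  expect_equal(probed$left_asis, truth$left_asis, tolerance = 1e-12)
  expect_equal(probed$symphysis, truth$symphysis, tolerance = 1e-12)
})

test_that("probing noise has the configured spread", {
  ph <- make_phantom()
  set.seed(101)
  n <- 3000  # 9000 coordinate draws per landmark set component
  devs <- matrix(NA_real_, n, 3)
  truth <- ph$landmarks$left_asis
  for (i in seq_len(n)) {
    probed <- probe_landmarks(ph, similarity_transform(),
                              noise_model(1, 0, 0, 0))
    devs[i, ] <- probed$left_asis - truth
  }
  sds <- apply(devs, 2, sd)
  expect_true(all(abs(sds - 1) < 0.05))
})

test_that("the symphysis bias displaces only the symphysis, along anterior", {
  ph <- make_phantom()
  probed <- probe_landmarks(ph, similarity_transform(),
                            noise_model(0, 5, 0, 0))
  expect_equal(probed$left_asis, ph$landmarks$left_asis)
  expect_equal(probed$right_asis, ph$landmarks$right_asis)
  shift <- probed$symphysis - ph$landmarks$symphysis
  expect_equal(sqrt(sum(shift^2)), 5, tolerance = 1e-9)
  expect_equal(sum(shift * ph$frame$anterior), 5, tolerance = 1e-9)
})

test_that("drilling with identity error and no noise reproduces the plan", {
  ph <- make_phantom()
  planned <- ph$planned$S1_right
  drilled <- simulate_drilling(planned)
  expect_equal(drilled$entry, planned$entry, tolerance = 1e-12)
  expect_equal(trajectory_tip(drilled), trajectory_tip(planned),
               tolerance = 1e-9)
})

test_that("a pure translation guidance error shifts the entry without tilting", {
  ph <- make_phantom()
  planned <- ph$planned$S2_left
  err <- similarity_transform(diag(3), c(2, 0, 0), 1)
  drilled <- simulate_drilling(planned, err, zero_noise())
  expect_equal(entry_deviation(planned, drilled), 2, tolerance = 1e-9)
  expect_equal(angular_deviation(planned, drilled), 0, tolerance = 1e-9)
})

test_that("a pure rotation guidance error tilts the axis by the expected angle", {
  ph <- make_phantom()
  planned <- ph$planned$S1_left
  lat <- ph$frame$lateral_right
  theta <- 4 * pi / 180
  K <- matrix(c(0, lat[3], -lat[2], -lat[3], 0, lat[1],
                lat[2], -lat[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  err <- similarity_transform(R)
  drilled <- simulate_drilling(planned, err, zero_noise())
  # direct vector oracle: angle between planned direction and its image
  dir0 <- trajectory_direction(planned)
  dir1 <- as.numeric(R %*% dir0)
  expected <- acos(min(max(sum(dir0 * dir1), -1), 1)) * 180 / pi
  expect_equal(angular_deviation(planned, drilled), expected, tolerance = 1e-9)
})

test_that("the phantom capsule mesh is closed and contains the corridor axes", {
  ph <- make_phantom(mesh = TRUE)
  mesh <- ph$mesh
  expect_s3_class(mesh, "pelvnav_mesh")
  # watertightness: every edge shared by exactly two triangles
  edges <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(keys) == 2))
  co <- ph$corridors$S1_right
  mid <- (co$axis_entry + co$axis_end) / 2
  inside <- point_in_mesh(mesh, rbind(mid, co$axis_entry + c(0, 0, 500)))
  expect_true(inside[1])
  expect_false(inside[2])
})
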