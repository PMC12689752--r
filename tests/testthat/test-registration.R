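# Paired-point similarity registration and registration-quality metrics.

test_that("identical landmark sets give the identity with zero residual", {
  lm <- rand_landmarks()
  fit <- fit_similarity(lm, lm)
  expect_equal(fit$transform$scale, 1, tolerance = 1e-12)
  expect_lt(max(abs(fit$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(fit$transform$translation)), 1e-9)
  expect_lt(fit$fre_rms, 1e-9)
  expect_false(fit$scale_warning)
})

test_that("an exact similarity correspondence is recovered exactly", {
  set.seed(5)
  lm <- rand_landmarks()
  truth <- similarity_transform(diag(3), c(10, -5, 3), 1.1)
  fit <- fit_similarity(lm, transform_landmarks(truth, lm))
  expect_equal(fit$transform$scale, 1.1, tolerance = 1e-9)
  expect_lt(fit$fre_rms, 1e-9)
})

test_that("noisy fits match a numerical least-squares oracle", {
  set.seed(17)
  rotvec_to_R <- function(rv) {
    th <- sqrt(sum(rv^2))
    if (th < 1e-12) return(diag(3))
    ax <- rv / th
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  # objective over the 3 rotation parameters only: for a fixed rotation the
  # optimal scale and translation are linear least squares and are profiled
  # out analytically
  obj_fun <- function(rv, Xc, Yc) {
    R <- rotvec_to_R(rv)
    num <- sum(Yc * (Xc %*% t(R)))
    s <- num / sum(Xc^2)
    sum((Xc %*% t(R) * s - Yc)^2)
  }
  for (i in 1:10) {
    lm <- rand_landmarks()
    truth <- rand_similarity()
    probed_clean <- transform_landmarks(truth, lm)
    probed <- landmark_set(
      probed_clean$left_asis + rnorm(3, sd = 2),
      probed_clean$right_asis + rnorm(3, sd = 2),
      probed_clean$symphysis + rnorm(3, sd = 2)
    )
    fit <- fit_similarity(lm, probed)
    X <- rbind(lm$left_asis, lm$right_asis, lm$symphysis)
    Y <- rbind(probed$left_asis, probed$right_asis, probed$symphysis)
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
    closed_form <- 3 * fit$fre_rms^2
    best <- Inf
    for (k in 1:30) {
      rv <- rnorm(3)
      rv <- rv / sqrt(sum(rv^2)) * runif(1, 0, pi)
      num <- optim(rv, obj_fun, Xc = Xc, Yc = Yc, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-14))
      best <- min(best, num$value)
    }
    # the closed form must be at least as good as the numerical optimum
    expect_lte(closed_form, best + 1e-6)
    expect_equal(closed_form, best, tolerance = 1e-4)
  }
})

test_that("a mirrored probe never yields a reflection", {
  set.seed(23)
  for (i in 1:20) {
    lm <- rand_landmarks()
    mirrored <- landmark_set(
      lm$left_asis * c(1, 1, -1),
      lm$right_asis * c(1, 1, -1),
      lm$symphysis * c(1, 1, -1)
    )
    fit <- fit_similarity(lm, mirrored)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  }
})

test_that("TRE is zero for identical transforms and matches closed forms", {
  tfa <- rand_similarity()
  targets <- matrix(runif(30, -100, 100), 10, 3)
  expect_equal(target_registration_error(tfa, tfa, targets), rep(0, 10))
  # pure 1 mm translation offset
  shifted <- compose_transform(
    similarity_transform(diag(3), c(1, 0, 0), 1), tfa)
  expect_equal(target_registration_error(shifted, tfa, targets), rep(1, 10),
               tolerance = 1e-9)
})

test_that("TRE of a rotation about the inter-ASIS axis grows as 2 sin(theta/2) r", {
  # 5 degree rotation about the x axis composed onto the truth
  truth <- similarity_transform()
  axis <- c(1, 0, 0)
  theta <- 5 * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  est <- compose_transform(similarity_transform(R), truth)
  set.seed(9)
  targets <- matrix(runif(60, -150, 150), 20, 3)
  r_axis <- sqrt(targets[, 2]^2 + targets[, 3]^2)  # distance from the x axis
  expected <- 2 * sin(theta / 2) * r_axis
  expect_equal(target_registration_error(est, truth, targets), expected,
               tolerance = 1e-6)
})

test_that("tidy/glance expose residuals and fit summary", {
  lm <- rand_landmarks()
  fit <- fit_similarity(lm, lm)
  td <- tidy(fit)
  expect_equal(td$landmark, c("left_asis", "right_asis", "symphysis"))
  expect_true(all(td$residual_mm < 1e-9))
  gl <- glance(fit)
  expect_equal(gl$scale, 1, tolerance = 1e-9)
  expect_false(gl$scale_warning)
})
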