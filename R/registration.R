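# Paired-point registration: closed-form absolute orientation with optional
# isotropic scale (Umeyama's SVD solution), plus registration-quality
# metrics (FRE at the fiducials, TRE at arbitrary targets).

#' Fit the least-squares similarity transform between two landmark sets
#'
#' Estimates the transform that "resizes and aligns" the planned model onto
#' the probed patient landmarks: the similarity (or rigid, with
#' `allow_scale = FALSE`) transform `T` minimising
#' `sum_i || T(model_i) - probed_i ||^2` over the three labelled fiducials.
#' The solution is the closed-form absolute-orientation optimum: SVD of the
#' cross-covariance of the centred landmark matrices, with the standard
#' determinant correction so the returned rotation is always proper (a
#' mirrored probe yields large residuals, never a reflection).
#'
#' With only three (planar) fiducials the cross-covariance is rank 2; the
#' determinant correction acts on the null singular vector, so exact
#' similarity correspondences are still recovered exactly.
#'
#' @param model,probed [landmark_set()] objects; correspondence is by label.
#' @param allow_scale Estimate isotropic scale (default `TRUE`, matching a
#'   workflow that resizes the model)? If `FALSE` a rigid fit is returned.
#' @param scale_band Length-2 plausibility band for the fitted scale; a fit
#'   outside it sets `scale_warning` (patient and model pelves should be
#'   within a factor ~2 in size).
#' @return Object of class `registration_fit` with fields `transform`
#'   ([similarity_transform()]), `fre_rms` (root-mean-square fiducial
#'   residual, mm), `per_landmark_residuals` (named numeric, mm) and
#'   `scale_warning` (logical).
#' @export
fit_similarity <- function(model, probed, allow_scale = TRUE,
                           scale_band = c(0.5, 2.0)) {
  stopifnot(inherits(model, "landmark_set"), inherits(probed, "landmark_set"))
  X <- landmark_matrix(model)   # n x 3, n = 3
  Y <- landmark_matrix(probed)
  n <- nrow(X)
  mu_x <- colMeans(X); mu_y <- colMeans(Y)
  Xc <- sweep(X, 2, mu_x); Yc <- sweep(Y, 2, mu_y)
  sigma_x2 <- sum(Xc^2) / n
  # cross-covariance (3x3): (1/n) sum_i y_i x_i^T
  S <- crossprod(Yc, Xc) / n
  sv <- svd(S)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  scale <- if (allow_scale) sum(sv$d * diag(D)) / sigma_x2 else 1
  if (!is.finite(scale) || scale <= 0) {
    stop("degenerate registration: non-positive fitted scale", call. = FALSE)
  }
  t_vec <- mu_y - scale * as.numeric(R %*% mu_x)
  transform <- similarity_transform(R, t_vec, scale)
  fitted <- transform_point(transform, X)
  res <- sqrt(rowSums((fitted - Y)^2))
  names(res) <- rownames(X)
  structure(
    list(
      transform = transform,
      fre_rms = sqrt(mean(res^2)),
      per_landmark_residuals = res,
      scale_warning = allow_scale &&
        (scale < scale_band[1] || scale > scale_band[2]),
      allow_scale = allow_scale
    ),
    class = "registration_fit"
  )
}

#' @export
print.registration_fit <- function(x, ...) {
  cat(sprintf("<registration_fit> %s\n",
              if (x$allow_scale) "similarity (scale fitted)" else "rigid"))
  print(x$transform)
  cat(sprintf("  FRE (rms): %.4g mm%s\n", x$fre_rms,
              if (x$scale_warning) "  [scale outside plausibility band]" else ""))
  invisible(x)
}

#' @rdname fit_similarity
#' @param x A `registration_fit`.
#' @param ... Unused.
#' @export
tidy.registration_fit <- function(x, ...) {
  tibble::tibble(
    landmark = names(x$per_landmark_residuals),
    residual_mm = as.numeric(x$per_landmark_residuals)
  )
}

#' @rdname fit_similarity
#' @export
glance.registration_fit <- function(x, ...) {
  tibble::tibble(
    fre_rms_mm = x$fre_rms,
    scale = x$transform$scale,
    rotation_deg = rotation_angle_deg(x$transform$rotation),
    translation_mm = vnorm(x$transform$translation),
    scale_warning = x$scale_warning
  )
}

#' Target registration error at points of surgical interest
#'
#' The fiducial residual (FRE) measures misfit at the probed landmarks; what
#' matters clinically is the displacement the registration error induces at
#' the screw corridors. For each target point `p` this returns
#' `|| est(p) - truth(p) ||` in mm, preserving input order.
#'
#' @param est,truth [similarity_transform()] objects (estimated and
#'   ground-truth model-to-world maps).
#' @param targets An n x 3 matrix, or a list of length-3 points.
#' @return Numeric vector of per-target errors (mm).
#' @export
target_registration_error <- function(est, truth, targets) {
  if (is.list(targets)) targets <- do.call(rbind, lapply(targets, as_point3))
  if (!is.matrix(targets) || ncol(targets) != 3 || nrow(targets) < 1) {
    stop("targets must be a non-empty n x 3 matrix or list of points",
         call. = FALSE)
  }
  sqrt(rowSums((transform_point(est, targets) -
                  transform_point(truth, targets))^2))
}
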