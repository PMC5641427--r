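#' Estimate elliptic Fourier descriptors of a closed contour
#'
#' Computes the harmonic coefficients \eqn{a_n, b_n, c_n, d_n} of the series
#' \deqn{X(t) = \sum_n a_n \cos(2n\pi t/T) + b_n \sin(2n\pi t/T)}
#' \deqn{Y(t) = \sum_n c_n \cos(2n\pi t/T) + d_n \sin(2n\pi t/T)}
#' where \eqn{t} is the cumulative arc length along the polygonal contour and
#' \eqn{T} its perimeter. The classical closed-form line-integral estimator
#' over polygon segments is used (the contour is treated as piecewise linear,
#' which is exact for chain-coded boundaries), together with the centroid
#' (DC) terms.
#'
#' @param contour Contour matrix (see [as_contour()]); at least 3 vertices,
#'   not all collinear.
#' @param n_harmonics Maximum harmonic number \eqn{N} (default 20).
#' @return An object of class \code{"efd"}: a list with elements
#'   \item{coef}{\eqn{N \times 4} matrix with columns \code{a}, \code{b},
#'     \code{c}, \code{d}.}
#'   \item{dc}{Centroid terms \eqn{(x_0, y_0)} in pixels.}
#'   \item{perimeter}{Total displacement \eqn{T}.}
#'   \item{normalized}{Flag; \code{FALSE} for raw coefficients.}
#'   \item{scale_px, rotation_rad, phase_rad}{Normalization record, \code{NA}
#'     until [efd_normalize()] is applied.}
#' @seealso [efd_normalize()], [efd_reconstruct()], [flatten_coeffs()]
#' @export
efd_estimate <- function(contour, n_harmonics = 20L) {
  xy <- as_contour(contour)
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  n_harmonics <- as.integer(n_harmonics)
  x <- xy[, 1L]; y <- xy[, 2L]
  dx <- diff(c(x, x[1L])); dy <- diff(c(y, y[1L]))
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0            # chain codes may revisit pixels; drop null steps
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  if (length(dt) < 3L) stop("zero-perimeter contour")
  tcum <- cumsum(dt)
  Tper <- tcum[length(tcum)]
  t0 <- c(0, tcum[-length(tcum)])
  # collinearity check via the span of the vertices
  if (abs(polygon_area(xy)) < 1e-12 * Tper^2) stop("degenerate (collinear) contour")

  n <- seq_len(n_harmonics)
  w <- 2 * pi * outer(n, 1 / Tper)            # N x 1
  ang1 <- outer(2 * pi * n / Tper, tcum)      # N x V
  ang0 <- outer(2 * pi * n / Tper, t0)
  dcos <- cos(ang1) - cos(ang0)
  dsin <- sin(ang1) - sin(ang0)
  K <- Tper / (2 * (n * pi)^2)
  vx <- dx / dt; vy <- dy / dt
  a <- K * as.vector(dcos %*% vx)
  b <- K * as.vector(dsin %*% vx)
  cc <- K * as.vector(dcos %*% vy)
  d <- K * as.vector(dsin %*% vy)

  # centroid terms: path average of the (piecewise linear) coordinates
  xs <- x[keep]; ys <- y[keep]
  xe <- c(xs[-1L], xs[1L]); ye <- c(ys[-1L], ys[1L])
  dc <- c(sum((xs + xe) / 2 * dt), sum((ys + ye) / 2 * dt)) / Tper

  structure(list(
    n_harmonics = n_harmonics,
    coef = cbind(a = a, b = b, c = cc, d = d),
    dc = dc,
    perimeter = Tper,
    normalized = FALSE,
    scale_px = NA_real_, rotation_rad = NA_real_, phase_rad = NA_real_
  ), class = "efd")
}

# Rotate the starting point of every harmonic by phase theta and the
# coordinate frame by psi; returns the transformed N x 4 coefficient matrix.
.efd_transform <- function(coef, theta, psi) {
  n <- seq_len(nrow(coef))
  cn <- cos(n * theta); sn <- sin(n * theta)
  ap <- coef[, "a"] * cn + coef[, "b"] * sn
  bp <- -coef[, "a"] * sn + coef[, "b"] * cn
  cp <- coef[, "c"] * cn + coef[, "d"] * sn
  dp <- -coef[, "c"] * sn + coef[, "d"] * cn
  cpsi <- cos(psi); spsi <- sin(psi)
  cbind(a = cpsi * ap + spsi * cp, b = cpsi * bp + spsi * dp,
        c = -spsi * ap + cpsi * cp, d = -spsi * bp + cpsi * dp)
}

#' Normalize elliptic Fourier descriptors to the first-harmonic ellipse
#'
#' Removes the starting-point phase and the orientation of the first-harmonic
#' ellipse and divides out its semi-major magnitude, so that
#' \eqn{a_1 = 1, b_1 = 0, c_1 = 0} and \eqn{d_1 \in (0, 1]} is the aspect
#' ratio (minor/major) of the first-harmonic ellipse. The removed scale,
#' rotation and phase are recorded.
#'
#' Of the discrete residual ambiguities (axis swap and 180-degree rotation)
#' the solution with the semi-major axis along +x and \eqn{a_1 > 0} is
#' chosen, oriented so that the head's anterior end sits at +x and its
#' dorsal bend opens toward -y. Because a 180-degree rotation of the frame
#' negates every even harmonic, the orientation is decided by the sign of
#' the even-harmonic asymmetry \eqn{a_2 + c_2} (positive for a bent, tapered
#' head with its apex at +x); centrally symmetric shapes with
#' \eqn{a_2 + c_2 = 0} (for example pure ellipses) fall back to the smallest
#' starting-point phase. The rule is intrinsic to the shape, which makes the
#' normalized coefficients invariant under rotation, scaling, translation
#' and start-vertex choice of the input contour.
#'
#' @param efd Raw \code{"efd"} object from [efd_estimate()].
#' @return A normalized \code{"efd"} object; \code{scale_px} holds the
#'   removed semi-major magnitude, \code{rotation_rad} the removed ellipse
#'   orientation and \code{phase_rad} the removed starting-point phase.
#' @export
efd_normalize <- function(efd) {
  stopifnot(inherits(efd, "efd"))
  if (isTRUE(efd$normalized)) return(efd)
  coef <- efd$coef
  a1 <- coef[1L, "a"]; b1 <- coef[1L, "b"]
  c1 <- coef[1L, "c"]; d1 <- coef[1L, "d"]
  mag <- sqrt(a1^2 + b1^2 + c1^2 + d1^2)
  if (mag < 1e-12) stop("zero first harmonic: cannot normalize")
  theta0 <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)

  best <- NULL
  for (k in 0:3) {
    theta <- theta0 + k * pi / 2
    tmp <- .efd_transform(coef, theta, 0)
    psi <- atan2(tmp[1L, "c"], tmp[1L, "a"])
    out <- .efd_transform(coef, theta, psi)
    E <- out[1L, "a"]                     # = sqrt(a1'^2 + c1'^2) >= 0
    if (E < 1e-12) next
    out <- out / E
    if (abs(out[1L, "d"]) > 1 + 1e-9) next  # semi-major must lie along x
    # anterior-end rule: a 180-degree frame rotation negates every even
    # harmonic, so the sign of a2 + c2 pins the orientation
    key <- if (nrow(out) >= 2L) out[2L, "a"] + out[2L, "c"] else 0
    cand <- list(coef = out, E = E, theta = theta %% (2 * pi), psi = psi,
                 key = key)
    if (is.null(best) ||
        cand$key > best$key + 1e-9 ||
        (abs(cand$key - best$key) <= 1e-9 && cand$theta < best$theta)) {
      best <- cand
    }
  }
  if (is.null(best)) stop("degenerate first harmonic: cannot normalize")
  out <- best$coef
  if (out[1L, "d"] < 0) {
    # a clockwise contour slipped through: mirror-correct
    warning("clockwise contour: mirror-correcting the y coefficients")
    out[, c("c", "d")] <- -out[, c("c", "d")]
  }
  efd$coef <- out
  efd$normalized <- TRUE
  efd$scale_px <- best$E
  efd$rotation_rad <- best$psi
  efd$phase_rad <- best$theta
  efd
}

#' Reconstruct a contour from elliptic Fourier descriptors
#'
#' Evaluates the truncated series at uniformly spaced values of the
#' parameter, inverting estimation (and normalization) up to truncation
#' error. Raw coefficients reproduce the contour in its original frame
#' (including the centroid offset); normalized coefficients reproduce the
#' size- and orientation-free shape.
#'
#' @param efd An \code{"efd"} object.
#' @param n_harmonics Number of harmonics to use (defaults to all; must not
#'   exceed the stored maximum).
#' @param n_points Number of points to evaluate (default 360).
#' @return A contour matrix.
#' @export
efd_reconstruct <- function(efd, n_harmonics = efd$n_harmonics, n_points = 360L) {
  stopifnot(inherits(efd, "efd"))
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (n_harmonics > efd$n_harmonics) stop("n_harmonics exceeds the stored maximum")
  tt <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  n <- seq_len(n_harmonics)
  Ct <- cos(outer(n, tt)); St <- sin(outer(n, tt))
  co <- efd$coef[n, , drop = FALSE]
  X <- as.vector(crossprod(Ct, co[, "a"]) + crossprod(St, co[, "b"]))
  Y <- as.vector(crossprod(Ct, co[, "c"]) + crossprod(St, co[, "d"]))
  if (!isTRUE(efd$normalized)) {
    X <- X + efd$dc[1L]; Y <- Y + efd$dc[2L]
  }
  cbind(x = X, y = Y)
}

#' Flatten normalized coefficients into the shape vector used for PCA
#'
#' After normalization the free parameters are \eqn{d_1} followed by
#' \eqn{a_n, b_n, c_n, d_n} for \eqn{n = 2..N}, giving a vector of length
#' \eqn{4N - 3} (77 at the default \eqn{N = 20}).
#'
#' @param efd Normalized \code{"efd"} object.
#' @return Named numeric vector (\code{d1}, \code{a2}, \code{b2},
#'   \code{c2}, \code{d2}, ...).
#' @export
flatten_coeffs <- function(efd) {
  stopifnot(inherits(efd, "efd"))
  if (!isTRUE(efd$normalized)) stop("flatten_coeffs needs normalized coefficients")
  N <- efd$n_harmonics
  v <- efd$coef[1L, "d"]
  names(v) <- "d1"
  if (N > 1L) {
    rest <- t(efd$coef[2:N, , drop = FALSE])   # columns per harmonic: a,b,c,d
    nm <- as.vector(vapply(2:N, function(n) paste0(c("a", "b", "c", "d"), n),
                           character(4L)))
    rest <- as.vector(rest)
    names(rest) <- nm
    v <- c(v, rest)
  }
  v
}

#' Rebuild an efd object from a flattened shape vector
#'
#' Inverse of [flatten_coeffs()]: restores \eqn{a_1 = 1, b_1 = 0, c_1 = 0}
#' and reshapes the remaining entries. The vector length must be
#' \eqn{4N - 3} for an integer \eqn{N}.
#'
#' @param v Numeric vector of length \eqn{4N - 3}.
#' @param scale_px Optional semi-major magnitude to attach (for absolute
#'   measurements).
#' @return A normalized \code{"efd"} object.
#' @export
unflatten_coeffs <- function(v, scale_px = NA_real_) {
  p <- length(v)
  if ((p + 3L) %% 4L != 0L) stop("vector length must be 4N - 3")
  N <- (p + 3L) %/% 4L
  coef <- matrix(0, N, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  coef[1L, ] <- c(1, 0, 0, v[[1L]])
  if (N > 1L) coef[2:N, ] <- matrix(v[-1L], ncol = 4L, byrow = TRUE)
  structure(list(
    n_harmonics = N, coef = coef, dc = c(0, 0), perimeter = NA_real_,
    normalized = TRUE, scale_px = scale_px,
    rotation_rad = NA_real_, phase_rad = NA_real_
  ), class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat(sprintf("Elliptic Fourier descriptors: N = %d (%s)\n", x$n_harmonics,
              if (isTRUE(x$normalized)) "normalized" else "raw"))
  if (isTRUE(x$normalized)) {
    cat(sprintf("  aspect ratio d1 = %.4f, scale = %.2f px\n",
                x$coef[1L, "d"], x$scale_px))
  }
  invisible(x)
}
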