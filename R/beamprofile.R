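#' FWHM of a 1-D intensity profile by Gaussian fit
#'
#' Least-squares fit of `a * exp(-(i - m)^2 / (2 s^2)) + c` to the samples
#' around the central peak; the FWHM is `2 * sqrt(2 * log(2)) * s *
#' pixel_size`. The profile must have a strict interior maximum; the fitted
#' centre must stay inside the sampled window or the fit is rejected.
#'
#' @param profile numeric vector of intensities.
#' @param pixel_size sample spacing in um.
#' @return FWHM in um.
#' @examples
#' x <- seq_len(41)
#' profile_fwhm(exp(-(x - 21)^2 / (2 * 2^2)), pixel_size = 4.4)  # 20.72 um
#' @export
profile_fwhm <- function(profile, pixel_size = 1) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 5L) stop("profile too short for a Gaussian fit")
  pk <- which.max(profile)
  if (pk == 1L || pk == n || diff(range(profile)) == 0)
    stop("profile has no strict interior maximum; Gaussian fit rejected")
  i <- seq_len(n)
  c0 <- min(profile)
  a0 <- profile[pk] - c0
  # moment-based sigma start around the peak
  w <- pmax(profile - c0, 0)
  s0 <- sqrt(sum(w * (i - pk)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- n / 6
  fit <- tryCatch(
    minpack.lm::nlsLM(profile ~ a * exp(-(i - m)^2 / (2 * s^2)) + c,
                      data = data.frame(profile = profile, i = i),
                      start = list(a = a0, m = pk, s = s0, c = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["m"]] < 1 || cf[["m"]] > n)
    stop("fitted centre lies outside the profile window; fit rejected")
  if (cf[["a"]] <= 0 || !is.finite(cf[["s"]]))
    stop("degenerate Gaussian fit (non-positive amplitude)")
  unname(2 * sqrt(2 * log(2)) * abs(cf[["s"]]) * pixel_size)
}

#' Characterise a light sheet from measured thickness versus position
#'
#' Fits a fifth-order polynomial to the sheet FWHM measured along the
#' propagation axis x. Real profiles are asymmetric about the focus
#' (spherical aberration), which the unconstrained polynomial accommodates.
#' The focal thickness `fwhm0` is the minimum of the fit within the data
#' range; the Rayleigh length is half the x-interval over which the fitted
#' thickness stays below `sqrt(2) * fwhm0`, reported as the mean of the two
#' one-sided half-widths (each found by bisection on the fitted curve);
#' the effective field of view is `2 * z_R`.
#'
#' @param x_positions strictly increasing x positions, um.
#' @param fwhm_values measured sheet FWHM at each position, um, > 0.
#' @return an object of class `"light_sheet_fit"`: list with `fwhm0`,
#'   `focus_x`, `rayleigh_length`, `efov`, `half_width_left`,
#'   `half_width_right`, `poly_coeffs` (6 coefficients, ascending powers).
#' @examples
#' x <- seq(-600, 600, by = 100)
#' f <- 7.9 * sqrt(1 + (x / 450)^2)
#' fit_beam(x, f)
#' @export
fit_beam <- function(x_positions, fwhm_values) {
  x <- as.numeric(x_positions)
  f <- as.numeric(fwhm_values)
  if (length(x) != length(f)) stop("x and FWHM vectors differ in length")
  if (length(x) < 7L) stop("need at least 7 points spanning the focus")
  if (any(diff(x) <= 0)) stop("x positions must be strictly increasing")
  if (any(f <= 0)) stop("FWHM values must be positive")
  # centred/scaled x for a well-conditioned raw polynomial fit
  xc <- mean(x); xs <- max(abs(x - xc))
  u <- (x - xc) / xs
  fit <- stats::lm(f ~ poly(u, 5, raw = TRUE))
  beta <- stats::coef(fit)
  predict_u <- function(uu) {
    drop(outer(uu, 0:5, `^`) %*% beta)
  }
  # minimum of the fitted curve within the data range
  grid <- seq(min(u), max(u), length.out = 2048L)
  gi <- which.min(predict_u(grid))
  lo <- grid[max(gi - 2L, 1L)]; hi <- grid[min(gi + 2L, length(grid))]
  opt <- stats::optimize(predict_u, c(lo, hi))
  u0 <- opt$minimum
  fwhm0 <- opt$objective
  if (fwhm0 <= 0) stop("fitted minimum thickness is non-positive")
  thresh <- sqrt(2) * fwhm0
  g <- function(uu) predict_u(uu) - thresh
  cross <- function(from, to) {
    # first bracketed sqrt(2)-enlargement crossing walking away from focus
    steps <- seq(from, to, length.out = 512L)
    vals <- g(steps)
    k <- which(vals[-1L] > 0 & vals[-length(vals)] <= 0)
    if (!length(k)) return(NA_real_)
    stats::uniroot(g, c(steps[k[1L]], steps[k[1L] + 1L]), tol = 1e-10)$root
  }
  right <- cross(u0, max(u))
  left <- cross(u0, min(u))
  if (is.na(right) || is.na(left))
    stop(sprintf(paste0("no sqrt(2) thickness enlargement inside the data ",
                        "range on the %s side; extend the measurement"),
                 if (is.na(left) && is.na(right)) "either"
                 else if (is.na(left)) "left" else "right"))
  hw_left <- (u0 - left) * xs
  hw_right <- (right - u0) * xs
  z_r <- (hw_left + hw_right) / 2
  # coefficients back on the original x scale (ascending powers of x)
  coeffs_x <- sapply(0:5, function(k) {
    sum(sapply(k:5, function(j)
      beta[j + 1L] * choose(j, k) * (-xc)^(j - k) / xs^j))
  })
  structure(list(fwhm0 = fwhm0,
                 focus_x = u0 * xs + xc,
                 rayleigh_length = z_r,
                 efov = 2 * z_r,
                 half_width_left = hw_left,
                 half_width_right = hw_right,
                 poly_coeffs = unname(coeffs_x)),
            class = "light_sheet_fit")
}

#' @export
print.light_sheet_fit <- function(x, ...) {
  cat("light_sheet_fit (5th-order polynomial)\n")
  cat(sprintf("  focal FWHM: %.3g um at x = %.4g um\n", x$fwhm0, x$focus_x))
  cat(sprintf("  Rayleigh length: %.4g um (half-widths %.4g / %.4g um)\n",
              x$rayleigh_length, x$half_width_left, x$half_width_right))
  cat(sprintf("  eFOV (2 x Rayleigh length): %.4g um\n", x$efov))
  invisible(x)
}

#' Convert an in-air eFOV (or Rayleigh length) to its in-medium value
#'
#' A higher-index medium elongates the Rayleigh length by a factor equal to
#' the refractive index. This is an explicit converter; [fit_beam()] never
#' applies it silently.
#'
#' @param efov_air eFOV (or Rayleigh length) measured in air, um.
#' @param n medium refractive index.
#' @return elongated value in the medium, um.
#' @export
efov_in_medium <- function(efov_air, n) {
  if (any(efov_air < 0)) stop("'efov_air' must be >= 0")
  if (any(n < 1)) stop("refractive index must be >= 1")
  efov_air * n
}
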