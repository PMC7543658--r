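#' @title Peak height of a point Gaussian atom at finite resolution
#'
#' @description
#' For a point Gaussian atom with isotropic ADP \eqn{B} the scattering factor
#' is \eqn{f(s) = \exp(-B s^2/4)} and the electron density at the atomic
#' centre, truncated at the resolution limit \eqn{s_{max} = 1/d_{max}}, is
#' \deqn{\rho(0) = \int_0^{s_{max}} 4\pi s^2 \exp(-B s^2/4)\, ds,}
#' with closed form in terms of the error function.  The map B value to
#' central peak height is strictly decreasing in \eqn{B}, so it carries the
#' ADP distribution to a "peak-height distribution" (PHD) in which modes
#' corresponding to distinct mobility regimes are typically better separated
#' than in B space.
#'
#' The \eqn{4\pi} prefactor is retained so absolute values are comparable
#' across implementations; every downstream use is a ratio or a clustering,
#' for which it cancels.
#'
#' @name peakheight
NULL

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# I(a, S) = int_0^S s^2 exp(-a s^2) ds.
# Closed form sqrt(pi) erf(S a^{1/2}) / (4 a^{3/2}) - S exp(-a S^2) / (2 a);
# for a S^2 < 1e-4 the two terms cancel catastrophically, so a short
# alternating series (error < 1e-15 relative there) is used instead.
gauss_s2_integral <- function(a, S) {
  stopifnot(all(a >= 0), S > 0)
  out <- numeric(length(a))
  small <- a * S^2 < 1e-4
  if (any(small)) {
    as <- a[small]
    acc <- 0
    for (k in 0:6) acc <- acc + (-as * S^2)^k / (factorial(k) * (2 * k + 3))
    out[small] <- S^3 * acc
  }
  if (any(!small)) {
    ab <- a[!small]
    out[!small] <- sqrt(pi) * erf(S * sqrt(ab)) / (4 * ab^1.5) -
      S * exp(-ab * S^2) / (2 * ab)
  }
  out
}

#' @rdname peakheight
#' @param b isotropic B value(s), \eqn{\mathrm{\AA}^2}, >= 0.
#' @param s_max resolution limit \eqn{1/d_{max}}, \eqn{\mathrm{\AA}^{-1}},
#'   > 0.
#' @return \code{peak_height}: central density value(s), arbitrary units on a
#'   shared scale; \code{(4\pi/3) s_{max}^3} at \code{b = 0}.
#' @examples
#' peak_height(0, 0.5) - 4 * pi * 0.5^3 / 3   # 0
#' peak_height(c(10, 50, 200), s_max = 0.5)   # strictly decreasing
#' @export
peak_height <- function(b, s_max) {
  if (any(!is.finite(b)) || any(b < 0)) stop("'b' must be finite and >= 0")
  if (!is.finite(s_max) || s_max <= 0) stop("'s_max' must be > 0")
  4 * pi * gauss_s2_integral(b / 4, s_max)
}

#' @rdname peakheight
#' @param p peak height value(s) in \code{(0, peak_height(0, s_max)]}.
#' @return \code{invert_peak_height}: the B value(s) whose peak height at
#'   \code{s_max} equals \code{p}.
#' @export
invert_peak_height <- function(p, s_max) {
  if (!is.finite(s_max) || s_max <= 0) stop("'s_max' must be > 0")
  pmaxv <- peak_height(0, s_max)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > pmaxv * (1 + 1e-12)))
    stop("'p' must lie in (0, peak_height(0, s_max)]")
  vapply(p, function(pi1) {
    if (pi1 >= pmaxv) return(0)
    # bracket the root by doubling, then bisect on the monotone map
    hi <- 100
    while (peak_height(hi, s_max) > pi1) hi <- hi * 2
    stats::uniroot(function(b) peak_height(b, s_max) - pi1,
                   lower = 0, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}

#' @rdname peakheight
#' @param model a \code{structure_model} from \code{\link{read_structure}}.
#' @return \code{phd_transform}: a list of class \code{phd_profile} with
#'   \code{s_max} and \code{values} (one peak height per retained atom, in
#'   atom order).
#' @export
phd_transform <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  structure(list(s_max = model$s_max,
                 values = peak_height(model$atoms$b_iso, model$s_max)),
            class = "phd_profile")
}
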