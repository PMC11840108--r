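#' Two-tailed P value of a Pearson correlation under the parametric null
#'
#' Computes the two-tailed P value of an observed Pearson correlation
#' coefficient under the null hypothesis of zero population correlation,
#' using the exact parametric result that
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} follows a t distribution with
#' \eqn{n - 2} degrees of freedom.
#'
#' @param r Observed correlation(s), \eqn{|r| \le 1}. Vectorised.
#' @param n Sample size(s) the correlation was computed at, \eqn{n \ge 4}.
#' @return P value(s) in (0, 1]. For \eqn{|r| = 1} the P value underflows;
#'   the smallest positive representable double is returned and the
#'   affected positions are recorded in an \code{"underflow"} attribute.
#' @seealso [critical_r()] for the inverse problem.
#' @export
#' @examples
#' p_two_tailed(0, 1000)      # 1
#' p_two_tailed(0.0878, 500)  # matches cor.test()
p_two_tailed <- function(r, n) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop("r must be finite with |r| <= 1")
  }
  if (any(n < 4)) stop("n must be >= 4")
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  under <- which(p == 0)
  if (length(under)) {
    p[under] <- .Machine$double.xmin
    attr(p, "underflow") <- under
  }
  p
}

#' Critical Pearson r for a two-tailed significance threshold
#'
#' Smallest non-negative correlation that is significant at level
#' \code{alpha} for sample size \code{n}, obtained by inverting the t
#' quantile: \eqn{r_c = t_c / \sqrt{n - 2 + t_c^2}} with
#' \eqn{t_c = t_{1-\alpha/2, n-2}}.
#'
#' @param n Sample size, \eqn{n \ge 4}. Vectorised.
#' @param alpha Two-tailed significance level in (0, 1).
#' @return Critical correlation in (0, 1).
#' @export
#' @examples
#' critical_r(1000, 0.05)           # ~0.062
#' critical_r(1000, 0.05 / 55278)   # Bonferroni-corrected cutoff
critical_r <- function(n, alpha) {
  stopifnot(all(n >= 4), all(alpha > 0), all(alpha < 1))
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Fisher z-transformation and its inverse
#'
#' \code{fisher_z} maps a correlation to the z scale, \eqn{z =
#' \mathrm{atanh}(r)}, on which the sampling distribution of a Pearson
#' correlation is approximately normal with standard deviation
#' \eqn{1/\sqrt{n-3}}. \code{fisher_z_inv} is \eqn{\tanh(z)}.
#'
#' @param r Correlation(s), \eqn{|r| < 1}.
#' @param z Fisher z value(s).
#' @return Transformed value(s).
#' @export
#' @examples
#' fisher_z(0.11)
#' fisher_z_inv(fisher_z(0.5)) # 0.5
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher z-transformation")
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Effect size reaching a target power (inverse power analysis)
#'
#' Returns the population correlation \eqn{\rho} whose analytical power at
#' sample size \code{n} and two-tailed level \code{alpha} equals
#' \code{power}, via the Fisher z approximation:
#' \deqn{\rho = \tanh\left(\frac{z_{1-\alpha/2} + z_{power}}{\sqrt{n-3}}\right).}
#' Equivalently written with standard normal deviates as
#' \eqn{(Z_\alpha - Z_\beta)/\sqrt{n-3}}, since \eqn{Z_\beta = -z_{power}}.
#'
#' @param n Sample size, \eqn{n \ge 4}.
#' @param alpha Two-tailed significance level in (0, 1).
#' @param power Target power in (0, 1). Vectorised.
#' @return Effect size(s) in (0, 1), increasing in \code{power}.
#' @seealso [analytical_power()] for the forward direction.
#' @export
#' @examples
#' r_critical_for_power(1000, 0.05 / 55278, 0.5)
r_critical_for_power <- function(n, alpha, power) {
  stopifnot(n >= 4, alpha > 0, alpha < 1, all(power > 0), all(power < 1))
  tanh((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3))
}

#' Analytical power of the two-tailed Pearson correlation test
#'
#' Power of detecting a population correlation \code{rho} at sample size
#' \code{n} and two-tailed level \code{alpha}, on the Fisher z scale:
#' \deqn{1-\beta = \Phi(\sqrt{n-3}\,\mathrm{atanh}|\rho| - z_{1-\alpha/2})
#'   + \Phi(-\sqrt{n-3}\,\mathrm{atanh}|\rho| - z_{1-\alpha/2}).}
#' The second (wrong-tail) term is negligible at realistic scales but makes
#' the function exact at \eqn{\rho = 0}, where power equals \code{alpha}.
#'
#' @param rho Population effect size(s), \eqn{|\rho| < 1}. Vectorised.
#' @param n Sample size, \eqn{n \ge 4}.
#' @param alpha Two-tailed significance level in (0, 1).
#' @return Power in (0, 1).
#' @export
#' @examples
#' analytical_power(0, 1000, 0.05)   # 0.05
#' analytical_power(r_critical_for_power(1000, 0.05, 0.8), 1000, 0.05) # 0.8
analytical_power <- function(rho, n, alpha) {
  stopifnot(all(abs(rho) < 1), n >= 4, alpha > 0, alpha < 1)
  s <- sqrt(n - 3)
  zr <- s * atanh(abs(rho))
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(zr - zc) + stats::pnorm(-zr - zc)
}

#' Analytical power curve across sample sizes
#'
#' @param rho Population effect size, \eqn{|\rho| < 1}.
#' @param alpha Two-tailed significance level in (0, 1).
#' @param sizes Integer vector of sample sizes (each \eqn{\ge 4}).
#' @return A data frame with columns \code{rho}, \code{alpha}, \code{size},
#'   \code{power}; power is non-decreasing in size for \eqn{\rho > 0}.
#' @export
power_curve <- function(rho, alpha, sizes = resample_sizes()) {
  stopifnot(all(sizes >= 4))
  data.frame(
    rho = rho, alpha = alpha, size = as.integer(sizes),
    power = vapply(sizes, function(n) analytical_power(rho, n, alpha),
                   numeric(1))
  )
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons.
#' @return \code{alpha / m}, e.g. \code{0.05 / 1225} (about 4e-5).
#' @export
bonferroni_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}
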