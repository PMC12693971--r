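#' Bonferroni-adjusted per-test significance level
#'
#' Divides a family-wise significance level equally over `m` tests.
#'
#' @param alpha_family Family-wise significance level, in (0, 1).
#' @param m Number of tests, a positive integer.
#' @param display_digits Digits used for the human-readable rounded form.
#'
#' @return A list with `alpha` (full precision, used in computation) and
#'   `display` (character, rounded to `display_digits` decimals).
#' @examples
#' bonferroni(0.05, 12)  # alpha = 0.0041667, displays "0.0042"
#' @export
bonferroni <- function(alpha_family, m, display_digits = 4) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != as.integer(m)) {
    stopf("`m` must be a positive integer (got %s)", format(m))
  }
  if (!is.numeric(alpha_family) || alpha_family <= 0 || alpha_family >= 1) {
    stopf("`alpha_family` must lie in (0, 1)")
  }
  alpha <- alpha_family / m
  list(alpha = alpha,
       display = formatC(round(alpha, display_digits),
                         format = "f", digits = display_digits))
}

check_power_domain <- function(f, N, alpha) {
  if (any(f <= 0 | f > 0.5)) stopf("`f` (MAF) must lie in (0, 0.5]")
  if (any(N < 1)) stopf("`N` must be a positive sample count")
  if (any(alpha <= 0 | alpha >= 1)) stopf("`alpha` must lie in (0, 1)")
  invisible(NULL)
}

#' Power of the additive single-variant association test
#'
#' Power of the two-sided 1-df chi-square test of an additive allelic
#' effect on a standardized quantitative trait. The noncentrality
#' parameter is `lambda = 2 f (1 - f) N beta^2`, the expected chi-square
#' statistic inflation for a variant with minor allele frequency `f`
#' genotyped in `N` individuals with standardized per-allele effect
#' `beta`.
#'
#' @param f Minor allele frequency, in (0, 0.5].
#' @param N Number of individuals.
#' @param beta Standardized additive effect size (phenotype SD per
#'   allele). May be negative; power depends on `beta^2`.
#' @param alpha Per-test significance level, in (0, 1).
#' @param method `"exact"` uses the noncentral chi-square tail;
#'   `"normal"` uses the normal approximation
#'   `power = Phi(sqrt(lambda) - z) + Phi(-sqrt(lambda) - z)` with
#'   `z = qnorm(1 - alpha/2)`, available for cross-checks.
#'
#' @return Power, a probability in `[0, 1]`. Vectorized over `f`, `N`,
#'   `beta`.
#' @examples
#' power_additive(0.00005, 423887, 0.5766, 0.05 / 12)
#' power_additive(0.1, 1000, 0, 0.05)  # equals alpha under the null
#' @seealso [detectable_beta()] for the inverse problem.
#' @export
power_additive <- function(f, N, beta, alpha, method = c("exact", "normal")) {
  method <- match.arg(method)
  check_power_domain(f, N, alpha)
  lambda <- 2 * f * (1 - f) * N * beta^2
  if (method == "exact") {
    crit <- qchisq(1 - alpha, df = 1)
    pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
  } else {
    z <- qnorm(1 - alpha / 2)
    s <- sqrt(lambda)
    pnorm(s - z) + pnorm(-s - z)
  }
}

#' Smallest detectable effect size at a target power
#'
#' Inverts [power_additive()] in `beta`: the unique positive standardized
#' effect whose additive 1-df chi-square power equals `target_power`.
#' Solved by bisection on a bracket grown geometrically from `[0, 1]`.
#'
#' @inheritParams power_additive
#' @param target_power Target power, in (`alpha`, 1).
#' @param tol Relative tolerance of the bisection, default `1e-9`.
#' @param max_grow Cap on bracket doublings before giving up.
#'
#' @return The detectable `beta` (phenotype SD per allele).
#' @examples
#' detectable_beta(0.00005, 423887, 0.05 / 12, 0.8)
#' @export
detectable_beta <- function(f, N, alpha, target_power = 0.8,
                            method = c("exact", "normal"),
                            tol = 1e-9, max_grow = 60) {
  method <- match.arg(method)
  check_power_domain(f, N, alpha)
  if (target_power <= alpha || target_power >= 1) {
    stopf("`target_power` must lie in (alpha, 1)")
  }
  pw <- function(b) power_additive(f, N, b, alpha, method = method)
  lo <- 0
  hi <- 1
  grow <- 0
  while (pw(hi) < target_power) {
    hi <- hi * 2
    grow <- grow + 1
    if (grow > max_grow) {
      stopf("could not bracket the detectable effect (power %.3g at beta = %.3g)",
            pw(hi), hi)
    }
  }
  while ((hi - lo) > tol * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (pw(mid) < target_power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
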