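#' Relative risk at an exposure level
#'
#' Log-linear extrapolation of a per-unit relative risk: the published RR
#' is the risk ratio per `unit` of (possibly transformed) concentration,
#' so `RR(x) = rr_unit ^ ((t(x) - t(x0)) / unit)` where `t` is the
#' identity or a floored log10. The result is floored at 1 whenever
#' `t(x) <= t(x0)` — exposure at or below the counterfactual level is
#' never protective, because the counterfactual here is the elimination of
#' pollution to background, not an optimum.
#'
#' For `transform = "log10"` (fecal-indicator dose response), the
#' concentration is floored at `floor` before taking logs so that months
#' with zero observed counts map to RR = 1 rather than minus infinity;
#' the default floor is 1 organism per 100 ml.
#'
#' @param x exposure level(s), natural units.
#' @param rr_unit relative risk per `unit` (> 0); may be a vector
#'   recycled against `x`.
#' @param unit size of the exposure step the RR refers to (e.g. 10 ug/m3,
#'   100 Bq/m3, 1 log10 unit); > 0.
#' @param x0 counterfactual exposure level (default 0).
#' @param transform `"linear"` or `"log10"`.
#' @param floor concentration floor applied before log10 (default 1).
#' @return vector of relative risks, >= 1.
#' @examples
#' rr_at(30, 1.06, 10, x0 = 20)        # one unit step -> 1.06
#' rr_at(100, 1.34, 1, x0 = 1, transform = "log10")  # two decades -> 1.34^2
#' @export
rr_at <- function(x, rr_unit, unit, x0 = 0,
                  transform = c("linear", "log10"), floor = 1) {
  transform <- match.arg(transform)
  if (any(rr_unit <= 0)) stop("'rr_unit' must be positive", call. = FALSE)
  if (!is.numeric(unit) || length(unit) != 1L || unit <= 0)
    stop("'unit' must be a positive number", call. = FALSE)
  t_ <- if (transform == "linear") identity
        else function(z) log10(pmax(z, floor))
  rr <- rr_unit ^ (pmax(t_(x) - t_(x0), 0) / unit)
  pmax(rr, 1)
}

#' PAF for a categorical exposure
#'
#' Population attributable fraction for an exposure described by discrete
#' categories, comparing the observed prevalence distribution `P(x)` with
#' a counterfactual distribution `P'(x)`:
#' \deqn{PAF = \frac{\sum_x P(x)RR(x) - \sum_x P'(x)RR(x)}{\sum_x P(x)RR(x)}}
#' with both sums including the implicit reference category at RR = 1.
#' With the default all-reference counterfactual this reduces to the
#' familiar closed form `sum(p*(RR-1)) / (1 + sum(p*(RR-1)))`.
#'
#' Inputs may be vectors (one draw, categories along the vector) or
#' matrices (draws in rows, categories in columns); a matrix input yields
#' one PAF per row.
#'
#' @param prevalences prevalence of each non-reference category; vector or
#'   draws-by-categories matrix. Row sums must not exceed 1 (the remainder
#'   is the reference category).
#' @param rrs relative risk of each non-reference category, same shape.
#' @param counterfactual_prevalences counterfactual prevalences, same
#'   shape; default `NULL` puts all counterfactual mass in the reference
#'   category.
#' @return PAF value(s) in (-1, 1); one per draw.
#' @examples
#' paf_categorical(0.19, 1.25)                   # single category
#' paf_categorical(c(0.4354, 0.4286), c(1.8, 1.2))
#' @export
paf_categorical <- function(prevalences, rrs,
                            counterfactual_prevalences = NULL) {
  p <- if (is.matrix(prevalences)) prevalences else rbind(c(prevalences))
  r <- if (is.matrix(rrs)) rrs else rbind(c(rrs))
  if (nrow(p) == 1L && nrow(r) > 1L) p <- p[rep(1L, nrow(r)), , drop = FALSE]
  if (nrow(r) == 1L && nrow(p) > 1L) r <- r[rep(1L, nrow(p)), , drop = FALSE]
  if (!all(dim(p) == dim(r)))
    stop("'prevalences' and 'rrs' must have matching dimensions",
         call. = FALSE)
  if (any(p < 0)) stop("negative prevalence", call. = FALSE)
  if (any(r <= 0)) stop("relative risks must be positive", call. = FALSE)
  psum <- rowSums(p)
  if (any(psum > 1 + 1e-9))
    stop("prevalences sum to more than 1", call. = FALSE)
  num_obs <- (1 - psum) + rowSums(p * r)     # reference at RR = 1
  if (is.null(counterfactual_prevalences)) {
    num_cf <- rep(1, nrow(p))
  } else {
    pc <- if (is.matrix(counterfactual_prevalences)) counterfactual_prevalences
          else rbind(c(counterfactual_prevalences))
    if (nrow(pc) == 1L && nrow(p) > 1L) pc <- pc[rep(1L, nrow(p)), , drop = FALSE]
    if (!all(dim(pc) == dim(p)))
      stop("counterfactual prevalences must match 'prevalences' shape",
           call. = FALSE)
    if (any(pc < 0)) stop("negative counterfactual prevalence", call. = FALSE)
    pcsum <- rowSums(pc)
    if (any(pcsum > 1 + 1e-9))
      stop("counterfactual prevalences sum to more than 1", call. = FALSE)
    num_cf <- (1 - pcsum) + rowSums(pc * r)
  }
  out <- (num_obs - num_cf) / num_obs
  if (is.matrix(prevalences) || is.matrix(rrs)) out else drop(out)
}

#' PAF for a continuous exposure distribution
#'
#' Continuous-exposure attributable fraction for one Monte Carlo draw of
#' the risk curve. The RR curve (fixed within the draw) is integrated over
#' the exposure and counterfactual distributions by deterministic
#' quadrature on `n_quad` equiprobable quantile points:
#' \deqn{PAF = \frac{E_P[RR(x)] - E_{P'}[RR(x)]}{E_P[RR(x)]}}
#' Exposure distributions here describe across-person / across-home
#' variability and are integrated out, while `rr_unit` carries parameter
#' uncertainty and is sampled upstream, one value per iteration.
#'
#' @param exposure a [dist_spec()] for the population exposure
#'   distribution (support >= 0 after truncation).
#' @param counterfactual a `dist_spec` for the counterfactual exposure;
#'   default point mass at 0.
#' @param rr_unit relative risk per `unit` for this draw (scalar or a
#'   vector of draws — vectorized over draws).
#' @param unit,transform,floor passed to [rr_at()].
#' @param n_quad number of quadrature points (>= 16, default 512).
#' @return PAF value(s), one per element of `rr_unit`.
#' @examples
#' paf_continuous(dist_point(10), rr_unit = 1.06, unit = 10)  # (RR-1)/RR
#' @export
paf_continuous <- function(exposure, counterfactual = dist_point(0),
                           rr_unit, unit, transform = c("linear", "log10"),
                           floor = 1, n_quad = 512) {
  transform <- match.arg(transform)
  if (!is_dist_spec(exposure)) stop("'exposure' must be a dist_spec",
                                    call. = FALSE)
  if (!is_dist_spec(counterfactual))
    stop("'counterfactual' must be a dist_spec", call. = FALSE)
  if (n_quad < 16) stop("'n_quad' must be >= 16", call. = FALSE)
  u <- (seq_len(n_quad) - 0.5) / n_quad
  x <- q_dist(exposure, u)
  x0 <- q_dist(counterfactual, u)
  if (any(!is.finite(x)))
    stop(sprintf("quadrature failed for exposure distribution '%s'",
                 exposure$kind), call. = FALSE)
  if (any(!is.finite(x0)))
    stop(sprintf("quadrature failed for counterfactual distribution '%s'",
                 counterfactual$kind), call. = FALSE)
  # E[RR] under each distribution, per rr_unit draw
  out <- vapply(rr_unit, function(r) {
    e_obs <- mean(rr_at(x, r, unit, x0 = 0, transform = transform,
                        floor = floor))
    e_cf <- mean(rr_at(x0, r, unit, x0 = 0, transform = transform,
                       floor = floor))
    (e_obs - e_cf) / e_obs
  }, numeric(1))
  if (length(rr_unit) == 1L) out[[1L]] else out
}

#' Combine attributable fractions of independently acting pollutants
#'
#' Multiplicative-complement combination for pollutants that act on the
#' same endpoint with uncorrelated exposures:
#' `PAF = 1 - prod(1 - PAF_i)`. The result is at least the largest input
#' and at most their sum. Matrix input (draws in rows, pollutants in
#' columns) combines row-wise.
#'
#' @param pafs vector of PAFs in \[0, 1), or a draws-by-pollutants matrix.
#' @return combined PAF (scalar, or one per row for matrix input).
#' @examples
#' combine_pafs(c(0.30, 0.028))
#' @export
combine_pafs <- function(pafs) {
  m <- if (is.matrix(pafs)) pafs else rbind(c(pafs))
  if (any(m >= 1)) stop("PAF values must be < 1 to combine", call. = FALSE)
  out <- 1 - apply(1 - m, 1L, prod)
  if (is.matrix(pafs)) out else drop(out)
}

#' Attributable cases
#'
#' Applies an attributable fraction to the observed baseline count:
#' `D_attrib = PAF * D_total`. Real-valued; rounding happens only at
#' report time.
#'
#' @param paf attributable fraction(s) in \[0, 1\].
#' @param d_total baseline count (>= 0).
#' @return attributable count(s).
#' @export
attributable_cases <- function(paf, d_total) {
  if (any(paf < 0 | paf > 1)) stop("'paf' must be in [0, 1]", call. = FALSE)
  if (any(d_total < 0)) stop("'d_total' must be >= 0", call. = FALSE)
  paf * d_total
}

#' Fixed-fraction attribution by sex
#'
#' For endpoints attributed as a fixed proportion of observed cases (e.g.
#' asbestos-related disease at 100%, or sex-specific fractions of
#' mesothelioma): `frac_male * cases_male + frac_female * cases_female`.
#'
#' @param cases_male,cases_female observed cases by sex (>= 0).
#' @param frac_male,frac_female attributed proportions in \[0, 1\].
#' @return attributable count.
#' @export
fixed_fraction_attribution <- function(cases_male, cases_female,
                                       frac_male, frac_female) {
  if (any(c(cases_male, cases_female) < 0))
    stop("case counts must be >= 0", call. = FALSE)
  if (any(c(frac_male, frac_female) < 0 | c(frac_male, frac_female) > 1))
    stop("fractions must be in [0, 1]", call. = FALSE)
  frac_male * cases_male + frac_female * cases_female
}
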