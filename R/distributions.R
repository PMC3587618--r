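#' Declarative distribution specifications
#'
#' A `dist_spec` describes one random input of the burden-of-disease model:
#' a distribution kind plus its parameters, with an optional lower
#' truncation bound in natural units. Specs are the unit of uncertainty and
#' variability: relative risks, exposure prevalences, concentrations and
#' population fractions are all carried around as `dist_spec` objects and
#' only turned into numbers by the sampler or by quadrature.
#'
#' Supported kinds and their parameters:
#' \describe{
#'   \item{point}{`value` — a degenerate (deterministic) input.}
#'   \item{uniform}{`lower`, `upper`.}
#'   \item{triangular}{`lower`, `mode`, `upper`.}
#'   \item{lognormal}{`meanlog`, `sdlog` (log-scale location and scale).}
#'   \item{normal}{`mean`, `sd`.}
#'   \item{bernoulli}{`prob`.}
#' }
#'
#' @param kind distribution kind, one of `"point"`, `"uniform"`,
#'   `"triangular"`, `"lognormal"`, `"normal"`, `"bernoulli"`.
#' @param ... kind-specific named parameters (see Details).
#' @param truncate_lower optional lower truncation bound in natural units;
#'   sampling and quadrature then use the inverse CDF on the truncated
#'   support, so no draw falls below the bound and stratification is
#'   preserved.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("uniform", lower = 1, upper = 4)
#' dist_spec("normal", mean = 50, sd = 20, truncate_lower = 0)
#' @export
dist_spec <- function(kind, ..., truncate_lower = NULL) {
  kind <- match.arg(kind,
    c("point", "uniform", "triangular", "lognormal", "normal", "bernoulli"))
  p <- list(...)
  need <- function(nms) {
    miss <- setdiff(nms, names(p))
    if (length(miss))
      stop(sprintf("dist_spec('%s'): missing parameter(s): %s",
                   kind, paste(miss, collapse = ", ")), call. = FALSE)
    for (nm in nms)
      if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
        stop(sprintf("dist_spec('%s'): parameter '%s' must be a finite number",
                     kind, nm), call. = FALSE)
  }
  switch(kind,
    point = need("value"),
    uniform = {
      need(c("lower", "upper"))
      if (p$lower > p$upper)
        stop("dist_spec('uniform'): 'lower' must be <= 'upper'", call. = FALSE)
    },
    triangular = {
      need(c("lower", "mode", "upper"))
      if (p$lower > p$mode || p$mode > p$upper)
        stop("dist_spec('triangular'): need lower <= mode <= upper",
             call. = FALSE)
    },
    lognormal = {
      need(c("meanlog", "sdlog"))
      if (p$sdlog < 0)
        stop("dist_spec('lognormal'): 'sdlog' must be >= 0", call. = FALSE)
    },
    normal = {
      need(c("mean", "sd"))
      if (p$sd < 0) stop("dist_spec('normal'): 'sd' must be >= 0",
                         call. = FALSE)
    },
    bernoulli = {
      need("prob")
      if (p$prob < 0 || p$prob > 1)
        stop("dist_spec('bernoulli'): 'prob' must be in [0, 1]", call. = FALSE)
    })
  if (!is.null(truncate_lower) &&
      (!is.numeric(truncate_lower) || length(truncate_lower) != 1L))
    stop("'truncate_lower' must be a single number", call. = FALSE)
  structure(list(kind = kind, params = p, truncate_lower = truncate_lower),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  ps <- paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
              collapse = ", ")
  tr <- if (is.null(x$truncate_lower)) ""
        else sprintf(" [truncated below at %g]", x$truncate_lower)
  cat(sprintf("<dist_spec> %s(%s)%s\n", x$kind, ps, tr))
  invisible(x)
}

# Shorthand constructors ------------------------------------------------

#' @rdname dist_spec
#' @param value,lower,upper,mode,meanlog,sdlog,mean,sd,prob distribution
#'   parameters, passed through to [dist_spec()].
#' @export
dist_point <- function(value) dist_spec("point", value = value)

#' @rdname dist_spec
#' @export
dist_uniform <- function(lower, upper)
  dist_spec("uniform", lower = lower, upper = upper)

#' @rdname dist_spec
#' @export
dist_triangular <- function(lower, mode, upper)
  dist_spec("triangular", lower = lower, mode = mode, upper = upper)

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog, truncate_lower = NULL)
  dist_spec("lognormal", meanlog = meanlog, sdlog = sdlog,
            truncate_lower = truncate_lower)

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd, truncate_lower = NULL)
  dist_spec("normal", mean = mean, sd = sd, truncate_lower = truncate_lower)

#' @rdname dist_spec
#' @export
dist_bernoulli <- function(prob) dist_spec("bernoulli", prob = prob)

is_dist_spec <- function(x) inherits(x, "dist_spec")

# Published-summary conversions ----------------------------------------

#' Lognormal spec from a published central estimate and 95% CI
#'
#' Epidemiologic relative risks are usually published as a central estimate
#' with a 95% confidence interval and are conventionally modelled as
#' lognormal. This anchors the published central estimate at the *median*
#' of the lognormal (`meanlog = log(median)`), which preserves the printed
#' point estimate under the log transform, and fits the single log-scale
#' spread parameter from the CI ratio:
#' `sdlog = log(ucl / lcl) / (2 * 1.96)`.
#'
#' When the printed CI is asymmetric around the central estimate only the
#' upper/lower ratio is used, never either half-width alone.
#'
#' @param median published central estimate (> 0).
#' @param lcl,ucl published 95% confidence limits, `0 < lcl <= median <= ucl`.
#' @return a lognormal `dist_spec` whose median equals `median`.
#' @examples
#' lognormal_from_median_ci(1.25, 1.17, 1.32)
#' @export
lognormal_from_median_ci <- function(median, lcl, ucl) {
  if (!is.numeric(median) || median <= 0)
    stop("'median' must be a positive number", call. = FALSE)
  if (!is.numeric(lcl) || lcl <= 0)
    stop("'lcl' must be a positive number", call. = FALSE)
  if (!is.numeric(ucl) || ucl <= 0)
    stop("'ucl' must be a positive number", call. = FALSE)
  if (lcl > median) stop("'lcl' must be <= 'median'", call. = FALSE)
  if (ucl < median) stop("'ucl' must be >= 'median'", call. = FALSE)
  dist_lognormal(meanlog = log(median),
                 sdlog = log(ucl / lcl) / (2 * stats::qnorm(0.975)))
}

#' Lognormal spec from a published arithmetic mean and SD
#'
#' Moment-matched lognormal for exposure distributions reported as an
#' arithmetic mean and standard deviation (e.g. household concentration
#' surveys): `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`, so that the arithmetic mean and sd
#' of the spec equal the inputs. `sd = 0` degenerates to a point mass at
#' `mean` (represented as a lognormal with `sdlog = 0`).
#'
#' @param mean arithmetic mean (> 0).
#' @param sd arithmetic standard deviation (>= 0).
#' @return a lognormal `dist_spec`.
#' @examples
#' lognormal_from_mean_sd(14.4, 7.37)
#' @export
lognormal_from_mean_sd <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0)
    stop("'mean' must be a positive number", call. = FALSE)
  if (!is.numeric(sd) || sd < 0)
    stop("'sd' must be a non-negative number", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  dist_lognormal(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Quantile / CDF machinery ----------------------------------------------

q_triangular <- function(p, lower, mode, upper) {
  if (upper == lower) return(rep(lower, length(p)))
  f <- (mode - lower) / (upper - lower)
  out <- ifelse(p < f,
                lower + sqrt(p * (upper - lower) * (mode - lower)),
                upper - sqrt((1 - p) * (upper - lower) * (upper - mode)))
  # guard endpoints against floating error
  pmin(pmax(out, lower), upper)
}

p_triangular <- function(q, lower, mode, upper) {
  if (upper == lower) return(as.numeric(q >= lower))
  out <- numeric(length(q))
  below <- q <= lower; above <- q >= upper
  left <- !below & !above & q < mode
  right <- !below & !above & !left
  if (mode > lower)
    out[left] <- (q[left] - lower)^2 / ((upper - lower) * (mode - lower))
  if (upper > mode)
    out[right] <- 1 - (upper - q[right])^2 / ((upper - lower) * (upper - mode))
  out[above] <- 1
  out
}

q_raw <- function(spec, p) {
  pr <- spec$params
  switch(spec$kind,
    point = rep(pr$value, length(p)),
    uniform = stats::qunif(p, pr$lower, pr$upper),
    triangular = q_triangular(p, pr$lower, pr$mode, pr$upper),
    lognormal = if (pr$sdlog == 0) rep(exp(pr$meanlog), length(p))
                else stats::qlnorm(p, pr$meanlog, pr$sdlog),
    normal = if (pr$sd == 0) rep(pr$mean, length(p))
             else stats::qnorm(p, pr$mean, pr$sd),
    bernoulli = as.numeric(p > 1 - pr$prob))
}

p_raw <- function(spec, q) {
  pr <- spec$params
  switch(spec$kind,
    point = as.numeric(q >= pr$value),
    uniform = stats::punif(q, pr$lower, pr$upper),
    triangular = p_triangular(q, pr$lower, pr$mode, pr$upper),
    lognormal = if (pr$sdlog == 0) as.numeric(q >= exp(pr$meanlog))
                else stats::plnorm(q, pr$meanlog, pr$sdlog),
    normal = if (pr$sd == 0) as.numeric(q >= pr$mean)
             else stats::pnorm(q, pr$mean, pr$sd),
    bernoulli = ifelse(q < 0, 0, ifelse(q < 1, 1 - pr$prob, 1)))
}

#' Quantile function of a distribution spec
#'
#' Inverse CDF of a [dist_spec()], honouring its truncation bound: for a
#' spec truncated below at `a`, probabilities are remapped onto
#' `[F(a), 1]` before inversion, so the truncated mass is renormalized and
#' Latin hypercube stratification survives truncation.
#'
#' @param spec a `dist_spec`.
#' @param p vector of probabilities in \[0, 1\].
#' @return vector of quantiles in natural units.
#' @export
q_dist <- function(spec, p) {
  stopifnot(is_dist_spec(spec))
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]",
                               call. = FALSE)
  if (!is.null(spec$truncate_lower)) {
    f0 <- p_raw(spec, spec$truncate_lower)
    if (f0 >= 1)
      stop("truncation bound leaves no probability mass", call. = FALSE)
    p <- f0 + p * (1 - f0)
  }
  out <- q_raw(spec, p)
  if (!is.null(spec$truncate_lower)) out <- pmax(out, spec$truncate_lower)
  out
}

#' Mean of a distribution spec
#'
#' Analytic mean where available; truncated specs fall back to quadrature
#' over 4096 equiprobable quantile points.
#'
#' @param spec a `dist_spec`.
#' @return the mean in natural units.
#' @export
dist_mean <- function(spec) {
  stopifnot(is_dist_spec(spec))
  if (!is.null(spec$truncate_lower))
    return(mean(q_dist(spec, (seq_len(4096) - 0.5) / 4096)))
  pr <- spec$params
  switch(spec$kind,
    point = pr$value,
    uniform = (pr$lower + pr$upper) / 2,
    triangular = (pr$lower + pr$mode + pr$upper) / 3,
    lognormal = exp(pr$meanlog + pr$sdlog^2 / 2),
    normal = pr$mean,
    bernoulli = pr$prob)
}

# Latin hypercube sampler ------------------------------------------------

# Deterministic 32-bit substream seed for a variable, keyed by name, so
# that adding or removing variables never perturbs the draws of others.
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((seed %% 2147483647 + h) %% 2147483647)
}

#' Latin hypercube sample of a set of distribution specs
#'
#' Draws `n` values from each spec by stratified inverse-CDF sampling: the
#' unit interval is split into `n` equiprobable strata, one uniform
#' sub-draw is taken inside each stratum, and the stratum order is
#' independently permuted per variable. Each variable consumes its own
#' deterministically derived random substream (keyed by the variable's
#' name and the root seed), so the draws for a given variable depend only
#' on `(seed, name, n)` and not on which other variables are present.
#'
#' @param specs named list of [dist_spec()] objects.
#' @param n number of iterations (rows), >= 1.
#' @param seed integer root seed.
#' @param method `"lhs"` (default) or `"srs"` for unstratified simple
#'   random sampling through the same substreams (used for comparisons).
#' @return an `n` x `length(specs)` numeric matrix with column names
#'   `names(specs)` and attributes `n` and `seed`; class `sample_matrix`.
#' @examples
#' m <- sample_lhs(list(rr = lognormal_from_median_ci(1.25, 1.17, 1.32)),
#'                 n = 100, seed = 1)
#' colMeans(m)
#' @export
sample_lhs <- function(specs, n, seed, method = c("lhs", "srs")) {
  method <- match.arg(method)
  if (!is.list(specs) || length(specs) == 0L)
    stop("'specs' must be a non-empty named list of dist_spec objects",
         call. = FALSE)
  if (is.null(names(specs)) || any(names(specs) == "") ||
      anyDuplicated(names(specs)))
    stop("'specs' must have unique non-empty names", call. = FALSE)
  ok <- vapply(specs, is_dist_spec, logical(1))
  if (!all(ok))
    stop(sprintf("not dist_spec objects: %s",
                 paste(names(specs)[!ok], collapse = ", ")), call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  out <- matrix(NA_real_, n, length(specs),
                dimnames = list(NULL, names(specs)))
  for (j in seq_along(specs)) {
    u <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(substream_seed(seed, names(specs)[j]))
      if (method == "lhs") {
        perm <- sample.int(n)
        (perm - stats::runif(n)) / n
      } else {
        stats::runif(n)
      }
    })
    out[, j] <- q_dist(specs[[j]], u)
  }
  structure(out, n = n, seed = seed, method = method,
            class = c("sample_matrix", "matrix", "array"))
}

#' Summarize Monte Carlo draws
#'
#' Central estimate and 95% percentile interval of a vector of draws:
#' the mean, and the 2.5th / 97.5th percentiles under the
#' linear-interpolation quantile convention (R's `type = 7`), fixed so
#' reported intervals are reproducible across runs and platforms.
#'
#' @param draws non-empty numeric vector.
#' @return named numeric vector `c(mean, p2.5, p97.5)`.
#' @export
summarize_draws <- function(draws) {
  if (!is.numeric(draws) || length(draws) == 0L)
    stop("'draws' must be a non-empty numeric vector", call. = FALSE)
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(draws), p2.5 = q[1], p97.5 = q[2])
}
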