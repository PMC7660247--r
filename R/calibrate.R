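# AAI-from-ANIb quadratic calibration and the extinction-anchored linear
# dating model.

#' Fit the quadratic AAI-from-ANIb calibration
#'
#' Ordinary least squares of AAI on the quadratic basis
#' `E[AAI] = c0 + c1*ANIb + c2*ANIb^2`. The fitted curve should be
#' monotone non-decreasing on the observed ANIb range for band inversion
#' to be well defined; a violation is warned about, not silently ignored.
#'
#' @param anib,aai Paired percent vectors (or a 2-column data.frame/matrix
#'   in `anib`).
#' @return A `quadratic_model`: list with `c0, c1, c2, rmse, n, domain`.
#' @export
fit_quadratic <- function(anib, aai = NULL) {
  if (is.null(aai)) {
    aai <- anib[[2]]
    anib <- anib[[1]]
  }
  if (length(anib) != length(aai)) stop("anib and aai lengths differ")
  if (length(unique(anib)) < 3)
    stop("need at least 3 distinct anib values")
  fit <- stats::lm(aai ~ anib + I(anib^2))
  cf <- unname(stats::coef(fit))
  model <- quadratic_model(cf[1], cf[2], cf[3],
                           rmse = sqrt(mean(stats::resid(fit)^2)),
                           n = length(anib),
                           domain = range(anib))
  model
}

#' Construct a quadratic calibration model directly
#' @param c0,c1,c2 Coefficients of `c0 + c1*x + c2*x^2`.
#' @param rmse Root-mean-square residual (percent), `NA` if unknown.
#' @param n Number of fitted points.
#' @param domain Numeric length-2 ANIb range on which the model applies.
#' @return A `quadratic_model`.
#' @export
quadratic_model <- function(c0, c1, c2, rmse = NA_real_, n = 0L,
                            domain = c(0, 100)) {
  m <- structure(list(c0 = c0, c1 = c1, c2 = c2, rmse = rmse, n = n,
                      domain = sort(domain)), class = "quadratic_model")
  d <- c1 + 2 * c2 * m$domain      # derivative at the domain endpoints
  if (any(d < -1e-12))
    warning("fitted quadratic is not monotone non-decreasing on its domain")
  m
}

#' Expected AAI at given ANIb values under a quadratic model
#' @param model A `quadratic_model`.
#' @param anib Numeric vector of ANIb percents.
#' @return Numeric vector of expected AAI percents.
#' @export
predict_aai <- function(model, anib) {
  model$c0 + model$c1 * anib + model$c2 * anib^2
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf(
    "<quadratic model: AAI = %.4g + %.4g*ANIb + %.4g*ANIb^2; rmse %.3g, n=%d>\n",
    x$c0, x$c1, x$c2, x$rmse, x$n))
  invisible(x)
}

#' Map an AAI band to the corresponding ANIb interval
#'
#' Inverts the quadratic calibration at each band edge by bisection (to
#' 1e-6) on the model's monotone domain, answering "which ANIb range
#' corresponds to this AAI gap".
#'
#' @param model A `quadratic_model`, monotone on its domain.
#' @param band A [gap_band()] of AAI values.
#' @return Named numeric vector `c(anib_low, anib_high)`.
#' @export
map_aai_band_to_anib <- function(model, band) {
  dom <- model$domain
  f_lo <- predict_aai(model, dom[1])
  f_hi <- predict_aai(model, dom[2])
  if (f_hi < f_lo)
    stop("model is decreasing on its domain; cannot invert")
  invert <- function(target) {
    if (target < f_lo || target > f_hi)
      stop("band edge ", target,
           "% is outside the attainable AAI range [",
           round(f_lo, 3), ", ", round(f_hi, 3), "]")
    stats::uniroot(function(x) predict_aai(model, x) - target,
                   interval = dom, tol = 1e-6)$root
  }
  c(anib_low = invert(band$low), anib_high = invert(band$high))
}

#' A dating anchor point
#'
#' Pairs an ANI value with a time before present, e.g. the identity gap
#' attributed to the Permian extinction (~252 MYA), the Triassic valley
#' (~201 MYA), or 100% ANI for the present.
#'
#' @param ani ANI percent in (0, 100].
#' @param time Time before present in MYA (>= 0).
#' @param label Free-text label.
#' @return An `anchor_point`.
#' @export
anchor_point <- function(ani, time, label = "") {
  if (!(ani > 0 && ani <= 100)) stop("ani must be in (0, 100]")
  if (time < 0) stop("time must be >= 0")
  structure(list(ani = ani, time = time, label = label),
            class = "anchor_point")
}

#' Default extinction anchors for the dating model
#'
#' Permian extinction at the midpoint of the 72.5-74% ANIb gap
#' (73.25%, 252 MYA), Triassic extinction at the ~80% ANIb valley
#' (201 MYA), and 100% ANI for the present. These are interpretive
#' anchors, fully overridable.
#'
#' @return List of [anchor_point()]s.
#' @export
default_dating_anchors <- function() {
  list(anchor_point(73.25, 252, "Permian"),
       anchor_point(80, 201, "Triassic"),
       anchor_point(100, 0, "present"))
}

#' Fit the linear extinction-anchored dating model
#'
#' Ordinary least squares of time (MYA) on ANI percent over the anchor
#' points. The slope must be negative (identity rises toward the present).
#'
#' @param anchors List of [anchor_point()]s with >= 2 distinct ANI values.
#' @return A `dating_model`: list with `slope` (MYA per ANI %),
#'   `intercept` (MYA), `anchors`, `residuals` (MYA).
#' @export
fit_dating <- function(anchors = default_dating_anchors()) {
  ani <- vapply(anchors, `[[`, numeric(1), "ani")
  time <- vapply(anchors, `[[`, numeric(1), "time")
  if (length(unique(ani)) < 2) stop("need >= 2 anchors with distinct ani")
  fit <- stats::lm(time ~ ani)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    warning("dating slope is non-negative; anchors imply identity falling ",
            "toward the present")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 anchors = anchors,
                 residuals = unname(stats::resid(fit))),
            class = "dating_model")
}

#' @export
print.dating_model <- function(x, ...) {
  cat(sprintf("<dating model: time = %.4g %+.4g*ANI MYA (%d anchors)>\n",
              x$intercept, x$slope, length(x$anchors)))
  invisible(x)
}

#' Predicted divergence time at an ANI value
#'
#' @param model A `dating_model`.
#' @param ani ANI percent, within `[min anchor ani, 100]`.
#' @return Predicted time before present (MYA), clamped below at 0.
#' @export
predict_divergence_time <- function(model, ani) {
  lo <- min(vapply(model$anchors, `[[`, numeric(1), "ani"))
  if (any(ani < lo | ani > 100))
    stop("ani outside the anchored range [", lo, ", 100]")
  pmax(0, model$slope * ani + model$intercept)
}
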