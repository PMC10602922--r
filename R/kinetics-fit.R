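## Initial velocities and Michaelis-Menten parameter extraction from
## fluorescence time courses.

#' Initial cleavage velocity of a time course
#'
#' Regresses the fluorescence over the first `windowS` seconds and converts
#' the AU/s slope to nM/s through the calibration (`1 / (mCl - mUcl)`). The
#' default estimator is the protocol's plain linear regression of the first
#' 600 s; `method = "quadratic"` instead fits a second-order polynomial and
#' reports its slope at t = 0, which removes most of the downward bias that
#' substrate depletion imposes on the 600-s chord when `k_cat E0 / (K_M + S)`
#' times the window is not small.
#'
#' @param series A [FluorescenceSeries-class].
#' @param calib A [CalibrationModel-class].
#' @param windowS Window length in seconds (default 600).
#' @param method `"linear"` (default) or `"quadratic"`.
#' @return Velocity in nM/s. A negative estimate beyond the residual noise
#'   level triggers a warning but is returned as-is.
#' @export
initialVelocity <- function(series, calib, windowS = 600,
                            method = c("linear", "quadratic")) {
  stopifnot(is(series, "FluorescenceSeries"), is(calib, "CalibrationModel"))
  method <- match.arg(method)
  denom <- calib@mCl - calib@mUcl
  if (denom <= .Machine$double.eps)
    stop("degenerate calibration: mCl must exceed mUcl")
  keep <- series@times <= windowS
  if (sum(keep) < 5L)
    stop("need at least 5 points inside the initial-velocity window")
  t <- series@times[keep]; f <- series@values[keep]
  if (method == "linear") {
    fit <- stats::lm(f ~ t)
    slope <- stats::coef(fit)[["t"]]
  } else {
    fit <- stats::lm(f ~ t + I(t^2))
    slope <- stats::coef(fit)[["t"]]
  }
  resid <- stats::residuals(fit)
  noise <- stats::sd(resid)
  v <- slope / denom
  if (v < 0 && abs(slope) > 3 * noise / sqrt(length(t)))
    warning("initial velocity is negative beyond the noise level")
  v
}

#' Fit the Michaelis-Menten law to velocity data
#'
#' Nonlinear least squares of `v = k_cat E0 S / (K_M + S)` over substrate
#' titration points, with starting values `k_cat = max(v)/E0` and
#' `K_M = median(S)`. Reports parameters, standard errors and catalytic
#' efficiency `k_cat/K_M` converted to /M/s.
#'
#' @param points data.frame with columns `S` (nM) and `v` (nM/s); replicate
#'   rows at the same `S` are allowed and enter the fit individually.
#' @param e0 Activated enzyme concentration used, nM (> 0).
#' @return An [MMFit-class]. A fitted `K_M` above 100 times the largest
#'   substrate level triggers a "poorly constrained" warning; near-equal
#'   velocities across the titration (saturated limit) are flagged in the
#'   diagnostics.
#' @examples
#' S <- c(31.25, 62.5, 125, 250, 500, 1000, 2000)
#' fitMichaelisMenten(data.frame(S = S, v = 1 * 1 * S / (500 + S)), e0 = 1)
#' @export
fitMichaelisMenten <- function(points, e0) {
  if (!is.data.frame(points) || !all(c("S", "v") %in% names(points)))
    stop("points must be a data.frame with columns S and v")
  stopifnot(e0 > 0)
  sLevels <- sort(unique(points$S))
  if (length(sLevels) < 4L)
    stop("need at least 4 distinct substrate levels")
  if (max(sLevels) / min(sLevels) < 4)
    stop("substrate levels must span at least a 4-fold range")
  start <- list(kcat = max(points$v) / e0, km = stats::median(points$S))
  fit <- try(minpack.lm::nlsLM(v ~ kcat * e0 * S / (km + S),
                               data = points, start = start,
                               lower = c(kcat = 0, km = 0),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Michaelis-Menten fit failed to converge: ",
         attr(fit, "condition")$message)
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kcat = NA_real_, km = NA_real_))
  diagnostics <- list(
    converged = fit$convInfo$isConv,
    residualSS = sum(stats::residuals(fit)^2),
    degenerateSaturated = stats::sd(points$v) < 1e-3 * mean(abs(points$v)))
  if (co[["km"]] > 100 * max(points$S))
    warning("K_M poorly constrained: fitted value exceeds 100x max substrate")
  if (diagnostics$degenerateSaturated)
    warning("velocities nearly constant across substrate levels; ",
            "K_M -> 0 degenerate saturated limit")
  new("MMFit", kCat = co[["kcat"]], kM = co[["km"]],
      kcatOverKM = co[["kcat"]] / co[["km"]] * 1e9, e0 = e0,
      velocities = points[c("S", "v")],
      se = c(kCat = unname(se[1]), kM = unname(se[2])),
      diagnostics = diagnostics)
}

#' Fit the first-order (low-substrate) progress model
#'
#' Fits `c_cl(t) = S0 (1 - exp(-r t))` to a concentration series; in the
#' `S0 << K_M` regime the rate constant `r` estimates `k_cat E0 / K_M`.
#'
#' @param series A [ConcentrationSeries-class] with nondecreasing `cCl`.
#' @return List with elements `rate` (/s) and `S0_hat` (nM).
#' @export
fitFirstOrderLimit <- function(series) {
  stopifnot(is(series, "ConcentrationSeries"))
  t <- series@times; y <- series@cCl
  if (!length(t)) stop("series is empty")
  if (any(diff(y) < -1e-6 * max(y, 1)))
    stop("cCl must be monotone nondecreasing")
  s0Guess <- max(y) * 1.05 + 1e-9
  rGuess <- -log(max(1 - y[length(y)] / s0Guess, 1e-6)) / t[length(t)]
  fit <- try(minpack.lm::nlsLM(y ~ s0 * (1 - exp(-r * t)),
                               data = data.frame(t = t, y = y),
                               start = list(s0 = s0Guess,
                                            r = max(rGuess, 1e-8)),
                               lower = c(s0 = 0, r = 0),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("first-order fit failed to converge: ",
         attr(fit, "condition")$message)
  co <- stats::coef(fit)
  list(rate = co[["r"]], S0_hat = co[["s0"]])
}
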