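# Quantification of in vitro elongation, fidelity and translocation-state
# assays from tabular inputs (time courses and gel band intensities).

#' Runoff time course container
#'
#' @param times observation times, s (a typical grid is 5, 10, 20, 40 s).
#' @param runoff_fraction fraction of runoff product at each time, in
#'   \[0, 1\].
#' @param enzyme label (e.g. `"WT"`, `"G1073A"`).
#' @return data.frame of class `runoff_course`.
#' @export
runoff_course <- function(times, runoff_fraction, enzyme = "WT") {
  if (length(times) != length(runoff_fraction))
    stop("times and runoff_fraction must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(runoff_fraction < 0 | runoff_fraction > 1))
    stop("runoff fractions must lie in [0, 1]")
  structure(data.frame(time_s = times, fraction = runoff_fraction,
                       enzyme = enzyme, stringsAsFactors = FALSE),
            class = c("runoff_course", "data.frame"))
}

#' Read runoff courses from delimited text
#'
#' Expects columns `enzyme`, `time_s`, `fraction` (tab- or
#' comma-separated).
#'
#' @param path input file.
#' @return Named list of [runoff_course()] objects, one per enzyme.
#' @export
read_runoff_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", fill = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("enzyme", "time_s", "fraction") %in% names(df)))
    stop("runoff table needs columns enzyme, time_s, fraction")
  out <- lapply(split(df, df$enzyme), function(d) {
    d <- d[order(d$time_s), ]
    runoff_course(d$time_s, d$fraction, d$enzyme[1L])
  })
  out
}

#' Fit a single-phase exponential to a runoff accumulation course
#'
#' Least-squares fit of `f(t) = A * (1 - exp(-k t))`, the standard model
#' for runoff accumulation; the apparent rate `k` summarises the
#' elongation rate of the enzyme over the transcribed template.  Asymptotic
#' standard errors come from the fit covariance.
#'
#' @param course a [runoff_course()] with at least 3 time points.
#' @param fix_amplitude if `TRUE`, pin A = 1 and fit only `k`.
#' @return List with `k` (1/s), `amplitude`, `se_k`, `se_amplitude`,
#'   `residual_ss`, `flagged` (TRUE when the optimum is degenerate, e.g.
#'   k <= 0 or an all-zero course) and `fit` (the nls object).
#' @export
fit_runoff_exponential <- function(course, fix_amplitude = FALSE) {
  stopifnot(inherits(course, "runoff_course"))
  if (nrow(course) < 3L) stop("need at least 3 time points to fit")
  t <- course$time_s
  y <- course$fraction
  if (all(y == 0))
    return(list(k = NA_real_, amplitude = 0, se_k = NA_real_,
                se_amplitude = NA_real_, residual_ss = 0, flagged = TRUE,
                fit = NULL))
  # start values: amplitude from the plateau, k from a log-linear guess
  A0 <- max(y) * 1.05
  pos <- y > 0 & y < A0
  k0 <- if (any(pos)) {
    max(1e-4, stats::median(-log(pmax(1e-10, 1 - y[pos] / A0)) / t[pos]))
  } else 0.1
  fit <- tryCatch({
    if (fix_amplitude)
      minpack.lm::nlsLM(y ~ 1 - exp(-k * t), start = list(k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)),
                        start = list(A = A0, k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e)
    stop("runoff fit did not converge: ", conditionMessage(e),
         " (times: ", paste(t, collapse = ","), ")"))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  k <- unname(cf["k"])
  A <- if (fix_amplitude) 1 else unname(cf["A"])
  list(k = k, amplitude = A,
       se_k = unname(se["k"]),
       se_amplitude = if (fix_amplitude) 0 else unname(se["A"]),
       residual_ss = sum(stats::residuals(fit)^2),
       flagged = !is.finite(k) || k <= 0,
       fit = fit)
}

#' Relative elongation rate with propagated error
#'
#' Ratio of fitted runoff rates, mutant over wild type, the usual way
#' elongation activities are reported relative to wild-type enzyme at a
#' fixed NTP concentration.  The error is first-order propagation of the
#' two fit standard errors.
#'
#' @param mutant_fit,wildtype_fit results of [fit_runoff_exponential()].
#' @return List with `ratio` and `se`.
#' @export
relative_elongation_rate <- function(mutant_fit, wildtype_fit) {
  kw <- wildtype_fit$k
  km <- mutant_fit$k
  if (!is.finite(kw) || abs(kw) < 1e-12)
    stop("wild-type rate is zero or undefined; ratio not defined")
  if (!is.finite(km)) stop("mutant rate is undefined")
  ratio <- km / kw
  se <- abs(ratio) * sqrt((mutant_fit$se_k / km)^2 +
                          (wildtype_fit$se_k / kw)^2)
  list(ratio = ratio, se = se)
}

#' Band intensity table
#'
#' One gel lane: named, nonnegative band intensities (e.g. `pre`/`post`
#' for exonuclease III footprints, `G10`/`A10` for competition fidelity
#' products).
#'
#' @param lane lane label.
#' @param intensities named numeric vector of at least two bands.
#' @return Object of class `band_table`.
#' @export
band_table <- function(lane, intensities) {
  if (length(intensities) < 2L || is.null(names(intensities)))
    stop("need at least two named band intensities")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("band intensities must be finite and nonnegative")
  structure(list(lane = lane, intensities = intensities),
            class = "band_table")
}

#' Read band tables from delimited text
#'
#' Expects columns `lane`, `band`, `intensity`.
#'
#' @param path input file.
#' @return Named list of [band_table()] objects, one per lane.
#' @export
read_band_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", fill = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("lane", "band", "intensity") %in% names(df)))
    stop("band table needs columns lane, band, intensity")
  lapply(split(df, df$lane), function(d)
    band_table(d$lane[1L], stats::setNames(d$intensity, d$band)))
}

#' Misincorporation ratio from a competition fidelity assay
#'
#' In the competition assay the correct substrate (limiting GTP, product
#' band `G10`) competes with an incorrect substrate at high concentration
#' (ATP, misincorporated product band `A10`); the error fraction is
#' error / (error + correct).
#'
#' @param bands a [band_table()] carrying the correct and error bands.
#' @param correct,error band names (defaults `"G10"`, `"A10"`).
#' @param display `"fraction"` (default), `"complement"` (1 - fraction) or
#'   `"reciprocal"` (correct/error, a fidelity ratio).
#' @return List with `error_fraction` (in \[0, 1\], `NA` and
#'   `flagged = TRUE` when both bands are zero) and `display_value`.
#' @export
misincorporation_ratio <- function(bands, correct = "G10", error = "A10",
                                   display = c("fraction", "complement",
                                               "reciprocal")) {
  stopifnot(inherits(bands, "band_table"))
  display <- match.arg(display)
  for (b in c(correct, error))
    if (!b %in% names(bands$intensities))
      stop("band not present in lane: ", b)
  g <- bands$intensities[[correct]]
  a <- bands$intensities[[error]]
  if (g + a == 0)
    return(list(error_fraction = NA_real_, display_value = NA_real_,
                flagged = TRUE))
  f <- a / (a + g)
  dv <- switch(display, fraction = f, complement = 1 - f,
               reciprocal = if (a == 0) Inf else g / a)
  list(error_fraction = f, display_value = dv, flagged = FALSE)
}

#' Pre/post translocation-state fractions from an exonuclease III footprint
#'
#' Normalised fractions of the pre- and post-translocated borders from one
#' footprinting lane; the two fractions sum to 1.
#'
#' @param bands a [band_table()] with `pre` and `post` bands.
#' @return Named numeric vector `c(pre = ..., post = ...)`.
#' @export
translocation_state_fractions <- function(bands) {
  stopifnot(inherits(bands, "band_table"))
  for (b in c("pre", "post"))
    if (!b %in% names(bands$intensities))
      stop("band not present in lane: ", b)
  p <- bands$intensities[["pre"]]
  q <- bands$intensities[["post"]]
  if (p + q == 0) stop("pre and post bands are both zero")
  c(pre = p / (p + q), post = q / (p + q))
}

#' NTP stimulation of the post-translocated state
#'
#' Fold change and percent increase of the post-translocated fraction
#' induced by the incoming cognate NTP.  A shift from 0.25 to 0.51 is an
#' approximately 2-fold (fold 2.04, +104 percent) stimulation.
#'
#' @param post_without_ntp post-translocated fraction without NTP, (0, 1\].
#' @param post_with_ntp post-translocated fraction with NTP, (0, 1\].
#' @return List with `fold` and `percent_increase`.
#' @examples
#' ntp_stimulation(0.25, 0.51)
#' @export
ntp_stimulation <- function(post_without_ntp, post_with_ntp) {
  if (post_without_ntp <= 0)
    stop("post fraction without NTP must be positive")
  if (post_without_ntp > 1 || post_with_ntp <= 0 || post_with_ntp > 1)
    stop("fractions must lie in (0, 1]")
  fold <- post_with_ntp / post_without_ntp
  list(fold = fold, percent_increase = 100 * (fold - 1))
}
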