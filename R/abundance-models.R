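#' Negative binomial regression of grouped fungal counts on a damage factor
#'
#' Fits `y_i ~ NegBin(mu_i, theta)` with
#' `log mu_i = b0 + sum_k b_k 1[x_i = k] + offset_i`, the dispersion `theta`
#' estimated by alternating maximum likelihood (the `MASS::glm.nb`
#' algorithm: IRLS for the coefficients interleaved with a score step for
#' theta). With the offset set to the log total reads of each sample, the
#' exponentiated non-reference coefficients are multiplicative changes in
#' *relative* abundance against the reference (no-damage) level; with no
#' offset the same model describes absolute abundance. Counts of grouped
#' taxa (guild or ERMI group sums) contain few zeros, so no zero adjustment
#' is applied; per-taxon counts would need a zero-adjusted variant, which
#' is out of scope here.
#'
#' Absolute-abundance responses (relative abundance x qPCR biomass) are not
#' integers; round them to the nearest integer before fitting, keeping the
#' biomass scale large (>= 1e3) so the rounding error is negligible.
#'
#' @param y Nonnegative integer response counts, one per sample.
#' @param x Damage category per sample (factor or character). The reference
#'   level is the no-damage category: the first of `ref`, if given, else
#'   the factor's first level.
#' @param offset_log_total Optional per-sample log total reads. `NULL`
#'   fits without an offset (absolute-abundance mode).
#' @param ref Optional reference level name.
#' @param damage_var Name of the damage variable, for reporting.
#' @return An object of class `nbfit` with components `coefficients`,
#'   `standard_errors`, `theta`, `log_likelihood`, `aic` (with theta
#'   counted as a parameter), `offset_used`, `design` (variable, levels,
#'   reference, per-level n) and the underlying glm fit.
#' @seealso [relative_change()], [wald_z_p()], [lrt_2df()],
#'   [compare_poisson_nb()]
#' @examples
#' set.seed(1)
#' n <- 60
#' x <- rep(c("no", "yes"), each = n / 2)
#' off <- log(sample(1e4:5e4, n, TRUE))
#' y <- rnbinom(n, mu = exp(-4 + log(2) * (x == "yes") + off), size = 2)
#' fit <- fit_nb(y, x, off)
#' relative_change(fit, "yes")
#' @export
fit_nb <- function(y, x, offset_log_total = NULL, ref = NULL,
                   damage_var = "damage") {
  if (any(y < 0) || any(y != round(y)))
    stop("y must be nonnegative integer counts")
  if (all(y == 0))
    stop("all responses are zero; grouped-taxon models assume few zeros ",
         "and a zero-adjusted model is out of scope")
  x <- as.factor(x)
  if (!is.null(ref)) x <- stats::relevel(x, ref = ref)
  x <- droplevels(x)
  n_lev <- table(x)
  if (any(n_lev < 2))
    stop("each damage level needs at least 2 samples; offending: ",
         paste(names(n_lev)[n_lev < 2], collapse = ", "))
  offset_used <- !is.null(offset_log_total)
  dat <- data.frame(y = y, x = x)
  if (offset_used) {
    if (length(offset_log_total) != length(y))
      stop("offset_log_total must match y in length")
    dat$off <- offset_log_total
  } else dat$off <- 0
  form <- if (nlevels(x) > 1) y ~ x + offset(off) else y ~ 1 + offset(off)
  # theta.ml's "iteration limit reached" warning just means theta drifted
  # very large (near-Poisson data) and is muffled. If the alternating
  # algorithm breaks down because the dispersion diverges (equidispersed
  # data), the fit is taken at the Poisson limit with a large fixed theta.
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(form, data = dat,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) e)
  if (inherits(fit, "error")) {
    theta_cap <- 1e6
    fit <- tryCatch(
      stats::glm(form, data = dat,
                 family = MASS::negative.binomial(theta_cap),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      error = function(e)
        stop("negative binomial fit failed to converge: ",
             conditionMessage(e), call. = FALSE))
    fit$theta <- theta_cap
    ll <- sum(stats::dnbinom(y, mu = stats::fitted(fit), size = theta_cap,
                             log = TRUE))
    fit$aic <- -2 * ll + 2 * (length(stats::coef(fit)) + 1)
    fit$twologlik <- 2 * ll
  }
  if (!isTRUE(fit$converged))
    stop("negative binomial IRLS did not converge within 100 iterations ",
         "(final deviance ", signif(fit$deviance, 6), ")", call. = FALSE)
  beta <- stats::coef(fit)
  names(beta) <- sub("^x", "", names(beta))
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- names(beta)
  structure(list(coefficients = beta,
                 standard_errors = se,
                 theta = fit$theta,
                 log_likelihood = fit$twologlik / 2,
                 aic = fit$aic,
                 offset_used = offset_used,
                 design = list(damage_var = damage_var,
                               levels = levels(x),
                               reference = levels(x)[1],
                               n_per_level = as.integer(n_lev)),
                 glm_fit = fit),
            class = "nbfit")
}

#' @export
print.nbfit <- function(x, ...) {
  cat("Negative binomial abundance model",
      if (x$offset_used) "(log-total offset: relative abundance)"
      else "(no offset: absolute abundance)", "\n")
  cat("damage variable:", x$design$damage_var,
      " reference:", x$design$reference, "\n")
  est <- exp(x$coefficients[-1])
  if (length(est)) {
    cat("relative changes vs reference:\n")
    print(round(est, 4))
  } else cat("(intercept-only fit)\n")
  cat("theta:", signif(x$theta, 4), " AIC:", round(x$aic, 2), "\n")
  invisible(x)
}

#' @export
summary.nbfit <- function(object, ...) {
  z <- object$coefficients / object$standard_errors
  tab <- data.frame(estimate = object$coefficients,
                    rel_change = exp(object$coefficients),
                    se = object$standard_errors,
                    z = z,
                    p_wald = 2 * stats::pnorm(-abs(z)))
  structure(list(table = tab, theta = object$theta, aic = object$aic,
                 log_likelihood = object$log_likelihood,
                 offset_used = object$offset_used, design = object$design),
            class = "summary.nbfit")
}

#' @export
print.summary.nbfit <- function(x, ...) {
  print(x$table)
  cat("theta:", signif(x$theta, 4), " logLik:", round(x$log_likelihood, 2),
      " AIC:", round(x$aic, 2), "\n")
  invisible(x)
}

#' @export
coef.nbfit <- function(object, ...) object$coefficients

#' @export
logLik.nbfit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients) + 1L, class = "logLik")
}

#' @export
predict.nbfit <- function(object, newdata = NULL, type = "response", ...) {
  stats::predict(object$glm_fit, newdata = newdata, type = type, ...)
}

#' @export
residuals.nbfit <- function(object, ...) stats::residuals(object$glm_fit, ...)

#' @export
simulate.nbfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::fitted(object$glm_fit)
  as.data.frame(replicate(nsim,
    stats::rnbinom(length(mu), mu = mu, size = object$theta)))
}

#' Multiplicative change in abundance for a damage level
#'
#' The exponentiated model coefficient of a damage level is the
#' multiplicative change in (relative or absolute) abundance in that level
#' compared to the no-damage reference. For two-level designs a two-sided
#' Wald Z p-value is attached; three-level designs should be judged with
#' the likelihood-ratio test ([lrt_2df()]) instead.
#'
#' @param fit An [fit_nb()] object.
#' @param level Damage level name; the reference level returns 1 with an
#'   undefined p-value.
#' @return A list (`relative_change_estimate`) with `level`,
#'   `relative_change`, `p_value`, `test`.
#' @export
relative_change <- function(fit, level) {
  stopifnot(inherits(fit, "nbfit"))
  if (!level %in% fit$design$levels)
    stop("level '", level, "' not in the design (levels: ",
         paste(fit$design$levels, collapse = ", "), ")")
  if (level == fit$design$reference)
    return(structure(list(level = level, relative_change = 1,
                          p_value = NA_real_, test = "reference"),
                     class = "relative_change_estimate"))
  est <- exp(fit$coefficients[[level]])
  two_level <- length(fit$design$levels) == 2
  p <- if (two_level) wald_z_p(fit, level) else NA_real_
  structure(list(level = level, relative_change = est, p_value = p,
                 test = if (two_level) "wald_z" else "lrt_chi2_2df"),
            class = "relative_change_estimate")
}

#' @export
print.relative_change_estimate <- function(x, ...) {
  cat(sprintf("level %s: relative change %.4g (test %s, p = %.4g)\n",
              x$level, x$relative_change, x$test, x$p_value))
  invisible(x)
}

#' Two-sided Wald Z p-value on a damage coefficient
#'
#' Appropriate for two-category damage variables; for three categories the
#' two-degree-of-freedom likelihood ratio test ([lrt_2df()]) is the
#' intended test and this function refuses.
#'
#' @param fit An [fit_nb()] object with a two-level design.
#' @param level Non-reference level name.
#' @return Two-sided normal p-value on `beta / se`.
#' @export
wald_z_p <- function(fit, level) {
  stopifnot(inherits(fit, "nbfit"))
  if (length(fit$design$levels) > 2)
    stop("Wald Z is for 2-category designs; use lrt_2df for ",
         length(fit$design$levels), " categories")
  if (!level %in% names(fit$coefficients))
    stop("no coefficient for level '", level, "'")
  z <- fit$coefficients[[level]] / fit$standard_errors[[level]]
  2 * stats::pnorm(-abs(z))
}

#' Likelihood-ratio chi-square test of full vs reduced model
#'
#' For a three-category damage variable the full model carries both
#' non-reference terms and the reduced model neither; the statistic
#' `2 (l_full - l_reduced)` is referred to a chi-square with degrees of
#' freedom equal to the difference in coefficient counts (two, in the
#' three-category case).
#'
#' @param full,reduced Nested [fit_nb()] objects on the same data and
#'   offset policy.
#' @return P-value, with the statistic and df as attributes.
#' @export
lrt_2df <- function(full, reduced) {
  stopifnot(inherits(full, "nbfit"), inherits(reduced, "nbfit"))
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0) stop("reduced model must be nested in the full model")
  stat <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (stat < -1e-6)
    stop("full model has lower likelihood than reduced: non-convergence")
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = max(df, 1L), lower.tail = FALSE)
  attr(p, "statistic") <- stat
  attr(p, "df") <- df
  p
}

#' Compare negative binomial and Poisson fits by AIC
#'
#' Overdispersed microbial counts are fit better by the negative binomial
#' than by the Poisson; this comparison makes that check explicit for a
#' given response.
#'
#' @inheritParams fit_nb
#' @return List with `aic_poisson`, `aic_nb`, `preferred`.
#' @export
compare_poisson_nb <- function(y, x, offset_log_total = NULL, ref = NULL) {
  nb <- fit_nb(y, x, offset_log_total, ref = ref)
  xf <- as.factor(x)
  if (!is.null(ref)) xf <- stats::relevel(xf, ref = ref)
  dat <- data.frame(y = y, x = droplevels(xf),
                    off = if (is.null(offset_log_total)) 0
                          else offset_log_total)
  form <- if (nlevels(dat$x) > 1) y ~ x + offset(off) else y ~ 1 + offset(off)
  pois <- stats::glm(form, data = dat, family = stats::poisson())
  list(aic_poisson = stats::AIC(pois), aic_nb = nb$aic,
       preferred = if (nb$aic < stats::AIC(pois)) "negative_binomial"
                   else "poisson")
}
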