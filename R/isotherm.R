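## Langmuir-like adsorption isotherm: a finite density of equivalent
## polymer-atom binding sites on the protein surface, A_s + P_s <=> A_P,
## gives AP = Ps_max Ka As / (1 + Ka As). The "literal" variant
## Ps_max Ka As / (Ka + As) is kept behind a flag for comparison; the
## standard form is the default because it saturates at Ps_max (which is
## what a maximum binding-site concentration means) and yields shell
## enrichment for the fitted parameter scale.

#' Evaluate the Langmuir isotherm
#'
#' @param Ps_max maximum shell binding-site concentration (fraction, in
#'   (0, 1]).
#' @param Ka dimensionless equilibrium constant (> 0).
#' @param As bulk polymer heavy-atom fraction(s).
#' @param form `"standard"`: `Ps_max Ka As / (1 + Ka As)` (default);
#'   `"literal"`: `Ps_max Ka As / (Ka + As)`.
#' @return Shell polymer fraction(s) `AP`.
#' @export
langmuir_ap <- function(Ps_max, Ka, As, form = c("standard", "literal")) {
  form <- match.arg(form)
  if (form == "standard") Ps_max * Ka * As / (1 + Ka * As)
  else Ps_max * Ka * As / (Ka + As)
}

#' Fit the Langmuir isotherm to shell-fraction data
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of `AP` against
#' `As`, with weights `1/sd^2` when per-point standard deviations are
#' available. A fixed log-spaced grid of `Ka` starting values guards
#' against local minima; the fit is deterministic given the data.
#'
#' @param data data.frame with columns `As`, `AP` and optionally `sd`
#'   (e.g. [generate_isotherm_data()] or assembled from [shell_fraction()]
#'   means).
#' @param fix_psmax optional fixed value of `Ps_max` (used when too few
#'   concentrations are available to identify both parameters).
#' @param form see [langmuir_ap()].
#' @param weighted use `1/sd^2` weights when `sd` is present.
#' @return List of class `langmuir_fit`: `Ps_max`, `Ka`, `se` (named
#'   standard errors), `fixed_psmax` flag, `rss`, `fitted`, `form`.
#' @export
fit_langmuir <- function(data, fix_psmax = NULL,
                         form = c("standard", "literal"), weighted = TRUE) {
  form <- match.arg(form)
  if (!all(c("As", "AP") %in% names(data)))
    stop("data needs columns As and AP", call. = FALSE)
  As <- data$As; AP <- data$AP
  if (!is.null(fix_psmax) && fix_psmax <= 0)
    stop("fix_psmax must be > 0", call. = FALSE)
  need <- if (is.null(fix_psmax)) 2L else 1L
  if (length(As) < need)
    stop("need at least ", need, " isotherm point(s)", call. = FALSE)
  if (is.null(fix_psmax) && length(unique(As)) < 2L)
    stop("all As identical: cannot identify two parameters", call. = FALSE)
  w <- if (weighted && "sd" %in% names(data) && all(data$sd > 0))
    1 / data$sd^2 else rep(1, length(As))

  if (!is.null(fix_psmax) && length(As) == 1L) {
    ## 1-dof exact inversion through the single point
    ap <- AP[1]; as_ <- As[1]
    if (ap >= fix_psmax && form == "standard")
      stop("point lies at or above the fixed Ps_max plateau", call. = FALSE)
    Ka <- if (form == "standard") ap / (as_ * (fix_psmax - ap))
          else ap * as_ / (fix_psmax * as_ - ap)
    fit <- list(Ps_max = fix_psmax, Ka = Ka,
                se = c(Ps_max = NA_real_, Ka = NA_real_),
                fixed_psmax = TRUE, rss = 0,
                fitted = langmuir_ap(fix_psmax, Ka, As, form), form = form)
    class(fit) <- "langmuir_fit"
    return(fit)
  }

  model_fun <- function(psm, ka) langmuir_ap(psm, ka, As, form)
  ka_grid <- c(0.1, 1, 10, 100)
  psm_start <- if (is.null(fix_psmax)) min(max(AP) * 1.2, 1) else fix_psmax
  if (psm_start <= 0) psm_start <- 0.5
  best <- NULL
  for (ka0 in ka_grid) {
    fml <- if (is.null(fix_psmax))
      AP ~ langmuir_ap(Ps_max, Ka, As, form = form)
    else AP ~ langmuir_ap(fix_psmax, Ka, As, form = form)
    start <- if (is.null(fix_psmax)) list(Ps_max = psm_start, Ka = ka0)
             else list(Ka = ka0)
    lower <- if (is.null(fix_psmax)) c(Ps_max = 1e-8, Ka = 1e-8)
             else c(Ka = 1e-8)
    fit_try <- tryCatch(
      minpack.lm::nlsLM(fml,
                        data = list(AP = AP, As = As, form = form,
                                    fix_psmax = fix_psmax),
                        start = start, weights = w, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit_try)) {
      rss <- sum(w * residuals(fit_try)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit_try, rss = rss)
    }
  }
  if (is.null(best))
    stop("Langmuir fit failed to converge from any starting value; ",
         "check that AP increases with As", call. = FALSE)
  cf <- coef(best$fit)
  sm <- tryCatch(summary(best$fit)$coefficients,
                 error = function(e) NULL)
  se <- c(Ps_max = NA_real_, Ka = NA_real_)
  if (!is.null(sm)) {
    if ("Ps_max" %in% rownames(sm)) se["Ps_max"] <- sm["Ps_max", "Std. Error"]
    if ("Ka" %in% rownames(sm)) se["Ka"] <- sm["Ka", "Std. Error"]
  }
  out <- list(
    Ps_max = if (is.null(fix_psmax)) unname(cf["Ps_max"]) else fix_psmax,
    Ka = unname(cf["Ka"]), se = se,
    fixed_psmax = !is.null(fix_psmax), rss = best$rss,
    fitted = unname(fitted(best$fit)), form = form)
  class(out) <- "langmuir_fit"
  out
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf(
    "langmuir_fit (%s form): Ps_max = %.4g%s, Ka = %.4g +- %.2g%s\n",
    x$form, x$Ps_max,
    if (x$fixed_psmax) " (fixed)" else sprintf(" +- %.2g", x$se["Ps_max"]),
    x$Ka, x$se["Ka"],
    sprintf("  (RSS %.3g)", x$rss)))
  invisible(x)
}
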