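#' Calibrate raw fluorescence into viable fractions
#'
#' Linear calibration against the plate's background and untreated
#' control: `fraction = (signal - background) / (mean control -
#' background)`, clipped to \[0, 1\]. Background rows carry
#' `role = "background"`; control rows are zero-concentration samples.
#'
#' @param raw Tibble with columns `concentration_uM`, `fluorescence`,
#'   `replicate` and `role` (`"sample"` or `"background"`).
#' @return A viability tibble (`concentration_uM`, `fraction_alive`,
#'   `replicate`).
#' @export
normalize_viability <- function(raw) {
  need <- c("concentration_uM", "fluorescence", "replicate", "role")
  if (!all(need %in% names(raw))) {
    up_abort("raw table needs concentration_uM, fluorescence, replicate, role")
  }
  bg_rows <- raw$role == "background"
  ctrl_rows <- !bg_rows & raw$concentration_uM == 0
  if (!any(bg_rows) || !any(ctrl_rows)) {
    up_abort("background and 0-concentration control rows are required")
  }
  bg <- mean(raw$fluorescence[bg_rows])
  ctrl <- mean(raw$fluorescence[ctrl_rows])
  if (ctrl <= bg) up_abort("control signal must exceed background")
  s <- raw[!bg_rows, ]
  tibble::tibble(
    concentration_uM = s$concentration_uM,
    fraction_alive = pmin(1, pmax(0, (s$fluorescence - bg) / (ctrl - bg))),
    replicate = s$replicate
  )
}

#' Probit dose-response fit for IC50
#'
#' Regresses the probit of the dead fraction on log10 concentration by
#' iteratively reweighted least squares (quasi-binomial GLM with probit
#' link, or logit with `link = "logit"`); zero-concentration control rows
#' are excluded. The IC50 is `10^(-intercept/slope)` with a delta-method
#' standard error. Fractions of exactly 0 or 1 are nudged by `1/(2n)`
#' so the transform stays finite.
#'
#' @param table Viability tibble (`concentration_uM`, `fraction_alive`,
#'   `replicate`); needs >= 3 distinct nonzero concentrations.
#' @param link `"probit"` (default) or `"logit"`.
#' @return An object of class `ic50_fit`: `ic50` (uM), `se` (uM),
#'   `slope` (per log10 uM), `intercept`, `n`, `converged`, plus the
#'   underlying `glm` fit.
#' @export
#' @examples
#' tab <- gen_dose_response(15, slope = 2, noise_sd = 0, seed = 1)
#' fit_probit_ic50(tab)
fit_probit_ic50 <- function(table, link = c("probit", "logit")) {
  link <- match.arg(link)
  d <- table[table$concentration_uM > 0, ]
  if (length(unique(d$concentration_uM)) < 3) {
    up_abort("need >= 3 distinct nonzero concentrations")
  }
  n <- nrow(d)
  dead <- 1 - d$fraction_alive
  dead <- pmin(1 - 1 / (2 * n), pmax(1 / (2 * n), dead))
  if (stats::sd(dead) < 1e-12) {
    up_abort("probit fit impossible: response may be flat or non-monotone")
  }
  x <- log10(d$concentration_uM)
  fit <- glm(dead ~ x, family = quasibinomial(link = link),
             control = list(epsilon = 1e-8, maxit = 100))
  b <- coef(fit)
  if (!fit$converged || !all(is.finite(b)) || b[2] <= 0) {
    up_abort(paste0(
      "probit fit did not converge to an increasing dose-response ",
      "(slope = ", signif(b[2], 3), "); response may be flat or non-monotone"))
  }
  log_ic50 <- unname(-b[1] / b[2])
  V <- vcov(fit)
  grad <- c(-1 / b[2], b[1] / b[2]^2)
  se_log <- sqrt(drop(t(grad) %*% V %*% grad))
  ic50 <- 10^log_ic50
  structure(list(
    ic50 = ic50,
    se = ic50 * log(10) * se_log,
    slope = unname(b[2]), intercept = unname(b[1]),
    n = n, converged = fit$converged, link = link, fit = fit,
    data = d
  ), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("%s dose-response fit: IC50 = %.3g uM (SE %.2g), slope %.3g per log10 uM, n = %d\n",
              x$link, x$ic50, x$se, x$slope, x$n))
  invisible(x)
}
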