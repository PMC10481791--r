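# Anhysteretic B-H constitutive models for soft magnetic core materials.

#' Anhysteretic B-H curve
#'
#' Single-valued magnetization curve relating flux density to field intensity,
#' `B = mu0 * mu_r(|H|) * H`. Two analytic forms are supported:
#'
#' * `"arctan"`: `mu0 * mu_r(H) = a1 * atan(a2 * H) / H + mu0`, with `a1` in
#'   tesla and `a2` in m/A. The ferromagnetic contribution to B saturates at
#'   `a1 * pi / 2`.
#' * `"froelich"`: `mu0 * mu_r(H) = 1 / (a1 + a2 * H) + mu0`, with `a1` in
#'   m/H and `a2` in 1/T. The ferromagnetic contribution saturates at `1 / a2`.
#'
#' Both forms include the vacuum term `+ mu0`, so the relative permeability
#' never drops below 1 — important for stable behavior deep in saturation.
#'
#' @param kind `"arctan"` or `"froelich"`
#' @param a1,a2 positive model coefficients (units depend on `kind`, see above)
#' @return an object of class `bh_curve`
#' @examples
#' crv <- bh_curve("froelich", a1 = 80, a2 = 0.82)
#' relative_permeability(crv, c(0, 1e3, 1e6))
#' @export
bh_curve <- function(kind = c("arctan", "froelich"), a1, a2) {
  kind <- match.arg(kind)
  if (!is.numeric(a1) || length(a1) != 1L || !is.finite(a1) || a1 <= 0)
    rlang::abort("`a1` must be a single positive number")
  if (!is.numeric(a2) || length(a2) != 1L || !is.finite(a2) || a2 <= 0)
    rlang::abort("`a2` must be a single positive number")
  structure(list(kind = kind, a1 = a1, a2 = a2), class = "bh_curve")
}

#' @export
print.bh_curve <- function(x, ...) {
  units <- if (x$kind == "arctan") c("T", "m/A") else c("m/H", "1/T")
  cat(sprintf("<bh_curve> %s model: a1 = %g %s, a2 = %g %s\n",
              x$kind, x$a1, units[1], x$a2, units[2]))
  cat(sprintf("  initial mu_r = %.4g, saturation contribution = %.4g T\n",
              initial_permeability(x), saturation_flux(x)))
  invisible(x)
}

check_H <- function(H_mag) {
  if (!is.numeric(H_mag) || anyNA(H_mag) || any(H_mag < 0))
    rlang::abort("`H_mag` must be non-negative field magnitudes in A/m")
  as.numeric(H_mag)
}

#' Relative permeability of a B-H curve
#'
#' @param curve a [bh_curve()]
#' @param H_mag vector of field magnitudes |H| in A/m (non-negative)
#' @return dimensionless relative permeability `mu_r(|H|) >= 1`
#' @details The `H -> 0` limit of the arctan model, `(a1 * a2 + mu0) / mu0`,
#'   is substituted analytically below `1e-6` A/m to avoid 0/0.
#' @export
relative_permeability <- function(curve, H_mag) {
  stopifnot(inherits(curve, "bh_curve"))
  H <- check_H(H_mag)
  if (curve$kind == "arctan") {
    mu <- ifelse(H < 1e-6,
                 curve$a1 * curve$a2 + MU0,
                 curve$a1 * atan(curve$a2 * H) / H + MU0)
  } else {
    mu <- 1 / (curve$a1 + curve$a2 * H) + MU0
  }
  mu / MU0
}

#' Flux density from a B-H curve
#'
#' @inheritParams relative_permeability
#' @return flux density `B = mu0 * mu_r(|H|) * |H|` in tesla
#' @export
flux_density <- function(curve, H_mag) {
  H <- check_H(H_mag)
  MU0 * relative_permeability(curve, H) * H
}

#' Small-signal (initial) relative permeability
#'
#' The `|H| -> 0` limit of the relative permeability:
#' `(a1 * a2 + mu0) / mu0` for the arctan model and `(1 / a1 + mu0) / mu0`
#' for the Froelich model.
#'
#' @param curve a [bh_curve()]
#' @return dimensionless `mu_r0`
#' @export
initial_permeability <- function(curve) {
  stopifnot(inherits(curve, "bh_curve"))
  if (curve$kind == "arctan") (curve$a1 * curve$a2 + MU0) / MU0
  else (1 / curve$a1 + MU0) / MU0
}

#' Saturation contribution of the ferromagnetic term
#'
#' The large-H limit of `B - mu0 * H`: `a1 * pi / 2` (arctan) or `1 / a2`
#' (Froelich), in tesla.
#'
#' @param curve a [bh_curve()]
#' @return saturation flux contribution in T
#' @export
saturation_flux <- function(curve) {
  if (curve$kind == "arctan") curve$a1 * pi / 2 else 1 / curve$a2
}

#' Maximum permeability variation rate
#'
#' Maximum over `H >= 0` of `|d(mu0 * mu_r) / d|H||`, in H/A. This rate
#' controls the stability of the successive-substitution nonlinear iteration:
#' very steep curves may require permeability smoothing or the face-averaging
#' stabilizer.
#'
#' For the Froelich model the maximum is attained at `H = 0` and equals
#' `a2 / a1^2` exactly. For the arctan model the maximum is interior; it is
#' located on a log-spaced grid over `[1e-2, 1e7]` A/m and refined with
#' local golden-section search.
#'
#' @param curve a [bh_curve()]
#' @return maximum rate in henry per ampere (H/A)
#' @export
max_permeability_rate <- function(curve) {
  stopifnot(inherits(curve, "bh_curve"))
  if (curve$kind == "froelich") return(curve$a2 / curve$a1^2)
  # |d/dH (a1 atan(a2 H)/H)| = a1 a2^2 (atan(u) - u/(1+u^2)) / u^2, u = a2 H
  rate <- function(H) {
    u <- curve$a2 * H
    ifelse(u < 1e-8, (2 / 3) * curve$a1 * curve$a2^2 * u,
           curve$a1 * curve$a2^2 * (atan(u) - u / (1 + u^2)) / u^2)
  }
  Hgrid <- 10^seq(-2, 7, length.out = 2000L)
  vals <- rate(Hgrid)
  i <- which.max(vals)
  lo <- Hgrid[max(1L, i - 1L)]
  hi <- Hgrid[min(length(Hgrid), i + 1L)]
  opt <- stats::optimize(rate, interval = c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  max(opt$objective, vals[i])
}

#' Preset core materials
#'
#' Three reference materials with gradually decreasing saturation field:
#'
#' 1. a generic high-saturation material (arctan model, `a1 = 5/pi` T,
#'    `a2 = 5e-4` m/A; saturation contribution 2.5 T);
#' 2. 2-mil M3 grain-oriented silicon steel at 2 kHz (Froelich model,
#'    `a1 = 40` m/H, `a2 = 0.50` 1/T; saturates near 1.7 T);
#' 3. METGLAS 2605-SA1 amorphous foil (Froelich model, `a1 = 80` m/H,
#'    `a2 = 0.82` 1/T; saturates near 1.2 T).
#'
#' @param id material id, 1, 2 or 3
#' @return a [bh_curve()]
#' @export
preset_material <- function(id) {
  if (length(id) != 1L || !id %in% c(1, 2, 3))
    rlang::abort("`id` must be 1, 2 or 3")
  switch(as.integer(id),
         bh_curve("arctan", a1 = 5 / pi, a2 = 5e-4),
         bh_curve("froelich", a1 = 40, a2 = 0.50),
         bh_curve("froelich", a1 = 80, a2 = 0.82))
}

#' Fit an anhysteretic curve to B-H locus points
#'
#' Estimates `(a1, a2)` of the chosen model from datasheet locus points,
#' typically the `(H_max, B_max)` pairs of symmetric hysteresis cycles. The
#' origin `(0, 0)` is implied by both models and is appended to the data.
#' Because loci span decades in H, the least squares uses relative B
#' residuals (weights `1/B^2`) with positivity-constrained parameters,
#' refined by Levenberg-Marquardt from closed-form starting values.
#'
#' @param loci data frame (or 2-column matrix) with columns `H` (A/m) and
#'   `B` (T); at least two rows with `H > 0`
#' @param kind model kind, `"arctan"` or `"froelich"`
#' @return a fitted [bh_curve()]; the RMS relative residual is attached as
#'   attribute `"rms_residual"`
#' @export
fit_bh_curve <- function(loci, kind = c("arctan", "froelich")) {
  kind <- match.arg(kind)
  if (is.matrix(loci)) loci <- data.frame(H = loci[, 1], B = loci[, 2])
  if (!all(c("H", "B") %in% names(loci)))
    rlang::abort("`loci` must have columns `H` (A/m) and `B` (T)")
  loci <- loci[is.finite(loci$H) & is.finite(loci$B) & loci$H > 0 & loci$B > 0, ]
  if (nrow(loci) < 2L)
    rlang::abort("need at least two locus points with positive H and B",
                 class = "coremag_bad_loci")
  dat <- rbind(data.frame(H = 0, B = 0), loci[order(loci$H), ])
  fitdat <- dat[dat$H > 0, ]  # the origin is satisfied identically by both models
  Bf <- fitdat$B - MU0 * fitdat$H
  if (kind == "froelich") {
    # H / (B - mu0 H) = a1 + a2 H is linear: exact on noiseless data
    ok <- Bf > 0
    if (sum(ok) < 2L) rlang::abort("locus points incompatible with a Froelich curve")
    lf <- stats::lm(y ~ H, data = data.frame(y = fitdat$H[ok] / Bf[ok], H = fitdat$H[ok]))
    start <- list(a1 = max(coef(lf)[1], 1e-9), a2 = max(coef(lf)[2], 1e-12))
    form <- B ~ H / (a1 + a2 * H) + MU0 * H
  } else {
    a1s <- max(Bf) * 2 / pi * 1.05
    slope <- Bf[1] / fitdat$H[1]
    start <- list(a1 = a1s, a2 = max(slope / a1s, 1e-12))
    form <- B ~ a1 * atan(a2 * H) + MU0 * H
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = fitdat, start = start,
                      weights = 1 / fitdat$B^2,
                      lower = c(1e-12, 1e-14),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) rlang::abort(
      paste0("curve fit failed to converge: ", conditionMessage(e)),
      class = "coremag_fit_failure"))
  p <- coef(fit)
  curve <- bh_curve(kind, a1 = unname(p["a1"]), a2 = unname(p["a2"]))
  rel <- (flux_density(curve, fitdat$H) - fitdat$B) / fitdat$B
  attr(curve, "rms_residual") <- sqrt(mean(rel^2))
  curve
}

#' @describeIn bh_curve plot the permeability and flux-density curves
#' @param object a `bh_curve`
#' @param H_range range of |H| (A/m) to display
#' @param ... unused
#' @export
autoplot.bh_curve <- function(object, H_range = c(1, 1e6), ...) {
  H <- 10^seq(log10(H_range[1]), log10(H_range[2]), length.out = 400)
  df <- tibble::tibble(
    H = rep(H, 2),
    value = c(relative_permeability(object, H), flux_density(object, H)),
    quantity = rep(c("relative permeability", "flux density B (T)"), each = length(H)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$H, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "|H| (A/m)", y = NULL,
                  title = sprintf("%s anhysteretic curve", object$kind))
}

#' @importFrom rlang .data
NULL
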