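#' One-compartment pharmacokinetic model with first-order absorption
#'
#' @param ka_per_h Absorption rate constant (1/h).
#' @param ke_per_h Elimination rate constant (1/h); must differ from
#'   `ka_per_h`.
#' @param v_scaled Apparent volume scale (dose units per (ng/mL)).
#' @param dose_amounts Dose amounts (arbitrary units), one per dose.
#' @param dose_times_h Dosing times in hours after the first dose.
#' @return An object of class `pk_model`.
#' @export
pk_model <- function(ka_per_h = 0.25, ke_per_h = 0.07, v_scaled = 1,
                     dose_amounts = c(1, 1, 1), dose_times_h = c(0, 4, 8)) {
  if (ka_per_h == ke_per_h) {
    stop("ka must differ from ke (flip-flop degenerate form not supported)")
  }
  stopifnot(ka_per_h > 0, ke_per_h > 0, v_scaled > 0,
            length(dose_amounts) == length(dose_times_h),
            all(dose_amounts >= 0))
  structure(
    list(ka_per_h = ka_per_h, ke_per_h = ke_per_h, v_scaled = v_scaled,
         dose_amounts = dose_amounts, dose_times_h = dose_times_h),
    class = "pk_model"
  )
}

#' Simulate plasma concentrations
#'
#' Superposition of one-compartment first-order-absorption responses over
#' all doses; zero before the first dose. Concentrations are linear in the
#' dose amounts.
#'
#' @param model A [pk_model()].
#' @param times_h Sorted, nonnegative evaluation times (hours after first
#'   dose).
#' @return Numeric vector of concentrations (ng/mL).
#' @export
simulate_pk <- function(model, times_h) {
  stopifnot(inherits(model, "pk_model"))
  if (is.unsorted(times_h) || any(times_h < 0)) {
    stop("times_h must be sorted and nonnegative")
  }
  ka <- model$ka_per_h
  ke <- model$ke_per_h
  conc <- numeric(length(times_h))
  for (d in seq_along(model$dose_amounts)) {
    tau <- times_h - model$dose_times_h[d]
    on <- tau > 0
    conc[on] <- conc[on] + model$dose_amounts[d] * ka /
      (model$v_scaled * (ka - ke)) * (exp(-ke * tau[on]) - exp(-ka * tau[on]))
  }
  conc
}

# Population Cmax and Tmax of a PK model on a fine grid.
pk_cmax <- function(model, until_h = 24, by_h = 0.05) {
  grid <- seq(0, until_h, by = by_h)
  conc <- simulate_pk(model, grid)
  i <- which.max(conc)
  list(cmax = conc[i], tmax_h = grid[i])
}

#' Rescale a PK model to a target population Cmax
#'
#' Uses PK linearity: adjusts `v_scaled` so the model's maximum
#' concentration over the dosing day equals `cmax_target`.
#'
#' @param model A [pk_model()].
#' @param cmax_target Target maximum concentration (ng/mL).
#' @return The rescaled `pk_model`.
#' @export
pk_calibrate_cmax <- function(model, cmax_target) {
  stopifnot(cmax_target > 0)
  raw <- pk_cmax(model)$cmax
  model$v_scaled <- model$v_scaled * raw / cmax_target
  model
}
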