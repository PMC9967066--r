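#' Published reference emission factors for pod- and mod-type devices
#'
#' Per-puff emission factors (average and standard error) reported from
#' exposure-chamber characterization of a pod-type and a mod-type device under
#' unventilated (static, 0 ACH, n = 4) and ventilated (dynamic, 3/h ACH,
#' n = 3) scenarios. Number EFs are in #/puff and mass EFs in ug/puff. These
#' values anchor scenario-ratio and unit-conversion calculations: the
#' unventilated scenario shows roughly 9x (pod) and 3x (mod) higher number
#' EFs, mass EFs 14x higher for the mod device unventilated but 7x higher for
#' the pod device ventilated, and unventilated mass EFs of 0.26 mg/puff (pod)
#' and 15.0 mg/puff (mod).
#'
#' @return Data frame with columns `device` (`pod`/`mod`), `scenario`
#'   (`unventilated`/`ventilated`), `metric` (`number`/`mass`), `ef` (mean,
#'   #/puff or ug/puff), `se`, and `n_replicates`.
#' @export
reference_emission_factors <- function() {
  data.frame(
    device = rep(c("pod", "mod"), times = 4),
    scenario = rep(c("unventilated", "unventilated", "ventilated", "ventilated"),
                   each = 2),
    metric = rep(c("number", "number", "mass", "mass"), times = 2),
    ef = c(4.92e10, 1.72e10, 2.58e2, 1.50e4,
           5.54e9, 5.00e9, 1.71e3, 1.09e3),
    se = c(0.70e10, 0.08e10, 0.60e2, 0.06e4,
           2.11e9, 1.91e9, 1.00e3, 0.64e3),
    n_replicates = rep(c(4L, 3L), each = 4)
  )
}

#' Studied device and e-liquid combinations
#'
#' Atomizer setups of the studied pod- and mod-type devices: coil resistance,
#' maximum applied power, and the e-liquid (flavor label and nicotine
#' strength) run with each setup.
#'
#' @return Data frame with columns `device_type`, `flavor`, `nicotine_pct`,
#'   `coil_resistance_ohm`, `power_W`.
#' @export
device_presets <- function() {
  data.frame(
    device_type = c(rep("pod", 3), rep("mod", 5)),
    flavor = c("Tobacco 1", "Tobacco 1", "Tobacco 2",
               "Tobacco 3", "Tobacco 3", "Tobacco 3", "Tobacco 3", "Tobacco 4"),
    nicotine_pct = c(5, 3, 5, 0.3, 0.3, 0.3, 0.3, 0.3),
    coil_resistance_ohm = c(2.0, 2.0, 2.0, 0.2, 0.2, 0.6, 0.6, 0.15),
    power_W = c(7, 7, 7, 45, 63, 22, 29, 51)
  )
}

#' Reported average loss coefficients
#'
#' Average first-order particle loss coefficients estimated from post-vaping
#' decay in the static chamber: the mod-type device loses particles faster
#' (its accumulation-mode particles deposit more readily) than the pod-type
#' device.
#'
#' @return Named numeric vector of rates in 1/s.
#' @export
reference_loss_coefficients <- function() {
  c(mod = 2.20e-4, pod = 1.34e-4)
}
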