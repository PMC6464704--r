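#' Parameters for the synthetic viability plate generator
#'
#' Emulates a resazurin-type fluorescence viability read-out: each well of a
#' condition with true viability `v` reads `vehicle_mean * v * (1 + e)`,
#' `e ~ Normal(0, cv)`. The vehicle condition (viability 1 by construction
#' of the normalization) must be present.
#'
#' @param true_viability named vector of per-condition viability fractions;
#'   must include the vehicle label.
#' @param vehicle_label name of the vehicle (untreated control) condition.
#' @param vehicle_mean mean vehicle fluorescence (AU).
#' @param cv coefficient of variation of the well noise.
#' @param n_wells wells per condition.
#' @param seed integer seed.
#' @return a list of class `plate_sim_params`.
#' @export
plate_sim_params <- function(true_viability = c(vehicle = 1, nmda_10uM = 0.76,
                                                nmda_100uM = 0.42,
                                                nmda_300uM = 0.38),
                             vehicle_label = "vehicle",
                             vehicle_mean = 1000, cv = 0.05, n_wells = 6,
                             seed = 1L) {
  check_that(!is.null(names(true_viability)) &&
               vehicle_label %in% names(true_viability),
             "true_viability", "must be named and include the vehicle label")
  check_that(all(true_viability >= 0), "true_viability", "must be >= 0")
  check_that(vehicle_mean > 0, "vehicle_mean", "must be > 0")
  check_that(cv >= 0, "cv", "must be >= 0")
  check_that(n_wells >= 1, "n_wells", "must be >= 1")
  structure(list(true_viability = true_viability,
                 vehicle_label = vehicle_label, vehicle_mean = vehicle_mean,
                 cv = cv, n_wells = as.integer(n_wells),
                 seed = as.integer(seed)),
            class = "plate_sim_params")
}

#' Generate a synthetic viability plate table
#'
#' @param params a [plate_sim_params()] object.
#' @return list with `plate` (data frame `well`, `condition`,
#'   `fluorescence`) and `truth` (the generative parameters).
#' @export
gen_plate <- function(params) {
  stopifnot(inherits(params, "plate_sim_params"))
  p <- params
  conds <- names(p$true_viability)
  n <- length(conds) * p$n_wells
  plate <- data.frame(
    well = sprintf("W%03d", seq_len(n)),
    condition = rep(conds, each = p$n_wells),
    stringsAsFactors = FALSE)
  mu <- p$vehicle_mean * p$true_viability[plate$condition]
  noise <- if (p$cv > 0) with_seed(p$seed, stats::rnorm(n, 0, p$cv)) else 0
  plate$fluorescence <- pmax(as.numeric(mu * (1 + noise)), 0)
  list(plate = plate,
       truth = list(params = unclass(p),
                    true_viability = p$true_viability))
}
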