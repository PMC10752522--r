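# Simulation <-> physical unit bridge. The conversion anchors are fixed
# once from the dual (simulation, physical) columns of the adhesion
# parameter table: length 0.3 sim = 0.3 um (factor 1), stiffness
# 10.58 sim = 0.51 uN/m, rate 100 sim = 5.42e4 1/s. Derived factors: time =
# 1/rate, velocity = length * rate, energy = stiffness * length^2.

.unit_factors <- local({
  length_f <- 1                # um per sim length unit
  stiff_f <- 0.51 / 10.58      # uN/m per sim stiffness unit
  rate_f <- 5.42e4 / 100       # 1/s per sim rate unit
  list(length = length_f,
       stiffness = stiff_f,
       rate = rate_f,
       time = 1 / rate_f,
       velocity = length_f * rate_f,
       energy = stiff_f * length_f^2,
       force = stiff_f * length_f)
})

#' Convert between simulation and physical units
#'
#' Conversion factors are derived once from the (length, stiffness, rate)
#' anchors of the model's dual-unit parameter table; round-trips are exact
#' to floating point.
#'
#' @param value numeric value(s).
#' @param quantity one of `"length"` (um), `"stiffness"` (uN/m), `"rate"`
#'   (1/s), `"time"` (s), `"velocity"` (um/s), `"energy"`, `"force"`.
#' @param direction `"sim_to_phys"` or `"phys_to_sim"`.
#' @return converted value(s).
#' @export
map_units <- function(value, quantity, direction = c("sim_to_phys",
                                                     "phys_to_sim")) {
  direction <- match.arg(direction)
  if (!quantity %in% names(.unit_factors))
    stop("unknown unit quantity: ", quantity)
  f <- .unit_factors[[quantity]]
  if (direction == "sim_to_phys") value * f else value / f
}
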