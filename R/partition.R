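# Gy kg / GBq for 90Y: total absorbed dose per unit activity per unit mass,
# taken as printed in the classical partition formula
.partition_const <- 49.8

#' Inputs to the two-compartment partition model
#'
#' @param A administered activity, GBq.
#' @param M total liver mass (tumor + normal), kg.
#' @param Mt tumor mass, kg (0 < Mt < M).
#' @param r tumor/normal-liver activity uptake ratio (from planar
#'   scintigraphy ROI counts), dimensionless, > 0.
#' @param lung_shunt_fraction optional fraction of the activity shunted to
#'   the lungs, subtracted from `A` before dosing (default 0).
#' @return object of class `partition_inputs`.
#' @export
partition_inputs <- function(A, M, Mt, r, lung_shunt_fraction = 0) {
  if (!(A > 0)) stop("administered activity must be positive", call. = FALSE)
  if (!(Mt > 0 && Mt < M))
    stop("tumor mass must satisfy 0 < Mt < M", call. = FALSE)
  if (!(r > 0)) stop("uptake ratio must be positive", call. = FALSE)
  if (lung_shunt_fraction < 0 || lung_shunt_fraction >= 1)
    stop("lung_shunt_fraction must be in [0, 1)", call. = FALSE)
  structure(list(A = A, M = M, Mt = Mt, r = r,
                 lung_shunt_fraction = lung_shunt_fraction),
            class = "partition_inputs")
}

#' Two-compartment partition-model doses
#'
#' With `C = 49.8 * A_eff / M` (Gy, `A_eff = A * (1 - shunt)`), the tumor
#' and normal-liver doses are
#' `Dt = C * r / (1 + (Mt/M)(r - 1))` and
#' `Dl = C / (1 + (Mt/M)(r - 1))`,
#' so `Dt / Dl = r` and the mass-weighted total
#' `Mt*Dt + (M - Mt)*Dl = 49.8 * A_eff` closes exactly.
#'
#' @param inp a [partition_inputs()].
#' @return list with `Dt` and `Dl` (Gy), plus the `energy_closure`
#'   `Mt*Dt + (M-Mt)*Dl` (Gy kg).
#' @export
partition_doses <- function(inp) {
  stopifnot(inherits(inp, "partition_inputs"))
  a_eff <- inp$A * (1 - inp$lung_shunt_fraction)
  C <- .partition_const * a_eff / inp$M
  denom <- 1 + (inp$Mt / inp$M) * (inp$r - 1)
  Dt <- C * inp$r / denom
  Dl <- C / denom
  list(Dt = Dt, Dl = Dl,
       energy_closure = inp$Mt * Dt + (inp$M - inp$Mt) * Dl)
}

#' Compare partition-model doses with voxel-based DVH means
#'
#' Percent difference is `(partition - voxel) / voxel * 100` per
#' compartment.
#'
#' @param inp a [partition_inputs()].
#' @param gtv_dvh `dvh_curve` of the target on the voxel dose map.
#' @param liver_dvh `dvh_curve` of the normal liver.
#' @return data.frame with one row per compartment: `partition_Gy`,
#'   `voxel_Gy`, `pct_diff`.
#' @export
compare_with_voxel_dose <- function(inp, gtv_dvh, liver_dvh) {
  stopifnot(inherits(gtv_dvh, "dvh_curve"), inherits(liver_dvh, "dvh_curve"))
  pd <- partition_doses(inp)
  data.frame(
    compartment = c("target", "normal_liver"),
    partition_Gy = c(pd$Dt, pd$Dl),
    voxel_Gy = c(gtv_dvh$mean, liver_dvh$mean),
    pct_diff = c((pd$Dt - gtv_dvh$mean) / gtv_dvh$mean,
                 (pd$Dl - liver_dvh$mean) / liver_dvh$mean) * 100
  )
}
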