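#' Kinetic parameter set for one patch hormone
#'
#' Bundles every per-hormone constant of the one-compartment patch model:
#' the release rate at application time `k_o`, clearance `Cl`, elimination
#' half-life and first-order elimination constant, apparent volume of
#' distribution `V_d`, the exponential attenuation constant of the
#' absorption rate (written \eqn{\alpha} for NGMN and \eqn{\beta} for EE),
#' and the therapeutic serum band.
#'
#' Internally all kinetics run in hours. `k_o` is entered in ug/day (the
#' unit patch labels use) and divided by 24 on ingestion; the attenuation
#' constant is entered in the unit named by `decay_unit` and converted to
#' 1/h. Concentrations are carried in the hormone's conventional serum unit
#' (`"ng/mL"` for NGMN, `"pg/mL"` for EE) end to end, so the intrinsic
#' zero-age absorption rate is
#' \deqn{k_o / V_d \quad \textrm{[conc-unit / h]}.}
#'
#' The constructor checks that `k_elim` and `t_half` agree through
#' `k_elim = ln 2 / t_half`. When they do not (within `tol`), the object is
#' kept verbatim but flagged `consistent = FALSE` rather than silently
#' reconciled; published parameter tables are sometimes internally
#' inconsistent and the flag lets callers decide which convention to trust.
#'
#' @param name hormone label, e.g. `"NGMN"` or `"EE"`.
#' @param k_o release rate at patch application (ug/day), >= 0 (0 models
#'   a non-releasing patch, leaving pure elimination).
#' @param Cl clearance (L/h), > 0.
#' @param t_half elimination half-life (h), > 0.
#' @param k_elim first-order elimination constant (1/h); default derived
#'   from `t_half` as `log(2) / t_half`.
#' @param V_d volume of distribution (mL); default derived as
#'   `Cl / k_elim` (in mL).
#' @param decay_const absorption attenuation constant, >= 0, in
#'   `decay_unit`.
#' @param decay_unit unit of `decay_const`: `"1/day"` (default) or `"1/h"`.
#' @param conc_unit serum concentration unit, `"ng/mL"` or `"pg/mL"`.
#' @param therapeutic_low,therapeutic_high therapeutic band bounds in
#'   `conc_unit`, `therapeutic_low < therapeutic_high`.
#' @param tol relative tolerance for the `k_elim` vs `ln2 / t_half`
#'   consistency check.
#'
#' @return An object of class `drug_params`: a list with the fields above
#'   plus `consistent` (logical) and the derived per-hour quantities
#'   `k0_rate` (zero-age absorption rate, conc-unit/h) and `decay_h`
#'   (attenuation constant, 1/h).
#' @seealso [pk_preset()] for the published parameter sets.
#' @examples
#' p <- drug_params("NGMN",
#'   k_o = 150, Cl = 7.89, t_half = 28.4, k_elim = 0.0244,
#'   V_d = 323300, decay_const = 0.0028,
#'   conc_unit = "ng/mL", therapeutic_low = 0.6, therapeutic_high = 1.2
#' )
#' p$k0_rate # ng/mL/h entering the plasma at patch age zero
#' @export
drug_params <- function(name, k_o, Cl, t_half,
                        k_elim = log(2) / t_half,
                        V_d = 1000 * Cl / k_elim,
                        decay_const,
                        decay_unit = c("1/day", "1/h"),
                        conc_unit = c("ng/mL", "pg/mL"),
                        therapeutic_low, therapeutic_high,
                        tol = 0.02) {
  decay_unit <- match.arg(decay_unit)
  conc_unit <- match.arg(conc_unit)
  stopifnot(
    is.character(name), length(name) == 1L,
    length(k_o) == 1L, length(Cl) == 1L, length(t_half) == 1L,
    length(k_elim) == 1L, length(V_d) == 1L, length(decay_const) == 1L
  )
  for (fld in c("Cl", "t_half", "k_elim", "V_d",
                "therapeutic_low", "therapeutic_high")) {
    v <- get(fld)
    if (!is.finite(v) || v <= 0) {
      stop("`", fld, "` must be strictly positive, got ", v, call. = FALSE)
    }
  }
  # k_o = 0 is allowed: a non-releasing (placebo) patch gives the
  # absorption-free decay limit, useful for elimination-only checks
  if (!is.finite(k_o) || k_o < 0) {
    stop("`k_o` must be non-negative, got ", k_o, call. = FALSE)
  }
  if (!is.finite(decay_const) || decay_const < 0) {
    stop("`decay_const` must be non-negative", call. = FALSE)
  }
  if (therapeutic_low >= therapeutic_high) {
    stop("`therapeutic_low` must be < `therapeutic_high`", call. = FALSE)
  }

  consistent <- abs(k_elim - log(2) / t_half) <= tol * k_elim
  # conc_unit fixes the mass scale: ug -> ng is 1e3, ug -> pg is 1e6
  mass_scale <- c("ng/mL" = 1e3, "pg/mL" = 1e6)[[conc_unit]]
  decay_h <- if (decay_unit == "1/day") decay_const / 24 else decay_const

  structure(
    list(
      name = name, k_o = k_o, Cl = Cl, t_half = t_half,
      k_elim = k_elim, V_d = V_d,
      decay_const = decay_const, decay_unit = decay_unit,
      conc_unit = conc_unit,
      therapeutic_low = therapeutic_low,
      therapeutic_high = therapeutic_high,
      consistent = consistent,
      k0_rate = k_o * mass_scale / V_d / 24,
      decay_h = decay_h
    ),
    class = "drug_params"
  )
}

#' @export
print.drug_params <- function(x, ...) {
  cat("<drug_params> ", x$name, "\n", sep = "")
  cat(sprintf("  k_o     %8.4g ug/day     Cl  %8.4g L/h\n", x$k_o, x$Cl))
  cat(sprintf("  t_half  %8.4g h          k_elim %8.4g /h%s\n",
              x$t_half, x$k_elim,
              if (x$consistent) "" else "  [inconsistent with t_half]"))
  cat(sprintf("  V_d     %8.6g mL       decay  %8.4g %s\n",
              x$V_d, x$decay_const, x$decay_unit))
  cat(sprintf("  therapeutic band [%g, %g] %s\n",
              x$therapeutic_low, x$therapeutic_high, x$conc_unit))
  invisible(x)
}

#' Published parameter presets for the Ortho Evra hormones
#'
#' Returns the kinetic constants for both hormones under one of three
#' conventions:
#' \describe{
#'   \item{`"table1-verbatim"`}{the constants exactly as published for the
#'     patch (k_o 150 / 20.5 ug/day). The EE row is internally
#'     inconsistent: its printed `k_elim` (0.0385/h) does not equal
#'     `ln2 / t_half` (0.0456/h), and its printed `V_d` matches
#'     `Cl / (ln2 / t_half)`, not `Cl / k_elim`. The EE object is therefore
#'     flagged `consistent = FALSE`. This is the default preset.}
#'   \item{`"halflife-consistent"`}{`k_elim` rederived as `ln2 / t_half`
#'     and `V_d` as `Cl / k_elim` for both hormones, giving internally
#'     consistent objects.}
#'   \item{`"updated-k0"`}{as `"table1-verbatim"` but with the
#'     manufacturer's updated average daily release rates (NGMN 200,
#'     EE 35 ug/day).}
#' }
#'
#' The absorption attenuation constants (0.0028 for NGMN, 0.0034 for EE)
#' were published without a unit. By default they are interpreted as 1/day,
#' the reading under which the model reproduces the published plateau
#' concentrations and weekly AUCs; `decay_unit = "1/h"` selects the
#' alternative reading (see the package vignette for why both matter).
#'
#' @param preset preset name (see Details).
#' @param decay_unit unit assigned to the attenuation constants, `"1/day"`
#'   (default) or `"1/h"`.
#' @return Named list with `drug_params` elements `NGMN` and `EE`.
#' @examples
#' pars <- pk_preset()
#' pars$NGMN$k_elim
#' pk_preset("halflife-consistent")$EE$k_elim # ln2 / 15.2
#' @export
pk_preset <- function(preset = c("table1-verbatim", "halflife-consistent",
                                 "updated-k0"),
                      decay_unit = c("1/day", "1/h")) {
  preset <- match.arg(preset)
  decay_unit <- match.arg(decay_unit)

  k_o <- switch(preset,
    "updated-k0" = c(NGMN = 200, EE = 35),
    c(NGMN = 150, EE = 20.5)
  )
  base <- list(
    NGMN = list(Cl = 7.89, t_half = 28.4, k_elim = 0.0244, V_d = 323300,
                decay = 0.0028, unit = "ng/mL", lo = 0.6, hi = 1.2),
    EE = list(Cl = 18.3, t_half = 15.2, k_elim = 0.0385, V_d = 401385,
              decay = 0.0034, unit = "pg/mL", lo = 25, hi = 75)
  )

  out <- lapply(names(base), function(h) {
    b <- base[[h]]
    if (preset == "halflife-consistent") {
      ke <- log(2) / b$t_half
      drug_params(h, k_o = k_o[[h]], Cl = b$Cl, t_half = b$t_half,
                  k_elim = ke, V_d = 1000 * b$Cl / ke,
                  decay_const = b$decay, decay_unit = decay_unit,
                  conc_unit = b$unit,
                  therapeutic_low = b$lo, therapeutic_high = b$hi)
    } else {
      drug_params(h, k_o = k_o[[h]], Cl = b$Cl, t_half = b$t_half,
                  k_elim = b$k_elim, V_d = b$V_d,
                  decay_const = b$decay, decay_unit = decay_unit,
                  conc_unit = b$unit,
                  therapeutic_low = b$lo, therapeutic_high = b$hi)
    }
  })
  names(out) <- names(base)
  out
}

#' Elimination half-life from the first-order elimination constant
#'
#' @param k_elim elimination constant (1/time), > 0.
#' @return `log(2) / k_elim`, in the inverse unit of `k_elim`.
#' @examples
#' half_life(0.0244) # about 28.4 h
#' @export
half_life <- function(k_elim) {
  if (!is.numeric(k_elim) || any(!is.finite(k_elim)) || any(k_elim <= 0)) {
    stop("`k_elim` must be strictly positive", call. = FALSE)
  }
  log(2) / k_elim
}

#' Volume of distribution from clearance and elimination constant
#'
#' The apparent volume relating amount of drug in the body to its serum
#' concentration, obtained as clearance over the elimination constant.
#'
#' @param Cl clearance (L/h), > 0.
#' @param k_elim elimination constant (1/h), > 0.
#' @return Volume of distribution in mL.
#' @examples
#' derive_vd(7.89, log(2) / 28.4) # about 323,300 mL
#' @export
derive_vd <- function(Cl, k_elim) {
  if (!is.numeric(Cl) || any(!is.finite(Cl)) || any(Cl <= 0)) {
    stop("`Cl` must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(k_elim) || any(!is.finite(k_elim)) || any(k_elim <= 0)) {
    stop("`k_elim` must be strictly positive", call. = FALSE)
  }
  1000 * Cl / k_elim
}
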