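#' Structure-free ssDNA polymer model
#'
#' Saturating two-parameter force-extension law used by all generators:
#' \deqn{L(F) = L_{max} \frac{F}{F + F_{1/2}(salt)}}
#' with \eqn{L_{max}} = contour length (nt) x rise per nucleotide (nm) and
#' the half-saturation force increasing linearly with monovalent salt,
#' \eqn{F_{1/2} = F_0 (1 + salt / s)}. The law is a stand-in: it is chosen
#' for closed-form works (exact oracles), not as a physical claim about
#' ssDNA elasticity. Extension is 0 at zero force, strictly increasing in
#' force, and approaches the contour length at high force; stiffness
#' (force needed for a given relative extension) increases with salt.
#'
#' @param contour_length_nt number of nucleotides.
#' @param rise_per_nt_nm extension per nucleotide at saturating force (nm).
#' @param F_half_pN half-saturation force at 0 mM salt (pN).
#' @param salt_scale_mM salt concentration scale for stiffening (mM).
#' @param salt_mM monovalent salt concentration (mM).
#' @return object of class \code{polymer_model}.
#' @examples
#' m <- polymer_model()
#' polymer_extension(m, c(0.5, 10.5))
#' @export
polymer_model <- function(contour_length_nt = 13552,
                          rise_per_nt_nm = 0.5,
                          F_half_pN = 1.2,
                          salt_scale_mM = 300,
                          salt_mM = 0) {
  stopifnot_scalar(contour_length_nt, "contour_length_nt", positive = TRUE)
  stopifnot_scalar(rise_per_nt_nm, "rise_per_nt_nm", positive = TRUE)
  stopifnot_scalar(F_half_pN, "F_half_pN", positive = TRUE)
  stopifnot_scalar(salt_scale_mM, "salt_scale_mM", positive = TRUE)
  stopifnot_scalar(salt_mM, "salt_mM", nonneg = TRUE)
  structure(list(contour_length_nt = contour_length_nt,
                 rise_per_nt_nm = rise_per_nt_nm,
                 F_half_pN = F_half_pN,
                 salt_scale_mM = salt_scale_mM,
                 salt_mM = salt_mM),
            class = "polymer_model")
}

model_L_max <- function(model) model$contour_length_nt * model$rise_per_nt_nm

model_F_half <- function(model) model$F_half_pN * (1 + model$salt_mM / model$salt_scale_mM)

#' Noiseless extension of the bare polymer at given forces
#' @param model a \code{\link{polymer_model}}.
#' @param force_pN vector of forces (pN), >= 0.
#' @return extensions in nm.
#' @export
polymer_extension <- function(model, force_pN) {
  stopifnot(inherits(model, "polymer_model"))
  if (any(force_pN < 0)) stop("forces must be >= 0", call. = FALSE)
  model_L_max(model) * force_pN / (force_pN + model_F_half(model))
}

#' Exact stretching work of the bare polymer between two forces
#'
#' Closed form of \eqn{\int F \, dL} along the structure-free law between
#' forces \code{F1} and \code{F2} (pN nm). Serves as the analytic oracle
#' for trapezoidal work integration.
#'
#' @param model a \code{\link{polymer_model}}.
#' @param F1,F2 force interval (pN).
#' @return work in pN nm.
#' @export
polymer_work <- function(model, F1, F2) {
  stopifnot(inherits(model, "polymer_model"))
  Fh <- model_F_half(model)
  Lm <- model_L_max(model)
  anti <- function(f) Lm * Fh * (log(f + Fh) + Fh / (f + Fh))
  anti(F2) - anti(F1)
}

#' Secondary-structure hysteresis model for bare ssDNA
#'
#' On the pulling branch a fraction of the contour is sequestered in
#' salt-stabilized secondary structure; the sequestered fraction declines
#' linearly from its zero-force value to 0 at the critical force, above
#' which structure is fully melted. The relaxing branch is structure-free.
#' Either supply the zero-force fraction directly, or prescribe the loop
#' energy (\code{target_hysteresis_energy_kBT}); the generator then solves
#' for the fraction so the pulling-minus-relaxing work equals the target
#' over the force schedule in use.
#'
#' @param sequestered_fraction_at_zero_force fraction in [0, 1], or NULL
#'   when calibrating from a target energy.
#' @param critical_force_pN force at which structure is fully melted (pN).
#' @param target_hysteresis_energy_kBT prescribed loop energy (kBT), >= 0;
#'   NULL to use the fraction as given.
#' @return object of class \code{hysteresis_model}.
#' @export
hysteresis_model <- function(sequestered_fraction_at_zero_force = NULL,
                             critical_force_pN = 8,
                             target_hysteresis_energy_kBT = NULL) {
  stopifnot_scalar(critical_force_pN, "critical_force_pN", positive = TRUE)
  if (is.null(sequestered_fraction_at_zero_force) &&
      is.null(target_hysteresis_energy_kBT)) {
    stop("supply either a sequestered fraction or a target hysteresis energy",
         call. = FALSE)
  }
  if (!is.null(sequestered_fraction_at_zero_force)) {
    stopifnot_scalar(sequestered_fraction_at_zero_force,
                     "sequestered_fraction_at_zero_force", nonneg = TRUE)
    if (sequestered_fraction_at_zero_force > 1) {
      stop("sequestered fraction must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(target_hysteresis_energy_kBT)) {
    stopifnot_scalar(target_hysteresis_energy_kBT,
                     "target_hysteresis_energy_kBT", nonneg = TRUE)
  }
  structure(list(
    sequestered_fraction_at_zero_force = sequestered_fraction_at_zero_force,
    critical_force_pN = critical_force_pN,
    target_hysteresis_energy_kBT = target_hysteresis_energy_kBT),
    class = "hysteresis_model")
}

# Sequestered-fraction profile at phi0 = 1 (unit knob).
seq_profile <- function(force_pN, Fc) pmax(0, 1 - force_pN / Fc)

# Pulling-minus-relaxing work for a unit sequestered fraction, over the
# schedule's force range [F1, F2]:
#   W_pull - W_relax = F1 D(F1) - F2 D(F2) + int_{F1}^{F2} D dF,
# where D(F) = L(F) * (1 - F/Fc)_+ is the sequestered length profile.
unit_hysteresis_area <- function(model, Fc, F1, F2, scale = 1) {
  D <- function(f) scale * polymer_extension(model, f) * seq_profile(f, Fc)
  upper <- min(F2, Fc)
  int <- if (upper > F1) {
    integrate(D, F1, upper, rel.tol = 1e-10)$value
  } else 0
  F1 * D(F1) - F2 * D(F2) + int
}

#' SSB coating model for coated-ssDNA generation
#'
#' The coated molecule follows the bare polymer law scaled by a
#' condensation factor \eqn{c \in (0, 1]} on both branches (protein coating
#' removes secondary-structure hysteresis). A positive
#' \code{bridging_energy_kBT} emulates RecOR-mediated bridging: the pulling
#' branch is stiffened (shortened below the bridging-rupture force) so that
#' the pulling-minus-relaxing work equals the prescribed energy.
#'
#' @param condensation_factor multiplicative length factor in (0, 1].
#' @param site_size_nt occluded nucleotides per tetramer at this salt.
#' @param bridging_energy_kBT excess pulling work from bridging (kBT),
#'   0 when absent.
#' @param bridging_critical_force_pN force at which all bridges are
#'   ruptured; NULL defaults to the top of the force schedule at
#'   generation time.
#' @return object of class \code{coating_model}.
#' @export
coating_model <- function(condensation_factor = 1,
                          site_size_nt = 65,
                          bridging_energy_kBT = 0,
                          bridging_critical_force_pN = NULL) {
  stopifnot_scalar(condensation_factor, "condensation_factor")
  if (condensation_factor <= 0 || condensation_factor > 1) {
    stop("condensation_factor must lie in (0, 1]", call. = FALSE)
  }
  stopifnot_scalar(site_size_nt, "site_size_nt", positive = TRUE)
  stopifnot_scalar(bridging_energy_kBT, "bridging_energy_kBT", nonneg = TRUE)
  if (!is.null(bridging_critical_force_pN)) {
    stopifnot_scalar(bridging_critical_force_pN, "bridging_critical_force_pN",
                     positive = TRUE)
  }
  structure(list(condensation_factor = condensation_factor,
                 site_size_nt = site_size_nt,
                 bridging_energy_kBT = bridging_energy_kBT,
                 bridging_critical_force_pN = bridging_critical_force_pN),
            class = "coating_model")
}

#' Solve the condensation factor that injects a prescribed net energy
#'
#' Finds \eqn{c} such that the completed coated curve (measured to
#' \code{F_max_measured}, then completed by a straight segment to the bare
#' ssDNA anchor at \code{F_target}) stores \code{target_ddE_kBT} more work
#' than the completed bare relaxing curve. The work difference is linear in
#' \eqn{c}, so the solve is closed-form.
#'
#' @param model bare \code{\link{polymer_model}} at the matching salt.
#' @param target_ddE_kBT net energy to inject (kBT), > 0.
#' @param F_min_pN lowest measured force (pN).
#' @param F_max_measured highest measured force before completion (pN).
#' @param F_target completion ceiling (pN).
#' @param kBT conversion constant (pN nm per kBT).
#' @return condensation factor in (0, 1).
#' @export
calibrate_condensation <- function(model, target_ddE_kBT,
                                   F_min_pN = 0.1,
                                   F_max_measured = 10.5,
                                   F_target = 17.5,
                                   kBT = KBT_PNNM_25C) {
  stopifnot(inherits(model, "polymer_model"))
  stopifnot_scalar(target_ddE_kBT, "target_ddE_kBT", positive = TRUE)
  Lm <- polymer_extension(model, F_max_measured)
  W  <- polymer_work(model, F_min_pN, F_max_measured)
  # ddE(c) * kBT = (c - 1) * (W - 0.5 (F_max + F_target) L(F_max))
  denom <- 0.5 * (F_max_measured + F_target) * Lm - W
  c_fac <- 1 - target_ddE_kBT * kBT / denom
  if (c_fac <= 0 || c_fac >= 1) {
    stop(sprintf(
      "target ddE of %g kBT is not attainable with this model/schedule (c = %.3g)",
      target_ddE_kBT, c_fac), call. = FALSE)
  }
  c_fac
}
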