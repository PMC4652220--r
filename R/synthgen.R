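#' @title Synthetic-data generators with recorded ground truth
#' @description Every generator is a pure function of its parameters and a
#'   mandatory seed, and attaches a \code{synthetic_truth} record holding
#'   all generating parameters plus analytic summaries (branch works, loop
#'   energies), sufficient to regenerate the dataset bit-identically.
#' @name synthgen
NULL

synthetic_truth <- function(generator, seed, ...) {
  structure(list(generator = generator, seed = as.integer(seed), ...),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>", x$generator, "seed", x$seed, "\n")
  str(x[setdiff(names(x), c("generator", "seed"))], max.level = 1,
      give.attr = FALSE)
  invisible(x)
}

check_schedule <- function(force_schedule) {
  if (length(force_schedule) < 2L || any(force_schedule <= 0)) {
    stop("force schedule must contain >= 2 strictly positive forces",
         call. = FALSE)
  }
  if (any(diff(force_schedule) <= 0)) {
    stop("force schedule must be strictly increasing (pulling order)",
         call. = FALSE)
  }
  force_schedule
}

# Resolve the zero-force sequestered fraction, calibrating against a
# prescribed loop energy over this schedule when one is given.
resolve_phi0 <- function(model, hyst, force_schedule, kBT = KBT_PNNM_25C) {
  if (!is.null(hyst$target_hysteresis_energy_kBT)) {
    target <- hyst$target_hysteresis_energy_kBT
    if (target == 0) return(0)
    base <- unit_hysteresis_area(model, hyst$critical_force_pN,
                                 min(force_schedule), max(force_schedule))
    phi0 <- target * kBT / base
    if (phi0 > 1) {
      stop(sprintf(
        "target hysteresis of %g kBT needs sequestered fraction %.3g > 1; not attainable",
        target, phi0), call. = FALSE)
    }
    phi0
  } else {
    hyst$sequestered_fraction_at_zero_force
  }
}

branch_works <- function(L_pull_fun, L_relax_fun, F1, F2) {
  # work = int F dL computed by quadrature of the generating functions
  w <- function(L_fun) {
    h <- 1e-6
    dL <- function(f) (L_fun(f + h) - L_fun(f - h)) / (2 * h)
    integrate(function(f) f * dL(f), F1, F2, rel.tol = 1e-9,
              subdivisions = 2000L)$value
  }
  c(pull = w(L_pull_fun), relax = w(L_relax_fun))
}

#' Generate a bare-ssDNA force-extension pulling/relaxing pair
#'
#' The relaxing branch follows the structure-free polymer law; the pulling
#' branch subtracts the sequestered length below the critical force, so the
#' branches display hysteresis whose loop energy is recorded (and, when the
#' hysteresis model prescribes a target energy, calibrated) analytically.
#'
#' @param model \code{\link{polymer_model}}.
#' @param hyst \code{\link{hysteresis_model}}.
#' @param force_schedule strictly increasing positive forces (pN); the
#'   relaxing branch uses the same forces in descending order.
#' @param noise_sd_nm additive Gaussian extension noise (nm), i.i.d.
#' @param seed integer seed (mandatory).
#' @return list with elements \code{pulling}, \code{relaxing} (objects of
#'   class \code{\link{fe_branch}}) and \code{truth}
#'   (\code{synthetic_truth} with analytic per-branch works in pN nm).
#' @examples
#' m <- polymer_model(salt_mM = 100)
#' h <- hysteresis_model(target_hysteresis_energy_kBT = 1400)
#' fec <- gen_fec_ssdna(m, h, seq(0.5, 10.5, by = 0.25), noise_sd_nm = 0,
#'                      seed = 1)
#' @export
gen_fec_ssdna <- function(model, hyst, force_schedule, noise_sd_nm = 0,
                          seed) {
  stopifnot(inherits(model, "polymer_model"),
            inherits(hyst, "hysteresis_model"))
  check_schedule(force_schedule)
  stopifnot_scalar(noise_sd_nm, "noise_sd_nm", nonneg = TRUE)
  seed <- check_seed(seed)

  phi0 <- resolve_phi0(model, hyst, force_schedule)
  Fc <- hyst$critical_force_pN
  L_relax <- function(f) polymer_extension(model, f)
  L_pull  <- function(f) L_relax(f) * (1 - phi0 * seq_profile(f, Fc))

  F1 <- min(force_schedule); F2 <- max(force_schedule)
  works <- branch_works(L_pull, L_relax, F1, F2)
  hyst_pNnm <- unit_hysteresis_area(model, Fc, F1, F2, scale = phi0)

  ext_pull  <- L_pull(force_schedule)
  ext_relax <- L_relax(rev(force_schedule))
  if (noise_sd_nm > 0) {
    withr::with_seed(seed, {
      ext_pull  <- ext_pull + rnorm(length(ext_pull), 0, noise_sd_nm)
      ext_relax <- ext_relax + rnorm(length(ext_relax), 0, noise_sd_nm)
    })
  }

  meta <- list(condition = "ssDNA", salt_mM = model$salt_mM, mg_mM = 0)
  list(
    pulling = fe_branch(force_schedule, ext_pull, condition = meta$condition,
                        salt_mM = meta$salt_mM, direction = "pulling"),
    relaxing = fe_branch(rev(force_schedule), ext_relax,
                         condition = meta$condition, salt_mM = meta$salt_mM,
                         direction = "relaxing"),
    truth = synthetic_truth(
      "gen_fec_ssdna", seed,
      model = unclass(model),
      sequestered_fraction_at_zero_force = phi0,
      critical_force_pN = Fc,
      noise_sd_nm = noise_sd_nm,
      force_schedule = force_schedule,
      work_pull_pNnm = works[["pull"]],
      work_relax_pNnm = works[["relax"]],
      hysteresis_pNnm = hyst_pNnm,
      hysteresis_kBT = hyst_pNnm / KBT_PNNM_25C)
  )
}

#' Generate an SSB-coated force-extension pulling/relaxing pair
#'
#' Both branches equal the condensation factor times the structure-free
#' polymer extension (coating removes secondary-structure hysteresis).
#' A positive bridging energy stiffens the pulling branch so that the
#' pulling-minus-relaxing work equals the prescribed energy, emulating
#' RecOR-mediated bridging of distant sites.
#'
#' @inheritParams gen_fec_ssdna
#' @param coat \code{\link{coating_model}}.
#' @return as \code{\link{gen_fec_ssdna}}; the condition label is
#'   \code{"+SSB"} (or \code{"+SSB+RecO+RecR"} when bridging is active).
#' @export
gen_fec_coated <- function(model, coat, force_schedule, noise_sd_nm = 0,
                           seed) {
  stopifnot(inherits(model, "polymer_model"),
            inherits(coat, "coating_model"))
  check_schedule(force_schedule)
  stopifnot_scalar(noise_sd_nm, "noise_sd_nm", nonneg = TRUE)
  seed <- check_seed(seed)

  c_fac <- coat$condensation_factor
  F1 <- min(force_schedule); F2 <- max(force_schedule)
  Fc <- if (is.null(coat$bridging_critical_force_pN)) F2 else
    coat$bridging_critical_force_pN

  psi0 <- 0
  if (coat$bridging_energy_kBT > 0) {
    base <- unit_hysteresis_area(model, Fc, F1, F2, scale = c_fac)
    psi0 <- coat$bridging_energy_kBT * KBT_PNNM_25C / base
    if (psi0 > 1) {
      stop(sprintf(
        "bridging energy of %g kBT needs bridged fraction %.3g > 1; not attainable",
        coat$bridging_energy_kBT, psi0), call. = FALSE)
    }
  }

  L_relax <- function(f) c_fac * polymer_extension(model, f)
  L_pull  <- function(f) L_relax(f) * (1 - psi0 * seq_profile(f, Fc))
  works <- branch_works(L_pull, L_relax, F1, F2)
  hyst_pNnm <- unit_hysteresis_area(model, Fc, F1, F2, scale = c_fac * psi0)

  ext_pull  <- L_pull(force_schedule)
  ext_relax <- L_relax(rev(force_schedule))
  if (noise_sd_nm > 0) {
    withr::with_seed(seed, {
      ext_pull  <- ext_pull + rnorm(length(ext_pull), 0, noise_sd_nm)
      ext_relax <- ext_relax + rnorm(length(ext_relax), 0, noise_sd_nm)
    })
  }

  condition <- if (psi0 > 0) "+SSB+RecO+RecR" else "+SSB"
  list(
    pulling = fe_branch(force_schedule, ext_pull, condition = condition,
                        salt_mM = model$salt_mM, direction = "pulling"),
    relaxing = fe_branch(rev(force_schedule), ext_relax,
                         condition = condition, salt_mM = model$salt_mM,
                         direction = "relaxing"),
    truth = synthetic_truth(
      "gen_fec_coated", seed,
      model = unclass(model),
      condensation_factor = c_fac,
      site_size_nt = coat$site_size_nt,
      bridging_energy_kBT = coat$bridging_energy_kBT,
      bridged_fraction = psi0,
      bridging_critical_force_pN = Fc,
      noise_sd_nm = noise_sd_nm,
      force_schedule = force_schedule,
      work_pull_pNnm = works[["pull"]],
      work_relax_pNnm = works[["relax"]],
      hysteresis_pNnm = hyst_pNnm,
      hysteresis_kBT = hyst_pNnm / KBT_PNNM_25C)
  )
}

#' Generate a stoichiometric fluorescence titration curve
#'
#' Noiseless signal rises linearly from the protein-only baseline (fold
#' enhancement 1) to \code{plateau_fold} at a DNA:protein ratio equal to
#' the site size, and is flat thereafter; noise is additive Gaussian.
#'
#' @param site_size_nt breakpoint in nucleotides per tetramer.
#' @param plateau_fold plateau fold-enhancement (> 1 for an identifiable
#'   breakpoint).
#' @param n_points number of titration points.
#' @param ratio_max largest nucleotide:tetramer ratio; must exceed the
#'   site size so the breakpoint is bracketed.
#' @param noise_sd additive Gaussian noise s.d. (fold-enhancement units).
#' @param seed integer seed.
#' @param salt_mM condition label carried in the curve.
#' @return list(curve = data.frame(ratio, fold_enhancement, salt_mM,
#'   replicate), truth).
#' @export
gen_titration <- function(site_size_nt, plateau_fold, n_points = 30,
                          ratio_max = 2 * site_size_nt, noise_sd = 0, seed,
                          salt_mM = 0) {
  stopifnot_scalar(site_size_nt, "site_size_nt", positive = TRUE)
  stopifnot_scalar(plateau_fold, "plateau_fold", positive = TRUE)
  if (plateau_fold < 1) stop("plateau_fold must be >= 1", call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (ratio_max <= site_size_nt) {
    stop("ratio_max must exceed the site size (breakpoint not bracketed)",
         call. = FALSE)
  }
  seed <- check_seed(seed)

  ratio <- seq(0, ratio_max, length.out = n_points)
  signal <- 1 + (plateau_fold - 1) * pmin(ratio / site_size_nt, 1)
  if (noise_sd > 0) {
    signal <- withr::with_seed(seed, signal + rnorm(n_points, 0, noise_sd))
  }
  list(
    curve = data.frame(ratio = ratio, fold_enhancement = signal,
                       salt_mM = salt_mM, replicate = 1L),
    truth = synthetic_truth("gen_titration", seed,
                            site_size_nt = site_size_nt,
                            plateau_fold = plateau_fold,
                            n_points = n_points, ratio_max = ratio_max,
                            noise_sd = noise_sd, salt_mM = salt_mM)
  )
}

#' Generate a salt back-titration (dissociation) table
#'
#' Piecewise model of the fluorescence of a pre-formed protein-ssDNA
#' complex as salt is raised: sharp linear rise to a peak, shallow linear
#' decline, then a logistic dissociation limb with half-signal (relative
#' to the extrapolated pre-transition line) at \code{midpoint_mM}.
#'
#' @param midpoint_mM salt at half-dissociation (must exceed
#'   \code{rise_peak_mM}).
#' @param rise_peak_mM salt at which the initial rise peaks.
#' @param decline_slope decline of the pre-transition line
#'   (signal units per mM, positive = declining).
#' @param n_points points on the salt grid.
#' @param noise_sd additive Gaussian noise s.d. (signal units).
#' @param seed integer seed.
#' @param peak_signal fold enhancement at the rise peak.
#' @param width_mM logistic width of the dissociation limb; default
#'   midpoint/20 (sharp transition).
#' @param salt_max_mM top of the salt grid; must cover the dissociation
#'   limb (default 1.6 x midpoint).
#' @return list(table = data.frame(salt_mM, signal), truth).
#' @export
gen_backtitration <- function(midpoint_mM, rise_peak_mM = 300,
                              decline_slope = 5e-4, n_points = 60,
                              noise_sd = 0, seed, peak_signal = 6,
                              width_mM = midpoint_mM / 20,
                              salt_max_mM = 1.6 * midpoint_mM) {
  stopifnot_scalar(midpoint_mM, "midpoint_mM", positive = TRUE)
  stopifnot_scalar(rise_peak_mM, "rise_peak_mM", positive = TRUE)
  if (midpoint_mM <= rise_peak_mM) {
    stop("midpoint_mM must exceed rise_peak_mM", call. = FALSE)
  }
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (salt_max_mM < midpoint_mM + 4 * width_mM) {
    stop("salt grid does not span the dissociation limb; raise salt_max_mM",
         call. = FALSE)
  }
  seed <- check_seed(seed)

  salt <- seq(0, salt_max_mM, length.out = n_points)
  pre <- ifelse(salt <= rise_peak_mM,
                1 + (peak_signal - 1) * salt / rise_peak_mM,
                peak_signal - decline_slope * (salt - rise_peak_mM))
  signal <- pre * plogis((midpoint_mM - salt) / width_mM)
  if (noise_sd > 0) {
    signal <- withr::with_seed(seed, signal + rnorm(n_points, 0, noise_sd))
  }
  list(
    table = data.frame(salt_mM = salt, signal = signal),
    truth = synthetic_truth("gen_backtitration", seed,
                            midpoint_mM = midpoint_mM,
                            rise_peak_mM = rise_peak_mM,
                            decline_slope = decline_slope,
                            peak_signal = peak_signal,
                            width_mM = width_mM, n_points = n_points,
                            noise_sd = noise_sd)
  )
}

#' Generate an exponential force-step relaxation time trace
#'
#' \eqn{L(t) = L_{eq} + (L_{start} - L_{eq}) e^{-t/\tau}} plus additive
#' Gaussian noise, emulating the kinetic response of a coated molecule
#' after a force step.
#'
#' @param L_start_nm,L_eq_nm initial and equilibrium extensions (nm).
#' @param tau_s relaxation time constant (s), > 0.
#' @param duration_s trace duration (s); a warning is issued below 5 tau.
#' @param dt_s sampling interval (s), > 0.
#' @param noise_sd_nm additive Gaussian extension noise (nm).
#' @param seed integer seed.
#' @param force_pN constant applied force carried in the trace metadata.
#' @return list(trace = data.frame(time_s, extension_nm, force_pN), truth).
#' @export
gen_timetrace <- function(L_start_nm, L_eq_nm, tau_s, duration_s,
                          dt_s = 0.05, noise_sd_nm = 0, seed,
                          force_pN = NA_real_) {
  stopifnot_scalar(tau_s, "tau_s", positive = TRUE)
  stopifnot_scalar(dt_s, "dt_s", positive = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(noise_sd_nm, "noise_sd_nm", nonneg = TRUE)
  if (duration_s < 5 * tau_s) {
    warning("duration is below 5 tau; equilibrium may not be reached",
            call. = FALSE)
  }
  seed <- check_seed(seed)

  t <- seq(0, duration_s, by = dt_s)
  L <- L_eq_nm + (L_start_nm - L_eq_nm) * exp(-t / tau_s)
  if (noise_sd_nm > 0) {
    L <- withr::with_seed(seed, L + rnorm(length(t), 0, noise_sd_nm))
  }
  list(
    trace = data.frame(time_s = t, extension_nm = L, force_pN = force_pN),
    truth = synthetic_truth("gen_timetrace", seed,
                            L_start_nm = L_start_nm, L_eq_nm = L_eq_nm,
                            tau_s = tau_s, duration_s = duration_s,
                            dt_s = dt_s, noise_sd_nm = noise_sd_nm,
                            force_pN = force_pN)
  )
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

blur_frame <- function(frame, sigma) {
  if (sigma <= 0) return(frame)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  conv1 <- function(v) {
    padded <- c(rep(0, r), v, rep(0, r))
    out <- numeric(length(v))
    for (i in seq_along(v)) out[i] <- sum(padded[i:(i + 2 * r)] * rev(k))
    out
  }
  frame <- apply(frame, 2, conv1)
  t(apply(frame, 1, conv1))
}

#' Generate a synthetic fiber image stack (kymograph frames)
#'
#' Each frame holds one fiber segment anchored at a fixed tether pixel,
#' extending along the flow axis (image rows) for the scheduled length,
#' with the scheduled mean intensity above background, convolved with a
#' Gaussian point-spread profile, plus Gaussian background noise.
#' Sub-pixel fiber ends are rendered with fractional intensity.
#'
#' @param length_schedule_um per-frame fiber lengths (um).
#' @param intensity_schedule per-frame fiber amplitudes above background
#'   (same length as \code{length_schedule_um}).
#' @param pixel_um pixel size (um), > 0.
#' @param psf_sigma_px Gaussian blur s.d. in pixels (0 = no blur).
#' @param background_mean,background_sd background level and noise.
#' @param seed integer seed.
#' @param n_rows,n_cols frame size in pixels; \code{n_rows = NULL} sizes
#'   the frame to fit the longest scheduled fiber plus margin.
#' @param tether_row,tether_col tether pixel (1-based; flow runs toward
#'   increasing row index).
#' @return list(stack = array(n_rows, n_cols, n_frames), truth).
#' @export
gen_kymograph <- function(length_schedule_um, intensity_schedule,
                          pixel_um = 0.16, psf_sigma_px = 0,
                          background_mean = 100, background_sd = 0, seed,
                          n_rows = NULL, n_cols = 11,
                          tether_row = 4, tether_col = (n_cols + 1) %/% 2) {
  if (length(length_schedule_um) != length(intensity_schedule)) {
    stop("length and intensity schedules must have equal length",
         call. = FALSE)
  }
  stopifnot_scalar(pixel_um, "pixel_um", positive = TRUE)
  stopifnot_scalar(psf_sigma_px, "psf_sigma_px", nonneg = TRUE)
  stopifnot_scalar(background_sd, "background_sd", nonneg = TRUE)
  seed <- check_seed(seed)

  len_px <- length_schedule_um / pixel_um
  if (is.null(n_rows)) n_rows <- tether_row + ceiling(max(len_px)) + 8L
  if (tether_row < 1 || tether_row > n_rows || tether_col < 1 ||
      tether_col > n_cols) {
    stop("tether pixel outside frame", call. = FALSE)
  }
  if (any(tether_row + ceiling(len_px) - 1 > n_rows)) {
    stop("scheduled fiber longer than frame", call. = FALSE)
  }

  n_frames <- length(len_px)
  stack <- array(0, dim = c(n_rows, n_cols, n_frames))
  withr::with_seed(seed, {
    for (f in seq_len(n_frames)) {
      frame <- matrix(0, n_rows, n_cols)
      n_full <- floor(len_px[f])
      frac <- len_px[f] - n_full
      amp <- intensity_schedule[f]
      if (n_full > 0) {
        frame[tether_row + seq_len(n_full) - 1L, tether_col] <- amp
      }
      if (frac > 0) frame[tether_row + n_full, tether_col] <- amp * frac
      frame <- blur_frame(frame, psf_sigma_px)
      bg <- matrix(background_mean, n_rows, n_cols)
      if (background_sd > 0) {
        bg <- bg + matrix(rnorm(n_rows * n_cols, 0, background_sd),
                          n_rows, n_cols)
      }
      stack[, , f] <- frame + bg
    }
  })
  list(
    stack = stack,
    truth = synthetic_truth("gen_kymograph", seed,
                            length_schedule_um = length_schedule_um,
                            intensity_schedule = intensity_schedule,
                            pixel_um = pixel_um,
                            psf_sigma_px = psf_sigma_px,
                            background_mean = background_mean,
                            background_sd = background_sd,
                            n_rows = n_rows, n_cols = n_cols,
                            tether_row = tether_row,
                            tether_col = tether_col,
                            flow_axis = "rows")
  )
}

#' Generate matched TIRF and tweezer relative-condensation profiles
#'
#' Convenience generator for flow-force matching: relative condensation
#' follows \eqn{L/L_0(salt, F) = \exp(-salt / (s_0 (1 + F/F_0)))}, so
#' condensation weakens with applied force. The "TIRF" profile is the
#' tweezer profile at \code{true_force_pN} plus multiplicative noise.
#'
#' @param forces_pN tweezer forces to tabulate.
#' @param salts_mM shared salt grid.
#' @param true_force_pN force generating the TIRF profile.
#' @param s0_mM salt decay scale at zero force.
#' @param F0_pN force scale of de-condensation.
#' @param noise_sd relative noise on the TIRF profile.
#' @param seed integer seed.
#' @return list(tirf = data.frame(salt_mM, L_rel),
#'   tweezer = data.frame(force_pN, salt_mM, L_rel), truth).
#' @export
gen_condensation_profiles <- function(forces_pN = c(0.1, 0.3, 1, 3, 8),
                                      salts_mM = c(0, 25, 50, 100, 250,
                                                   500, 750),
                                      true_force_pN = 0.3, s0_mM = 300,
                                      F0_pN = 1, noise_sd = 0, seed) {
  seed <- check_seed(seed)
  rel <- function(salt, f) exp(-salt / (s0_mM * (1 + f / F0_pN)))
  tweezer <- do.call(rbind, lapply(forces_pN, function(f) {
    data.frame(force_pN = f, salt_mM = salts_mM,
               L_rel = rel(salts_mM, f))
  }))
  tirf <- data.frame(salt_mM = salts_mM,
                     L_rel = rel(salts_mM, true_force_pN))
  if (noise_sd > 0) {
    tirf$L_rel <- withr::with_seed(
      seed, tirf$L_rel * (1 + rnorm(nrow(tirf), 0, noise_sd)))
    tirf$L_rel[tirf$salt_mM == 0] <- 1  # normalization anchor
  }
  list(tirf = tirf, tweezer = tweezer,
       truth = synthetic_truth("gen_condensation_profiles", seed,
                               true_force_pN = true_force_pN,
                               s0_mM = s0_mM, F0_pN = F0_pN,
                               forces_pN = forces_pN, salts_mM = salts_mM,
                               noise_sd = noise_sd))
}
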