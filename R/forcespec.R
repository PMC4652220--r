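#' Force-extension branch
#'
#' One pulling or relaxing sweep under one condition: ordered
#' (force, extension) points plus condition metadata. Forces must be
#' strictly monotone along the sweep (increasing for pulling, decreasing
#' for relaxing).
#'
#' @param force_pN forces along the sweep (pN).
#' @param extension_nm extensions (nm).
#' @param condition condition label, e.g. "ssDNA", "+SSB", "+SSB+RecO".
#' @param salt_mM,mg_mM buffer composition.
#' @param direction "pulling" or "relaxing".
#' @return data.frame of class \code{fe_branch} with attributes
#'   \code{condition}, \code{salt_mM}, \code{mg_mM}, \code{direction}.
#' @export
fe_branch <- function(force_pN, extension_nm, condition = "ssDNA",
                      salt_mM = 0, mg_mM = 0,
                      direction = c("pulling", "relaxing")) {
  direction <- match.arg(direction)
  if (length(force_pN) != length(extension_nm)) {
    stop("force and extension vectors must have equal length", call. = FALSE)
  }
  d <- diff(force_pN)
  ok <- if (direction == "pulling") all(d > 0) else all(d < 0)
  if (length(force_pN) > 1L && !ok) {
    stop(sprintf("forces must be strictly %s along a %s sweep",
                 if (direction == "pulling") "increasing" else "decreasing",
                 direction), call. = FALSE)
  }
  out <- data.frame(force_pN = force_pN, extension_nm = extension_nm)
  attr(out, "condition") <- condition
  attr(out, "salt_mM") <- salt_mM
  attr(out, "mg_mM") <- mg_mM
  attr(out, "direction") <- direction
  class(out) <- c("fe_branch", "data.frame")
  out
}

branch_meta <- function(b) {
  list(condition = attr(b, "condition"), salt_mM = attr(b, "salt_mM"),
       mg_mM = attr(b, "mg_mM"), direction = attr(b, "direction"))
}

#' @export
print.fe_branch <- function(x, ...) {
  m <- branch_meta(x)
  cat(sprintf("<fe_branch> %s | %g mM NaOAc | %g mM Mg | %s | %d points\n",
              m$condition, m$salt_mM, m$mg_mM, m$direction, nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Fit a single-exponential equilibrium approach to a force-step segment
#'
#' Least-squares fit of \eqn{L(t) = L_{eq} + A e^{-t/\tau}} to one
#' constant-force segment of a time trace. For a fixed \eqn{\tau} the
#' model is linear in \eqn{(L_{eq}, A)}, so the fit profiles the residual
#' sum of squares over \eqn{\log\tau} (golden-section search), which is
#' robust without starting values. A segment is flagged converged when the
#' fitted drift over its final 20% is below 1% of the fitted amplitude
#' (or the amplitude is negligible); constant traces return amplitude 0
#' and \code{tau_s = NA}.
#'
#' @param time_s,extension_nm the segment samples (>= 10 points), or a
#'   data.frame with those columns passed as \code{time_s}.
#' @return object of class \code{equilibrium_fit}: list(L_eq_nm, tau_s,
#'   amplitude_nm, converged, rss, n).
#' @export
fit_equilibrium <- function(time_s, extension_nm = NULL) {
  if (is.data.frame(time_s)) {
    extension_nm <- time_s$extension_nm
    time_s <- time_s$time_s
  }
  n <- length(time_s)
  if (n < 10L) stop("segment must contain at least 10 samples", call. = FALSE)
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing",
                                   call. = FALSE)
  t0 <- time_s - time_s[1]
  span <- max(t0)

  lin_fit <- function(tau) {
    b <- exp(-t0 / tau)
    X <- cbind(1, b)
    cf <- tryCatch(qr.coef(qr(X), extension_nm), error = function(e) c(NA, NA))
    if (anyNA(cf)) return(list(rss = Inf, L_eq = NA, A = NA))
    r <- extension_nm - X %*% cf
    list(rss = sum(r^2), L_eq = cf[1], A = cf[2])
  }

  # constant-trace / negligible-amplitude guard
  scale_nm <- max(abs(extension_nm), 1)
  if (sd(extension_nm) < 1e-9 * scale_nm) {
    return(structure(list(L_eq_nm = mean(extension_nm), tau_s = NA_real_,
                          amplitude_nm = 0, converged = TRUE, rss = 0, n = n),
                     class = "equilibrium_fit"))
  }

  obj <- function(log_tau) lin_fit(exp(log_tau))$rss
  opt <- optimize(obj, interval = log(c(span / 1e4, span * 10)), tol = 1e-8)
  tau <- exp(opt$minimum)
  fit <- lin_fit(tau)

  # compare against a flat model: amplitude may be spurious
  rss_flat <- sum((extension_nm - mean(extension_nm))^2)
  if (fit$rss >= rss_flat * (1 - 1e-10)) {
    return(structure(list(L_eq_nm = mean(extension_nm), tau_s = NA_real_,
                          amplitude_nm = 0, converged = TRUE,
                          rss = rss_flat, n = n),
                     class = "equilibrium_fit"))
  }

  drift <- abs(fit$A) * abs(exp(-0.8 * span / tau) - exp(-span / tau))
  converged <- (abs(fit$A) < 1e-9 * scale_nm) || (drift < 0.01 * abs(fit$A))
  structure(list(L_eq_nm = unname(fit$L_eq), tau_s = tau,
                 amplitude_nm = unname(fit$A), converged = converged,
                 rss = fit$rss, n = n),
            class = "equilibrium_fit")
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  cat(sprintf("<equilibrium_fit> L_eq = %.1f nm, tau = %s s, A = %.1f nm, %s\n",
              x$L_eq_nm,
              if (is.na(x$tau_s)) "NA" else sprintf("%.3g", x$tau_s),
              x$amplitude_nm,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Assemble equilibrium fits into a pulling/relaxing branch pair
#'
#' @param fits list of \code{\link{fit_equilibrium}} results, one per
#'   force step.
#' @param force_pN applied force for each fit (pN).
#' @param direction "pulling" or "relaxing" for each fit.
#' @param condition,salt_mM,mg_mM shared condition metadata.
#' @return list(pulling = fe_branch, relaxing = fe_branch).
#' @export
assemble_branches <- function(fits, force_pN, direction,
                              condition = "ssDNA", salt_mM = 0, mg_mM = 0) {
  stopifnot(length(fits) == length(force_pN),
            length(fits) == length(direction))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv)) {
    stop(sprintf("unconverged equilibrium fits at force(s): %s pN",
                 paste(force_pN[!conv], collapse = ", ")), call. = FALSE)
  }
  direction <- match.arg(direction, c("pulling", "relaxing"),
                         several.ok = TRUE)
  if (!all(c("pulling", "relaxing") %in% direction)) {
    stop("both a pulling and a relaxing sweep are required", call. = FALSE)
  }
  L <- vapply(fits, function(f) f$L_eq_nm, numeric(1))
  one <- function(dir) {
    i <- which(direction == dir)
    i <- i[order(force_pN[i], decreasing = (dir == "relaxing"))]
    fe_branch(force_pN[i], L[i], condition = condition, salt_mM = salt_mM,
              mg_mM = mg_mM, direction = dir)
  }
  list(pulling = one("pulling"), relaxing = one("relaxing"))
}

#' Complete a truncated branch to the common force ceiling
#'
#' Branches measured only to \code{F_max_measured} (10.5 pN by default)
#' are completed with a straight segment from their last measured point to
#' the anchor extension at \code{F_target} (17.5 pN), the force at which
#' all curves converge onto bare ssDNA. Branches already reaching the
#' target are returned unchanged. The attached
#' \code{extrapolation_error_bound_pNnm} is the worst case over all
#' monotone completions: half the force gap times the appended extension
#' gap.
#'
#' @param branch an \code{\link{fe_branch}}.
#' @param F_max_measured force the branch must reach (pN).
#' @param F_target completion ceiling (pN).
#' @param anchor_nm extension at \code{F_target} (bare-ssDNA convergence
#'   extension at the same salt); required unless the branch already
#'   reaches the target.
#' @return the completed branch, with attributes \code{completed} and
#'   \code{extrapolation_error_bound_pNnm}.
#' @export
complete_branch <- function(branch, F_max_measured = 10.5, F_target = 17.5,
                            anchor_nm = NULL) {
  stopifnot(inherits(branch, "fe_branch"))
  m <- branch_meta(branch)
  f <- branch$force_pN
  if (max(f) >= F_target) {
    attr(branch, "completed") <- FALSE
    attr(branch, "extrapolation_error_bound_pNnm") <- 0
    return(branch)
  }
  if (max(f) < F_max_measured) {
    stop(sprintf("branch ends at %.3g pN, below the measured ceiling %.3g pN",
                 max(f), F_max_measured), call. = FALSE)
  }
  if (is.null(anchor_nm)) {
    stop("anchor extension at F_target is required to complete the branch",
         call. = FALSE)
  }
  i_last <- which.max(f)
  L_last <- branch$extension_nm[i_last]
  dL <- anchor_nm - L_last
  if (m$direction == "pulling") {
    out <- fe_branch(c(f, F_target), c(branch$extension_nm, anchor_nm),
                     condition = m$condition, salt_mM = m$salt_mM,
                     mg_mM = m$mg_mM, direction = "pulling")
  } else {
    out <- fe_branch(c(F_target, f), c(anchor_nm, branch$extension_nm),
                     condition = m$condition, salt_mM = m$salt_mM,
                     mg_mM = m$mg_mM, direction = "relaxing")
  }
  attr(out, "completed") <- TRUE
  attr(out, "extrapolation_error_bound_pNnm") <-
    0.5 * (F_target - max(f)) * abs(dL)
  out
}

#' Trapezoidal stretching work of a branch
#'
#' \eqn{\int F \, dL} with extension as the integration variable, oriented
#' so stretching work is positive; pulling minus relaxing work is then the
#' classical hysteresis loop energy.
#'
#' @param branch an \code{\link{fe_branch}} (or data.frame with
#'   \code{force_pN}, \code{extension_nm}).
#' @return work in pN nm.
#' @export
integrate_work <- function(branch) {
  f <- branch$force_pN
  L <- branch$extension_nm
  if (length(f) < 2L) return(0)
  if (any(diff(f) > 0) && any(diff(f) < 0)) {
    stop("branch forces must be sorted monotonically", call. = FALSE)
  }
  o <- order(f)
  trapz(L[o], f[o])
}

#' Propagated noise bound on a hysteresis estimate
#'
#' For i.i.d. Gaussian extension noise of s.d. \code{noise_sd_nm} on every
#' point of both branches, the trapezoidal work difference is a linear
#' combination of the noisy extensions; this returns the two-sided
#' \code{level} quantile of its propagated standard deviation, i.e. the
#' bound below which |hysteresis| should fall for bridging-free curves.
#'
#' @param pulling,relaxing the two branches.
#' @param noise_sd_nm per-point extension noise s.d. (nm).
#' @param level coverage level (default 0.95).
#' @return energy bound in pN nm.
#' @export
hysteresis_noise_bound <- function(pulling, relaxing, noise_sd_nm,
                                   level = 0.95) {
  coefs <- function(b) {
    f <- sort(b$force_pN)
    n <- length(f)
    a <- numeric(n)
    a[1] <- -0.5 * (f[1] + f[2])
    a[n] <- 0.5 * (f[n - 1] + f[n])
    if (n > 2) a[2:(n - 1)] <- 0.5 * (f[3:n] - f[1:(n - 2)])
    # W = sum a_i L_i up to sign conventions; only sum a^2 matters
    sum(a^2)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  z * noise_sd_nm * sqrt(coefs(pulling) + coefs(relaxing))
}

#' Energy ledger: per-branch works, dE, ddE and hysteresis
#'
#' Integrates every completed branch, expresses each work relative to the
#' reference (bare ssDNA at 0 mM salt) in kBT, forms the per-condition
#' hysteresis (pulling minus relaxing work), and the net SSB/RecOR
#' contribution ddE against the bare-ssDNA branch at matching salt
#' (relaxing by default, the biologically relevant comparison since the
#' coated complex shows no hysteresis).
#'
#' @param branches list of completed \code{\link{fe_branch}} objects.
#' @param reference_condition,reference_salt_mM identity of the reference
#'   branch (default ssDNA at 0 mM).
#' @param reference_direction direction of the reference branch.
#' @param baseline_direction direction of the matching-salt ssDNA branch
#'   used for ddE ("relaxing" default, "pulling" by flag).
#' @param kBT conversion constant in pN nm per kBT (default 4.1, the
#'   thermal energy at 25 C).
#' @return object of class \code{energy_ledger}: list(entries, hysteresis,
#'   reference, kBT). \code{entries} has one row per branch with
#'   work_pNnm, dE_kBT, ddE_kBT and extrapolation_error_bound_pNnm;
#'   \code{hysteresis} one row per (condition, salt).
#' @export
energy_ledger <- function(branches,
                          reference_condition = "ssDNA",
                          reference_salt_mM = 0,
                          reference_direction = "relaxing",
                          baseline_direction = c("relaxing", "pulling"),
                          kBT = KBT_PNNM_25C) {
  baseline_direction <- match.arg(baseline_direction)
  stopifnot(length(branches) >= 1L)
  meta <- lapply(branches, branch_meta)
  entries <- data.frame(
    condition = vapply(meta, `[[`, "", "condition"),
    salt_mM = vapply(meta, `[[`, 0, "salt_mM"),
    mg_mM = vapply(meta, `[[`, 0, "mg_mM"),
    direction = vapply(meta, `[[`, "", "direction"),
    work_pNnm = vapply(branches, integrate_work, numeric(1)),
    extrapolation_error_bound_pNnm = vapply(branches, function(b) {
      bd <- attr(b, "extrapolation_error_bound_pNnm")
      if (is.null(bd)) 0 else bd
    }, numeric(1)),
    stringsAsFactors = FALSE)

  ceilings <- vapply(branches, function(b) max(b$force_pN), numeric(1))
  if (diff(range(ceilings)) > 1e-6 * max(ceilings)) {
    stop(sprintf(
      "branches completed to different force ceilings (%.4g .. %.4g pN)",
      min(ceilings), max(ceilings)), call. = FALSE)
  }

  i_ref <- which(entries$condition == reference_condition &
                 entries$salt_mM == reference_salt_mM &
                 entries$direction == reference_direction)
  if (length(i_ref) != 1L) {
    stop(sprintf("reference branch (%s, %g mM, %s) missing or not unique",
                 reference_condition, reference_salt_mM,
                 reference_direction), call. = FALSE)
  }
  entries$dE_kBT <- (entries$work_pNnm - entries$work_pNnm[i_ref]) / kBT

  # ddE against the bare-ssDNA branch at matching salt
  entries$ddE_kBT <- vapply(seq_len(nrow(entries)), function(i) {
    j <- which(entries$condition == reference_condition &
               entries$salt_mM == entries$salt_mM[i] &
               entries$direction == baseline_direction)
    if (length(j) != 1L) return(NA_real_)
    entries$dE_kBT[i] - entries$dE_kBT[j]
  }, numeric(1))

  key <- paste(entries$condition, entries$salt_mM, sep = "@")
  hyst <- do.call(rbind, lapply(unique(key), function(k) {
    i <- which(key == k)
    ip <- i[entries$direction[i] == "pulling"]
    ir <- i[entries$direction[i] == "relaxing"]
    if (length(ip) != 1L || length(ir) != 1L) return(NULL)
    data.frame(condition = entries$condition[ip],
               salt_mM = entries$salt_mM[ip],
               hysteresis_kBT = (entries$work_pNnm[ip] -
                                 entries$work_pNnm[ir]) / kBT,
               stringsAsFactors = FALSE)
  }))
  structure(list(entries = entries,
                 hysteresis = hyst,
                 reference = list(condition = reference_condition,
                                  salt_mM = reference_salt_mM,
                                  direction = reference_direction),
                 baseline_direction = baseline_direction,
                 kBT = kBT),
            class = "energy_ledger")
}

#' @export
print.energy_ledger <- function(x, ...) {
  cat(sprintf("<energy_ledger> reference: %s at %g mM (%s), kBT = %g pN nm\n",
              x$reference$condition, x$reference$salt_mM,
              x$reference$direction, x$kBT))
  print(x$entries, digits = 4)
  if (!is.null(x$hysteresis) && nrow(x$hysteresis)) {
    cat("hysteresis (pulling - relaxing):\n")
    print(x$hysteresis, digits = 4)
  }
  invisible(x)
}

#' Per-tetramer energy accounting
#'
#' Divides a net energy by the number of tetramers on the substrate,
#' n = round(length / site size) (half away from zero).
#'
#' @param ddE_kBT net energy (kBT).
#' @param ssDNA_length_nt substrate length in nucleotides (default the
#'   13,552-nt tweezer substrate).
#' @param site_size_nt occluded site size at the relevant salt; a warning
#'   is issued outside the 30-80 nt range of known binding modes.
#' @return object of class \code{tetramer_accounting}: list(ssDNA_length_nt,
#'   site_size_nt, n_tetramers, energy_per_tetramer_kBT).
#' @examples
#' per_tetramer_energy(250, 13552, 65)  # ~1.2 kBT per tetramer
#' @export
per_tetramer_energy <- function(ddE_kBT, ssDNA_length_nt = 13552,
                                site_size_nt) {
  stopifnot_scalar(ddE_kBT, "ddE_kBT")
  stopifnot_scalar(ssDNA_length_nt, "ssDNA_length_nt", positive = TRUE)
  stopifnot_scalar(site_size_nt, "site_size_nt", positive = TRUE)
  if (ssDNA_length_nt <= site_size_nt) {
    stop("substrate length must exceed the site size", call. = FALSE)
  }
  if (site_size_nt < 30 || site_size_nt > 80) {
    warning("site size outside the 30-80 nt range of known binding modes",
            call. = FALSE)
  }
  n <- round_half_away(ssDNA_length_nt / site_size_nt)
  structure(list(ssDNA_length_nt = ssDNA_length_nt,
                 site_size_nt = site_size_nt,
                 n_tetramers = n,
                 energy_per_tetramer_kBT = ddE_kBT / n),
            class = "tetramer_accounting")
}

#' @export
print.tetramer_accounting <- function(x, ...) {
  cat(sprintf("<tetramer_accounting> %d tetramers (%g nt / %g nt), %.2f kBT per tetramer\n",
              x$n_tetramers, x$ssDNA_length_nt, x$site_size_nt,
              x$energy_per_tetramer_kBT))
  invisible(x)
}

#' Slope of energy against log salt concentration
#'
#' Ordinary least squares of dE (kBT) on the natural log of salt (mM);
#' 0 mM points are not admitted (ln 0 undefined) and must be excluded by
#' the caller.
#'
#' @param dE_kBT energies (kBT).
#' @param salt_mM matching salt concentrations, all > 0.
#' @return list(slope_kBT_per_ln_mM, slope_se, intercept, n, fit).
#' @export
fit_energy_slope <- function(dE_kBT, salt_mM) {
  stopifnot(length(dE_kBT) == length(salt_mM))
  if (any(salt_mM <= 0)) {
    stop("all salt concentrations must be > 0 for a log-salt fit; drop 0 mM",
         call. = FALSE)
  }
  if (length(salt_mM) < 2L) stop("need at least 2 salts", call. = FALSE)
  if (length(unique(salt_mM)) < 3L) {
    warning("fewer than 3 distinct salts; slope is an interpolation",
            call. = FALSE)
  }
  fit <- lm(dE_kBT ~ log(salt_mM))
  cf <- summary(fit)$coefficients
  list(slope_kBT_per_ln_mM = unname(cf[2, 1]),
       slope_se = if (nrow(cf) >= 2 && ncol(cf) >= 2)
         unname(cf[2, 2]) else NA_real_,
       intercept = unname(cf[1, 1]),
       n = length(salt_mM), fit = fit)
}

#' Relative condensation profile L/L0
#'
#' Normalizes lengths at each force by the same-force length at 0 mM
#' salt.
#'
#' @param lengths data.frame with columns \code{force_pN},
#'   \code{salt_mM}, \code{length_nm} (or \code{extension_nm}).
#' @return the input with an added \code{L_rel} column; rows at 0 mM are
#'   identically 1.
#' @export
relative_condensation <- function(lengths) {
  stopifnot(is.data.frame(lengths))
  if (!"length_nm" %in% names(lengths) && "extension_nm" %in% names(lengths)) {
    lengths$length_nm <- lengths$extension_nm
  }
  stopifnot(all(c("force_pN", "salt_mM", "length_nm") %in% names(lengths)))
  out <- lengths
  out$L_rel <- NA_real_
  for (f in unique(out$force_pN)) {
    i <- which(out$force_pN == f)
    i0 <- i[out$salt_mM[i] == 0]
    if (length(i0) != 1L) {
      stop(sprintf("missing (or duplicated) 0 mM entry at force %g pN", f),
           call. = FALSE)
    }
    out$L_rel[i] <- out$length_nm[i] / out$length_nm[i0]
  }
  out
}

#' Estimate the flow shear force from condensation profiles
#'
#' Matches a flow-stretch (TIRF) relative-condensation-vs-salt profile
#' against tweezer profiles at known forces; returns the force minimizing
#' the summed squared difference across the shared salt grid, with the
#' bracketing interval of forces whose misfit is within twice the minimum.
#'
#' @param tirf_profile data.frame(salt_mM, L_rel).
#' @param tweezer_profiles data.frame(force_pN, salt_mM, L_rel).
#' @return list(force_pN, interval_pN = c(lo, hi), misfit = data.frame).
#' @export
estimate_flow_force <- function(tirf_profile, tweezer_profiles) {
  stopifnot(all(c("salt_mM", "L_rel") %in% names(tirf_profile)),
            all(c("force_pN", "salt_mM", "L_rel") %in%
                  names(tweezer_profiles)))
  forces <- sort(unique(tweezer_profiles$force_pN))
  if (length(forces) < 2L) stop("need profiles at >= 2 forces", call. = FALSE)
  sse <- vapply(forces, function(f) {
    tw <- tweezer_profiles[tweezer_profiles$force_pN == f, ]
    lo <- max(min(tw$salt_mM), min(tirf_profile$salt_mM))
    hi <- min(max(tw$salt_mM), max(tirf_profile$salt_mM))
    keep <- tirf_profile$salt_mM >= lo & tirf_profile$salt_mM <= hi
    if (!any(keep)) {
      stop("tweezer and TIRF salt ranges do not overlap", call. = FALSE)
    }
    pred <- approx(tw$salt_mM, tw$L_rel,
                   xout = tirf_profile$salt_mM[keep])$y
    sum((tirf_profile$L_rel[keep] - pred)^2)
  }, numeric(1))
  best <- which.min(sse)  # ties resolve to the smallest force
  within <- forces[sse <= 2 * sse[best] + 1e-300]
  list(force_pN = forces[best],
       interval_pN = range(within),
       misfit = data.frame(force_pN = forces, sse = sse))
}

#' Fold condensation between two lengths
#'
#' @param L_ref,L_cond reference (extended) and condensed lengths, same
#'   units, both > 0.
#' @param digits significant digits for reporting (default 2, matching
#'   common reporting precision).
#' @return L_ref / L_cond rounded to \code{digits} significant digits.
#' @examples
#' fold_condensation(6.5, 0.5)  # 13
#' fold_condensation(920, 560)  # 1.6
#' @export
fold_condensation <- function(L_ref, L_cond, digits = 2) {
  stopifnot_scalar(L_ref, "L_ref", positive = TRUE)
  stopifnot_scalar(L_cond, "L_cond", positive = TRUE)
  signif(L_ref / L_cond, digits)
}

#' Predict a contour length scaled by genome-length ratio
#'
#' Scales a reference nucleoprotein contour length (nm) by a genome length
#' ratio and reports the prediction in um at 1 decimal place.
#'
#' @param reference_contour_nm reference contour length (nm).
#' @param genome_length_ratio dimensionless genome-length ratio.
#' @return predicted length in um, 1 d.p.
#' @examples
#' predict_scaled_length(920, 6.6)  # 6.1 um
#' @export
predict_scaled_length <- function(reference_contour_nm, genome_length_ratio) {
  stopifnot_scalar(reference_contour_nm, "reference_contour_nm",
                   positive = TRUE)
  stopifnot_scalar(genome_length_ratio, "genome_length_ratio",
                   positive = TRUE)
  round(reference_contour_nm * genome_length_ratio / 1000, 1)
}
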