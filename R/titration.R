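#' Two-segment breakpoint fit: apparent site size and plateau amplitude
#'
#' Fits the classic stoichiometric-titration model to fold-enhancement
#' data: the baseline-subtracted signal (signal - 1) rises linearly
#' through the origin up to the breakpoint and is flat (zero slope) past
#' it, with continuity enforced at the breakpoint. The breakpoint is the
#' stoichiometric endpoint of the titration, i.e. the apparent occluded
#' site size in nucleotides per tetramer.
#'
#' For a fixed breakpoint b the model is linear in the plateau amplitude,
#' so the residual sum of squares is profiled over b. The profile is
#' smooth between consecutive data ratios (the active set is fixed), so
#' the global minimum is found exactly by optimizing within every such
#' interval; ties break toward the smaller breakpoint. This reproduces an
#' exhaustive fine-grid search and is equivariant under rescaling of the
#' ratio axis.
#'
#' @param curve data.frame with columns \code{ratio} (nucleotides per
#'   tetramer, strictly increasing) and \code{fold_enhancement}.
#' @param n_boot case-resampling bootstrap replicates for the breakpoint
#'   standard error (0 to skip; default 1000).
#' @param boot_seed seed for the bootstrap resampling.
#' @return object of class \code{site_size_fit}: list(site_size_nt,
#'   amplitude_fold, breakpoint_se, residual_ss, n).
#' @examples
#' tc <- gen_titration(65, 6, n_points = 30, ratio_max = 130, seed = 1)
#' fit_site_size(tc$curve, n_boot = 0)
#' @export
fit_site_size <- function(curve, n_boot = 1000, boot_seed = 1L) {
  stopifnot(is.data.frame(curve),
            all(c("ratio", "fold_enhancement") %in% names(curve)))
  x <- curve$ratio
  y <- curve$fold_enhancement - 1  # baseline-subtracted signal
  if (any(diff(x) <= 0)) stop("ratios must be strictly increasing",
                              call. = FALSE)
  n <- length(x)
  if (n < 8L) stop("need at least 8 titration points", call. = FALSE)
  if (max(y) <= 1e-9 * max(1, abs(y[1]))) {
    stop("flat titration: breakpoint unidentifiable (no enhancement)",
         call. = FALSE)
  }
  if (y[n] < 0.5 * max(y)) {
    warning("signal declines after its maximum; titration is non-monotone",
            call. = FALSE)
  }

  solve_bp <- function(x, y) {
    pos <- x[x > 0]
    lo <- min(pos); hi <- max(x)
    # profile RSS: basis p_i(b) = min(x_i / b, 1); amplitude solved exactly
    prss <- function(b) {
      p <- pmin(x / b, 1)
      a <- sum(y * p) / sum(p * p)
      sum((y - a * p)^2)
    }
    knots <- sort(unique(c(lo, pos[pos >= lo & pos <= hi], hi)))
    best_b <- NA_real_; best_r <- Inf
    for (i in seq_len(length(knots) - 1L)) {
      op <- optimize(prss, c(knots[i], knots[i + 1L]), tol = 1e-9)
      cand <- c(op$minimum, knots[i], knots[i + 1L])
      for (b in cand) {
        r <- prss(b)
        better <- if (!is.finite(best_r)) TRUE else {
          tol <- 1e-12 * max(1, best_r, r)
          (r < best_r - tol) || (r <= best_r + tol && b < best_b)
        }
        if (better) { best_r <- r; best_b <- b }
      }
    }
    c(b = best_b, rss = best_r)
  }

  sol <- solve_bp(x, y)
  b <- sol[["b"]]
  if (b <= min(x[x > 0]) * (1 + 1e-9) || b >= max(x) * (1 - 1e-9)) {
    stop("breakpoint not bracketed by the data range", call. = FALSE)
  }
  p <- pmin(x / b, 1)
  amp <- sum(y * p) / sum(p * p)

  se <- NA_real_
  if (n_boot > 0) {
    se <- withr::with_seed(boot_seed, {
      bs <- vapply(seq_len(n_boot), function(i) {
        idx <- sort(sample.int(n, n, replace = TRUE))
        xi <- x[idx]; yi <- y[idx]
        keep <- !duplicated(xi)
        if (sum(keep) < 4L) return(NA_real_)
        solve_bp(xi[keep], yi[keep])[["b"]]
      }, numeric(1))
      sd(bs, na.rm = TRUE)
    })
  }

  structure(list(site_size_nt = b, amplitude_fold = amp + 1,
                 breakpoint_se = se, residual_ss = sol[["rss"]], n = n),
            class = "site_size_fit")
}

#' @export
print.site_size_fit <- function(x, ...) {
  cat(sprintf(
    "<site_size_fit> site size = %.1f nt/tetramer (se %.2g), amplitude = %.2f-fold, rss = %.3g\n",
    x$site_size_nt, x$breakpoint_se, x$amplitude_fold, x$residual_ss))
  invisible(x)
}

#' Tabulate plateau amplitudes against salt
#'
#' @param fits list of \code{\link{fit_site_size}} results.
#' @param salt_mM matching salt concentrations (no duplicates).
#' @return data.frame(salt_mM, amplitude_fold, site_size_nt) sorted by
#'   salt.
#' @export
amplitude_vs_salt <- function(fits, salt_mM) {
  stopifnot(length(fits) == length(salt_mM))
  if (anyDuplicated(salt_mM)) stop("duplicate salt keys", call. = FALSE)
  out <- data.frame(
    salt_mM = salt_mM,
    amplitude_fold = vapply(fits, function(f) f$amplitude_fold, numeric(1)),
    site_size_nt = vapply(fits, function(f) f$site_size_nt, numeric(1)))
  out[order(out$salt_mM), , drop = FALSE]
}

#' Salt back-titration midpoint
#'
#' Fits a declining line times a logistic dissociation factor,
#' \eqn{s(salt) = (a + b \, salt) / (1 + e^{(salt - m)/w})}, to the points
#' past the signal maximum (the pre-transition rise is excluded), and
#' returns the inflection salt m: the salt-titration midpoint at which
#' half of the pre-formed complex has dissociated.
#'
#' @param table data.frame(salt_mM, signal) covering the full
#'   dissociation limb (signal must fall below half of its local
#'   plateau).
#' @return object of class \code{backtitration_result}: list(midpoint_mM,
#'   peak_signal, decline_slope, width_mM, rss).
#' @export
find_salt_midpoint <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("salt_mM", "signal") %in% names(table)))
  s <- table$salt_mM
  y <- table$signal
  o <- order(s); s <- s[o]; y <- y[o]
  i_max <- which.max(y)
  post <- seq(i_max, length(s))
  if (length(post) < 6L || min(y[post]) > 0.5 * y[i_max]) {
    stop(sprintf(
      "dissociation limb not covered: signal never falls below half of its peak beyond %g mM; extend the titration above %g mM",
      s[i_max], max(s)), call. = FALSE)
  }
  sp <- s[post]; yp <- y[post]

  # starting values: half-peak crossing and the early-decline line
  half <- 0.5 * yp[1]
  i_cross <- which(yp <= half)[1]
  m0 <- approx(yp[c(i_cross - 1L, i_cross)], sp[c(i_cross - 1L, i_cross)],
               xout = half)$y
  w0 <- diff(range(sp)) / 20
  early <- sp < m0 - 2 * w0
  line0 <- if (sum(early) >= 2) coef(lm(yp[early] ~ sp[early])) else
    c(yp[1], 0)

  rss_fun <- function(par) {
    a <- par[1]; b <- par[2]; m <- par[3]; w <- exp(par[4])
    pred <- (a + b * sp) * plogis((m - sp) / w)
    sum((yp - pred)^2)
  }
  opt <- stats::optim(c(line0[1], line0[2], m0, log(w0)), rss_fun,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  # polish
  opt <- stats::optim(opt$par, rss_fun, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  p <- unname(opt$par)
  midpoint <- p[3]
  if (midpoint < min(sp) || midpoint > max(sp)) {
    stop("fitted midpoint falls outside the data range", call. = FALSE)
  }
  structure(list(midpoint_mM = midpoint,
                 peak_signal = y[i_max],
                 decline_slope = -p[2],
                 width_mM = exp(p[4]),
                 rss = opt$value),
            class = "backtitration_result")
}

#' @export
print.backtitration_result <- function(x, ...) {
  cat(sprintf(
    "<backtitration_result> midpoint = %.0f mM, peak = %.2f, width = %.0f mM\n",
    x$midpoint_mM, x$peak_signal, x$width_mM))
  invisible(x)
}
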