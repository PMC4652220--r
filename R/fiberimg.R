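#' Measure fiber length in one frame
#'
#' The fiber extends from the tether pixel along the flow axis (image
#' rows, increasing index). Background level and noise are estimated from
#' the flanking columns (the outermost column on each side) unless given.
#' Pixels are classified by the rule threshold = background mean +
#' k x background s.d., and the length is the contiguous above-threshold
#' run starting at the tether row (on the per-row maximum across the
#' non-flanking columns), times the pixel size. Counting the contiguous
#' run from the tether, rather than all bright pixels, is robust to
#' detached debris elsewhere in the frame.
#'
#' @param frame 2-D intensity matrix (rows = flow axis).
#' @param tether c(row, col) of the tether pixel (1-based).
#' @param pixel_um pixel size (um).
#' @param k threshold stringency in background s.d. units (default 3).
#' @param background optional c(mean, sd) to use instead of the flanking
#'   estimate.
#' @return fiber length in um.
#' @export
measure_fiber_length <- function(frame, tether, pixel_um, k = 3,
                                 background = NULL) {
  stopifnot(is.matrix(frame), length(tether) == 2L)
  stopifnot_scalar(pixel_um, "pixel_um", positive = TRUE)
  nr <- nrow(frame); nc <- ncol(frame)
  tr <- tether[1]; tc <- tether[2]
  if (tr < 1 || tr > nr || tc < 1 || tc > nc) {
    stop("tether pixel outside frame", call. = FALSE)
  }
  if (is.null(background)) {
    flank <- frame[, c(1L, nc)]
    background <- c(mean(flank), sd(flank))
  }
  thr <- background[1] + k * max(background[2], 0) + 1e-12
  body_cols <- if (nc > 2L) 2L:(nc - 1L) else seq_len(nc)
  profile <- apply(frame[, body_cols, drop = FALSE], 1, max)
  if (profile[tr] <= thr) {
    stop("fiber not found: tether pixel not above threshold", call. = FALSE)
  }
  run <- 0L
  for (r in tr:nr) {
    if (profile[r] > thr) run <- run + 1L else break
  }
  run * pixel_um
}

#' Mean and s.d. of a region of interest
#'
#' @param frame 2-D intensity matrix.
#' @param roi c(row1, row2, col1, col2), inclusive 1-based bounds.
#' @param background background level to subtract when
#'   \code{subtract_background = TRUE}.
#' @param subtract_background subtract the background level from the mean?
#' @return c(mean, sd) of the ROI pixels.
#' @export
measure_roi_intensity <- function(frame, roi, background = 0,
                                  subtract_background = FALSE) {
  stopifnot(is.matrix(frame), length(roi) == 4L)
  if (roi[1] < 1 || roi[2] > nrow(frame) || roi[3] < 1 ||
      roi[4] > ncol(frame) || roi[1] > roi[2] || roi[3] > roi[4]) {
    stop("ROI empty or outside frame", call. = FALSE)
  }
  px <- frame[roi[1]:roi[2], roi[3]:roi[4]]
  m <- mean(px)
  if (subtract_background) m <- m - background
  c(mean = m, sd = if (length(px) > 1L) sd(px) else 0)
}

#' Per-frame fiber trace from an image stack
#'
#' Applies \code{\link{measure_fiber_length}} and
#' \code{\link{measure_roi_intensity}} to every frame of a stack. The ROI
#' defaults to a fixed rectangle around the tether spanning the maximum
#' observed fiber extent (all rows from the tether down, the body
#' columns).
#'
#' @param stack 3-D array (rows, cols, frames).
#' @param tether c(row, col) tether pixel.
#' @param pixel_um pixel size (um).
#' @param frame_interval_s seconds per frame.
#' @param k threshold stringency (background s.d. units).
#' @param roi optional c(row1, row2, col1, col2); NULL for the default.
#' @param subtract_background subtract the flanking-column background
#'   from ROI means?
#' @return data.frame(frame, time_s, length_um, roi_mean, roi_sd) of class
#'   \code{fiber_trace}.
#' @export
analyze_fiber_stack <- function(stack, tether, pixel_um,
                                frame_interval_s = 1, k = 3, roi = NULL,
                                subtract_background = FALSE) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nf <- dim(stack)[3]
  if (is.null(roi)) {
    roi <- c(tether[1], nr, max(2L, tether[2] - 2L),
             min(nc - 1L, tether[2] + 2L))
  }
  rows <- lapply(seq_len(nf), function(f) {
    frame <- stack[, , f]
    flank <- frame[, c(1L, nc)]
    bg <- c(mean(flank), sd(flank))
    len <- measure_fiber_length(frame, tether, pixel_um, k = k,
                                background = bg)
    inten <- measure_roi_intensity(frame, roi, background = bg[1],
                                   subtract_background = subtract_background)
    data.frame(frame = f, time_s = (f - 1) * frame_interval_s,
               length_um = len, roi_mean = inten[["mean"]],
               roi_sd = inten[["sd"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fiber_trace", "data.frame")
  out
}

#' Normalize fiber intensities to a reference condition
#'
#' @param trace a \code{fiber_trace} (or any data.frame with a
#'   \code{roi_mean} column).
#' @param reference mean ROI intensity of the 0 mM reference condition,
#'   > 0.
#' @return the trace with a \code{normalized_intensity} column added.
#' @export
normalize_intensity <- function(trace, reference) {
  stopifnot(is.data.frame(trace), "roi_mean" %in% names(trace))
  stopifnot_scalar(reference, "reference", positive = TRUE)
  trace$normalized_intensity <- trace$roi_mean / reference
  trace
}

#' Gaussian summary of a length population
#'
#' Maximum-likelihood normal fit on the raw per-molecule lengths; the
#' estimates are the sample mean and sample standard deviation (the
#' bin-free equivalent of fitting a Gaussian to a histogram).
#'
#' @param lengths_um per-molecule lengths (um), >= 2 distinct values;
#'   a warning is issued below 10 molecules.
#' @param condition optional condition label.
#' @return object of class \code{length_distribution}: list(condition,
#'   mu_um, sigma_um, n_molecules, lengths_um).
#' @export
fit_length_distribution <- function(lengths_um, condition = NA_character_) {
  lengths_um <- lengths_um[is.finite(lengths_um)]
  n <- length(lengths_um)
  if (length(unique(lengths_um)) < 2L) {
    stop("need at least 2 distinct lengths (degenerate variance)",
         call. = FALSE)
  }
  if (n < 10L) warning("fewer than 10 molecules in this condition",
                       call. = FALSE)
  structure(list(condition = condition, mu_um = mean(lengths_um),
                 sigma_um = sd(lengths_um), n_molecules = n,
                 lengths_um = lengths_um),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("<length_distribution> %s: mu = %.2f um, sigma = %.2f um, n = %d\n",
              x$condition, x$mu_um, x$sigma_um, x$n_molecules))
  invisible(x)
}

#' Condensation series: length summaries across salt
#'
#' @param distributions list of \code{\link{fit_length_distribution}}
#'   results.
#' @param salt_mM matching salt concentrations.
#' @return data.frame(salt_mM, mu_um, sigma_um, n_molecules, L_rel) sorted
#'   by salt; \code{L_rel} is mu / mu(0 mM) and is omitted (with a
#'   warning) when no 0 mM condition is present.
#' @export
condensation_series <- function(distributions, salt_mM) {
  stopifnot(length(distributions) == length(salt_mM))
  out <- data.frame(
    salt_mM = salt_mM,
    mu_um = vapply(distributions, function(d) d$mu_um, numeric(1)),
    sigma_um = vapply(distributions, function(d) d$sigma_um, numeric(1)),
    n_molecules = vapply(distributions, function(d) d$n_molecules,
                         integer(1)))
  out <- out[order(out$salt_mM), , drop = FALSE]
  if (any(out$salt_mM == 0)) {
    out$L_rel <- out$mu_um / out$mu_um[out$salt_mM == 0][1]
  } else {
    warning("no 0 mM condition; L/L0 omitted", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
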