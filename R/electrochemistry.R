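#' Polarization curve from a resistance sweep
#'
#' Holds the (external resistance, steady voltage) points of a
#' polarization experiment and derives, per point, the circuit current
#' I = V/R, the current density I/A and the power density V I / A, both
#' normalized to the cathode area.
#'
#' @param resistance_ohm External resistances (Ohm), > 0.
#' @param voltage_v Steady cell voltage at each resistance (V), >= 0.
#' @param cathode_area_m2 Cathode area (m2).
#' @return Object of class \code{polarization_curve}; the \code{points}
#'   data frame carries the derived densities.
#' @export
polarization_curve <- function(resistance_ohm, voltage_v,
                               cathode_area_m2 = 7e-4) {
  if (length(resistance_ohm) != length(voltage_v))
    stop("resistance_ohm and voltage_v must have the same length")
  if (any(!is.finite(resistance_ohm)) || any(resistance_ohm <= 0))
    stop("resistances must be positive and finite")
  if (any(!is.finite(voltage_v)) || any(voltage_v < 0))
    stop("voltages must be >= 0 and finite")
  dup <- duplicated(resistance_ohm)
  if (any(dup)) {
    for (r in unique(resistance_ohm[dup])) {
      v <- voltage_v[resistance_ohm == r]
      if (diff(range(v)) > 0.05 * max(max(v), 1e-12))
        stop("conflicting voltages at duplicated resistance ", r, " Ohm")
    }
  }
  o <- order(resistance_ohm)
  current_a <- voltage_v / resistance_ohm
  pts <- data.frame(resistance_ohm = resistance_ohm[o],
                    voltage_v = voltage_v[o],
                    current_a = current_a[o],
                    current_density_a_m2 = current_a[o] / cathode_area_m2,
                    power_density_w_m2 =
                      (voltage_v[o] * current_a[o]) / cathode_area_m2)
  structure(list(points = pts, cathode_area_m2 = cathode_area_m2),
            class = "polarization_curve")
}

#' @export
print.polarization_curve <- function(x, ...) {
  cat(sprintf("Polarization curve: %d points, R = %g..%g Ohm, cathode %.1f cm2\n",
              nrow(x$points), min(x$points$resistance_ohm),
              max(x$points$resistance_ohm), x$cathode_area_m2 * 1e4))
  print(x$points, digits = 4)
  invisible(x)
}

#' @export
plot.polarization_curve <- function(x, ...) {
  p <- x$points
  plot(p$current_density_a_m2, p$power_density_w_m2, type = "b",
       xlab = "current density (A/m2)", ylab = "power density (W/m2)", ...)
  invisible(x)
}

#' Maximum power density and internal resistance of a polarization sweep
#'
#' The maximum power density (MPD) is taken over the measured points (no
#' interpolation, matching a discrete resistance sweep).  The internal
#' resistance is estimated from the negated least-squares slope of the
#' cell polarization line V = OCV - R_int I; by the maximum power
#' transfer theorem the MPD of a linear cell falls at R_ext = R_int.
#'
#' @param curve A \code{\link{polarization_curve}}.
#' @return List with \code{mpd_w_m2}, \code{current_density_at_mpd_a_m2},
#'   \code{mpd_resistance_ohm}, \code{internal_resistance_ohm},
#'   \code{ocv_v} and \code{flags} (character; e.g. the maximum lies on
#'   the sweep boundary, so the true peak may not be bracketed).
#' @examples
#' pc <- simulate_polarization(0.7, 200, resistances = c(100, 150, 200,
#'                                                       300, 500, 1000, 5000))
#' polarization_analysis(pc)
#' @export
polarization_analysis <- function(curve) {
  stopifnot(inherits(curve, "polarization_curve"))
  p <- curve$points
  flags <- character()
  i <- which.max(p$power_density_w_m2)
  if (length(unique(p$resistance_ohm)) < 3)
    flags <- c(flags, "fewer than 3 distinct resistances: maximum not bracketed")
  else if (i == 1L || i == nrow(p))
    flags <- c(flags, "maximum at sweep boundary: true peak may lie outside")
  if (length(unique(p$resistance_ohm)) >= 2 &&
      stats::sd(p$current_a) > 0) {
    fit <- stats::lm(voltage_v ~ current_a, data = p)
    r_int <- -unname(stats::coef(fit)[2])
    ocv <- unname(stats::coef(fit)[1])
  } else {
    r_int <- NA_real_; ocv <- NA_real_
  }
  list(mpd_w_m2 = p$power_density_w_m2[i],
       current_density_at_mpd_a_m2 = p$current_density_a_m2[i],
       mpd_resistance_ohm = p$resistance_ohm[i],
       internal_resistance_ohm = r_int,
       ocv_v = ocv,
       flags = flags)
}

# ---------------------------------------------------------------------------
# Cyclic voltammetry

#' Cyclic voltammogram container
#'
#' One CV scan: potential vs. a reference electrode (typically Ag/AgCl)
#' and the current response, split into sweep-direction segments.  If
#' \code{segment} is not given it is inferred from the sign of the
#' potential increments (increasing potential = anodic sweep).
#'
#' @param potential_v Electrode potential (V).
#' @param current_a Current (A); anodic (oxidation) current positive.
#' @param scan_rate_v_s Scan rate (V/s), default 1 mV/s.
#' @param segment Optional character/factor: \code{"anodic"} or
#'   \code{"cathodic"} per sample.
#' @return Object of class \code{voltammogram}.
#' @export
voltammogram <- function(potential_v, current_a, scan_rate_v_s = 0.001,
                         segment = NULL) {
  n <- length(potential_v)
  if (length(current_a) != n)
    stop("potential_v and current_a must have the same length")
  if (n < 3) stop("a voltammogram needs at least 3 samples")
  if (is.null(segment)) {
    dir <- sign(diff(potential_v))
    dir[dir == 0] <- 1
    segment <- c(ifelse(dir > 0, "anodic", "cathodic"),
                 ifelse(dir[n - 1] > 0, "anodic", "cathodic"))
  }
  segment <- as.character(segment)
  if (!all(segment %in% c("anodic", "cathodic")))
    stop("segment values must be 'anodic' or 'cathodic'")
  structure(list(data = data.frame(potential_v = potential_v,
                                   current_a = current_a,
                                   segment = segment),
                 scan_rate_v_s = scan_rate_v_s),
            class = "voltammogram")
}

#' @export
print.voltammogram <- function(x, ...) {
  d <- x$data
  cat(sprintf("Voltammogram: %d samples, %.3g..%.3g V, scan rate %g mV/s\n",
              nrow(d), min(d$potential_v), max(d$potential_v),
              x$scan_rate_v_s * 1000))
  cat("  segments:", paste(sprintf("%s (%d)", names(table(d$segment)),
                                   table(d$segment)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.voltammogram <- function(x, ...) {
  d <- x$data
  plot(d$potential_v, d$current_a * 1e3, type = "l",
       xlab = "potential (V vs. ref)", ylab = "current (mA)", ...)
  invisible(x)
}

# split rows into the voltammogram's sweep segments, preserving order
segment_rows <- function(v) {
  d <- v$data
  split(seq_len(nrow(d)), cumsum(c(TRUE, d$segment[-1] != d$segment[-nrow(d)])))
}

#' First derivative dI/dE of a voltammogram
#'
#' Smooths the current of each sweep segment with a Savitzky-Golay
#' moving polynomial (order 2) and differentiates by centered finite
#' differences (one-sided at the segment ends).  The raw derivative of
#' 1 mV-step data is noise-dominated, hence smoothing first.
#'
#' @param v A \code{\link{voltammogram}}.
#' @param smooth_window Odd window length (samples) for the smoother;
#'   must be shorter than every segment.
#' @param poly_order Polynomial order of the smoother.
#' @return Data frame with \code{potential_v}, \code{didE_a_v},
#'   \code{segment}.
#' @export
cv_first_derivative <- function(v, smooth_window = 11, poly_order = 2) {
  stopifnot(inherits(v, "voltammogram"))
  if (smooth_window %% 2 != 1 || smooth_window < poly_order + 2)
    stop("smooth_window must be odd and exceed the polynomial order + 1")
  out <- lapply(segment_rows(v), function(idx) {
    d <- v$data[idx, ]
    if (smooth_window >= nrow(d))
      stop("smooth_window (", smooth_window,
           ") must be shorter than the segment (", nrow(d), " samples)")
    if (any(diff(d$potential_v) == 0) ||
        length(unique(sign(diff(d$potential_v)))) != 1)
      stop("potential must be strictly monotone within a sweep segment")
    sm <- signal::sgolayfilt(d$current_a, p = poly_order, n = smooth_window)
    data.frame(potential_v = d$potential_v,
               didE_a_v = pracma::gradient(sm, d$potential_v),
               segment = d$segment)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# local maxima of y with topographic prominence >= min_prom;
# returns indices sorted by position
peaks_with_prominence <- function(y, min_prom) {
  n <- length(y)
  if (n < 3) return(integer())
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand[vapply(cand, function(i) prominence_of(y, i) >= min_prom, logical(1))]
}

#' Detect redox peaks and inflection structure in a voltammogram
#'
#' Oxidation peaks are local current maxima in anodic sweep segments and
#' reduction peaks local minima in cathodic segments, each required to
#' have topographic prominence of at least \code{prominence_fraction}
#' times the segment's current scale — the larger of the smoothed
#' current's range and its maximum magnitude, so a flat capacitive trace
#' carrying only instrument noise yields an empty report.  Prominence is
#' computed on the smoothed signal; for peaks well above threshold,
#' detected potentials are invariant to a constant current offset and
#' the report is equivariant to current scaling.  Inflection points of the
#' current-potential curve are located as extrema of the smoothed first
#' derivative dI/dE; closely spaced redox centres that merge into one
#' broad current peak still show up as separate inflection structures.
#'
#' @param v A \code{\link{voltammogram}}.
#' @param prominence_fraction Fraction of the segment current range a
#'   peak must rise above its surroundings.
#' @param smooth_window,poly_order Smoother settings, as in
#'   \code{\link{cv_first_derivative}}.
#' @return Object of class \code{peak_report}: data frames
#'   \code{oxidation_peaks} and \code{reduction_peaks}
#'   (\code{potential_v}, \code{height_a}, \code{prominence_a}) and
#'   \code{inflections} (\code{potential_v}, \code{segment}).  An empty
#'   report is legitimate.
#' @examples
#' cv <- simulate_cv(data.frame(center_v = c(-0.21, -0.185),
#'                              height_a = c(2e-4, 1.5e-4),
#'                              width_v = c(0.03, 0.03),
#'                              kind = c("anodic", "cathodic")))
#' detect_redox_peaks(cv)
#' @export
detect_redox_peaks <- function(v, prominence_fraction = 0.05,
                               smooth_window = 11, poly_order = 2) {
  stopifnot(inherits(v, "voltammogram"))
  ox <- red <- data.frame(potential_v = numeric(), height_a = numeric(),
                          prominence_a = numeric())
  infl <- data.frame(potential_v = numeric(), segment = character())
  for (idx in segment_rows(v)) {
    d <- v$data[idx, ]
    if (nrow(d) <= smooth_window) next
    sm <- signal::sgolayfilt(d$current_a, p = poly_order, n = smooth_window)
    # reference scale: the larger of the current range and its magnitude,
    # so a flat capacitive trace with a little noise yields no detections
    rng <- max(diff(range(sm)), max(abs(sm)))
    if (rng == 0) next
    anodic <- d$segment[1] == "anodic"
    y <- if (anodic) sm else -sm
    pk <- peaks_with_prominence(y, prominence_fraction * rng)
    rows <- data.frame(potential_v = d$potential_v[pk],
                       height_a = d$current_a[pk],
                       prominence_a = abs(vapply(pk, function(i)
                         prominence_of(y, i), numeric(1))))
    if (anodic) ox <- rbind(ox, rows) else red <- rbind(red, rows)
    # inflections: extrema of dI/dE within the segment
    dv <- pracma::gradient(sm, d$potential_v)
    drng <- diff(range(dv))
    if (drng > 0) {
      up <- peaks_with_prominence(dv, prominence_fraction * drng)
      dn <- peaks_with_prominence(-dv, prominence_fraction * drng)
      ii <- sort(c(up, dn))
      if (length(ii))
        infl <- rbind(infl, data.frame(potential_v = d$potential_v[ii],
                                       segment = d$segment[1]))
    }
  }
  structure(list(oxidation_peaks = ox, reduction_peaks = red,
                 inflections = infl,
                 prominence_fraction = prominence_fraction),
            class = "peak_report")
}

# topographic prominence of index i in y (i must be a local maximum)
prominence_of <- function(y, i) {
  n <- length(y)
  left <- if (i > 1 && any(y[seq_len(i - 1)] > y[i])) {
    k <- max(which(y[seq_len(i - 1)] > y[i])); min(y[k:i])
  } else min(y[1:i])
  right <- if (i < n && any(y[(i + 1):n] > y[i])) {
    k <- i + min(which(y[(i + 1):n] > y[i])); min(y[i:k])
  } else min(y[i:n])
  y[i] - max(left, right)
}

#' @export
print.peak_report <- function(x, ...) {
  cat("Redox peak report:\n")
  cat("  oxidation peaks:",
      if (nrow(x$oxidation_peaks))
        paste(sprintf("%.3f V", x$oxidation_peaks$potential_v),
              collapse = ", ") else "none", "\n")
  cat("  reduction peaks:",
      if (nrow(x$reduction_peaks))
        paste(sprintf("%.3f V", x$reduction_peaks$potential_v),
              collapse = ", ") else "none", "\n")
  cat("  inflection points:", nrow(x$inflections), "\n")
  invisible(x)
}

#' Locate the five CV sampling stages of a batch cycle
#'
#' Segments one complete voltage cycle into the five stages at which
#' voltammograms are customarily collected: (1) the initial rise (first
#' sample above 10\% of the maximum), (2) the maximum, (3) the middle of
#' the plateau (samples within 95\% of the maximum), (4) the decline
#' (first drop below 50\% of maximum after the plateau), and (5) cycle
#' end (first drop below the 20 mV medium-replacement threshold).  The
#' threshold fractions are conventions, exposed as arguments.
#'
#' @param time_h Sample times (h).
#' @param voltage_v Cell voltage (V).
#' @param rise_fraction,plateau_fraction,fall_fraction Stage thresholds
#'   as fractions of the maximum voltage.
#' @param end_voltage_v Cycle-end voltage (V).
#' @return Named numeric vector \code{stage1}..\code{stage5} of times
#'   (h), \code{NA} where a stage is undefined, with a
#'   \code{"flags"} attribute describing degeneracies.
#' @export
stage_batch_for_cv <- function(time_h, voltage_v, rise_fraction = 0.10,
                               plateau_fraction = 0.95,
                               fall_fraction = 0.50,
                               end_voltage_v = 0.02) {
  if (length(time_h) != length(voltage_v))
    stop("time_h and voltage_v must have the same length")
  flags <- character()
  vmax <- max(voltage_v)
  if (vmax <= 0) stop("voltage never rises above zero: no cycle to stage")
  imax <- which.max(voltage_v)
  s1 <- time_h[which(voltage_v > rise_fraction * vmax)[1]]
  s2 <- time_h[imax]
  if (s1 == s2) flags <- c(flags, "stages 1 and 2 coincide (degenerate rise)")
  # contiguous plateau run containing the maximum
  hi <- voltage_v >= plateau_fraction * vmax
  runs <- rle(hi)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  k <- which(runs$values & starts <= imax & ends >= imax)
  p_from <- starts[k]; p_to <- ends[k]
  if (p_to - p_from < 2) {
    flags <- c(flags, "no plateau detected: stage 3 poorly defined")
    s3 <- s2
  } else {
    mid <- (time_h[p_from] + time_h[p_to]) / 2
    s3 <- time_h[p_from:p_to][which.min(abs(time_h[p_from:p_to] - mid))]
  }
  after <- if (p_to < length(voltage_v)) (p_to + 1L):length(voltage_v)
           else integer()
  i4 <- after[which(voltage_v[after] < fall_fraction * vmax)[1]]
  if (length(i4) && !is.na(i4)) s4 <- time_h[i4] else {
    s4 <- NA_real_
    flags <- c(flags, "voltage never fell below the decline threshold")
  }
  i5 <- after[which(voltage_v[after] < end_voltage_v)[1]]
  if (length(i5) && !is.na(i5)) s5 <- time_h[i5]
  else if (!is.na(s4)) s5 <- time_h[length(time_h)]
  else {
    s5 <- NA_real_
    flags <- c(flags, "cycle end (20 mV rule) not reached")
  }
  structure(c(stage1 = s1, stage2 = s2, stage3 = s3, stage4 = s4,
              stage5 = s5), flags = flags)
}
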