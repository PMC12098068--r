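#' Low-pass filter specification
#'
#' Describes the zero-lag recursive Butterworth filter applied to kinematic
#' and kinetic signals before any feature extraction: a fourth-order
#' low-pass with a 20 Hz cut-off, run forward then backward so the net
#' phase shift is zero.
#'
#' @param fs Sampling rate of the signal in Hz.
#' @param order Filter order of each pass.
#' @param cutoff Cut-off frequency in Hz; must lie below the Nyquist
#'   frequency `fs / 2`.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(fs, order = 4, cutoff = 20) {
  if (!is_count(order, 1L)) abort("filter order must be a positive integer")
  if (cutoff <= 0 || cutoff >= fs / 2)
    abort("cutoff %g Hz must lie strictly between 0 and the Nyquist frequency %g Hz",
          cutoff, fs / 2)
  structure(list(fs = fs, order = as.integer(order), cutoff = cutoff),
            class = "filter_spec")
}

# Steady-state initial filter state for a unit-amplitude step input
# (companion-matrix construction); scaling it by the first sample removes
# the start-up transient of the recursive filter.
lfilter_zi <- function(b, a) {
  n <- length(a)
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(comp), b[-1] - a[-1] * b[1])
}

#' Zero-lag Butterworth low-pass filter
#'
#' Applies a recursive Butterworth low-pass forward and then backward over
#' the series, cancelling phase distortion (zero net lag) at the cost of
#' squaring the magnitude response. Edges are extended by odd-symmetric
#' reflection over `3 * order` samples, and each pass starts from the
#' steady-state initial conditions of its first sample, which removes the
#' start-up transient (a constant series passes through exactly). Output
#' length equals input length.
#'
#' @param x Numeric series.
#' @param spec A [filter_spec()].
#' @return Filtered series, same length as `x`.
#' @export
zero_lag_butterworth <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  pad <- 3L * spec$order
  if (n <= pad)
    abort("series of length %d is too short to filter (need > %d samples)",
          n, pad)
  bf <- signal::butter(spec$order, spec$cutoff / (spec$fs / 2), type = "low")
  b <- as.numeric(bf$b)
  a <- as.numeric(bf$a)
  zi <- lfilter_zi(b, a)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  y <- as.numeric(iir_filter_cpp(b, a, xp, zi * xp[1]))
  y <- rev(as.numeric(iir_filter_cpp(b, a, rev(y), zi * y[length(y)])))
  y[(pad + 1):(pad + n)]
}

#' Detect heel strikes by GRF threshold crossing
#'
#' A heel strike is an ascending crossing of the vertical GRF through the
#' threshold (10 N by convention): the first sample at or above the
#' threshold whose predecessor is below it. Crossings closer than
#' `min_separation` samples to the previously kept event are discarded
#' (the first crossing wins), which suppresses threshold chatter.
#'
#' @param vgrf Vertical GRF series in newtons.
#' @param threshold Detection threshold in newtons.
#' @param min_separation Minimum distance between consecutive events, in
#'   samples (e.g. `0.4 * fs` for a 0.4 s refractory period).
#' @return A list of class `event_list` with `indices` (strictly
#'   increasing integer sample indices, possibly empty) and `threshold`.
#' @export
detect_heel_strikes <- function(vgrf, threshold = 10, min_separation = 0) {
  if (any(!is.finite(vgrf))) abort("vgrf contains non-finite values")
  n <- length(vgrf)
  idx <- integer(0)
  if (n >= 2) {
    up <- which(vgrf[-1] >= threshold & vgrf[-n] < threshold) + 1L
    if (length(up) && min_separation > 0) {
      keep <- up[1]
      for (i in up[-1]) if (i - keep[length(keep)] >= min_separation)
        keep <- c(keep, i)
      up <- keep
    }
    idx <- as.integer(up)
  }
  structure(list(indices = idx, threshold = threshold),
            class = "event_list")
}

#' Segment a stream into time-normalized gait cycles
#'
#' Cuts multichannel data at consecutive events (heel strikes) and linearly
#' resamples each cycle to a fixed number of points (101 by convention,
#' i.e. 0--100% of the gait cycle). `k + 1` events yield `k` cycles; cycle
#' `i` spans samples `events[i]` to `events[i + 1]` inclusive, and its
#' pre-resampling sample count is recorded as `events[i + 1] - events[i]`
#' so counts over consecutive cycles tile the event span exactly.
#'
#' @param channels Numeric matrix (channels x samples) or vector.
#' @param events An [detect_heel_strikes()] `event_list` or an integer
#'   vector of event indices.
#' @param n_points Number of points per normalized cycle (>= 2).
#' @return A list of channel matrices (channels x `n_points`), each with
#'   attribute `n_samples`; empty (with a warning) when fewer than two
#'   events are supplied.
#' @export
segment_and_normalize <- function(channels, events, n_points = 101) {
  if (inherits(events, "event_list")) events <- events$indices
  if (!is_count(n_points, 2L)) abort("n_points must be an integer >= 2")
  if (is.vector(channels)) channels <- matrix(channels, nrow = 1)
  if (length(events) < 2) {
    warning("fewer than 2 events; no cycles segmented", call. = FALSE)
    return(list())
  }
  events <- as.integer(events)
  if (any(diff(events) <= 0)) abort("event indices must be strictly increasing")
  if (events[1] < 1 || events[length(events)] > ncol(channels))
    abort("event indices outside the data range")
  lapply(seq_len(length(events) - 1L), function(i) {
    s <- events[i]; e <- events[i + 1L]
    seg <- channels[, s:e, drop = FALSE]
    len <- ncol(seg)
    out <- if (len == n_points) seg else {
      x0 <- seq(0, 1, length.out = len)
      x1 <- seq(0, 1, length.out = n_points)
      t(apply(seg, 1, function(row) approx(x0, row, xout = x1)$y))
    }
    rownames(out) <- rownames(channels)
    attr(out, "n_samples") <- e - s
    out
  })
}

#' Normalize a force to body weights
#'
#' @param force Force in newtons (scalar or vector).
#' @param body_weight_force Subject body weight force in newtons
#'   (mass times gravitational acceleration); must be positive.
#' @return `force / body_weight_force`, in BW.
#' @export
normalize_force_bw <- function(force, body_weight_force) {
  if (!is.numeric(body_weight_force) || length(body_weight_force) != 1L ||
      !is.finite(body_weight_force) || body_weight_force <= 0)
    abort("body_weight_force must be a positive scalar, got %s",
          paste(body_weight_force, collapse = ", "))
  force / body_weight_force
}

# Names of the numeric static features, in model input order.
static_feature_names <- function(include_rom_t3 = FALSE) {
  nm <- c("height", "weight", "bmi", "rom_t0", "rom_t1", "rom_t2",
          "quad_30", "quad_60", "quad_180", "quad_330")
  if (include_rom_t3) nm <- c(nm, "rom_t3")
  nm
}

#' Fit a standardization scaler on training subjects
#'
#' Computes per-feature means and standard deviations of the static
#' clinical features over a set of (training) subject profiles. Stage-T3
#' ROM is excluded by default: T3 is the prediction stage, and the model's
#' static inputs are the pre-T3 variables; set `include_rom_t3 = TRUE` to
#' add it. Constant features keep a unit scale so standardization stays
#' finite. Scalers must be fitted on training subjects only and re-fitted
#' per cross-validation fold to avoid information leakage.
#'
#' @param profiles A `data.frame` of subject profiles.
#' @param include_rom_t3 Include stage-T3 ROM as a static feature?
#' @return A list of class `static_scaler` with `center`, `scale`,
#'   `features` and `include_rom_t3`.
#' @export
fit_static_scaler <- function(profiles, include_rom_t3 = FALSE) {
  nm <- static_feature_names(include_rom_t3)
  missing <- setdiff(nm, names(profiles))
  if (length(missing))
    abort("profiles are missing static feature(s): %s",
          paste(missing, collapse = ", "))
  center <- vapply(nm, function(f) mean(profiles[[f]]), numeric(1))
  scale <- vapply(nm, function(f) sd(profiles[[f]]), numeric(1))
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale, features = nm,
                 include_rom_t3 = include_rom_t3),
            class = "static_scaler")
}

#' Build the standardized static feature vector of one subject
#'
#' Fixed ordering: height, weight, BMI, ROM at T0/T1/T2, quadriceps peak
#' torque at the four isokinetic speeds, then a binary EG-group indicator
#' (1 for the resistive brace group). All numeric features are z-scored
#' with the supplied scaler; the group indicator is passed through
#' unscaled. The default vector has length 11 (12 when the scaler includes
#' stage-T3 ROM).
#'
#' @param profile One subject profile (a row of the profiles table).
#' @param scaler A [fit_static_scaler()] result.
#' @return Named numeric vector of standardized features.
#' @export
build_feature_vector <- function(profile, scaler) {
  stopifnot(inherits(scaler, "static_scaler"))
  missing <- setdiff(c(scaler$features, "group"), names(profile))
  if (length(missing))
    abort("profile is missing field(s): %s", paste(missing, collapse = ", "))
  vals <- vapply(scaler$features, function(f) as.numeric(profile[[f]]),
                 numeric(1))
  if (any(!is.finite(vals)))
    abort("profile has non-finite static feature(s): %s",
          paste(scaler$features[!is.finite(vals)], collapse = ", "))
  z <- (vals - scaler$center) / scaler$scale
  c(z, group_eg = as.numeric(profile$group == "EG"))
}

#' @rdname build_feature_vector
#' @param profiles A `data.frame` of subject profiles.
#' @return `build_feature_matrix()`: a features x subjects matrix.
#' @export
build_feature_matrix <- function(profiles, scaler) {
  vapply(seq_len(nrow(profiles)),
         function(i) build_feature_vector(profiles[i, , drop = FALSE], scaler),
         numeric(length(scaler$features) + 1L))
}

#' Preprocess a raw cohort into labelled training records
#'
#' Runs the full signal pipeline on a raw simulated cohort: zero-lag
#' Butterworth filtering of kinematics and GRF at their native rates,
#' heel-strike detection on the filtered GRF (ascending 10 N crossing with
#' a refractory period), per-cycle segmentation, linear time normalization
#' of every channel to `n_points`, and body-weight normalization of the
#' GRF channel. Filtered GRF is clipped at zero (a contact force cannot
#' pull) before event detection. Events are mapped onto the kinematic
#' clock by their time stamps so all four channels are cut consistently.
#'
#' @param raw A [simulate_cohort_raw()] result.
#' @param order,cutoff Butterworth order and cut-off (Hz).
#' @param grf_threshold Heel-strike threshold in newtons.
#' @param min_separation Event refractory period in seconds.
#' @param n_points Normalized cycle length (0--100% of the gait cycle).
#' @return A list of class `gait_cohort`: `profiles`, `series` (array
#'   channels x `n_points` x records, channels `hip`, `knee`, `ankle` in
#'   degrees and `grf_bw` in BW), `labels` (BW), `meta` (record table) and
#'   the preprocessing settings.
#' @export
preprocess_cohort <- function(raw, order = 4, cutoff = 20,
                              grf_threshold = 10, min_separation = 0.4,
                              n_points = 101) {
  stopifnot(inherits(raw, "gait_raw"))
  fs_kin <- raw$params$gait$fs_kin
  fs_grf <- raw$params$gait$fs_grf
  spec_kin <- filter_spec(fs_kin, order, cutoff)
  spec_grf <- filter_spec(fs_grf, order, cutoff)
  n_cyc <- raw$cycles_per_subject
  per_subject <- vector("list", raw$n_subjects)
  for (i in seq_len(raw$n_subjects)) {
    prof <- raw$profiles[i, , drop = FALSE]
    st <- raw$streams[[i]]
    kin_f <- t(apply(st$kin, 1, zero_lag_butterworth, spec = spec_kin))
    rownames(kin_f) <- rownames(st$kin)
    grf_f <- pmax(0, zero_lag_butterworth(st$grf, spec_grf))
    ev <- detect_heel_strikes(grf_f, grf_threshold,
                              min_separation * fs_grf)
    if (length(ev$indices) < n_cyc + 1L)
      abort("subject %d: found %d heel strikes, need %d", i,
            length(ev$indices), n_cyc + 1L)
    ev_g <- ev$indices[seq_len(n_cyc + 1L)]
    t_ev <- (ev_g - 1) / fs_grf
    ev_k <- pmin(pmax(round(t_ev * fs_kin) + 1L, 1L), ncol(kin_f))
    cyc_kin <- segment_and_normalize(kin_f, ev_k, n_points)
    cyc_grf <- segment_and_normalize(grf_f, ev_g, n_points)
    arr <- array(0, dim = c(4L, n_points, n_cyc))
    for (j in seq_len(n_cyc)) {
      arr[1:3, , j] <- cyc_kin[[j]]
      arr[4, , j] <- normalize_force_bw(cyc_grf[[j]][1, ],
                                        prof$body_weight_force)
    }
    per_subject[[i]] <- arr
  }
  series <- array(unlist(per_subject, use.names = FALSE),
                  dim = c(4L, n_points, raw$n_subjects * n_cyc))
  dimnames(series) <- list(c("hip", "knee", "ankle", "grf_bw"), NULL, NULL)
  meta <- data.frame(
    record_id = seq_len(dim(series)[3]),
    subject_id = rep(seq_len(raw$n_subjects), each = n_cyc),
    cycle_index = rep(seq_len(n_cyc) - 1L, raw$n_subjects))
  meta$group <- raw$profiles$group[meta$subject_id]
  structure(list(profiles = raw$profiles, series = series,
                 labels = raw$labels$acl_force_bw, meta = meta,
                 n_points = as.integer(n_points),
                 channels = c("hip", "knee", "ankle", "grf_bw"),
                 preprocess = list(order = order, cutoff = cutoff,
                                   grf_threshold = grf_threshold,
                                   min_separation = min_separation,
                                   n_points = n_points),
                 oracle = raw$oracle, seed = raw$seed,
                 cycles_per_subject = n_cyc, group_split = raw$group_split),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects x %d cycles = %d records (%d x %d series)\n",
              nrow(x$profiles), x$cycles_per_subject, length(x$labels),
              dim(x$series)[1], dim(x$series)[2]))
  cat(sprintf("  groups: %s | labels (BW): mean %.3f sd %.3f\n",
              paste(sprintf("%s=%d", names(table(x$profiles$group)),
                            table(x$profiles$group)), collapse = " "),
              mean(x$labels), sd(x$labels)))
  invisible(x)
}

# Subset a cohort's records (used by cross-validation).
cohort_subset <- function(cohort, idx) {
  list(series = cohort$series[, , idx, drop = FALSE],
       labels = cohort$labels[idx],
       meta = cohort$meta[idx, , drop = FALSE])
}

# Static feature matrix for a set of records (columns = records).
cohort_statics <- function(cohort, scaler, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(cohort$labels)
  subj <- cohort$meta$subject_id[idx]
  per_subject <- build_feature_matrix(cohort$profiles, scaler)
  per_subject[, subj, drop = FALSE]
}
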