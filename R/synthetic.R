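#' Default cohort simulation parameters
#'
#' Group-specific targets for the synthetic rehabilitation cohort: two brace
#' groups of martial artists after ACL reconstruction, an experimental group
#' (`EG`) rehabilitated with a resistive knee brace and a control group
#' (`CG`) with a traditional range-of-motion brace. Anthropometrics and
#' staged knee range of motion (ROM, stages T0 preoperative through T3 at 60
#' days) are drawn from truncated normals with the group means/SDs below;
#' isokinetic quadriceps strength (peak torque at 30/60/180/330 deg/s) is
#' drawn around a 60 deg/s base value with a fixed speed-decay profile.
#'
#' @param cycle_duration Nominal gait-cycle duration in seconds.
#' @param fs_kin,fs_grf Sampling rates (Hz) for kinematics and vertical
#'   ground reaction force (GRF).
#' @return A list of simulation parameters, to be passed to
#'   [generate_subject()] and [generate_cohort()].
#' @export
cohort_params <- function(cycle_duration = 1.10, fs_kin = 200,
                          fs_grf = 1000) {
  list(
    groups = list(
      EG = list(p_female = 0.50,
                height = c(171.3, 7.4), weight = c(66.5, 8.7),
                rom_t0 = c(45.6, 6.9), rom_t1 = c(13.2, 8.8),
                rom_t2 = c(34.4, 6.6), rom_t3 = c(47.1, 7.3)),
      CG = list(p_female = 0.45,
                height = c(172.3, 7.7), weight = c(65.5, 9.1),
                rom_t0 = c(43.2, 6.2), rom_t1 = c(16.1, 9.0),
                rom_t2 = c(25.4, 7.4), rom_t3 = c(37.7, 8.8))
    ),
    height_range = c(150, 200),
    weight_range = c(40, 110),
    quad = list(speeds = c(30, 60, 180, 330),
                base60 = c(140, 30), base_range = c(60, 260),
                speed_scale = c(1.10, 1.00, 0.80, 0.65),
                within_sd = 0.03),
    gait = list(
      fs_kin = fs_kin, fs_grf = fs_grf,
      cycle_duration = cycle_duration, duration_jitter_sd = 0.03,
      stance_fraction = 0.62,
      grf_bumps = list(amp = c(1.15, 0.45, 1.10),
                       center = c(0.17, 0.31, 0.45),
                       width = c(0.34, 0.30, 0.34)),
      grf_amp_jitter_sd = 0.04, grf_noise_sd = 0.02,
      knee_baseline = 3, knee_stance_amp = 18, knee_swing_scale = 1.0,
      knee_amp_jitter_sd = 0.04, kin_noise_sd = 0.75
    ),
    gravity = 9.81
  )
}

#' Parameters of the sagittal-plane ACL shear oracle
#'
#' The simulator labels each gait cycle with a ground-truth peak ACL force
#' produced by a closed-form sagittal-plane shear balance: a quadriceps
#' force proxy pulls the tibia anteriorly through the patellar tendon angle,
#' hamstring co-contraction and the tibiofemoral geometry resist it, and the
#' GRF contributes a direct shear component (see [acl_force_oracle()]).
#' This oracle is a deliberately simple, fully documented stand-in for
#' laboratory musculoskeletal modelling: it gives the package a testable,
#' reproducible ground truth with the clinically expected group ordering
#' (resistive-brace subjects carry lower ACL load).
#'
#' @param patellar_intercept,patellar_slope Patellar tendon angle model
#'   `alpha(theta) = max(0, intercept + slope * theta)` in degrees, with
#'   `theta` the knee flexion angle in degrees.
#' @param hamstring_cofactor Unitless weight on the hamstring
#'   co-contraction term.
#' @param resistance_modulation Multiplier in `(0, 1]` applied to the
#'   quadriceps shear demand of resistive-brace (EG) subjects; control
#'   subjects always use 1.
#' @param quad_gain Unitless gain mapping GRF to the quadriceps force proxy.
#' @param quad_ref Reference quadriceps torque (N m) used to normalize a
#'   subject's mean isokinetic strength.
#' @param shear_gain Unitless gain of the direct GRF shear component.
#' @param noise_sd Standard deviation (body weights, BW) of the Gaussian
#'   label noise; set to 0 for noiseless labels.
#' @return A list of oracle parameters.
#' @export
oracle_params <- function(patellar_intercept = 20, patellar_slope = -0.25,
                          hamstring_cofactor = 0.3,
                          resistance_modulation = 0.8,
                          quad_gain = 2.6, quad_ref = 125,
                          shear_gain = 0.15, noise_sd = 0.05) {
  if (!(resistance_modulation > 0 && resistance_modulation <= 1))
    abort("resistance_modulation must be in (0, 1], got %g",
          resistance_modulation)
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  list(patellar_intercept = patellar_intercept,
       patellar_slope = patellar_slope,
       hamstring_cofactor = hamstring_cofactor,
       resistance_modulation = resistance_modulation,
       quad_gain = quad_gain, quad_ref = quad_ref,
       shear_gain = shear_gain, noise_sd = noise_sd)
}

#' Generate one synthetic subject profile
#'
#' Draws the static clinical features of one simulated athlete: sex,
#' anthropometrics (with BMI computed exactly from height and weight),
#' knee ROM at stages T0--T3 and isokinetic quadriceps peak torque at four
#' speeds. All draws come from mean-corrected truncated normals
#' ([rtruncnorm_mean()]) so cohort means recover the configured targets.
#'
#' @param group `"EG"` (resistive brace) or `"CG"` (traditional brace).
#' @param seed Non-negative integer seed; the profile is a deterministic
#'   function of `(group, seed)`.
#' @param subject_id Integer identifier stored in the profile.
#' @param params Simulation parameters, see [cohort_params()].
#' @return A one-row `data.frame` of class `subject_profile`.
#' @export
generate_subject <- function(group, seed, subject_id = 1L,
                             params = cohort_params()) {
  if (!is.character(group) || length(group) != 1L ||
      !group %in% names(params$groups))
    abort("unknown group '%s'; valid groups are: %s",
          as.character(group)[1L],
          paste(names(params$groups), collapse = ", "))
  if (!is_count(seed)) abort("seed must be a non-negative integer")
  g <- params$groups[[group]]
  q <- params$quad
  prof <- with_seed(seed, {
    sex <- if (runif(1) < g$p_female) "F" else "M"
    height <- rtruncnorm_mean(1, g$height[1], g$height[2],
                              params$height_range[1], params$height_range[2])
    weight <- rtruncnorm_mean(1, g$weight[1], g$weight[2],
                              params$weight_range[1], params$weight_range[2])
    roms <- vapply(c("rom_t0", "rom_t1", "rom_t2", "rom_t3"), function(nm)
      rtruncnorm_mean(1, g[[nm]][1], g[[nm]][2], 0, Inf), numeric(1))
    base <- rtruncnorm_mean(1, q$base60[1], q$base60[2],
                            q$base_range[1], q$base_range[2])
    quad <- base * q$speed_scale * exp(rnorm(4, 0, q$within_sd))
    data.frame(subject_id = as.integer(subject_id), group = group,
               sex = sex, height = height, weight = weight,
               bmi = weight / (height / 100)^2,
               rom_t0 = roms[["rom_t0"]], rom_t1 = roms[["rom_t1"]],
               rom_t2 = roms[["rom_t2"]], rom_t3 = roms[["rom_t3"]],
               quad_30 = quad[1], quad_60 = quad[2],
               quad_180 = quad[3], quad_330 = quad[4],
               body_weight_force = weight * params$gravity,
               stringsAsFactors = FALSE)
  })
  class(prof) <- c("subject_profile", "data.frame")
  prof
}

# Smooth compact-support bump: raised cosine of width w centred at c,
# evaluated on the normalized cycle phase u in [0, 1).
hann_bump <- function(u, center, width) {
  ifelse(abs(u - center) < width / 2, cos(pi * (u - center) / width)^2, 0)
}

# Smooth periodic perturbation: low-order random Fourier series.
fourier_noise <- function(u, amps, phases) {
  out <- numeric(length(u))
  for (j in seq_along(amps))
    out <- out + amps[j] * sin(2 * pi * j * u + phases[j])
  out
}

#' Simulate one raw gait cycle
#'
#' Emits one step (stance plus swing) of raw multichannel data at native
#' sampling rates: hip/knee/ankle angle trajectories on the kinematic clock
#' and vertical GRF on the force-platform clock. The knee trajectory is a
#' smooth two-wave flexion curve (stance flexion wave, then a larger swing
#' flexion wave whose amplitude scales with the subject's stage-T3 ROM);
#' the GRF is a double-hump stance profile peaking near 1.0--1.2 BW with an
#' exact-zero swing phase. Per-cycle amplitude and duration jitter and
#' smooth low-order noise are drawn from `seed`.
#'
#' @param profile A [generate_subject()] profile.
#' @param cycle_index Integer cycle counter (stored with the cycle).
#' @param seed Non-negative integer seed.
#' @param params Simulation parameters, see [cohort_params()].
#' @return A list of class `gait_cycle` with elements `kin` (3 x n matrix,
#'   rows `hip`, `knee`, `ankle`, degrees), `grf` (numeric, newtons),
#'   `fs_kin`, `fs_grf`, `duration` and `cycle_index`.
#' @export
simulate_gait_cycle <- function(profile, cycle_index, seed,
                                params = cohort_params()) {
  stopifnot(inherits(profile, "subject_profile"))
  gp <- params$gait
  if (gp$fs_kin <= 0 || gp$fs_grf <= 0)
    abort("sampling rates must be positive (fs_kin = %g, fs_grf = %g)",
          gp$fs_kin, gp$fs_grf)
  if (gp$cycle_duration <= 0) abort("cycle_duration must be positive")
  with_seed(seed, {
    duration <- gp$cycle_duration * exp(rnorm(1, 0, gp$duration_jitter_sd))
    amp_j <- exp(rnorm(3, 0, gp$grf_amp_jitter_sd))
    grf_noise <- list(a = rnorm(2, 0, gp$grf_noise_sd),
                      p = runif(2, 0, 2 * pi))
    knee_j <- exp(rnorm(2, 0, gp$knee_amp_jitter_sd))
    kin_noise <- lapply(1:3, function(i)
      list(a = rnorm(3, 0, gp$kin_noise_sd * c(1, 0.6, 0.4)),
           p = runif(3, 0, 2 * pi)))

    n_k <- max(8L, round(duration * gp$fs_kin))
    n_g <- max(8L, round(duration * gp$fs_grf))
    u_k <- (seq_len(n_k) - 1) / n_k
    u_g <- (seq_len(n_g) - 1) / n_g

    gb <- gp$grf_bumps
    grf_bw <- numeric(n_g)
    for (i in seq_along(gb$amp))
      grf_bw <- grf_bw + gb$amp[i] * amp_j[i] *
        hann_bump(u_g, gb$center[i], gb$width[i])
    mult <- 1 + fourier_noise(u_g, grf_noise$a, grf_noise$p)
    grf <- pmax(0, grf_bw * mult) * profile$body_weight_force

    knee <- gp$knee_baseline +
      gp$knee_stance_amp * knee_j[1] * hann_bump(u_k, 0.18, 0.36) +
      gp$knee_swing_scale * profile$rom_t3 * knee_j[2] *
        hann_bump(u_k, 0.78, 0.36) +
      fourier_noise(u_k, kin_noise[[2]]$a, kin_noise[[2]]$p)
    hip <- 5 + 25 * cos(2 * pi * (u_k - 0.02)) +
      fourier_noise(u_k, kin_noise[[1]]$a, kin_noise[[1]]$p)
    ankle <- -3 + 6 * hann_bump(u_k, 0.40, 0.55) -
      16 * hann_bump(u_k, 0.64, 0.22) +
      6 * hann_bump(u_k, 0.85, 0.25) +
      fourier_noise(u_k, kin_noise[[3]]$a, kin_noise[[3]]$p)

    structure(list(kin = rbind(hip = hip, knee = knee, ankle = ankle),
                   grf = grf, fs_kin = gp$fs_kin, fs_grf = gp$fs_grf,
                   duration = duration,
                   cycle_index = as.integer(cycle_index)),
              class = "gait_cycle")
  })
}

#' Align a raw gait cycle onto the kinematic clock
#'
#' Linearly interpolates the GRF channel (native force-platform rate) onto
#' the kinematic sampling instants so all channels share one time base.
#'
#' @param cycle A [simulate_gait_cycle()] result.
#' @return A 4 x n matrix with rows `hip`, `knee`, `ankle` (degrees) and
#'   `grf` (newtons).
#' @export
align_gait_cycle <- function(cycle) {
  stopifnot(inherits(cycle, "gait_cycle"))
  n_k <- ncol(cycle$kin)
  t_k <- (seq_len(n_k) - 1) / cycle$fs_kin
  t_g <- (seq_along(cycle$grf) - 1) / cycle$fs_grf
  grf_k <- approx(t_g, cycle$grf, xout = t_k, rule = 2)$y
  rbind(cycle$kin, grf = grf_k)
}

#' Sagittal-plane ACL force oracle
#'
#' Computes the ground-truth label of one gait cycle from knee flexion and
#' vertical GRF aligned on a common time base. The instantaneous anterior
#' shear is
#' `F(t) = max(0, Fq(t) sin(alpha(theta)) m - c Fh(t) cos(theta) + s(t))`
#' where `theta(t)` is knee flexion, `alpha(theta)` the patellar tendon
#' angle, `Fq` a quadriceps force proxy proportional to GRF and the
#' subject's mean isokinetic strength, `Fh = GRF` a hamstring
#' co-contraction proxy, `s(t)` a direct GRF shear component and `m` the
#' resistive-brace modulation (EG subjects only). The label is the cycle
#' peak of `F(t)` divided by the subject's body weight force, plus optional
#' Gaussian noise, floored at zero.
#'
#' @param knee_deg Knee flexion series in degrees.
#' @param grf_n Vertical GRF series in newtons, same length as `knee_deg`.
#' @param profile Subject profile (supplies strength, group and body
#'   weight).
#' @param params Oracle parameters, see [oracle_params()].
#' @param noise_seed Optional seed for the label noise draw; with
#'   `params$noise_sd = 0` the label is an exact deterministic function of
#'   its inputs.
#' @return Peak ACL force in body weights (non-negative scalar).
#' @seealso [acl_shear_series()] for the full shear trajectory.
#' @export
acl_force_oracle <- function(knee_deg, grf_n, profile,
                             params = oracle_params(), noise_seed = NULL) {
  f <- acl_shear_series(knee_deg, grf_n, profile, params)
  label <- max(f) / profile$body_weight_force
  if (params$noise_sd > 0) {
    eps <- if (is.null(noise_seed)) rnorm(1, 0, params$noise_sd)
           else with_seed(noise_seed, rnorm(1, 0, params$noise_sd))
    label <- label + eps
  }
  max(label, 0)
}

#' @rdname acl_force_oracle
#' @return `acl_shear_series()`: the instantaneous anterior shear `F(t)` in
#'   newtons.
#' @export
acl_shear_series <- function(knee_deg, grf_n, profile,
                             params = oracle_params()) {
  if (length(knee_deg) != length(grf_n))
    abort("knee and GRF series must share a time base (lengths %d and %d)",
          length(knee_deg), length(grf_n))
  theta <- knee_deg * pi / 180
  alpha_deg <- pmax(0, params$patellar_intercept +
                      params$patellar_slope * knee_deg)
  alpha <- alpha_deg * pi / 180
  qs_norm <- mean(c(profile$quad_30, profile$quad_60,
                    profile$quad_180, profile$quad_330)) / params$quad_ref
  m <- if (profile$group == "EG") params$resistance_modulation else 1
  fq <- params$quad_gain * qs_norm * grf_n
  fh <- grf_n
  s <- params$shear_gain * grf_n * sin(theta)
  pmax(0, fq * sin(alpha) * m -
         params$hamstring_cofactor * fh * cos(theta) + s)
}

# Round-robin group assignment honouring the requested EG fraction.
assign_groups <- function(n, split) {
  grp <- character(n)
  eg <- 0L
  for (i in seq_len(n)) {
    if (eg < ceiling(i * split) - 1e-9) {
      grp[i] <- "EG"; eg <- eg + 1L
    } else grp[i] <- "CG"
  }
  grp
}

#' Simulate a raw synthetic cohort
#'
#' Generates subject profiles, continuous per-subject raw data streams
#' (concatenated gait cycles at native rates) and per-cycle ground-truth
#' ACL force labels. One extra cycle per subject is simulated so that the
#' downstream heel-strike segmentation recovers exactly
#' `cycles_per_subject` complete cycles.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param cycles_per_subject Gait cycles retained per subject.
#' @param group_split Fraction of subjects assigned to the EG group.
#' @param seed Master seed; the whole cohort is reproducible from it.
#' @param params Simulation parameters ([cohort_params()]).
#' @param oracle Oracle parameters ([oracle_params()]).
#' @return A list of class `gait_raw` with `profiles`, `streams` (per
#'   subject: `kin` 3 x n matrix, `grf` vector), `labels` (data frame of
#'   per-cycle BW labels) and the generating parameters.
#' @export
simulate_cohort_raw <- function(n_subjects, cycles_per_subject = 10,
                                group_split = 0.5, seed = 1,
                                params = cohort_params(),
                                oracle = oracle_params()) {
  if (!is_count(n_subjects, 2L)) abort("n_subjects must be an integer >= 2")
  if (!is_count(cycles_per_subject, 1L))
    abort("cycles_per_subject must be an integer >= 1")
  if (group_split < 0 || group_split > 1)
    abort("group_split must be in [0, 1]")
  groups <- assign_groups(n_subjects, group_split)
  n_sim <- cycles_per_subject + 1L
  profiles <- vector("list", n_subjects)
  streams <- vector("list", n_subjects)
  labels <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    prof <- generate_subject(groups[i], derive_seed(seed, i), subject_id = i,
                             params = params)
    cycles <- lapply(seq_len(n_sim), function(j)
      simulate_gait_cycle(prof, j - 1L,
                          derive_seed(seed, 1000000 + (i - 1) * n_sim + j),
                          params = params))
    lab <- vapply(seq_len(cycles_per_subject), function(j) {
      aligned <- align_gait_cycle(cycles[[j]])
      acl_force_oracle(aligned["knee", ], aligned["grf", ], prof,
                       params = oracle,
                       noise_seed = derive_seed(seed,
                                                2000000 + (i - 1) * n_sim + j))
    }, numeric(1))
    profiles[[i]] <- prof
    streams[[i]] <- list(
      kin = do.call(cbind, lapply(cycles, `[[`, "kin")),
      grf = unlist(lapply(cycles, `[[`, "grf"), use.names = FALSE))
    labels[[i]] <- data.frame(subject_id = i,
                              cycle_index = seq_len(cycles_per_subject) - 1L,
                              acl_force_bw = lab)
  }
  structure(list(profiles = do.call(rbind, profiles),
                 streams = streams,
                 labels = do.call(rbind, labels),
                 n_subjects = n_subjects,
                 cycles_per_subject = as.integer(cycles_per_subject),
                 group_split = group_split, seed = seed,
                 params = params, oracle = oracle),
            class = "gait_raw")
}

#' Generate a preprocessed synthetic cohort
#'
#' Convenience wrapper chaining [simulate_cohort_raw()] and
#' [preprocess_cohort()]: simulates the raw cohort and runs the full signal
#' pipeline (zero-lag Butterworth filtering, 10 N heel-strike detection,
#' segmentation, time normalization to `n_points`, BW normalization of the
#' GRF), yielding exactly `n_subjects * cycles_per_subject` labelled gait
#' cycle records.
#'
#' @inheritParams simulate_cohort_raw
#' @param preprocess Named list of overrides passed to
#'   [preprocess_cohort()] (e.g. `cutoff`, `grf_threshold`, `n_points`).
#' @return A `gait_cohort` object, see [preprocess_cohort()].
#' @export
generate_cohort <- function(n_subjects, cycles_per_subject = 10,
                            group_split = 0.5, seed = 1,
                            params = cohort_params(),
                            oracle = oracle_params(),
                            preprocess = list()) {
  raw <- simulate_cohort_raw(n_subjects, cycles_per_subject, group_split,
                             seed, params, oracle)
  do.call(preprocess_cohort, c(list(raw = raw), preprocess))
}
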