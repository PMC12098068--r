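test_that("subject generation is deterministic and respects the group enum", {
  a <- generate_subject("EG", 123)
  b <- generate_subject("EG", 123)
  expect_identical(a, b)
  c <- generate_subject("EG", 124)
  expect_false(identical(a, c))
  expect_error(generate_subject("XX", 1), "EG, CG")
})

test_that("BMI is exactly weight over height squared", {
  for (s in 1:20) {
    p <- generate_subject(if (s %% 2) "EG" else "CG", s)
    expect_equal(p$bmi, p$weight / (p$height / 100)^2, tolerance = 1e-12)
    expect_equal(p$body_weight_force, p$weight * 9.81, tolerance = 1e-12)
  }
  # worked example: 66.5 kg at 171.3 cm
  expect_equal(66.5 / 1.713^2, 22.66, tolerance = 1e-2)
})

test_that("large EG cohorts recover the configured stage-T3 ROM mean", {
  rom <- vapply(1:200, function(i)
    generate_subject("EG", 1000 + i)$rom_t3, numeric(1))
  se <- 7.3 / sqrt(200)
  expect_lt(abs(mean(rom) - 47.1), 2 * se)
  expect_true(all(vapply(1:50, function(i) {
    p <- generate_subject("CG", 2000 + i)
    all(c(p$rom_t0, p$rom_t1, p$rom_t2, p$rom_t3) >= 0)
  }, logical(1))))
})

test_that("cohort means are recovered across replicates (mean-corrected truncation)", {
  # The truncated-normal location adjustment makes sample means unbiased;
  # the fraction of replicates whose mean falls within 2 SE of the target
  # must be consistent with the nominal ~95% coverage (one-sided Monte
  # Carlo tolerance at 100 replicates).
  fields <- c(height = 171.3, rom_t1 = 13.2, rom_t3 = 47.1)
  sds <- c(height = 7.4, rom_t1 = 8.8, rom_t3 = 7.3)
  n <- 200
  reps <- 100
  hits <- matrix(FALSE, reps, length(fields),
                 dimnames = list(NULL, names(fields)))
  for (r in seq_len(reps)) {
    profs <- do.call(rbind, lapply(1:n, function(i)
      generate_subject("EG", r * 10000 + i)))
    for (f in names(fields)) {
      se <- sds[[f]] / sqrt(n)
      hits[r, f] <- abs(mean(profs[[f]]) - fields[[f]]) < 2 * se
    }
  }
  min_cov <- 0.95 - 1.645 * sqrt(0.95 * 0.05 / reps)
  for (f in names(fields)) expect_gte(mean(hits[, f]), min_cov)
})

test_that("simulated cycles have non-negative GRF and one 10 N rise per step", {
  p <- generate_subject("CG", 5)
  for (s in 1:10) {
    cy <- simulate_gait_cycle(p, 0, 300 + s)
    expect_true(all(cy$grf >= 0))
    g <- cy$grf
    crossings <- sum(g[-1] >= 10 & g[-length(g)] < 10)
    expect_identical(crossings, 1L)
    expect_equal(length(cy$grf) / cy$fs_grf, ncol(cy$kin) / cy$fs_kin,
                 tolerance = 0.01)
  }
})

test_that("swing-phase peak knee flexion scales with stage-T3 ROM", {
  p1 <- generate_subject("EG", 9)
  p2 <- p1
  p2$rom_t3 <- p1$rom_t3 * 1.3
  c1 <- simulate_gait_cycle(p1, 0, 77)
  c2 <- simulate_gait_cycle(p2, 0, 77)
  n <- ncol(c1$kin)
  swing <- seq(round(0.62 * n), n)
  expect_gt(max(c2$kin["knee", swing]), max(c1$kin["knee", swing]))
})

test_that("the ACL shear oracle matches a sample-by-sample re-evaluation", {
  p <- generate_subject("EG", 21)
  cy <- simulate_gait_cycle(p, 0, 22)
  al <- align_gait_cycle(cy)
  par <- oracle_params(noise_sd = 0)
  f <- acl_shear_series(al["knee", ], al["grf", ], p, par)
  qs <- mean(c(p$quad_30, p$quad_60, p$quad_180, p$quad_330)) / par$quad_ref
  ref <- vapply(seq_along(f), function(t) {
    th <- al["knee", t] * pi / 180
    alpha <- max(0, par$patellar_intercept +
                   par$patellar_slope * al["knee", t]) * pi / 180
    g <- al["grf", t]
    max(0, par$quad_gain * qs * g * sin(alpha) * par$resistance_modulation -
          par$hamstring_cofactor * g * cos(th) + par$shear_gain * g * sin(th))
  }, numeric(1))
  expect_equal(f, ref, tolerance = 1e-9)
  expect_equal(acl_force_oracle(al["knee", ], al["grf", ], p, par),
               max(f) / p$body_weight_force, tolerance = 1e-12)
})

test_that("the oracle degenerates and orders correctly", {
  p <- generate_subject("CG", 31)
  n <- 50
  knee <- rep(20, n)
  expect_equal(acl_force_oracle(knee, rep(0, n), p, oracle_params(noise_sd = 0)),
               0)
  expect_error(acl_force_oracle(knee, rep(0, n - 1), p), "time base")
  # non-decreasing in the quadriceps gain, noise off
  grf <- seq(0, 700, length.out = n)
  l1 <- acl_force_oracle(knee, grf, p, oracle_params(quad_gain = 2, noise_sd = 0))
  l2 <- acl_force_oracle(knee, grf, p, oracle_params(quad_gain = 3, noise_sd = 0))
  expect_gte(l2, l1)
  # EG below CG on one default cohort
  raw <- simulate_cohort_raw(44, 2, 0.5, seed = 7)
  lab <- merge(raw$labels, raw$profiles[, c("subject_id", "group")])
  expect_lt(mean(lab$acl_force_bw[lab$group == "EG"]),
            mean(lab$acl_force_bw[lab$group == "CG"]))
})

test_that("cohort generation is reproducible and sized exactly", {
  co <- tiny_cohort()
  expect_identical(dim(co$series), c(4L, 101L, 24L))
  expect_length(co$labels, 24)
  expect_true(all(co$series[4, , ] >= 0))
  expect_true(all(co$labels >= 0))
  co2 <- generate_cohort(8, 3, 0.5, seed = 42)
  expect_identical(co, co2)
  # minimal cohort: one record per group
  co3 <- generate_cohort(2, 1, 0.5, seed = 1)
  expect_length(co3$labels, 2)
  expect_setequal(co3$profiles$group, c("EG", "CG"))
  expect_error(simulate_cohort_raw(1, 1, 0.5, 1), ">= 2")
})
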