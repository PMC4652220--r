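test_that("fit_equilibrium recovers noiseless exponentials exactly", {
  g <- gen_timetrace(1500, 2000, tau_s = 5, duration_s = 40, dt_s = 0.05,
                     seed = 1)
  fit <- fit_equilibrium(g$trace)
  expect_equal(fit$L_eq_nm, 2000, tolerance = 1e-6)
  expect_equal(fit$tau_s, 5, tolerance = 1e-4)
  expect_equal(fit$amplitude_nm, -500, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("constant traces yield amplitude 0 and an NA tau sentinel", {
  fit <- fit_equilibrium(data.frame(time_s = seq(0, 5, 0.1),
                                    extension_nm = 1500))
  expect_equal(fit$L_eq_nm, 1500)
  expect_equal(fit$amplitude_nm, 0)
  expect_true(is.na(fit$tau_s))
  expect_true(fit$converged)

  expect_error(fit_equilibrium(data.frame(time_s = 1:5,
                                          extension_nm = 1:5)),
               "10 samples")
})

test_that("tau and L_eq are recovered from noisy traces", {
  res <- vapply(1:20, function(seed) {
    g <- gen_timetrace(1500, 2000, tau_s = 5, duration_s = 40, dt_s = 0.05,
                       noise_sd_nm = 10, seed = seed)
    fit <- fit_equilibrium(g$trace)
    c(tau = abs(fit$tau_s - 5) / 5, leq = abs(fit$L_eq_nm - 2000) / 2000)
  }, numeric(2))
  expect_true(all(res["tau", ] < 0.10))
  expect_true(all(res["leq", ] < 0.01))
})

test_that("assemble_branches builds a consistent pair and enforces preconditions", {
  forces <- c(0.5, 1, 2, 4, 8)
  mk_fit <- function(f, seed) {
    L <- polymer_extension(make_model(0), f)
    fit_equilibrium(gen_timetrace(L * 0.9, L, tau_s = 2, duration_s = 20,
                                  dt_s = 0.05, seed = seed)$trace)
  }
  fits <- c(lapply(seq_along(forces), function(i) mk_fit(forces[i], i)),
            lapply(seq_along(forces), function(i) mk_fit(forces[i], i + 50)))
  dirs <- rep(c("pulling", "relaxing"), each = length(forces))
  pair <- assemble_branches(fits, rep(forces, 2), dirs, condition = "ssDNA",
                            salt_mM = 0)
  expect_s3_class(pair$pulling, "fe_branch")
  expect_equal(pair$pulling$extension_nm, rev(pair$relaxing$extension_nm),
               tolerance = 1e-3)
  # end-to-end: assembled branch matches the generating law within 1%
  expect_equal(pair$pulling$extension_nm,
               polymer_extension(make_model(0), forces), tolerance = 0.01)

  expect_error(assemble_branches(fits[1:5], forces, rep("pulling", 5)),
               "both a pulling and a relaxing")
  bad <- fits
  bad[[2]]$converged <- FALSE
  expect_error(assemble_branches(bad, rep(forces, 2), dirs),
               "unconverged.*1")
})

test_that("complete_branch appends the documented trapezoid", {
  b <- fe_branch(c(0.5, 5, 10.5), c(1000, 3000, 4000), direction = "pulling")
  done <- complete_branch(b, anchor_nm = 4700)
  expect_equal(nrow(done), 4L)
  expect_equal(done$force_pN[4], 17.5)
  expect_equal(done$extension_nm[4], 4700)
  appended <- integrate_work(done) - integrate_work(b)
  expect_equal(appended, 0.5 * (10.5 + 17.5) * 700)
  expect_equal(attr(done, "extrapolation_error_bound_pNnm"),
               0.5 * (17.5 - 10.5) * 700)

  full <- fe_branch(c(0.5, 10, 17.5), c(1000, 4000, 4700),
                    direction = "pulling")
  expect_identical(nrow(complete_branch(full, anchor_nm = 4700)), 3L)

  short <- fe_branch(c(0.5, 5), c(1000, 3000), direction = "pulling")
  expect_error(complete_branch(short, anchor_nm = 4700), "below")
})

test_that("completion-induced work error respects the reported bound", {
  m <- make_model(100)
  sched_full <- seq(0.5, 17.5, by = 0.04)  # contains 10.5 exactly
  sched_cut <- sched_full[sched_full <= 10.5]
  full <- gen_fec_ssdna(m, no_hyst(), sched_full, 0, seed = 1)$pulling
  cut <- gen_fec_ssdna(m, no_hyst(), sched_cut, 0, seed = 1)$pulling
  done <- complete_branch(cut, anchor_nm = polymer_extension(m, 17.5))
  err <- abs(integrate_work(done) - integrate_work(full))
  expect_lte(err, attr(done, "extrapolation_error_bound_pNnm"))
})

test_that("integrate_work handles rectangles, degenerate input and matches quadrature", {
  expect_equal(integrate_work(data.frame(force_pN = c(2, 2),
                                         extension_nm = c(0, 1000))), 2000)
  expect_equal(integrate_work(data.frame(force_pN = 2,
                                         extension_nm = 500)), 0)
  expect_error(integrate_work(data.frame(force_pN = c(1, 3, 2),
                                         extension_nm = c(0, 10, 5))),
               "sorted")

  m <- make_model(250)
  f <- seq(0.5, 10.5, length.out = 1000)
  w_trap <- integrate_work(data.frame(force_pN = f,
                                      extension_nm = polymer_extension(m, f)))
  w_exact <- polymer_work(m, 0.5, 10.5)
  expect_lt(abs(w_trap - w_exact) / w_exact, 0.001)
})

test_that("energy ledger zeroes out on identical branches and converts at 4.1", {
  f <- seq(0.5, 17.5, length.out = 50)
  mk <- function(cond, dir, ext) {
    fe_branch(if (dir == "relaxing") rev(f) else f,
              if (dir == "relaxing") rev(ext) else ext,
              condition = cond, salt_mM = 0, direction = dir)
  }
  ext <- polymer_extension(make_model(0), f)
  led <- energy_ledger(list(mk("ssDNA", "pulling", ext),
                            mk("ssDNA", "relaxing", ext)))
  expect_true(all(abs(led$entries$dE_kBT) < 1e-9))
  expect_true(all(abs(led$entries$ddE_kBT) < 1e-9))
  expect_true(all(abs(led$hysteresis$hysteresis_kBT) < 1e-9))

  # a 4100 pN nm work difference is exactly 1000 kBT
  w0 <- integrate_work(mk("ssDNA", "pulling", ext))
  k <- 1 + 4100 / w0  # work scales linearly with the extension axis
  led2 <- energy_ledger(list(mk("ssDNA", "pulling", ext),
                             mk("ssDNA", "relaxing", ext),
                             mk("+SSB", "pulling", k * ext),
                             mk("+SSB", "relaxing", k * ext)))
  ssb <- led2$entries$condition == "+SSB"
  expect_equal(led2$entries$dE_kBT[ssb], c(1000, 1000), tolerance = 1e-6)
})

test_that("ledger conservation: hysteresis equals dE_pull minus dE_relax", {
  m <- make_model(100)
  sched <- dense_schedule(120)
  fec <- gen_fec_ssdna(m, hysteresis_model(target_hysteresis_energy_kBT = 900),
                       sched, 0, seed = 1)
  bare0 <- gen_fec_ssdna(make_model(0), no_hyst(), sched, 0, seed = 2)
  anchor0 <- polymer_extension(make_model(0), 17.5)
  anchor <- polymer_extension(m, 17.5)
  branches <- list(
    complete_branch(bare0$pulling, anchor_nm = anchor0),
    complete_branch(bare0$relaxing, anchor_nm = anchor0),
    complete_branch(fec$pulling, anchor_nm = anchor),
    complete_branch(fec$relaxing, anchor_nm = anchor))
  led <- energy_ledger(branches)
  e <- led$entries
  for (i in seq_len(nrow(led$hysteresis))) {
    h <- led$hysteresis[i, ]
    sel <- e$condition == h$condition & e$salt_mM == h$salt_mM
    expect_equal(h$hysteresis_kBT,
                 e$dE_kBT[sel & e$direction == "pulling"] -
                   e$dE_kBT[sel & e$direction == "relaxing"])
  }
})

test_that("ledger rejects missing references and mismatched ceilings", {
  f <- seq(0.5, 17.5, length.out = 20)
  ext <- polymer_extension(make_model(0), f)
  b1 <- fe_branch(f, ext, condition = "ssDNA", salt_mM = 100,
                  direction = "pulling")
  expect_error(energy_ledger(list(b1)), "reference")

  b0 <- fe_branch(rev(f), rev(ext), condition = "ssDNA", salt_mM = 0,
                  direction = "relaxing")
  f2 <- seq(0.5, 10.5, length.out = 20)
  b2 <- fe_branch(f2, polymer_extension(make_model(0), f2),
                  condition = "+SSB", salt_mM = 0, direction = "pulling")
  expect_error(energy_ledger(list(b0, b2)), "ceiling")
})

test_that("per-tetramer accounting reproduces the worked arithmetic", {
  a <- per_tetramer_energy(250, 13552, 65)
  expect_identical(a$n_tetramers, 208)
  expect_equal(round(a$energy_per_tetramer_kBT, 1), 1.2)
  expect_equal(per_tetramer_energy(2000, 13552, 65)$energy_per_tetramer_kBT,
               2000 / 208)
  expect_equal(per_tetramer_energy(0, 13552, 65)$energy_per_tetramer_kBT, 0)
  expect_warning(per_tetramer_energy(100, 13552, 100), "30-80")
  expect_error(per_tetramer_energy(100, 50, 65), "exceed")
})

test_that("energy-vs-log-salt slope fitting works and validates input", {
  expect_error(fit_energy_slope(c(1, 2), c(0, 100)), "> 0")
  expect_warning(fit_energy_slope(c(1, 2), c(50, 100)), "interpolation")

  flat <- suppressWarnings(fit_energy_slope(rep(5, 4), c(25, 50, 100, 250)))
  expect_equal(flat$slope_kBT_per_ln_mM, 0, tolerance = 1e-9)

  ok <- 0L
  for (seed in 1:30) {
    salt <- c(25, 50, 100, 250, 750)
    dE <- withr::with_seed(seed, 100 + 1000 * log(salt) + rnorm(5, 0, 150))
    f <- fit_energy_slope(dE, salt)
    if (abs(f$slope_kBT_per_ln_mM - 1000) <= 2 * f$slope_se) ok <- ok + 1L
  }
  expect_gte(ok, 26L)  # ~95% coverage of a 2 s.e. interval
})

test_that("relative condensation normalizes to the 0 mM row", {
  tab <- data.frame(force_pN = rep(c(0.3, 1), each = 2),
                    salt_mM = rep(c(0, 750), 2),
                    length_nm = c(6500, 500, 7000, 1400))
  rc <- relative_condensation(tab)
  expect_equal(rc$L_rel[rc$salt_mM == 0], c(1, 1))
  expect_equal(rc$L_rel[rc$force_pN == 0.3 & rc$salt_mM == 750],
               500 / 6500)
  expect_equal(fold_condensation(6.5, 0.5), 13)

  expect_error(relative_condensation(tab[tab$salt_mM != 0, ]), "0 mM")
})

test_that("flow-force matching recovers exact matches and breaks ties low", {
  g <- gen_condensation_profiles(noise_sd = 0, seed = 1)
  res <- estimate_flow_force(g$tirf, g$tweezer)
  expect_equal(res$force_pN, 0.3)

  flat <- g$tweezer
  flat$L_rel <- rep(g$tirf$L_rel, length(unique(flat$force_pN)))
  res2 <- estimate_flow_force(g$tirf, flat)
  expect_equal(res2$force_pN, min(flat$force_pN))
  expect_equal(res2$interval_pN, range(flat$force_pN))
})

test_that("worked-example helpers reproduce the published arithmetic", {
  expect_equal(fold_condensation(6.5, 0.5), 13)
  expect_equal(fold_condensation(920, 560), 1.6)
  expect_equal(fold_condensation(77, 35), 2.2)
  expect_equal(fold_condensation(5, 5), 1)
  expect_error(fold_condensation(-1, 5), "> 0")

  expect_equal(predict_scaled_length(920, 6.6), 6.1)
  expect_equal(predict_scaled_length(560, 6.6), 3.7)
  expect_equal(predict_scaled_length(500, 1), 0.5)

  # Boltzmann x 298 K expressed in pN nm, to 2 significant figures
  expect_equal(signif(kBT_pNnm(25), 2), 4.1)
})

test_that("zero-bridging coated curves are flagged hysteresis-free under noise", {
  m <- make_model(100)
  sched <- dense_schedule(80)
  ok <- 0L
  n_seeds <- 40L
  for (seed in seq_len(n_seeds)) {
    fc <- gen_fec_coated(m, coating_model(condensation_factor = 0.6), sched,
                         noise_sd_nm = 10, seed = seed)
    h <- integrate_work(fc$pulling) - integrate_work(fc$relaxing)
    bound <- hysteresis_noise_bound(fc$pulling, fc$relaxing, 10)
    if (abs(h) <= bound) ok <- ok + 1L
  }
  expect_gte(ok / n_seeds, 0.9)
})
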