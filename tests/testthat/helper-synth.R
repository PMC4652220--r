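# Shared fixtures: a mid-salt polymer model and dense force schedules.

make_model <- function(salt_mM = 100, nt = 13552) {
  polymer_model(contour_length_nt = nt, salt_mM = salt_mM)
}

dense_schedule <- function(n = 500, lo = 0.5, hi = 10.5) {
  seq(lo, hi, length.out = n)
}

no_hyst <- function() hysteresis_model(target_hysteresis_energy_kBT = 0)

# noiseless bare + coated branch set completed to 17.5 pN, for ledger tests
make_completed_set <- function(model_salt, c_fac, seed, noise_sd_nm = 0,
                               n = 200) {
  m0 <- make_model(0)
  ms <- make_model(model_salt)
  sched <- dense_schedule(n)
  bare0 <- gen_fec_ssdna(m0, no_hyst(), sched, noise_sd_nm, seed = seed)
  bare <- gen_fec_ssdna(ms, no_hyst(), sched, noise_sd_nm, seed = seed + 1L)
  coat <- gen_fec_coated(ms, coating_model(condensation_factor = c_fac),
                         sched, noise_sd_nm, seed = seed + 2L)
  anchor0 <- polymer_extension(m0, 17.5)
  anchors <- polymer_extension(ms, 17.5)
  cb <- function(b) {
    a <- if (attr(b, "salt_mM") == 0) anchor0 else anchors
    complete_branch(b, anchor_nm = a)
  }
  lapply(list(bare0$pulling, bare0$relaxing, bare$pulling, bare$relaxing,
              coat$pulling, coat$relaxing), cb)
}
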