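#' Configuration for the synthetic respirometry study generator
#'
#' Defines the generative model for a two-ecotype lake-fish cohort and
#' its overnight post-chase respirometry trials. Defaults emulate a
#' perch study at 18 degrees C: 22 littoral and 29 pelagic fish of
#' roughly 27 g, a 180/30/210 s flush/wait/measure loop repeated 121
#' times, trials that start at maximum metabolic rate (post-chase) and
#' decay exponentially toward standard metabolic rate with spontaneous
#' activity bursts, linearly drifting background respiration, and
#' Gaussian sensor noise on oxygen concentration.
#'
#' Metabolic truth is drawn on the log10 scale from an allometric model:
#' `log10(SMR) = log10(smr_ref) + smr_exponent * log10(mass/mass_ref) +
#' habitat effect + sex effect + noise`, and analogously for MMR (no
#' habitat or sex effect by default). Littoral delta-13C is a
#' two-component Gaussian mixture (benthic-feeding vs pelagic-feeding
#' subgroups); pelagic delta-13C is a single component.
#'
#' @param n_littoral,n_pelagic Fish per capture habitat.
#' @param mass_mean,mass_sd Named numeric, body mass (g) per habitat.
#' @param length_mean,length_sd Named numeric, total length (mm).
#' @param mass_ref Reference mass (g) at which `smr_ref`/`mmr_ref` apply.
#' @param smr_ref Littoral female SMR at the reference mass (mg O2/h).
#' @param smr_exponent Allometric scaling exponent for SMR.
#' @param smr_sd_log10 Residual SD of log10(SMR).
#' @param smr_habitat_effect_log10 Additive log10 shift of pelagic SMR
#'   (0.062 corresponds to pelagic SMR about 15% above littoral).
#' @param smr_sex_effect_log10 Additive log10 shift of male SMR.
#' @param mmr_ref,mmr_exponent,mmr_sd_log10,mmr_habitat_effect_log10
#'   As above, for MMR.
#' @param mmr_floor_factor MMR is floored at this multiple of SMR.
#' @param post_chase_decay_tau_s Time constant of the post-chase decay
#'   from MMR to SMR (seconds).
#' @param burst_rate_per_h Poisson rate of spontaneous activity bursts.
#' @param burst_meanlog,burst_sdlog Lognormal burst magnitude (mg O2/h).
#' @param burst_decay_s Exponential decay time of a burst (seconds).
#' @param bg_pre,bg_post Background respiration at trial start and end
#'   (mg O2/h); interpolated linearly in between.
#' @param sensor_noise_sd Gaussian sensor noise SD (mg O2/L per point).
#' @param o2_saturation Air-saturated oxygen concentration (mg O2/L).
#' @param chamber_volume_l Chamber volume (L) for a fish of `mass_ref`
#'   grams. Chambers are size-matched to each fish, as in real systems:
#'   a fish of mass m gets a chamber of
#'   `chamber_volume_l * m / mass_ref` litres, keeping the
#'   signal-to-noise ratio of the oxygen decline comparable across body
#'   sizes.
#' @param d13c_littoral_means,d13c_littoral_sds Two-component littoral
#'   delta-13C mixture (permil); first component is the lower (more
#'   pelagic-reliant) mode.
#' @param d13c_littoral_weight_low Mixing weight of the lower component.
#' @param d13c_pelagic_mean,d13c_pelagic_sd Pelagic delta-13C (permil).
#' @param d15n_mean,d15n_sd Named numeric per habitat (permil).
#' @param cn_mean,cn_sd C:N ratio of muscle tissue.
#' @param prop_male Probability a fish is male.
#' @param n_loops Measurement loops per trial.
#' @param dt_s Sampling interval of the oxygen sensor (seconds).
#' @param bg_duration_s Length of each sealed background measurement.
#' @param protocol A [protocol_config()].
#' @param seed Default RNG seed used by the simulators.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_littoral = 22, n_pelagic = 29,
                       mass_mean = c(LITTORAL = 27.7, PELAGIC = 26.9),
                       mass_sd = c(LITTORAL = 9.7, PELAGIC = 9.3),
                       length_mean = c(LITTORAL = 140, PELAGIC = 141),
                       length_sd = c(LITTORAL = 17, PELAGIC = 17),
                       mass_ref = 27,
                       smr_ref = 3.0, smr_exponent = 0.8,
                       smr_sd_log10 = 0.04,
                       smr_habitat_effect_log10 = 0.062,
                       smr_sex_effect_log10 = 0.03,
                       mmr_ref = 12.0, mmr_exponent = 0.8,
                       mmr_sd_log10 = 0.05,
                       mmr_habitat_effect_log10 = 0,
                       mmr_floor_factor = 1.2,
                       post_chase_decay_tau_s = 3600,
                       burst_rate_per_h = 2,
                       burst_meanlog = 0, burst_sdlog = 0.5,
                       burst_decay_s = 120,
                       bg_pre = 0.1, bg_post = 0.3,
                       sensor_noise_sd = 0.02,
                       o2_saturation = 9.4,
                       chamber_volume_l = 0.5,
                       d13c_littoral_means = c(-24.7, -23.3),
                       d13c_littoral_sds = c(0.5, 0.5),
                       d13c_littoral_weight_low = 0.45,
                       d13c_pelagic_mean = -24.96, d13c_pelagic_sd = 0.61,
                       d15n_mean = c(LITTORAL = 12.8, PELAGIC = 13.2),
                       d15n_sd = c(LITTORAL = 0.5, PELAGIC = 0.5),
                       cn_mean = 3.22, cn_sd = 0.04,
                       prop_male = 0.5,
                       n_loops = 121, dt_s = 1, bg_duration_s = 600,
                       protocol = protocol_config(),
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(
      n_littoral >= 0, n_pelagic >= 0,
      all(mass_sd >= 0), all(length_sd >= 0),
      smr_ref > 0, mmr_ref > 0, smr_ref < mmr_ref,
      smr_sd_log10 >= 0, mmr_sd_log10 >= 0,
      post_chase_decay_tau_s >= 0, burst_rate_per_h >= 0,
      bg_pre >= 0, bg_post >= 0, sensor_noise_sd >= 0,
      o2_saturation > 0, chamber_volume_l > 0,
      length(d13c_littoral_means) == 2, all(d13c_littoral_sds >= 0),
      d13c_littoral_weight_low >= 0, d13c_littoral_weight_low <= 1,
      d13c_pelagic_sd >= 0,
      prop_male >= 0, prop_male <= 1,
      n_loops >= 1, dt_s > 0
    )
  })
  structure(cfg, class = "sim_config")
}

# Positive truncated normal draw (rejection at <= lo).
rnorm_pos <- function(n, mean, sd, lo = 0) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lo)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a study cohort with latent metabolic truth
#'
#' Draws per-fish metadata (habitat, sex, mass, length), muscle isotope
#' values, and the latent standard and maximum metabolic rates that the
#' trial simulator and the downstream pipeline try to recover.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`. The same seed always
#'   yields identical output.
#' @return A list with elements `cohort` (a `cohort_table` data frame)
#'   and `truth` (data frame: `fish_id`, `habitat`, `sex`, `mass_g`,
#'   `smr_true`, `mmr_true` in mg O2/h).
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_littoral + config$n_pelagic
  habitat <- rep(c("LITTORAL", "PELAGIC"),
                 c(config$n_littoral, config$n_pelagic))
  fish_id <- sprintf("F%03d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$prop_male, "M", "F")
  mass_g <- rnorm_pos(n, config$mass_mean[habitat], config$mass_sd[habitat],
                      lo = 2)
  length_mm <- rnorm_pos(n, config$length_mean[habitat],
                         config$length_sd[habitat], lo = 30)

  lsmr <- log10(config$smr_ref) +
    config$smr_exponent * log10(mass_g / config$mass_ref) +
    config$smr_habitat_effect_log10 * (habitat == "PELAGIC") +
    config$smr_sex_effect_log10 * (sex == "M") +
    stats::rnorm(n, 0, config$smr_sd_log10)
  lmmr <- log10(config$mmr_ref) +
    config$mmr_exponent * log10(mass_g / config$mass_ref) +
    config$mmr_habitat_effect_log10 * (habitat == "PELAGIC") +
    stats::rnorm(n, 0, config$mmr_sd_log10)
  smr_true <- 10^lsmr
  mmr_true <- pmax(10^lmmr, config$mmr_floor_factor * smr_true)

  is_lit <- habitat == "LITTORAL"
  d13c <- numeric(n)
  low_comp <- stats::runif(sum(is_lit)) < config$d13c_littoral_weight_low
  comp <- ifelse(low_comp, 1L, 2L)
  d13c[is_lit] <- stats::rnorm(sum(is_lit),
                               config$d13c_littoral_means[comp],
                               config$d13c_littoral_sds[comp])
  d13c[!is_lit] <- stats::rnorm(sum(!is_lit), config$d13c_pelagic_mean,
                                config$d13c_pelagic_sd)
  d15n <- stats::rnorm(n, config$d15n_mean[habitat], config$d15n_sd[habitat])
  cn <- rnorm_pos(n, config$cn_mean, config$cn_sd)

  cohort <- validate_cohort(data.frame(
    fish_id = fish_id, habitat = habitat, sex = sex,
    mass_g = mass_g, length_mm = length_mm,
    chamber_volume_l = config$chamber_volume_l * mass_g / config$mass_ref,
    d13c = d13c, d15n = d15n, cn_ratio = cn
  ))
  truth <- data.frame(fish_id = fish_id, habitat = habitat, sex = sex,
                      mass_g = mass_g, smr_true = smr_true,
                      mmr_true = mmr_true)
  truth <- truth[order(truth$fish_id), , drop = FALSE]
  rownames(truth) <- NULL
  attr(truth, "littoral_component") <-
    stats::setNames(comp, fish_id[is_lit])[order(fish_id[is_lit])]
  list(cohort = cohort, truth = truth)
}

# Evaluate the latent MO2 trajectory (mg O2/h) at times t (s):
# post-chase exponential decay from MMR to SMR plus burst pulses,
# truncated at MMR.
mo2_trajectory <- function(t, smr, mmr, tau, burst_times, burst_mags,
                           burst_decay) {
  base <- if (tau > 0) smr + (mmr - smr) * exp(-t / tau) else
    ifelse(t <= 0, mmr, smr)
  for (j in seq_along(burst_times)) {
    after <- t >= burst_times[j]
    base[after] <- base[after] +
      burst_mags[j] * exp(-(t[after] - burst_times[j]) / burst_decay)
  }
  pmin(base, mmr)
}

#' Simulate one post-chase respirometry trial
#'
#' Generates the oxygen trace of a single fish plus the matching pre-
#' and post-trial background (empty chamber) measurements. During sealed
#' measurement phases oxygen declines at
#' `(MO2_true(t) + bg_true(t)) / (3600 * V_eff)` mg O2/L/s, where
#' `V_eff = chamber_volume_l - mass_g/1000` is the water volume
#' displaced-corrected for the fish (density 1 g/ml); flush phases reset
#' oxygen to air saturation and wait phases hold it. Gaussian sensor
#' noise is added per point. The latent trajectory starts at MMR
#' (`t = 0` is the moment the chased fish enters the chamber) and decays
#' to SMR with time constant `post_chase_decay_tau_s`, punctuated by
#' Poisson activity bursts with lognormal magnitudes, truncated at MMR.
#'
#' Background respiration grows linearly from `bg_pre` at trial start to
#' `bg_post` at trial end; the background traces are sealed empty-chamber
#' measurements taken immediately before and after the trial (full
#' chamber volume, no fish).
#'
#' @param truth One row of the `truth` data frame from
#'   [simulate_cohort()] (needs `fish_id`, `mass_g`, `smr_true`,
#'   `mmr_true`).
#' @param config A [sim_config()].
#' @param seed RNG seed for this trial.
#' @return A list: `trace` ([resp_trace()]), `bg_pre` and `bg_post`
#'   ([background_trace()]), and `truth` (list with `smr_true`,
#'   `mmr_true`, `v_eff_l`, burst process, and the vectorised functions
#'   `mo2_fun(t)` and `bg_fun(t)` in mg O2/h).
#' @export
simulate_trial <- function(truth, config = sim_config(),
                           seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  smr <- truth$smr_true
  mmr <- truth$mmr_true
  v_chamber <- config$chamber_volume_l * truth$mass_g / config$mass_ref
  v_eff <- v_chamber - truth$mass_g / 1000
  if (v_eff <= 0) stop("effective volume <= 0: fish too large for chamber")
  set.seed(seed)
  proto <- config$protocol
  t_end <- config$n_loops * proto$loop_s
  t <- seq(0, t_end - config$dt_s, by = config$dt_s)
  phase <- infer_phases(t, proto)
  loop_index <- as.integer(t %/% proto$loop_s)

  n_burst <- stats::rpois(1, config$burst_rate_per_h * t_end / 3600)
  burst_times <- sort(stats::runif(n_burst, 0, t_end))
  burst_mags <- stats::rlnorm(n_burst, config$burst_meanlog,
                              config$burst_sdlog)
  mo2_fun <- function(tt) mo2_trajectory(tt, smr, mmr,
                                         config$post_chase_decay_tau_s,
                                         burst_times, burst_mags,
                                         config$burst_decay_s)
  bg_fun <- function(tt) {
    config$bg_pre + (config$bg_post - config$bg_pre) *
      pmin(pmax(tt / t_end, 0), 1)
  }

  # mg O2/L consumed per dt step while sealed
  dec <- (mo2_fun(t) + bg_fun(t)) / (3600 * v_eff) * config$dt_s
  dec[phase != "MEASURE"] <- 0
  # cumulative decline, reset to saturation at the start of every loop's
  # measurement phase (flush re-oxygenates, wait holds at saturation)
  seg <- paste0(loop_index, phase)
  cum <- stats::ave(dec, seg, FUN = cumsum)
  o2 <- config$o2_saturation - cum
  o2 <- o2 + stats::rnorm(length(o2), 0, config$sensor_noise_sd)
  o2 <- pmax(o2, 0)
  temp <- config$protocol$temp_c +
    as.numeric(stats::filter(stats::rnorm(length(t), 0, 0.01), 0.9,
                             method = "recursive"))

  trace <- resp_trace(truth$fish_id, time_s = t, o2 = o2, phase = phase,
                      loop_index = loop_index, temp_c = temp)

  make_bg <- function(when, t0, bg_rate) {
    tb <- seq(t0, t0 + config$bg_duration_s - config$dt_s, by = config$dt_s)
    slope <- -bg_rate / (3600 * v_chamber)
    o2b <- config$o2_saturation + slope * (tb - t0) +
      stats::rnorm(length(tb), 0, config$sensor_noise_sd)
    background_trace(truth$fish_id, when, time_s = tb, o2 = pmax(o2b, 0),
                     temp_c = config$protocol$temp_c)
  }
  bg_pre <- make_bg("PRE", -config$bg_duration_s - 60, config$bg_pre)
  bg_post <- make_bg("POST", t_end + 60, config$bg_post)

  list(
    trace = trace, bg_pre = bg_pre, bg_post = bg_post,
    truth = list(fish_id = truth$fish_id, smr_true = smr, mmr_true = mmr,
                 v_eff_l = v_eff, burst_times = burst_times,
                 burst_mags = burst_mags, mo2_fun = mo2_fun,
                 bg_fun = bg_fun, t_end = t_end)
  )
}

#' Simulate a full study: cohort plus one trial per fish
#'
#' Convenience wrapper: draws the cohort, then simulates every fish's
#' trial with a per-fish seed derived from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Master RNG seed.
#' @return A list: `cohort`, `truth`, and `trials` (named list of
#'   [simulate_trial()] results, keyed by fish id).
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed) {
  sim <- simulate_cohort(config, seed = seed)
  trials <- vector("list", nrow(sim$truth))
  names(trials) <- sim$truth$fish_id
  for (i in seq_len(nrow(sim$truth))) {
    trials[[i]] <- simulate_trial(sim$truth[i, ], config,
                                  seed = (seed + 7919L * i) %% 2147483647L)
  }
  c(sim, list(trials = trials))
}
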