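# Ground-truth generator replicating the study design: 11 groups x 4 fish,
# bimodal respirometry traces (68 cycles over 17 hr) and 15-min group trials
# across an aquatic oxygen ladder (100 -> 20% air saturation), with
# aggression-triggered, temporally clustered air-breathing.

#' Simulation configuration
#'
#' Bundles every generator parameter with its default study condition.
#' Defaults mirror the replicated design: 11 groups of 4 fish, oxygen ladder
#' 100/80/60/40/20% air saturation, 900-s trials, 68 respirometry cycles of
#' 900 s (600 s closed + 300 s flush). Physiology and behaviour defaults are
#' chosen so that simulated summaries (breaths per group-trial, dispersion
#' coefficients, proximity fractions) fall in realistic ranges for a social
#' air-breathing catfish; see the methods vignette for the rationale.
#'
#' @param seed mandatory RNG seed.
#' @param ... overrides of any default, as nested lists (e.g.
#'   `behaviour = list(p_follow = 0)` replaces only that entry).
#' @return object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, behaviour = list(p_follow = 0))
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    n_groups = 11L,
    group_size = 4L,
    oxygen_levels = c(100, 80, 60, 40, 20),
    include_recovery = TRUE,
    trial_duration = 900,
    respirometry = list(
      n_cycles = 68L,
      closed_duration = 600,
      flush_duration = 300,
      sample_every = 5,
      noise_sd_air = 0.02,      # kPa per sample
      noise_sd_water = 0.15,    # %sat per sample
      settle_amplitude = 0.08,  # transient mixing artefact, first ~60 s
      settle_tau = 15,
      air_volume = 0.2,
      total_volume = 2.5,
      temperature = 26.5,
      barometric_pressure = 101.325
    ),
    physiology = list(
      smr_meanlog = log(3),     # mmol O2/kg/hr, lognormal across fish
      smr_sdlog = 0.15,
      pct_air_mean = 30,        # % of uptake from air, truncated normal
      pct_air_sd = 10,
      pct_air_range = c(5, 70),
      mass_mean = 0.0641,       # kg
      mass_sd = 0.01134,
      active_prob = 0.75,       # share of cycles with an activity surcharge
      surcharge_meanlog = log(0.3),
      surcharge_sdlog = 0.6
    ),
    behaviour = list(
      breath_rate = 0.005,           # baseline breaths /s/fish in a group
      breath_hypoxia_slope = 0.4,    # fractional increase at 20% saturation
      attack_rate = 0.0025,          # subordinate attacks /s/fish
      attack_hypoxia_slope = 0.5,
      dominant_multiplier = 5,
      push_rate = 0.0013,            # pushes /s/fish
      avoid_prob = 0.6,              # avoid response after attack/push
      avoid_lag_max = 2,
      p_breath_given_attack_actor = 0.4,
      p_breath_given_attack_target = 0.4,
      trigger_lag_scale = 2,         # Exponential mean, truncated at 5 s
      trigger_lag_max = 5,
      p_follow = 0.15,               # follower breath after another's breath
      follow_lag_max = 5,
      fish_breath_sdlog = 0.3,       # among-fish rate heterogeneity
      fish_attack_sdlog = 0.5,
      group_attack_sdlog = 0.6,      # among-group aggression heterogeneity
      activity_a = 200,              # distance = a + b * attacks + noise
      activity_b = 50,
      activity_sd = 50,
      facilitation_factor = 5        # group baseline / isolation baseline
    )
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  b <- cfg$behaviour
  pr <- c(b$p_breath_given_attack_actor, b$p_breath_given_attack_target,
          b$p_follow, b$avoid_prob, cfg$physiology$active_prob)
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(b$breath_rate, b$attack_rate, b$push_rate) < 0)) {
    stop("rates must be non-negative")
  }
  if (b$trigger_lag_scale <= 0) stop("trigger lag scale must be positive")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d groups x %d fish, O2 ladder %s%%, seed %d\n",
              x$n_groups, x$group_size,
              paste(x$oxygen_levels, collapse = "/"), x$seed))
  invisible(x)
}

# hypoxia multiplier: 1 at 100% air saturation, 1 + slope at 20%
.hypoxia_factor <- function(oxygen_level, slope) {
  o <- suppressWarnings(as.numeric(oxygen_level))
  if (is.na(o)) o <- 100  # "recovery" behaves as normoxia
  1 + slope * (100 - o) / 80
}

# truncated exponential lags via inverse CDF
.rtexp <- function(n, scale, upper) {
  u <- stats::runif(n)
  -scale * log(1 - u * (1 - exp(-upper / scale)))
}

#' Simulate bimodal respirometry traces with known ground truth
#'
#' For each fish, draws true SMR (lognormal), %MO2AIR (truncated normal) and
#' mass, then forward-simulates 68 stopped-flow cycles: per-cycle RMR is SMR
#' times (1 + an activity surcharge present in a random subset of cycles,
#' lognormally distributed, so that the low quantile of per-cycle RMR
#' identifies SMR), partitioned into air and water uptake by the true
#' %MO2AIR. O2 declines are generated through the inverse of the analysis
#' equations (ideal gas for the air phase, solubility-scaled for the water
#' phase) plus Gaussian sensor noise and an exponentially decaying mixing
#' artefact over the first seconds of each closed phase.
#'
#' @param cfg a [sim_config()].
#' @param n_fish number of fish (default groups x group size).
#' @param seed RNG seed (default `cfg$seed`).
#' @param fish_ids optional ids; default F01, F02, ...
#' @return list with `log` (optode log `data.frame` in the format of
#'   [read_optode_log()]), `truth` (fish_id, mass, smr_true, pct_air_true),
#'   and `geometries` (named list of [respirometer_geometry()]).
#' @export
simulate_respirometry <- function(cfg, n_fish = cfg$n_groups * cfg$group_size,
                                  seed = cfg$seed, fish_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  rsp <- cfg$respirometry
  phy <- cfg$physiology
  if (is.null(fish_ids)) fish_ids <- sprintf("F%02d", seq_len(n_fish))

  mass <- pmax(0.02, stats::rnorm(n_fish, phy$mass_mean, phy$mass_sd))
  smr <- stats::rlnorm(n_fish, phy$smr_meanlog, phy$smr_sdlog)
  pct <- pmin(phy$pct_air_range[2],
              pmax(phy$pct_air_range[1],
                   stats::rnorm(n_fish, phy$pct_air_mean, phy$pct_air_sd)))

  geoms <- lapply(seq_len(n_fish), function(i) {
    respirometer_geometry(fish_mass = mass[i],
                          total_volume = rsp$total_volume,
                          air_volume = rsp$air_volume,
                          temperature = rsp$temperature,
                          barometric_pressure = rsp$barometric_pressure)
  })
  names(geoms) <- fish_ids
  sol <- o2_solubility(rsp$temperature, rsp$barometric_pressure)
  p_amb <- po2_air_saturation(rsp$temperature, rsp$barometric_pressure)

  period <- rsp$closed_duration + rsp$flush_duration
  t_closed <- seq(0, rsp$closed_duration, by = rsp$sample_every)
  # flush samples run to the cycle boundary so the trace spans n_cycles
  # full periods; the duplicated boundary sample is dropped below
  t_flush <- seq(rsp$closed_duration + rsp$sample_every, period,
                 by = rsp$sample_every)
  nc <- length(t_closed)
  nf <- length(t_flush)
  n_cyc <- rsp$n_cycles

  logs <- vector("list", n_fish)
  for (i in seq_len(n_fish)) {
    g <- geoms[[i]]
    active <- stats::rbinom(n_cyc, 1, phy$active_prob)
    surch <- active * stats::rlnorm(n_cyc, phy$surcharge_meanlog,
                                    phy$surcharge_sdlog)
    rmr_c <- smr[i] * (1 + surch)
    mo2a <- pct[i] / 100 * rmr_c
    mo2w <- rmr_c - mo2a
    # invert the uptake equations to per-hour slopes
    sl_air <- -mo2a * g$fish_mass * (.R_GAS * (g$temperature + 273.15)) /
      g$air_volume
    sl_wat <- -mo2w * g$fish_mass / (sol * g$water_volume_effective) * 100

    cyc0 <- rep((seq_len(n_cyc) - 1) * period, each = nc + nf)
    t_rel <- rep(c(t_closed, t_flush), times = n_cyc)
    closed <- rep(c(rep(TRUE, nc), rep(FALSE, nf)), times = n_cyc)
    # same decaying mixing transient in both phases (the water optode sees
    # a proportionally larger swing in %sat units)
    shape <- exp(-t_rel / rsp$settle_tau) * closed
    air_v <- ifelse(closed,
                    p_amb + rep(sl_air, each = nc + nf) * t_rel / 3600,
                    p_amb) +
      rsp$settle_amplitude * shape +
      stats::rnorm(length(t_rel), 0, rsp$noise_sd_air)
    wat_v <- ifelse(closed,
                    100 + rep(sl_wat, each = nc + nf) * t_rel / 3600,
                    100) +
      5 * rsp$settle_amplitude * shape +
      stats::rnorm(length(t_rel), 0, rsp$noise_sd_water)
    df <- data.frame(
      time_s = c(cyc0 + t_rel, cyc0 + t_rel),
      chamber_id = fish_ids[i],
      phase = rep(c("air", "water"), each = length(t_rel)),
      unit = rep(c("kPa", "pct_sat"), each = length(t_rel)),
      value = c(air_v, wat_v),
      stringsAsFactors = FALSE
    )
    logs[[i]] <- df[!duplicated(df[, c("phase", "time_s")]), , drop = FALSE]
  }
  list(
    log = do.call(rbind, logs),
    truth = data.frame(fish_id = fish_ids, mass = mass, smr_true = smr,
                       pct_air_true = pct, stringsAsFactors = FALSE),
    geometries = geoms
  )
}

#' Simulate one group trial as a marked point process
#'
#' Events on \\[0, duration\\]: (i) attacks, Poisson per fish with the
#' dominant's rate multiplied, each with a random target; pushes likewise;
#' avoids emitted by targets of agonism with probability `avoid_prob`;
#' (ii) baseline breaths, Poisson with rate rising as oxygen falls;
#' (iii) triggered breaths: after each attack the actor and the target each
#' breathe with their trigger probabilities at an Exponential lag truncated
#' to the trigger window, and after each parent breath every other fish
#' breathes with probability `p_follow` at a Uniform(0, follow window) lag.
#' Follower breaths do not recursively trigger further followers.
#'
#' @param cfg a [sim_config()].
#' @param group_id group identifier.
#' @param oxygen_level % air saturation, or "recovery" (treated as 100).
#' @param seed RNG seed (default `cfg$seed`).
#' @param roster fish ids (default `<group_id>_F1..F4`).
#' @param fish_effects optional `data.frame(fish_id, breath_mult,
#'   attack_mult, dominant)` holding the among-fish latent effects, so the
#'   same fish keep their multipliers across that group's trials.
#' @param group_attack_mult optional group-level aggression multiplier.
#' @return list with `trial` (a [trial()]) and `truth` (latent effects,
#'   trigger probabilities, per-origin event counts).
#' @export
simulate_group_trial <- function(cfg, group_id, oxygen_level,
                                 seed = cfg$seed, roster = NULL,
                                 fish_effects = NULL,
                                 group_attack_mult = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  b <- cfg$behaviour
  dur <- cfg$trial_duration
  if (is.null(roster)) {
    roster <- paste0(group_id, "_F", seq_len(cfg$group_size))
  }
  n <- length(roster)
  if (is.null(fish_effects)) {
    fish_effects <- data.frame(
      fish_id = roster,
      breath_mult = stats::rlnorm(n, 0, b$fish_breath_sdlog),
      attack_mult = stats::rlnorm(n, 0, b$fish_attack_sdlog),
      dominant = seq_len(n) == 1L,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(group_attack_mult)) {
    group_attack_mult <- stats::rlnorm(1, 0, b$group_attack_sdlog)
  }
  of_b <- .hypoxia_factor(oxygen_level, b$breath_hypoxia_slope)
  of_a <- .hypoxia_factor(oxygen_level, b$attack_hypoxia_slope)

  pois_times <- function(rate) {
    k <- stats::rpois(1, rate * dur)
    sort(stats::runif(k, 0, dur))
  }
  rows <- list()
  add <- function(time, fish, beh, target = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time = time, fish_id = fish, behaviour = beh, target_id = target,
      stringsAsFactors = FALSE)
  }

  # (i) agonism
  attacks <- list()
  for (i in seq_len(n)) {
    rate <- b$attack_rate * fish_effects$attack_mult[i] * group_attack_mult *
      of_a * (if (fish_effects$dominant[i]) b$dominant_multiplier else 1)
    at <- pois_times(rate)
    if (length(at)) {
      tg <- sample(roster[-i], length(at), replace = TRUE)
      add(at, roster[i], "attack", tg)
      attacks[[i]] <- data.frame(time = at, actor = roster[i], target = tg,
                                 stringsAsFactors = FALSE)
    }
    pt <- pois_times(b$push_rate)
    if (length(pt)) {
      add(pt, roster[i], "push", sample(roster[-i], length(pt),
                                        replace = TRUE))
    }
  }
  atk <- if (length(attacks)) do.call(rbind, attacks) else
    data.frame(time = numeric(0), actor = character(0),
               target = character(0), stringsAsFactors = FALSE)
  # avoid responses by targets of agonism
  ago <- do.call(rbind, lapply(rows, function(r) {
    r[r$behaviour %in% c("attack", "push"), c("time", "target_id")]
  }))
  n_avoid <- 0L
  if (!is.null(ago) && nrow(ago)) {
    resp <- stats::runif(nrow(ago)) < b$avoid_prob
    if (any(resp)) {
      av_t <- ago$time[resp] + stats::runif(sum(resp), 0, b$avoid_lag_max)
      keep <- av_t <= dur
      if (any(keep)) {
        add(av_t[keep], ago$target_id[resp][keep], "avoid")
        n_avoid <- sum(keep)
      }
    }
  }

  # (ii) baseline breaths
  parents <- list()
  for (i in seq_len(n)) {
    bt <- pois_times(b$breath_rate * fish_effects$breath_mult[i] * of_b)
    if (length(bt)) {
      parents[[length(parents) + 1L]] <- data.frame(
        time = bt, fish_id = roster[i], stringsAsFactors = FALSE)
    }
  }
  n_baseline <- sum(vapply(parents, nrow, integer(1)))

  # (iii) attack-triggered breaths (actor and target)
  n_trig <- 0L
  if (nrow(atk)) {
    for (role in c("actor", "target")) {
      p <- if (role == "actor") b$p_breath_given_attack_actor else
        b$p_breath_given_attack_target
      hit <- stats::runif(nrow(atk)) < p
      if (any(hit)) {
        lag <- .rtexp(sum(hit), b$trigger_lag_scale, b$trigger_lag_max)
        tt <- atk$time[hit] + lag
        keep <- tt <= dur
        if (any(keep)) {
          parents[[length(parents) + 1L]] <- data.frame(
            time = tt[keep], fish_id = atk[[role]][hit][keep],
            stringsAsFactors = FALSE)
          n_trig <- n_trig + sum(keep)
        }
      }
    }
  }
  par_df <- if (length(parents)) do.call(rbind, parents) else
    data.frame(time = numeric(0), fish_id = character(0))

  # follower breaths (single generation)
  n_follow <- 0L
  if (nrow(par_df) && b$p_follow > 0) {
    for (j in seq_len(nrow(par_df))) {
      others <- setdiff(roster, par_df$fish_id[j])
      hit <- stats::runif(length(others)) < b$p_follow
      if (any(hit)) {
        ft <- par_df$time[j] + stats::runif(sum(hit), 0, b$follow_lag_max)
        keep <- ft <= dur
        if (any(keep)) {
          add(ft[keep], others[hit][keep], "breath")
          n_follow <- n_follow + sum(keep)
        }
      }
    }
  }
  if (nrow(par_df)) add(par_df$time, par_df$fish_id, "breath")

  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(0), fish_id = character(0),
               behaviour = character(0), target_id = character(0),
               stringsAsFactors = FALSE)
  own_attacks <- table(factor(atk$actor, levels = roster))
  activity <- stats::setNames(
    b$activity_a + b$activity_b * as.numeric(own_attacks) +
      stats::rnorm(n, 0, b$activity_sd),
    roster)
  tr <- trial(ev, group_id = group_id, oxygen_level = oxygen_level,
              duration = dur, roster = roster, activity = activity)
  list(
    trial = tr,
    truth = list(
      fish_effects = fish_effects,
      group_attack_mult = group_attack_mult,
      dominant_id = fish_effects$fish_id[fish_effects$dominant][1],
      p_breath_given_attack_actor = b$p_breath_given_attack_actor,
      p_breath_given_attack_target = b$p_breath_given_attack_target,
      p_follow = b$p_follow,
      n_baseline = n_baseline, n_attack_triggered = n_trig,
      n_follow = n_follow, n_attacks = nrow(atk), n_avoids = n_avoid
    )
  )
}

#' Simulate an isolation (single-fish) trial
#'
#' A lone fish breathes as a Poisson stream whose baseline rate is the group
#' baseline divided by the social facilitation factor, rising with hypoxia.
#'
#' @param cfg a [sim_config()].
#' @param fish_id identifier.
#' @param oxygen_level % air saturation.
#' @param seed RNG seed (default `cfg$seed`).
#' @param breath_mult the fish's latent breath-rate multiplier.
#' @return a [trial()] with a one-fish roster.
#' @export
simulate_isolation_trial <- function(cfg, fish_id, oxygen_level,
                                     seed = cfg$seed, breath_mult = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  b <- cfg$behaviour
  rate <- b$breath_rate / b$facilitation_factor * breath_mult *
    .hypoxia_factor(oxygen_level, b$breath_hypoxia_slope)
  k <- stats::rpois(1, rate * cfg$trial_duration)
  ev <- if (k > 0) {
    data.frame(time = sort(stats::runif(k, 0, cfg$trial_duration)),
               fish_id = fish_id, behaviour = "breath",
               target_id = NA_character_, stringsAsFactors = FALSE)
  } else {
    data.frame(time = numeric(0), fish_id = character(0),
               behaviour = character(0), target_id = character(0),
               stringsAsFactors = FALSE)
  }
  trial(ev, group_id = fish_id, oxygen_level = oxygen_level,
        duration = cfg$trial_duration, roster = fish_id)
}

#' Simulate the complete study
#'
#' Respirometry traces for every fish, group trials for every group at every
#' oxygen level (plus a recovery observation when configured), and isolation
#' trials at normoxia and severe hypoxia, with a serialisable ground-truth
#' record sufficient to score every recovery test.
#'
#' @param cfg a [sim_config()].
#' @param respirometry simulate optode traces too (slowest stage; can be
#'   switched off when only behaviour is needed).
#' @return list with `optode_log`, `resp_truth`, `geometries`, `trials`
#'   (named list of group trials), `isolation_trials`, `behaviour_truth`
#'   (per-group latent effects), and `roster` (fish_id -> group_id map).
#' @export
simulate_study <- function(cfg, respirometry = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  b <- cfg$behaviour
  groups <- sprintf("G%02d", seq_len(cfg$n_groups))
  roster <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group_id = g,
               fish_id = paste0(g, "_F", seq_len(cfg$group_size)),
               stringsAsFactors = FALSE)
  }))

  # latent among-fish / among-group effects, drawn once
  set.seed(cfg$seed)
  eff <- lapply(groups, function(g) {
    ids <- roster$fish_id[roster$group_id == g]
    list(
      fish = data.frame(
        fish_id = ids,
        breath_mult = stats::rlnorm(length(ids), 0, b$fish_breath_sdlog),
        attack_mult = stats::rlnorm(length(ids), 0, b$fish_attack_sdlog),
        dominant = seq_along(ids) == sample.int(length(ids), 1),
        stringsAsFactors = FALSE),
      group_attack_mult = stats::rlnorm(1, 0, b$group_attack_sdlog)
    )
  })
  names(eff) <- groups

  levels_run <- cfg$oxygen_levels
  if (isTRUE(cfg$include_recovery)) levels_run <- c(levels_run, "recovery")
  trials <- list()
  k <- 0L
  for (g in groups) {
    for (ox in levels_run) {
      k <- k + 1L
      sim <- simulate_group_trial(
        cfg, g, ox, seed = cfg$seed + 1000L + k,
        roster = roster$fish_id[roster$group_id == g],
        fish_effects = eff[[g]]$fish,
        group_attack_mult = eff[[g]]$group_attack_mult)
      trials[[paste0(g, "_", ox)]] <- sim$trial
    }
  }

  iso <- list()
  for (i in seq_len(nrow(roster))) {
    fe <- eff[[roster$group_id[i]]]$fish
    bm <- fe$breath_mult[fe$fish_id == roster$fish_id[i]]
    for (ox in c(100, 20)) {
      iso[[paste0(roster$fish_id[i], "_", ox)]] <-
        simulate_isolation_trial(cfg, roster$fish_id[i], ox,
                                 seed = cfg$seed + 20000L + 2L * i + (ox == 20),
                                 breath_mult = bm)
    }
  }

  resp <- if (respirometry) {
    simulate_respirometry(cfg, n_fish = nrow(roster),
                          seed = cfg$seed + 500L, fish_ids = roster$fish_id)
  } else NULL

  list(
    optode_log = resp$log,
    resp_truth = resp$truth,
    geometries = resp$geometries,
    trials = trials,
    isolation_trials = iso,
    behaviour_truth = eff,
    roster = roster
  )
}

#' Gaussian trait table with known variance components
#'
#' Generates the mixed-model test bed: `n_id` individuals nested in groups,
#' observed once per oxygen level, with individual-, group- and residual-
#' level Gaussian variance and a known fixed-effect structure mirroring the
#' individual air-breathing analysis (real activity and log-attack effects;
#' SMR, mass and %MO2AIR included as null covariates).
#'
#' @param seed RNG seed.
#' @param n_id number of individuals (default 44).
#' @param n_group number of groups (default 11; ids are split evenly).
#' @param oxygen_levels contexts; one observation per individual per level.
#' @param v_id,v_group,v_res variance components of the response.
#' @param beta_activity,beta_attacks real fixed-effect slopes.
#' @param beta_oxygen named vector of offsets for the non-reference oxygen
#'   levels (default small, mostly null, as in the replicated design).
#' @return `data.frame` with columns `fish_id, group_id, oxygen_level, y,
#'   activity, attacks, smr, mass, pct_air` and attribute `truth` (the
#'   generating parameters).
#' @export
simulate_trait_table <- function(seed, n_id = 44, n_group = 11,
                                 oxygen_levels = c(100, 80, 60, 40, 20),
                                 v_id = 0.3, v_group = 0.1, v_res = 0.6,
                                 beta_activity = 2.1, beta_attacks = 1.7,
                                 beta_oxygen = NULL) {
  set.seed(seed)
  n_obs <- length(oxygen_levels)
  if (is.null(beta_oxygen)) {
    beta_oxygen <- stats::setNames(rep(0.2, n_obs - 1),
                                   as.character(oxygen_levels[-1]))
  }
  gid <- sprintf("G%02d", rep_len(seq_len(n_group), n_id))
  fid <- sprintf("%s_F%02d", gid, seq_len(n_id))
  u_id <- stats::rnorm(n_id, 0, sqrt(v_id))
  u_gr <- stats::setNames(stats::rnorm(n_group, 0, sqrt(v_group)),
                          sprintf("G%02d", seq_len(n_group)))
  smr <- stats::rnorm(n_id, 1.1, 0.15)    # log scale, individual-level
  mass <- stats::rnorm(n_id, -2.75, 0.17)
  pcta <- stats::rnorm(n_id, 30, 10)

  df <- data.frame(
    fish_id = rep(fid, each = n_obs),
    group_id = rep(gid, each = n_obs),
    oxygen_level = factor(rep(as.character(oxygen_levels), n_id),
                          levels = as.character(oxygen_levels)),
    smr = rep(smr, each = n_obs),
    mass = rep(mass, each = n_obs),
    pct_air = rep(pcta, each = n_obs),
    activity = stats::rnorm(n_id * n_obs, 6, 0.5),
    attacks = stats::rnorm(n_id * n_obs, 1.2, 0.7),
    stringsAsFactors = FALSE
  )
  oxeff <- c(0, beta_oxygen)[as.integer(df$oxygen_level)]
  df$y <- beta_activity * df$activity + beta_attacks * df$attacks + oxeff +
    rep(u_id, each = n_obs) + u_gr[df$group_id] +
    stats::rnorm(nrow(df), 0, sqrt(v_res))
  attr(df, "truth") <- list(v_id = v_id, v_group = v_group, v_res = v_res,
                            beta_activity = beta_activity,
                            beta_attacks = beta_attacks,
                            beta_oxygen = beta_oxygen)
  df
}

#' Write / read a ground-truth record as structured text
#'
#' Serialises the generator's per-fish truth table alongside simulated data
#' so recovery tests can be scored without re-running the generator.
#'
#' @param truth a `data.frame` (e.g. `resp_truth`).
#' @param path file path.
#' @export
write_sim_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
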