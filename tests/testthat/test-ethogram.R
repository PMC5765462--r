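# Event streams: tallies, dispersion, proximity attribution, dominance.

mk_trial <- function(times, fish, beh, target = NA, duration = 900) {
  trial(data.frame(time = times, fish_id = fish, behaviour = beh,
                   target_id = target, stringsAsFactors = FALSE),
        group_id = "G1", oxygen_level = 100, duration = duration,
        roster = c("A", "B", "C", "D"))
}

test_that("trial construction enforces the ethogram and roster", {
  expect_error(mk_trial(10, "A", "yawn"), "unknown behaviour")
  expect_error(mk_trial(10, "A", "attack", target = "A"), "target")
  expect_error(mk_trial(1000, "A", "breath"), "within")
  tr <- mk_trial(c(30, 10), c("A", "B"), c("breath", "breath"))
  expect_equal(tr$events$time, c(10, 30))  # sorted on construction
  expect_error(
    trial(data.frame(time = 1, fish_id = "Z", behaviour = "breath",
                     target_id = NA), "G", 100, roster = c("A", "B")),
    "roster")
})

test_that("tallies are exact per fish and per group", {
  tr0 <- trial(data.frame(time = numeric(0), fish_id = character(0),
                          behaviour = character(0), target_id = character(0)),
               "G1", 100, roster = c("A", "B", "C", "D"))
  expect_equal(tally(tr0, "breath", by_fish = TRUE),
               c(A = 0L, B = 0L, C = 0L, D = 0L))
  tr <- mk_trial(c(1, 2, 3, 4, 5), c("A", "A", "A", "B", "B"),
                 rep("breath", 5))
  expect_equal(tally(tr, "breath", by_fish = TRUE),
               c(A = 3L, B = 2L, C = 0L, D = 0L))
  expect_equal(tally(tr, "breath"), 5L)
  expect_error(tally(tr, "yawn"), "unknown behaviour")
})

test_that("per-fish counts match Poisson expectation in the generator", {
  cfg <- sim_config(seed = 31, behaviour = list(
    p_follow = 0, p_breath_given_attack_actor = 0,
    p_breath_given_attack_target = 0, fish_breath_sdlog = 0))
  tot <- 0
  n_rep <- 200
  for (i in 1:n_rep) {
    tr <- simulate_group_trial(cfg, "G", 100, seed = 1000 + i)$trial
    tot <- tot + tally(tr, "breath")
  }
  lambda <- cfg$behaviour$breath_rate * 900 * 4 * n_rep
  # total is Poisson(lambda): stay within a 99.9% envelope
  expect_lt(abs(tot - lambda), 3.3 * sqrt(lambda))
})

test_that("coefficient of dispersion matches hand and loop oracles", {
  # one event in each of 30 bins: perfectly uniform
  r <- coefficient_of_dispersion(seq(15, 885, by = 30), 900, 30)
  expect_equal(r$cd, 0)
  expect_equal(r$n_bins, 30)
  expect_equal(sum(r$counts), 30)
  # counts (2,0,1,1) over 4 bins: cd = (2/3)/1
  r2 <- coefficient_of_dispersion(c(1, 2, 35, 50), duration = 60,
                                  bin_width = 15)
  expect_equal(r2$counts, c(2, 0, 1, 1))
  expect_equal(r2$cd, (2 / 3) / 1)
  expect_warning(r3 <- coefficient_of_dispersion(numeric(0), 900, 30),
                 "undefined")
  expect_true(is.na(r3$cd))
  expect_warning(coefficient_of_dispersion(c(1, 2), 100, 30), "partial bin")
  set.seed(33)
  for (i in 1:60) {
    times <- runif(sample(3:60, 1), 0, 900)
    expect_equal(coefficient_of_dispersion(times, 900, 30)$cd,
                 oracle_cd(times, 900, 30), tolerance = 1e-12)
  }
})

test_that("proximity window is half-open (0, w] and counts breaths once", {
  # reference 4 s before the breath counts
  tr <- mk_trial(c(6, 10), c("B", "A"), c("breath", "breath"))
  expect_equal(proximity_fraction(tr, "breath_by_other")$fraction, 0.5)
  # lag exactly 0 does not count
  tr0 <- mk_trial(c(10, 10), c("B", "A"), c("breath", "breath"))
  expect_equal(proximity_fraction(tr0, "breath_by_other")$fraction, 0)
  # lag exactly w counts (closed upper bound)
  tr5 <- mk_trial(c(5, 10), c("B", "A"), c("breath", "breath"))
  expect_equal(proximity_fraction(tr5, "breath_by_other")$fraction, 0.5)
  # several qualifying references still count the breath once
  # A@10 is preceded by three qualifying breaths yet counts once
  trm <- mk_trial(c(6, 7, 8, 10), c("B", "C", "B", "A"),
                  c("breath", "breath", "breath", "breath"))
  r <- proximity_fraction(trm, "breath_by_other")
  expect_equal(r$n_qualifying, 3L)  # B@6 has no earlier reference
  expect_equal(r$fraction, 3 / 4)
  tre <- mk_trial(10, "A", "attack", target = "B")
  expect_warning(rx <- proximity_fraction(tre, "own_attack"), "no breaths")
  expect_true(is.na(rx$fraction))
  expect_error(proximity_fraction(tr, "nonsense"), "category")
})

test_that("proximity categories agree with the pair-loop oracle", {
  set.seed(34)
  cats <- c("breath_by_other", "own_attack", "being_attacked", "own_avoid",
            "any_interaction")
  for (i in 1:60) {
    tr <- random_small_trial()
    for (cat in cats) {
      got <- suppressWarnings(proximity_fraction(tr, cat, 5)$fraction)
      expect_identical(got, oracle_proximity(tr, cat, 5),
                       label = paste(cat, "rep", i))
    }
  }
})

test_that("interaction superset never loses qualifying breaths", {
  set.seed(35)
  for (i in 1:100) {
    tr <- random_small_trial(n_events = 40)
    fa <- suppressWarnings(proximity_fraction(tr, "any_interaction")$fraction)
    fo <- suppressWarnings(proximity_fraction(tr, "own_attack")$fraction)
    if (!is.na(fa) && !is.na(fo)) expect_gte(fa, fo)
  }
})

test_that("trigger attribution scores per-attack follow-up breaths", {
  tr <- mk_trial(c(10, 12, 30, 40, 41), c("A", "B", "A", "B", "A"),
                 c("attack", "breath", "attack", "attack", "breath"),
                 target = c("B", NA, "C", "A", NA))
  # attacks: A@10 (B breathes at 12: target hit, actor no),
  #          A@30 (no one), B@40 (A breathes at 41: actor no, target A yes)
  expect_equal(trigger_attribution(tr, "actor")$fraction, 0)
  expect_equal(trigger_attribution(tr, "target")$fraction, 2 / 3)
  trn <- mk_trial(10, "A", "breath")
  expect_true(is.na(trigger_attribution(trn, "actor")$fraction))
})

test_that("dominance uses attacks then pushes then id, deterministically", {
  tr <- mk_trial(1:12, rep(c("A", "B"), c(10, 2)), rep("attack", 12),
                 target = rep("C", 12))
  d <- dominant_individual(tr)
  expect_equal(d$fish_id, "A")
  expect_equal(d$tie_break, "attacks")
  # tie on attacks, broken by pushes
  tr2 <- mk_trial(c(1:10, 11:14), c(rep(c("A", "B"), each = 5), rep("A", 3), "B"),
                  c(rep("attack", 10), rep("push", 4)),
                  target = c(rep("C", 10), rep("D", 4)))
  d2 <- dominant_individual(tr2)
  expect_equal(d2$fish_id, "A")
  expect_equal(d2$tie_break, "attacks_pushes")
  # full tie falls back to lexicographic id
  tr3 <- mk_trial(c(1, 2), c("B", "A"), c("attack", "attack"),
                  target = c("C", "C"))
  d3 <- dominant_individual(tr3)
  expect_equal(d3$fish_id, "A")
  expect_equal(d3$tie_break, "lexicographic")
  tr4 <- mk_trial(1, "A", "breath")
  expect_error(dominant_individual(tr4), "no dominant")
})

test_that("a 5x attack-rate dominant is identified almost always", {
  cfg <- sim_config(seed = 36)
  hits <- 0L
  n_groups <- 100L
  for (g in seq_len(n_groups)) {
    eff <- data.frame(fish_id = c("F1", "F2", "F3", "F4"),
                      breath_mult = 1, attack_mult = 1,
                      dominant = c(TRUE, FALSE, FALSE, FALSE))
    trs <- lapply(seq_along(c(100, 80, 60, 40, 20)), function(j) {
      simulate_group_trial(cfg, "G", c(100, 80, 60, 40, 20)[j],
                           seed = 5000 + 10 * g + j,
                           roster = eff$fish_id, fish_effects = eff,
                           group_attack_mult = 1)$trial
    })
    d <- tryCatch(dominant_individual(trs)$fish_id, error = function(e) NA)
    if (identical(d, "F1")) hits <- hits + 1L
  }
  expect_gte(hits / n_groups, 0.99)
})

test_that("group breath totals excluding a fish match brute subtraction", {
  tr <- mk_trial(1:6, c("A", "A", "A", "A", "B", "C"), rep("breath", 6))
  expect_equal(unname(group_breaths_excluding(list(tr), "A")), 2)
  expect_equal(unname(group_breaths_excluding(list(tr), "D")), 6)
  expect_error(group_breaths_excluding(list(tr), "Z"), "roster")
  set.seed(37)
  for (i in 1:50) {
    tr <- random_small_trial(n_events = 30)
    ex <- sample(tr$roster, 1)
    brute <- sum(tr$events$behaviour == "breath" & tr$events$fish_id != ex)
    expect_equal(unname(group_breaths_excluding(list(tr), ex)), brute)
  }
})

test_that("event logs round-trip through the writer and reader", {
  cfg <- sim_config(seed = 38)
  trs <- list(
    t1 = simulate_group_trial(cfg, "G01", 100, seed = 1)$trial,
    t2 = simulate_group_trial(cfg, "G01", 20, seed = 2)$trial
  )
  f <- tempfile(fileext = ".tsv")
  write_event_log(trs, f)
  back <- read_event_log(f, rosters = list(G01 = trs$t1$roster))
  expect_equal(names(back), c("t1", "t2"))
  for (nm in names(trs)) {
    expect_equal(back[[nm]]$events$time, trs[[nm]]$events$time,
                 tolerance = 1e-9)
    expect_equal(back[[nm]]$events$behaviour, trs[[nm]]$events$behaviour)
    expect_equal(back[[nm]]$events$fish_id, trs[[nm]]$events$fish_id)
    expect_equal(is.na(back[[nm]]$events$target_id),
                 is.na(trs[[nm]]$events$target_id))
  }
  unlink(f)
})

test_that("ethogram tables cover every trial, fish and category", {
  cfg <- sim_config(seed = 39)
  trs <- list(a = simulate_group_trial(cfg, "G01", 100, seed = 3)$trial,
              b = simulate_group_trial(cfg, "G01", 20, seed = 4)$trial)
  tabs <- ethogram_tables(trs)
  expect_equal(nrow(tabs$tallies), 8)  # 2 trials x 4 fish
  expect_equal(nrow(tabs$synchrony), 2)
  expect_equal(nrow(tabs$proximity), 10)  # 2 trials x 5 categories
  expect_equal(sum(tabs$tallies$breaths),
               sum(vapply(trs, tally, integer(1), behaviour = "breath")))
})
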