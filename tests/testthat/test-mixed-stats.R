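# Mixed models: fitting, random-structure choice, elimination, R2,
# repeatability.

test_that("null covariates stay within 3 SE of zero", {
  set.seed(41)
  d <- simulate_trait_table(seed = 41, beta_activity = 0, beta_attacks = 0,
                            beta_oxygen = setNames(rep(0, 4),
                                                   c("80", "60", "40", "20")))
  fit <- fit_lme(y ~ activity + attacks + smr + (1 | group_id/fish_id), d)
  ct <- coef_table(fit)
  slopes <- ct[ct$term != "(Intercept)", ]
  expect_true(all(abs(slopes$estimate) < 3 * slopes$se))
})

test_that("a built-in log-attacks slope is recovered within its Wald CI", {
  hits <- 0L
  n_sim <- 100L
  for (s in seq_len(n_sim)) {
    d <- simulate_trait_table(seed = 4100 + s)
    fit <- lme4::lmer(y ~ activity + attacks + oxygen_level +
                        (1 | group_id/fish_id), data = d, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    est <- lme4::fixef(fit)[["attacks"]]
    se <- sqrt(diag(as.matrix(vcov(fit))))[["attacks"]]
    if (abs(est - 1.7) <= 1.96 * se) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.9)
})

test_that("zero individual variance fits at the boundary", {
  d <- simulate_trait_table(seed = 43, v_id = 0)
  fit <- fit_lme(y ~ activity + attacks + (1 | group_id/fish_id), d,
                 REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_id <- vc$vcov[grepl("fish_id", vc$grp)]
  expect_lt(v_id, 0.03)
})

test_that("random slopes are only kept when slope heterogeneity exists", {
  # no slope heterogeneity: intercept-only structure chosen nearly always
  # nominal retention of the simpler structure is >= 95% (the LRT is
  # boundary-conservative); allow the binomial envelope around that rate
  n_int <- 0L
  n_rep <- 40L
  for (s in seq_len(n_rep)) {
    d <- simulate_trait_table(seed = 4400 + s)
    d$oxygen_num <- as.numeric(as.character(d$oxygen_level)) / 100
    ch <- compare_random_structures(
      "y", c("activity", "attacks", "oxygen_level"), d)$choice
    if (ch == "intercept") n_int <- n_int + 1L
  }
  expect_gte(n_int / n_rep, 0.875)
  # strong per-fish oxygen slopes: slope structure chosen
  d <- simulate_trait_table(seed = 45, v_id = 0.1)
  d$oxygen_num <- as.numeric(as.character(d$oxygen_level)) / 100
  slope_eff <- rnorm(44, 0, 3)
  d$y <- d$y + slope_eff[as.integer(factor(d$fish_id))] * d$oxygen_num
  ch <- compare_random_structures(
    "y", c("activity", "attacks", "oxygen_level"), d)
  expect_equal(ch$choice, "slope")
  expect_lt(ch$lrt_p, 0.05)
})

test_that("backward elimination drops noise, keeps signal, obeys hierarchy", {
  d <- simulate_trait_table(seed = 46)
  # single irrelevant covariate is dropped
  el <- backward_eliminate("y", c("activity", "attacks", "smr"),
                           "(1 | group_id/fish_id)", d)
  expect_false("smr" %in% el$final_terms)
  expect_true(all(c("activity", "attacks") %in% el$final_terms))
  # alpha = 1 returns the full model unchanged
  el1 <- backward_eliminate("y", c("activity", "attacks", "smr"),
                            "(1 | group_id/fish_id)", d, alpha = 1)
  expect_setequal(el1$final_terms, c("activity", "attacks", "smr"))
  expect_true(all(el1$trail$decision == "kept"))
  # a main effect inside an interaction is never a drop candidate
  d$z <- rnorm(nrow(d))
  el2 <- backward_eliminate("y", c("activity", "z", "activity:z"),
                            "(1 | group_id/fish_id)", d)
  tr <- el2$trail
  i_main <- match("z", tr$term)
  i_int <- match("activity:z", tr$term)
  expect_false(is.na(i_int))
  if (!is.na(i_main)) expect_lt(i_int, i_main)
  # the trail replays deterministically
  el3 <- backward_eliminate("y", c("activity", "attacks", "smr"),
                            "(1 | group_id/fish_id)", d)
  expect_identical(el$trail, el3$trail)
})

test_that("R2 pair obeys its limits and recovers a known component mix", {
  # perfect fixed fit, no random variance: both R2 tend to 1
  set.seed(47)
  n <- 200
  d0 <- data.frame(x = rnorm(n), g = rep(letters[1:10], each = 20),
                   id = rep(sprintf("i%02d", 1:40), each = 5))
  d0$y <- 2 * d0$x + rnorm(n, 0, 1e-4)
  f0 <- suppressMessages(lme4::lmer(y ~ x + (1 | g), data = d0))
  r0 <- r2_nakagawa(f0)
  expect_gt(r0$r2_marginal, 0.999)
  expect_gt(r0$r2_conditional, 0.999)
  # null fixed effects with v_id = v_res: (~0, ~0.5)
  d1 <- simulate_trait_table(seed = 48, n_id = 200, v_id = 0.5, v_group = 0,
                             v_res = 0.5, beta_activity = 0, beta_attacks = 0,
                             beta_oxygen = setNames(rep(0, 4),
                                                    c("80", "60", "40", "20")))
  f1 <- lme4::lmer(y ~ 1 + (1 | fish_id), data = d1)
  r1 <- r2_nakagawa(f1)
  expect_lt(r1$r2_marginal, 0.02)
  expect_equal(r1$r2_conditional, 0.5, tolerance = 0.07)
  # known mix at the study size: recovered within 0.05 (median of 5 runs)
  v_f_true <- 2.1^2 * 0.25 + 1.7^2 * 0.49 + 0.0064
  r2m_true <- v_f_true / (v_f_true + 1)
  r2c_true <- (v_f_true + 0.4) / (v_f_true + 1)
  est <- t(sapply(1:5, function(s) {
    d <- simulate_trait_table(seed = 4900 + s)
    f <- lme4::lmer(y ~ activity + attacks + oxygen_level +
                      (1 | group_id) + (1 | fish_id), data = d, REML = TRUE)
    r <- r2_nakagawa(f)
    c(r$r2_marginal, r$r2_conditional)
  }))
  expect_lt(abs(median(est[, 1]) - r2m_true), 0.05)
  expect_lt(abs(median(est[, 2]) - r2c_true), 0.05)
})

test_that("R2 invariants hold across random fits and rescaling", {
  for (s in 1:10) {
    d <- simulate_trait_table(seed = 5000 + s,
                              v_id = runif(1, 0, 0.5),
                              v_group = runif(1, 0, 0.3))
    f <- lme4::lmer(y ~ activity + (1 | group_id/fish_id), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
    r <- r2_nakagawa(f)
    expect_lte(r$r2_marginal, r$r2_conditional)
    expect_gte(r$r2_marginal, 0); expect_lte(r$r2_conditional, 1)
    # affine rescaling of the response leaves both unchanged
    d$y2 <- 3.7 * d$y - 11
    f2 <- lme4::lmer(y2 ~ activity + (1 | group_id/fish_id), data = d,
                     REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    r2 <- r2_nakagawa(f2)
    expect_equal(r2$r2_marginal, r$r2_marginal, tolerance = 1e-4)
    expect_equal(r2$r2_conditional, r$r2_conditional, tolerance = 1e-4)
  }
})

test_that("repeatability handles boundaries and is shift/label invariant", {
  # truth v_id = 0: estimate near zero, CI includes 0
  d0 <- simulate_trait_table(seed = 51, v_id = 0)
  r0 <- repeatability(d0, "y", adjust = c("activity", "attacks"),
                      group = "group_id", n_boot = 50, seed = 1)
  expect_lt(r0$r, 0.1)
  expect_equal(r0$ci_low, 0)
  # exact duplicates per id, no noise: R -> 1
  ids <- sprintf("i%02d", 1:30)
  val <- rnorm(30)
  d1 <- data.frame(fish_id = rep(ids, each = 2), y = rep(val, each = 2))
  r1 <- suppressWarnings(repeatability(d1, "y", n_boot = 0, seed = 1))
  expect_gt(r1$r, 0.999)
  # single observation per id is unidentifiable, never a number
  d2 <- data.frame(fish_id = ids, y = val)
  expect_error(repeatability(d2, "y", n_boot = 0, seed = 1),
               "unidentifiable")
  # shift invariance and label-permutation invariance
  d <- simulate_trait_table(seed = 52)
  ra <- repeatability(d, "y", adjust = "oxygen_level", group = "group_id",
                      n_boot = 0, seed = 1)
  d$y <- d$y + 100
  rb <- repeatability(d, "y", adjust = "oxygen_level", group = "group_id",
                      n_boot = 0, seed = 1)
  expect_equal(rb$r, ra$r, tolerance = 1e-6)
  map <- setNames(sample(unique(d$fish_id)), unique(d$fish_id))
  d$fish_id <- unname(map[d$fish_id])
  rc <- repeatability(d, "y", adjust = "oxygen_level", group = "group_id",
                      n_boot = 0, seed = 1)
  expect_equal(rc$r, ra$r, tolerance = 1e-6)
  # invariant: ci_low <= r <= ci_high
  rci <- repeatability(d, "y", adjust = "oxygen_level", group = "group_id",
                       n_boot = 60, seed = 2)
  expect_lte(rci$ci_low, rci$r); expect_gte(rci$ci_high, rci$r)
  expect_gte(rci$ci_low, 0); expect_lte(rci$ci_high, 1)
  expect_error(repeatability(d, "y"), "seed")
})

test_that("the boundary LRT reports strong evidence only when id variance exists", {
  d <- simulate_trait_table(seed = 53, v_id = 0.5)
  r <- repeatability(d, "y", adjust = c("activity", "attacks"),
                     group = "group_id", n_boot = 0, seed = 1)
  expect_lt(r$p, 1e-4)
  d0 <- simulate_trait_table(seed = 54, v_id = 0)
  r0 <- repeatability(d0, "y", adjust = c("activity", "attacks"),
                      group = "group_id", n_boot = 0, seed = 1)
  expect_gt(r0$p, 0.05)
})
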