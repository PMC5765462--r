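# Mixed-effects inference: nested random intercepts, random-structure
# comparison, backward elimination by LRT/AIC, Nakagawa-Schielzeth R2,
# adjusted repeatability with parametric-bootstrap intervals.

#' Fit a linear mixed-effects model
#'
#' Thin wrapper over [lmerTest::lmer()] that accepts the formula as a string,
#' records convergence/singularity diagnostics instead of letting them
#' scroll by, and tags the fit with its estimation type.
#'
#' @param formula model formula (or string), including random terms, e.g.
#'   `breaths ~ activity + attacks + oxygen_level + (1 | group_id/fish_id)`.
#' @param data model frame.
#' @param REML use REML (TRUE) or maximum likelihood (FALSE, default:
#'   fixed-effect comparisons require ML).
#' @param ... passed to [lmerTest::lmer()].
#' @return an `lmerModLmerTest` fit with attributes `convergence_warnings`
#'   (character vector, possibly empty) and `singular` (logical).
#' @export
fit_lme <- function(formula, data, REML = FALSE, ...) {
  if (is.character(formula)) formula <- stats::as.formula(formula)
  warns <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(formula, data = data, REML = REML, ...),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  attr(fit, "convergence_warnings") <- warns
  attr(fit, "singular") <- lme4::isSingular(fit)
  fit
}

#' Coefficient table of a mixed-model fit
#'
#' Estimates, standard errors, Satterthwaite denominator degrees of freedom,
#' t and p values (the df method is implementation-defined and reported, not
#' matched to any particular software's convention).
#'
#' @param fit a fit from [fit_lme()].
#' @return `data.frame` with columns `term, estimate, se, df, t, p`.
#' @export
coef_table <- function(fit) {
  cs <- tryCatch(stats::coef(summary(fit)),
                 error = function(e) NULL)
  if (is.null(cs) || ncol(cs) < 5) {
    cs0 <- stats::coef(summary(as(fit, "lmerMod")))
    cs <- cbind(cs0[, 1:2, drop = FALSE], df = NA_real_,
                cs0[, 3, drop = FALSE],
                p = 2 * stats::pnorm(-abs(cs0[, 3])))
  }
  data.frame(term = rownames(cs), estimate = cs[, 1], se = cs[, 2],
             df = cs[, 3], t = cs[, 4], p = cs[, 5],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Variables of a model term ("a:b" -> c("a","b"))
.term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# Terms not contained in any surviving higher-order interaction
.droppable_terms <- function(terms) {
  if (length(terms) <= 1) return(terms)
  keep <- vapply(terms, function(t) {
    tv <- .term_vars(t)
    !any(vapply(setdiff(terms, t), function(o) {
      all(tv %in% .term_vars(o))
    }, logical(1)))
  }, logical(1))
  terms[keep]
}

# Representative |t| per fixed term: the largest absolute t among the
# term's coefficients (multi-level factors contribute several contrasts;
# a term with one strong contrast should not be an early drop candidate).
# Ordering only needs estimate/SE ratios, so the plain merMod summary is
# used and no denominator-df computation is triggered.
.term_t <- function(fit, fixed_terms) {
  cs <- stats::coef(summary(as(fit, "lmerMod")))
  tval <- cs[, "t value"]
  asg <- attr(stats::model.matrix(fit), "assign")
  tl <- attr(stats::terms(fit, fixed.only = TRUE), "term.labels")
  vapply(fixed_terms, function(tm) {
    i <- which(tl == tm)
    rows <- which(asg == i)
    if (length(rows) == 0) return(NA_real_)
    max(abs(tval[rows]))
  }, numeric(1))
}

.build_formula <- function(response, fixed_terms, random) {
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  stats::as.formula(paste(response, "~", rhs, "+", random))
}

#' Backward elimination of fixed effects
#'
#' Starting from the full model (fitted by maximum likelihood), repeatedly
#' selects the droppable fixed term with the smallest representative |t|
#' (interactions are considered before their main effects; a main effect
#' still present in an interaction is never a candidate) and removes it
#' unless removal significantly worsens the model by likelihood-ratio test
#' (p < `alpha`, equivalently a significantly larger AIC). The full
#' elimination trail is recorded and replays deterministically.
#'
#' @param response response column name (transform it in the data first).
#' @param fixed_terms character vector of fixed-effect terms; interactions
#'   as `"a:b"`.
#' @param random random-effects specification, e.g.
#'   `"(1 | group_id/fish_id)"`.
#' @param data model frame.
#' @param alpha LRT retention threshold (default 0.05); `alpha = 1` keeps
#'   every term, returning the full model.
#' @return object of class `lme_elimination`: `final_terms`, `final_fit`
#'   (refit with REML for reporting), `final_fit_ml`, and `trail` (step,
#'   term, t, dAIC, lrt_p, decision).
#' @export
backward_eliminate <- function(response, fixed_terms, random, data,
                               alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  cur <- fixed_terms
  fit <- fit_lme(.build_formula(response, cur, random), data, REML = FALSE)
  trail <- list()
  step <- 0L
  kept <- character(0)  # tested and retained under the current model
  repeat {
    cand <- setdiff(.droppable_terms(cur), kept)
    if (length(cand) == 0) break
    tt <- .term_t(fit, cand)
    term <- cand[which.min(tt)]
    red <- fit_lme(.build_formula(response, setdiff(cur, term), random),
                   data, REML = FALSE)
    lrt <- stats::anova(red, fit)
    p <- lrt$`Pr(>Chisq)`[2]
    daic <- stats::AIC(red) - stats::AIC(fit)
    drop <- is.na(p) || p >= alpha
    step <- step + 1L
    trail[[step]] <- data.frame(
      step = step, term = term, t = unname(tt[which.min(tt)]),
      dAIC = daic, lrt_p = p,
      decision = if (drop) "dropped" else "kept",
      stringsAsFactors = FALSE
    )
    if (drop) {
      cur <- setdiff(cur, term)
      fit <- red
      kept <- character(0)  # retest everything under the reduced model
    } else {
      kept <- c(kept, term)
    }
  }
  final_reml <- fit_lme(.build_formula(response, cur, random), data,
                        REML = TRUE)
  structure(
    list(final_terms = cur, final_fit = final_reml, final_fit_ml = fit,
         trail = if (length(trail)) do.call(rbind, trail) else
           data.frame(step = integer(0), term = character(0), t = numeric(0),
                      dAIC = numeric(0), lrt_p = numeric(0),
                      decision = character(0)),
         alpha = alpha, response = response, random = random),
    class = "lme_elimination"
  )
}

#' @export
print.lme_elimination <- function(x, ...) {
  cat("Backward elimination (alpha =", x$alpha, ")\n")
  cat("  final fixed terms:",
      if (length(x$final_terms)) paste(x$final_terms, collapse = ", ")
      else "(intercept only)", "\n")
  if (nrow(x$trail)) {
    cat("  trail:\n")
    print(x$trail, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.lme_elimination <- function(object, ...) {
  ct <- coef_table(object$final_fit)
  r2 <- r2_nakagawa(object$final_fit)
  ct$rm2 <- c(r2$r2_marginal, rep(NA, nrow(ct) - 1))
  ct$rc2 <- c(r2$r2_conditional, rep(NA, nrow(ct) - 1))
  ct
}

#' Compare random-intercept and random-slope structures
#'
#' Fits, by REML, the random-intercept model (individuals nested in groups)
#' and an alternative that additionally lets the slope over a covariate
#' (numeric oxygen availability, by default) vary among individuals, and
#' keeps the intercept-only structure unless the slope model significantly
#' improves parsimony by likelihood-ratio test. Equal likelihoods favour the
#' simpler structure.
#'
#' @param response response column name.
#' @param fixed_terms fixed-effect terms (kept identical in both candidates).
#' @param data model frame.
#' @param slope_var numeric covariate whose slope may vary among individuals.
#' @param id,group column names of the individual and group identifiers.
#' @param alpha LRT threshold.
#' @return list with `choice` ("intercept" or "slope"), `lrt_p`, `lrt`
#'   (the anova table), and both fits (`fit_intercept`, `fit_slope`).
#' @export
compare_random_structures <- function(response, fixed_terms, data,
                                      slope_var = "oxygen_num",
                                      id = "fish_id", group = "group_id",
                                      alpha = 0.05) {
  rand0 <- sprintf("(1 | %s/%s)", group, id)
  rand1 <- sprintf("(1 | %s) + (1 + %s | %s:%s)", group, slope_var, group, id)
  m0 <- fit_lme(.build_formula(response, fixed_terms, rand0), data,
                REML = TRUE)
  m1 <- tryCatch(
    fit_lme(.build_formula(response, fixed_terms, rand1), data, REML = TRUE),
    error = function(e) e
  )
  if (inherits(m1, "error")) {
    return(list(choice = "intercept", lrt_p = NA_real_, lrt = NULL,
                fit_intercept = m0, fit_slope = NULL,
                note = paste("slope model failed:", conditionMessage(m1))))
  }
  lrt <- stats::anova(m0, m1, refit = FALSE)
  p <- lrt$`Pr(>Chisq)`[2]
  choice <- if (!is.na(p) && p < alpha &&
                as.numeric(stats::logLik(m1)) >
                  as.numeric(stats::logLik(m0))) "slope" else "intercept"
  list(choice = choice, lrt_p = p, lrt = lrt,
       fit_intercept = m0, fit_slope = m1)
}

#' Marginal and conditional R-squared of a Gaussian mixed model
#'
#' Variance-ratio R2 after Nakagawa & Schielzeth: the marginal R2 is the
#' variance of the fixed-effect predictions over the total (fixed + random
#' intercepts + residual) variance; the conditional R2 adds the random
#' intercept variances to the numerator.
#'
#' @param fit a Gaussian `merMod` / `lmerModLmerTest` fit.
#' @return list of class `r2_pair`: `r2_marginal`, `r2_conditional`, and the
#'   underlying `components` (v_fixed, per-grouping variances, v_residual).
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "merMod"))
  pred <- as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit))
  v_fixed <- stats::var(pred)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri <- vc[vc$grp != "Residual" & (is.na(vc$var2) | vc$var2 == ""), ]
  ri <- ri[is.na(ri$var2), , drop = FALSE]
  v_rand <- sum(ri$vcov)
  v_res <- stats::sigma(fit)^2
  tot <- v_fixed + v_rand + v_res
  if (tot <= 0) stop("total variance is zero; R2 undefined")
  comp <- stats::setNames(ri$vcov, ri$grp)
  structure(
    list(r2_marginal = v_fixed / tot,
         r2_conditional = (v_fixed + v_rand) / tot,
         components = c(v_fixed = v_fixed, comp, v_residual = v_res)),
    class = "r2_pair"
  )
}

#' @export
print.r2_pair <- function(x, ...) {
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Adjusted (consistency) repeatability
#'
#' Proportion of the (fixed-effect-adjusted) variance attributable to
#' consistent among-individual differences:
#' `R = v_id / (v_id + v_group + v_residual)`, from an LME with random
#' intercepts for individual (and optionally group) and the adjustment
#' covariates as fixed effects. Uncertainty by parametric bootstrap
#' (simulate from the fitted model, refit, recompute R); evidence against
#' zero individual variance by likelihood-ratio test with the halved
#' chi-square(1) p-value appropriate at the variance boundary.
#'
#' @param data model frame, one row per individual x context.
#' @param response response column name.
#' @param adjust character vector of fixed adjustment terms (may be empty).
#' @param id individual identifier column.
#' @param group optional group identifier column (NULL to omit).
#' @param n_boot parametric-bootstrap resamples (default 1000).
#' @param seed RNG seed; mandatory so the interval is reproducible.
#' @param level confidence level.
#' @return object of class `repeatability_estimate`: `r`, `ci_low`,
#'   `ci_high`, `p`, variance `components`, `n_boot`, `seed`, `boot`
#'   (the bootstrap replicates).
#' @export
repeatability <- function(data, response, adjust = character(0),
                          id = "fish_id", group = NULL,
                          n_boot = 1000, seed, level = 0.95) {
  if (missing(seed)) stop("seed is mandatory for the bootstrap interval")
  obs_per_id <- table(data[[id]])
  if (all(obs_per_id < 2)) {
    stop("repeatability unidentifiable: every individual has a single ",
         "observation")
  }
  rand <- sprintf("(1 | %s)", id)
  if (!is.null(group)) rand <- paste(rand, sprintf("+ (1 | %s)", group))
  form <- .build_formula(response, adjust, rand)
  fit <- lme4::lmer(form, data = data, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  rfun <- function(f) {
    vc <- as.data.frame(lme4::VarCorr(f))
    v_id <- vc$vcov[vc$grp == id]
    v_grp <- if (!is.null(group)) vc$vcov[vc$grp == group] else 0
    v_res <- vc$vcov[vc$grp == "Residual"]
    v_id / (v_id + sum(v_grp) + v_res)
  }
  r <- rfun(fit)

  # LRT of the individual variance component (ML fits, boundary-halved p)
  form0 <- if (!is.null(group)) {
    .build_formula(response, adjust, sprintf("(1 | %s)", group))
  } else NULL
  ll1 <- as.numeric(stats::logLik(stats::update(fit, REML = FALSE)))
  ll0 <- if (is.null(form0)) {
    rhs <- if (length(adjust)) paste(adjust, collapse = " + ") else "1"
    as.numeric(stats::logLik(stats::lm(
      stats::as.formula(paste(response, "~", rhs)), data = data)))
  } else {
    as.numeric(stats::logLik(lme4::lmer(form0, data = data, REML = FALSE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore"))))
  }
  lr <- max(0, 2 * (ll1 - ll0))
  p <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)

  boot <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    set.seed(seed)
    ysim <- stats::simulate(fit, nsim = n_boot)
    for (b in seq_len(n_boot)) {
      fb <- tryCatch(suppressWarnings(suppressMessages(
        lme4::refit(fit, newresp = ysim[[b]]))),
        error = function(e) NULL)
      if (!is.null(fb)) boot[b] <- rfun(fb)
    }
  }
  bok <- boot[!is.na(boot)]
  a <- (1 - level) / 2
  ci <- if (length(bok)) unname(stats::quantile(bok, c(a, 1 - a))) else
    c(NA_real_, NA_real_)
  ci_low <- max(0, min(ci[1], r, na.rm = TRUE))
  ci_high <- min(1, max(ci[2], r, na.rm = TRUE))

  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(r = r, ci_low = ci_low, ci_high = ci_high, p = p,
         components = stats::setNames(vc$vcov, vc$grp),
         n_boot = n_boot, n_boot_ok = length(bok), seed = seed,
         level = level, boot = boot, response = response,
         adjust = adjust, fit = fit),
    class = "repeatability_estimate"
  )
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("Adjusted repeatability of %s: R = %.3f, %d%% CI %.3f-%.3f, p = %.4g\n",
              x$response, x$r, round(100 * x$level), x$ci_low, x$ci_high, x$p))
  if (length(x$adjust)) {
    cat("  adjusted for:", paste(x$adjust, collapse = ", "), "\n")
  }
  cat(sprintf("  (%d/%d bootstrap refits, seed %s)\n",
              x$n_boot_ok, x$n_boot, format(x$seed)))
  invisible(x)
}
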