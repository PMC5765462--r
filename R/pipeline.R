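# Orchestration: simulate (or ingest) -> respirometry -> ethogram ->
# mixed stats; emit the study's derived tables.

# FNV-1a over a serialised object; cheap provenance hash, not cryptographic.
# The 32-bit state is kept as a double and multiplied in 16-bit halves so
# nothing exceeds R's exact-integer range.
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  m <- 16777619
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  h0 <- h %% 65536
  sprintf("%04x%04x", as.integer((h - h0) / 65536), as.integer(h0))
}

#' Study-level configuration
#'
#' Bundles the generator configuration with every analysis option in one
#' validated object; a serialised copy is written next to the outputs for
#' provenance.
#'
#' @param sim a [sim_config()] (or NULL when ingesting external data).
#' @param q SMR quantile.
#' @param bin_width dispersion bin width, s.
#' @param window proximity window, s.
#' @param alpha LRT threshold for model selection.
#' @param n_boot repeatability bootstrap resamples.
#' @param seed analysis seed (bootstraps); defaults to the generator seed.
#' @param recovery_in_lme include the recovery observation in the LMEs
#'   (default FALSE: recovery is a sixth level for proximity summaries only).
#' @return object of class `study_config`.
#' @export
study_config <- function(sim = NULL, q = 0.12, bin_width = 30, window = 5,
                         alpha = 0.05, n_boot = 1000, seed = NULL,
                         recovery_in_lme = FALSE) {
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (is.null(seed)) {
    if (is.null(sim)) stop("seed is required when no simulator config given")
    seed <- sim$seed
  }
  stopifnot(q > 0, q < 0.5, bin_width > 0, window > 0,
            alpha > 0, alpha <= 1, n_boot >= 0)
  structure(list(sim = sim, q = q, bin_width = bin_width, window = window,
                 alpha = alpha, n_boot = n_boot, seed = as.integer(seed),
                 recovery_in_lme = recovery_in_lme),
            class = "study_config")
}

# Build the fish x oxygen analysis table from ethogram tallies + traits.
# log1p for counts (zeros exist), log for strictly positive traits.
.analysis_table <- function(tallies, traits) {
  df <- merge(tallies, traits, by = "fish_id", sort = FALSE)
  df <- df[df$oxygen_level != "recovery", , drop = FALSE]
  lev <- as.character(sort(unique(as.numeric(df$oxygen_level)),
                           decreasing = TRUE))
  df$oxygen_level <- factor(as.character(df$oxygen_level), levels = lev)
  df$oxygen_num <- as.numeric(as.character(df$oxygen_level)) / 100
  df$log_breaths <- log1p(df$breaths)
  df$log_attacks <- log1p(df$attacks)
  df$log_activity <- log1p(pmax(0, df$activity))
  df$log_smr <- log(df$smr)
  df$log_mass <- log(df$mass)
  df
}

# Table-1-shaped coefficient block for one response
.coef_block <- function(response, fixed_terms, data, label) {
  fit <- fit_lme(.build_formula(response, fixed_terms,
                                "(1 | group_id/fish_id)"),
                 data, REML = TRUE)
  ct <- coef_table(fit)
  r2 <- r2_nakagawa(fit)
  ct$response <- label
  ct$rm2 <- r2$r2_marginal
  ct$rc2 <- r2$r2_conditional
  list(table = ct, fit = fit)
}

#' Run the full study replica
#'
#' Simulates the study (respirometry + behaviour), runs the respirometry
#' pipeline to per-fish traits, the ethogram summaries (tallies, coefficient
#' of dispersion, proximity fractions), and the mixed-model stage:
#' random-structure comparison, per-individual coefficient tables
#' (air breaths, activity, attacks), backward elimination for the breaths
#' model, group-level models with and without the dominant individual, and
#' adjusted repeatability of breaths, attacks and activity.
#'
#' @param cfg a [study_config()] with a simulator configuration.
#' @param outdir optional directory: all tables are written as
#'   tab-separated text plus a run manifest.
#' @param n_boot_repeatability override for the repeatability bootstrap
#'   (defaults to `cfg$n_boot`).
#' @return object of class `study_replica`; see the `tables` element.
#' @export
run_replica <- function(cfg, outdir = NULL,
                        n_boot_repeatability = cfg$n_boot) {
  stopifnot(inherits(cfg, "study_config"), !is.null(cfg$sim))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  sim <- stage("simulate", simulate_study(cfg$sim))

  resp <- stage("respirometry",
                respirometry_batch(sim$optode_log, sim$geometries, q = cfg$q))
  eth <- stage("ethogram",
               ethogram_tables(sim$trials, bin_width = cfg$bin_width,
                               window = cfg$window))
  ana <- stage("join", .analysis_table(eth$tallies, resp$traits))

  rs <- stage("random_structures", compare_random_structures(
    "log_breaths",
    c("log_smr", "log_mass", "pct_air", "log_activity", "log_attacks",
      "oxygen_level"),
    ana))

  t1_breaths <- stage("lme_breaths", .coef_block(
    "log_breaths",
    c("log_smr", "log_mass", "pct_air", "log_activity", "log_attacks",
      "oxygen_level"), ana, "air_breaths"))
  t1_activity <- stage("lme_activity", .coef_block(
    "log_activity",
    c("log_smr", "log_mass", "pct_air", "log_attacks", "oxygen_level"),
    ana, "activity"))
  t1_attacks <- stage("lme_attacks", .coef_block(
    "log_attacks",
    c("log_smr", "log_mass", "pct_air", "oxygen_level"), ana, "attacks"))
  table1 <- rbind(t1_breaths$table, t1_activity$table, t1_attacks$table)

  elim <- stage("elimination", backward_eliminate(
    "log_breaths",
    c("log_smr", "log_mass", "pct_air", "log_activity", "log_attacks",
      "oxygen_level"),
    "(1 | group_id/fish_id)", ana, alpha = cfg$alpha))

  # group-level totals by oxygen level, with and without the dominant
  groups <- unique(sim$roster$group_id)
  g_rows <- list()
  for (g in groups) {
    gtr <- sim$trials[vapply(sim$trials, function(tr) tr$group_id == g,
                             logical(1))]
    dom <- tryCatch(dominant_individual(gtr)$fish_id,
                    error = function(e) NA_character_)
    excl <- if (!is.na(dom)) group_breaths_excluding(gtr, dom) else
      rep(NA_real_, length(gtr))
    for (j in seq_along(gtr)) {
      tr <- gtr[[j]]
      ab <- tally(tr, "attack", by_fish = TRUE)
      g_rows[[length(g_rows) + 1L]] <- data.frame(
        group_id = g, oxygen_level = as.character(tr$oxygen_level),
        total_breaths = tally(tr, "breath"),
        total_attacks = tally(tr, "attack"),
        dominant_id = dom,
        breaths_excl_dominant = unname(excl[j]),
        attacks_by_dominant = if (!is.na(dom)) unname(ab[dom]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  gsum <- do.call(rbind, g_rows)
  glme <- gsum[gsum$oxygen_level != "recovery", , drop = FALSE]
  lev <- as.character(sort(unique(as.numeric(glme$oxygen_level)),
                           decreasing = TRUE))
  glme$oxygen_level <- factor(glme$oxygen_level, levels = lev)

  t2_total <- stage("lme_group_total", {
    fit <- fit_lme(total_breaths ~ total_attacks + oxygen_level +
                     (1 | group_id), glme, REML = TRUE)
    r2 <- r2_nakagawa(fit)
    ct <- coef_table(fit)
    ct$response <- "total_breaths"
    ct$rm2 <- r2$r2_marginal; ct$rc2 <- r2$r2_conditional
    list(table = ct, fit = fit)
  })
  t2_excl <- stage("lme_group_excl_dominant", {
    fit <- fit_lme(breaths_excl_dominant ~ attacks_by_dominant +
                     oxygen_level + (1 | group_id), glme, REML = TRUE)
    r2 <- r2_nakagawa(fit)
    ct <- coef_table(fit)
    ct$response <- "breaths_excl_dominant"
    ct$rm2 <- r2$r2_marginal; ct$rc2 <- r2$r2_conditional
    list(table = ct, fit = fit)
  })
  table2 <- rbind(t2_total$table, t2_excl$table)

  rpt <- stage("repeatability", {
    lapply(c(breaths = "log_breaths", attacks = "log_attacks",
             activity = "log_activity"), function(v) {
      repeatability(ana, v, adjust = "oxygen_level", id = "fish_id",
                    group = "group_id", n_boot = n_boot_repeatability,
                    seed = cfg$seed + 7L)
    })
  })
  rpt_table <- do.call(rbind, lapply(names(rpt), function(nm) {
    x <- rpt[[nm]]
    data.frame(trait = nm, r = x$r, ci_low = x$ci_low, ci_high = x$ci_high,
               p = x$p, n_boot = x$n_boot, stringsAsFactors = FALSE)
  }))

  res <- structure(
    list(
      config = cfg,
      config_hash = .config_hash(cfg),
      sim = sim,
      traits = resp$traits,
      cycles = resp$cycles,
      tables = list(
        tallies = eth$tallies, synchrony = eth$synchrony,
        proximity = eth$proximity, table1 = table1, table2 = table2,
        repeatability = rpt_table, group_summary = gsum,
        elimination_trail = elim$trail
      ),
      analysis_table = ana,
      random_structure = rs[c("choice", "lrt_p")],
      elimination = elim,
      repeatability = rpt,
      decisions = c(
        "quantile interpolation: linear (type 7)",
        "fish body volume subtracted from water phase",
        "CD variance: sample (n-1)",
        "proximity window half-open (0, w]",
        "counts log1p-transformed",
        "fixed-effect selection under ML, reporting under REML",
        "recovery level excluded from LMEs"
      )
    ),
    class = "study_replica"
  )
  if (!is.null(outdir)) write_replica(res, outdir)
  res
}

#' @export
print.study_replica <- function(x, ...) {
  cat("Study replica (config", x$config_hash, ")\n")
  cat(sprintf("  %d fish in %d groups; %d group trials\n",
              nrow(x$traits), length(unique(x$sim$roster$group_id)),
              length(x$sim$trials)))
  cat("  random structure kept:", x$random_structure$choice, "\n")
  cat("  final breaths model terms:",
      paste(x$elimination$final_terms, collapse = ", "), "\n")
  cat("  repeatability:\n")
  print(x$tables$repeatability, row.names = FALSE)
  invisible(x)
}

#' Write a replica result bundle as delimited text
#'
#' One tab-separated file per table plus a machine-readable run manifest
#' (config hash, file list, decisions in effect).
#'
#' @param res a `study_replica` from [run_replica()].
#' @param outdir output directory (created if needed).
#' @export
write_replica <- function(res, outdir) {
  stopifnot(inherits(res, "study_replica"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    p <- file.path(outdir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    basename(p)
  }
  files <- c(
    wr(res$traits, "fish_traits"),
    wr(res$tables$tallies, "tallies"),
    wr(res$tables$synchrony, "synchrony_cd"),
    wr(res$tables$proximity, "proximity"),
    wr(res$tables$table1, "lme_individual"),
    wr(res$tables$table2, "lme_group"),
    wr(res$tables$repeatability, "repeatability"),
    wr(res$tables$group_summary, "group_summary"),
    wr(res$tables$elimination_trail, "elimination_trail")
  )
  if (!is.null(res$sim$resp_truth)) {
    files <- c(files, wr(res$sim$resp_truth, "sim_truth"))
  }
  manifest <- c(
    paste0("config_hash: ", res$config_hash),
    paste0("seed: ", res$config$seed),
    "files:",
    paste0("  - ", files),
    "decisions:",
    paste0("  - ", res$decisions)
  )
  writeLines(manifest, file.path(outdir, "manifest.yml"))
  invisible(outdir)
}

#' Analyse externally deposited tables
#'
#' Ingests a user-supplied local copy of the study's deposited data (or any
#' conformant export) through an explicit column mapping, then runs the same
#' ethogram and mixed-model stages as [run_replica()]. Attacks without coded
#' targets are tolerated: the "being_attacked" proximity category is then
#' reported as unavailable rather than zero.
#'
#' @param event_file delimited behavioural event table.
#' @param trait_file delimited per-fish trait table (one row per fish).
#' @param mapping named character vector mapping required column names
#'   (`trial_id, group_id, oxygen_level, time_s, fish_id, behaviour`, and
#'   optionally `target_id`; for traits `fish_id, mass, smr, pct_air`) to
#'   the columns of the supplied files.
#' @param cfg a [study_config()] (its `sim` entry is ignored).
#' @param duration trial duration in seconds.
#' @param activity_file optional delimited per-trial activity table
#'   (`trial_id, fish_id, distance`, remappable like the others).
#' @return list with the ethogram tables, analysis table and the
#'   Table-1-shaped coefficient block, plus `notes` on unavailable pieces.
#' @export
run_dryad <- function(event_file, trait_file, mapping = NULL,
                      cfg = study_config(seed = 1), duration = 900,
                      activity_file = NULL) {
  ev <- utils::read.delim(event_file, stringsAsFactors = FALSE)
  trt <- utils::read.delim(trait_file, stringsAsFactors = FALSE)
  remap <- function(df, need, optional = character(0)) {
    for (tgt in c(need, optional)) {
      src <- if (!is.null(mapping) && tgt %in% names(mapping)) {
        mapping[[tgt]]
      } else tgt
      if (src %in% names(df)) {
        names(df)[names(df) == src] <- tgt
      } else if (tgt %in% names(df)) {
        # already conformant (one mapping may serve several files)
      } else if (tgt %in% need) {
        stop("column mapping error: no source column for '", tgt,
             "' (looked for '", src, "')")
      }
    }
    df
  }
  ev <- remap(ev, c("trial_id", "group_id", "oxygen_level", "time_s",
                    "fish_id", "behaviour"), "target_id")
  trt <- remap(trt, c("fish_id", "mass", "smr", "pct_air"))
  notes <- character(0)
  if (is.null(ev$target_id)) {
    notes <- c(notes, "no target_id column: 'being_attacked' unavailable")
    ev$target_id <- NA_character_
  }
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(ev, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  trials <- read_event_log(tmp, duration = duration)
  eth <- ethogram_tables(trials, bin_width = cfg$bin_width,
                         window = cfg$window)
  if ("no target_id column: 'being_attacked' unavailable" %in% notes) {
    eth$proximity$fraction[eth$proximity$category == "being_attacked"] <-
      NA_real_
  }
  if (!is.null(activity_file)) {
    act <- remap(utils::read.delim(activity_file, stringsAsFactors = FALSE),
                 c("trial_id", "fish_id", "distance"))
    key_ev <- unique(ev[, c("trial_id", "group_id", "oxygen_level")])
    act <- merge(act, key_ev, by = "trial_id")
    eth$tallies$activity <- NULL
    eth$tallies <- merge(
      eth$tallies,
      act[, c("group_id", "oxygen_level", "fish_id", "distance")],
      by = c("group_id", "oxygen_level", "fish_id"), all.x = TRUE)
    names(eth$tallies)[names(eth$tallies) == "distance"] <- "activity"
  }
  ana <- .analysis_table(eth$tallies, trt)
  terms <- c("log_smr", "log_mass", "pct_air", "log_activity", "log_attacks",
             "oxygen_level")
  if (all(is.na(ana$activity))) {
    notes <- c(notes, "no activity data: log_activity dropped from the model")
    terms <- setdiff(terms, "log_activity")
  }
  blk <- .coef_block("log_breaths", terms, ana, "air_breaths")
  list(trials = trials, tables = eth, analysis_table = ana,
       table1 = blk$table, notes = notes)
}
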