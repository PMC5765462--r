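# Behavioural event streams: tallies, synchrony (coefficient of dispersion),
# 5-s event-proximity attribution, dominance.

.BEHAVIOURS <- c("breath", "attack", "push", "avoid")
.PROX_CATEGORIES <- c("breath_by_other", "own_attack", "being_attacked",
                      "own_avoid", "any_interaction")

#' Construct a behavioural trial
#'
#' One trial is a 15-min (by default) observation of one group of fish at a
#' single aquatic oxygen level, holding a time-ordered stream of coded
#' behaviour events (breath, attack, push, avoid) plus per-fish activity
#' (total distance moved).
#'
#' @param events `data.frame` with columns `time` (s from trial start),
#'   `fish_id`, `behaviour` and optionally `target_id` (attacks/pushes).
#' @param group_id group identifier.
#' @param oxygen_level % air saturation (100, 80, 60, 40, 20) or "recovery".
#' @param duration trial length in seconds.
#' @param roster character vector of the fish in this group; defaults to the
#'   ids present in `events`.
#' @param activity optional named numeric vector of distance moved per fish.
#' @return object of class `trial`.
#' @export
trial <- function(events, group_id, oxygen_level, duration = 900,
                  roster = NULL, activity = NULL) {
  stopifnot(is.data.frame(events), duration > 0)
  if (nrow(events) > 0) {
    need <- c("time", "fish_id", "behaviour")
    miss <- setdiff(need, names(events))
    if (length(miss)) stop("events missing columns: ",
                           paste(miss, collapse = ", "))
    bad <- setdiff(unique(events$behaviour), .BEHAVIOURS)
    if (length(bad)) stop("unknown behaviour code(s): ",
                          paste(bad, collapse = ", "))
    if (any(events$time < 0 | events$time > duration)) {
      stop("event times must lie within [0, duration]")
    }
    if (is.null(events$target_id)) events$target_id <- NA_character_
    self <- !is.na(events$target_id) & events$target_id == events$fish_id
    if (any(self)) stop("event target must differ from actor")
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
  } else {
    events <- data.frame(time = numeric(0), fish_id = character(0),
                         behaviour = character(0), target_id = character(0),
                         stringsAsFactors = FALSE)
  }
  if (is.null(roster)) roster <- sort(unique(as.character(events$fish_id)))
  extra <- setdiff(unique(as.character(events$fish_id)), roster)
  if (length(extra)) stop("fish not on roster: ", paste(extra, collapse = ", "))
  structure(
    list(events = events, group_id = group_id, oxygen_level = oxygen_level,
         duration = duration, roster = roster, activity = activity),
    class = "trial"
  )
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("Trial: group %s at %s%% air saturation, %d s\n",
              x$group_id, as.character(x$oxygen_level), x$duration))
  tab <- table(factor(x$events$behaviour, levels = .BEHAVIOURS))
  cat("  events:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Count events in a trial
#'
#' @param x a [trial()].
#' @param behaviour one of "breath", "attack", "push", "avoid".
#' @param by_fish if TRUE return a named vector over the roster (zeros
#'   included), else the group total.
#' @return integer count(s).
#' @export
tally <- function(x, behaviour = "breath", by_fish = FALSE) {
  stopifnot(inherits(x, "trial"))
  if (!behaviour %in% .BEHAVIOURS) {
    stop("unknown behaviour code: ", behaviour)
  }
  ev <- x$events[x$events$behaviour == behaviour, , drop = FALSE]
  if (!by_fish) return(nrow(ev))
  cnt <- table(factor(as.character(ev$fish_id), levels = x$roster))
  out <- as.integer(cnt)
  names(out) <- x$roster
  out
}

#' Coefficient of dispersion of event times
#'
#' Splits the trial into fixed-width bins anchored at time zero and computes
#' the variance-to-mean ratio of the per-bin event counts. Values above 1
#' indicate temporal clumping (synchrony); below 1, a more uniform spread
#' than a Poisson process. The sample variance (n - 1 denominator) is used
#' and recorded in the result.
#'
#' @param event_times numeric vector of event times in seconds.
#' @param duration trial duration in seconds.
#' @param bin_width bin width in seconds (default 30, chosen to capture
#'   chains of surfacing spread over tens of seconds).
#' @return object of class `synchrony_cd` with fields `cd`, `bin_width`,
#'   `n_bins`, `counts`, `n_events`, `variance` ("sample"). `cd` is `NA`
#'   (with a warning) when there are no events: an empty stream has an
#'   undefined, not zero, dispersion.
#' @examples
#' coefficient_of_dispersion(c(15, 45, 75, 105), duration = 120)$cd  # 0
#' @export
coefficient_of_dispersion <- function(event_times, duration = 900,
                                      bin_width = 30) {
  stopifnot(bin_width > 0, duration > 0)
  n_bins <- duration %/% bin_width
  if (n_bins < 2) stop("need at least 2 bins")
  if (duration %% bin_width != 0) {
    warning("duration not a multiple of bin_width; trailing partial bin dropped")
  }
  event_times <- event_times[event_times >= 0 & event_times < n_bins * bin_width]
  counts <- tabulate(pmin(floor(event_times / bin_width) + 1L, n_bins),
                     nbins = n_bins)
  if (length(event_times) == 0) {
    warning("no events: coefficient of dispersion undefined")
    cd <- NA_real_
  } else {
    cd <- stats::var(counts) / mean(counts)
  }
  structure(
    list(cd = cd, bin_width = bin_width, n_bins = n_bins, counts = counts,
         n_events = length(event_times), variance = "sample"),
    class = "synchrony_cd"
  )
}

#' @export
print.synchrony_cd <- function(x, ...) {
  cat(sprintf("Coefficient of dispersion: %.3f (%d events, %d x %d-s bins)\n",
              x$cd, x$n_events, x$n_bins, x$bin_width))
  invisible(x)
}

# Qualifying reference event times for one breath's category, relative to a
# focal fish f. Returns times of all events of the category in the trial.
.prox_ref_times <- function(ev, f, category) {
  switch(category,
    breath_by_other = ev$time[ev$behaviour == "breath" & ev$fish_id != f],
    own_attack = ev$time[ev$behaviour == "attack" & ev$fish_id == f],
    being_attacked = ev$time[ev$behaviour == "attack" &
                               !is.na(ev$target_id) & ev$target_id == f],
    own_avoid = ev$time[ev$behaviour == "avoid" & ev$fish_id == f],
    any_interaction = ev$time[ev$behaviour %in% c("attack", "push", "avoid") &
                                (ev$fish_id == f |
                                   (!is.na(ev$target_id) & ev$target_id == f))],
    stop("unknown proximity category: ", category)
  )
}

#' Fraction of air breaths preceded by a social event
#'
#' For each breath by a fish f, the breath qualifies for a category when at
#' least one reference event occurred at lag in (0, window] seconds before
#' it. The lower bound is open: simultaneous events do not count. A breath
#' with several qualifying reference events still counts once. Categories:
#' `breath_by_other` (breath by any other fish), `own_attack` (attack by f),
#' `being_attacked` (attack targeting f), `own_avoid` (avoid by f),
#' `any_interaction` (attack, push or avoid with f as actor or target;
#' avoids involve the avoider only).
#'
#' @param x a [trial()].
#' @param category one of the five categories above.
#' @param window seconds; default 5.
#' @param scope fish id(s) whose breaths are scored; default the full roster.
#' @return object of class `proximity_result` with `fraction`, `n_breaths`,
#'   `n_qualifying`, `category`, `window`. With zero breaths in scope the
#'   fraction is `NA` with a warning (undefined, not zero).
#' @export
proximity_fraction <- function(x, category = "breath_by_other", window = 5,
                               scope = NULL) {
  stopifnot(inherits(x, "trial"), window > 0)
  if (!category %in% .PROX_CATEGORIES) {
    stop("unknown proximity category: ", category)
  }
  if (is.null(scope)) scope <- x$roster
  ev <- x$events
  breaths <- ev[ev$behaviour == "breath" & ev$fish_id %in% scope, ,
                drop = FALSE]
  if (nrow(breaths) == 0) {
    warning("no breaths in scope: proximity fraction undefined")
    return(structure(list(category = category, window = window,
                          fraction = NA_real_, n_breaths = 0L,
                          n_qualifying = 0L),
                     class = "proximity_result"))
  }
  qual <- logical(nrow(breaths))
  for (f in unique(as.character(breaths$fish_id))) {
    ref <- .prox_ref_times(ev, f, category)
    idx <- which(breaths$fish_id == f)
    if (length(ref) == 0) next
    for (i in idx) {
      lag <- breaths$time[i] - ref
      qual[i] <- any(lag > 0 & lag <= window)
    }
  }
  structure(
    list(category = category, window = window,
         fraction = mean(qual), n_breaths = nrow(breaths),
         n_qualifying = sum(qual)),
    class = "proximity_result"
  )
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("Proximity [%s, (0, %g s]]: %.1f%% of %d breaths\n",
              x$category, x$window, 100 * x$fraction, x$n_breaths))
  invisible(x)
}

#' Per-attack trigger attribution
#'
#' The converse of [proximity_fraction()]: the fraction of attacks that are
#' followed within `window` seconds by a breath of the attack's actor
#' (`role = "actor"`) or target (`role = "target"`). When the baseline
#' breathing rate is negligible this fraction identifies the probability
#' that an attack triggers a breath in that participant.
#'
#' @param x a [trial()].
#' @param role "actor" or "target".
#' @param window seconds; default 5.
#' @return list with `fraction` and `n_attacks` (`fraction` NA when there
#'   are no attacks, or no targeted attacks for `role = "target"`).
#' @export
trigger_attribution <- function(x, role = c("actor", "target"), window = 5) {
  stopifnot(inherits(x, "trial"), window > 0)
  role <- match.arg(role)
  ev <- x$events
  atk <- ev[ev$behaviour == "attack", , drop = FALSE]
  if (role == "target") atk <- atk[!is.na(atk$target_id), , drop = FALSE]
  if (nrow(atk) == 0) return(list(fraction = NA_real_, n_attacks = 0L))
  who <- if (role == "actor") atk$fish_id else atk$target_id
  br <- ev[ev$behaviour == "breath", , drop = FALSE]
  hit <- vapply(seq_len(nrow(atk)), function(i) {
    lag <- br$time[br$fish_id == who[i]] - atk$time[i]
    any(lag > 0 & lag <= window)
  }, logical(1))
  list(fraction = mean(hit), n_attacks = nrow(atk))
}

#' Identify the dominant individual of a group
#'
#' The dominant is the fish performing the most attacks summed across the
#' group's trials. Ties are broken deterministically: total attacks, then
#' attacks + pushes, then lexicographic fish id; the tie-break path taken is
#' recorded in the result.
#'
#' @param trials list of [trial()] objects for one group.
#' @return list with `fish_id`, per-fish `attacks`, and `tie_break`
#'   ("attacks", "attacks_pushes" or "lexicographic").
#' @export
dominant_individual <- function(trials) {
  if (inherits(trials, "trial")) trials <- list(trials)
  stopifnot(length(trials) >= 1, all(vapply(trials, inherits, TRUE, "trial")))
  roster <- trials[[1]]$roster
  atk <- Reduce(`+`, lapply(trials, tally, behaviour = "attack",
                            by_fish = TRUE))
  if (sum(atk) == 0) stop("no attacks in group: no dominant individual")
  top <- names(atk)[atk == max(atk)]
  tie_break <- "attacks"
  if (length(top) > 1) {
    psh <- Reduce(`+`, lapply(trials, tally, behaviour = "push",
                              by_fish = TRUE))
    ap <- atk[top] + psh[top]
    top <- names(ap)[ap == max(ap)]
    tie_break <- "attacks_pushes"
    if (length(top) > 1) {
      top <- sort(top)[1]
      tie_break <- "lexicographic"
    }
  }
  list(fish_id = top[1], attacks = atk, tie_break = tie_break)
}

#' Group breath totals excluding one fish
#'
#' Per-trial totals of breaths performed by all group members except the
#' excluded fish (typically the dominant individual).
#'
#' @param trials list of [trial()] objects for one group.
#' @param exclude fish id to exclude; must be on the roster.
#' @return numeric vector, one total per trial (named by oxygen level).
#' @export
group_breaths_excluding <- function(trials, exclude) {
  if (inherits(trials, "trial")) trials <- list(trials)
  stopifnot(all(vapply(trials, inherits, TRUE, "trial")))
  roster <- trials[[1]]$roster
  if (!exclude %in% roster) stop("excluded fish '", exclude,
                                 "' not on roster")
  out <- vapply(trials, function(tr) {
    b <- tally(tr, "breath", by_fish = TRUE)
    sum(b[setdiff(roster, exclude)])
  }, numeric(1))
  names(out) <- vapply(trials, function(tr) as.character(tr$oxygen_level),
                       character(1))
  out
}

#' Read / write delimited behavioural event logs
#'
#' One row per event: `trial_id, group_id, oxygen_level, time_s, fish_id,
#' behaviour, target_id` (tab-separated, header; empty target for breaths
#' and avoids). `read_event_log()` reconstructs one [trial()] per trial_id.
#'
#' @param path file path.
#' @param duration trial duration passed to [trial()].
#' @param rosters optional named list of rosters keyed by group id.
#' @return named list of [trial()] objects.
#' @export
read_event_log <- function(path, duration = 900, rosters = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(fish_id = "character"))
  need <- c("trial_id", "group_id", "oxygen_level", "time_s", "fish_id",
            "behaviour")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event log missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(df$target_id)) df$target_id <- NA_character_
  df$target_id <- as.character(df$target_id)
  df$target_id[df$target_id == ""] <- NA_character_
  out <- lapply(split(df, df$trial_id), function(d) {
    g <- as.character(d$group_id[1])
    trial(
      data.frame(time = d$time_s, fish_id = as.character(d$fish_id),
                 behaviour = d$behaviour, target_id = d$target_id,
                 stringsAsFactors = FALSE),
      group_id = g, oxygen_level = d$oxygen_level[1], duration = duration,
      roster = if (!is.null(rosters)) rosters[[g]] else NULL
    )
  })
  out[unique(df$trial_id)]
}

#' @rdname read_event_log
#' @param trials named list of [trial()] objects (names become trial ids).
#' @export
write_event_log <- function(trials, path) {
  if (inherits(trials, "trial")) trials <- list(trial1 = trials)
  if (is.null(names(trials))) {
    names(trials) <- paste0("trial", seq_along(trials))
  }
  rows <- lapply(names(trials), function(id) {
    tr <- trials[[id]]
    if (nrow(tr$events) == 0) return(NULL)
    data.frame(trial_id = id, group_id = tr$group_id,
               oxygen_level = tr$oxygen_level, time_s = tr$events$time,
               fish_id = tr$events$fish_id, behaviour = tr$events$behaviour,
               target_id = ifelse(is.na(tr$events$target_id), "",
                                  tr$events$target_id),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise a set of trials into tidy ethogram tables
#'
#' Produces, keyed by (group, oxygen level): per-fish and per-group tallies,
#' the coefficient of dispersion for breaths and attacks, and proximity
#' fractions for every category.
#'
#' @param trials list of [trial()] objects.
#' @param bin_width CD bin width, s.
#' @param window proximity window, s.
#' @return list of `data.frame`s: `tallies`, `synchrony`, `proximity`.
#' @export
ethogram_tables <- function(trials, bin_width = 30, window = 5) {
  if (inherits(trials, "trial")) trials <- list(trials)
  tl <- do.call(rbind, lapply(trials, function(tr) {
    b <- tally(tr, "breath", by_fish = TRUE)
    a <- tally(tr, "attack", by_fish = TRUE)
    p <- tally(tr, "push", by_fish = TRUE)
    v <- tally(tr, "avoid", by_fish = TRUE)
    act <- if (!is.null(tr$activity)) unname(tr$activity[tr$roster]) else NA
    data.frame(group_id = tr$group_id, oxygen_level = tr$oxygen_level,
               fish_id = tr$roster, breaths = unname(b), attacks = unname(a),
               pushes = unname(p), avoids = unname(v), activity = act,
               stringsAsFactors = FALSE)
  }))
  sy <- do.call(rbind, lapply(trials, function(tr) {
    bt <- tr$events$time[tr$events$behaviour == "breath"]
    at <- tr$events$time[tr$events$behaviour == "attack"]
    cdb <- if (length(bt)) coefficient_of_dispersion(bt, tr$duration,
                                                     bin_width)$cd else NA_real_
    cda <- if (length(at)) coefficient_of_dispersion(at, tr$duration,
                                                     bin_width)$cd else NA_real_
    data.frame(group_id = tr$group_id, oxygen_level = tr$oxygen_level,
               cd_breaths = cdb, cd_attacks = cda,
               stringsAsFactors = FALSE)
  }))
  px <- do.call(rbind, lapply(trials, function(tr) {
    fr <- vapply(.PROX_CATEGORIES, function(cat) {
      suppressWarnings(proximity_fraction(tr, cat, window)$fraction)
    }, numeric(1))
    data.frame(group_id = tr$group_id, oxygen_level = tr$oxygen_level,
               category = .PROX_CATEGORIES, fraction = unname(fr),
               stringsAsFactors = FALSE)
  }))
  rownames(tl) <- rownames(sy) <- rownames(px) <- NULL
  list(tallies = tl, synchrony = sy, proximity = px)
}
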