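# Independent brute-force oracles, kept deliberately naive: plain loops and
# first-principles formulas, no shared code with the implementation paths
# they check.

# q-th quantile with linear interpolation between order statistics
oracle_quantile <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * q
  lo <- floor(h)
  if (lo + 1 >= n) return(xs[n])
  xs[lo + 1] + (h - lo) * (xs[lo + 2] - xs[lo + 1])
}

# variance/mean ratio of per-bin counts, loop-based, sample variance
oracle_cd <- function(times, duration, bin_width) {
  n_bins <- duration %/% bin_width
  counts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) * bin_width
    hi <- b * bin_width
    for (t in times) if (t >= lo && t < hi) counts[b] <- counts[b] + 1L
  }
  m <- sum(counts) / n_bins
  v <- sum((counts - m)^2) / (n_bins - 1)
  v / m
}

# per-breath proximity fraction by explicit pair loop
oracle_proximity <- function(tr, category, window) {
  ev <- tr$events
  br <- which(ev$behaviour == "breath")
  if (length(br) == 0) return(NA_real_)
  n_qual <- 0L
  for (i in br) {
    f <- ev$fish_id[i]
    t <- ev$time[i]
    qual <- FALSE
    for (j in seq_len(nrow(ev))) {
      lag <- t - ev$time[j]
      if (lag <= 0 || lag > window) next
      hit <- switch(category,
        breath_by_other = ev$behaviour[j] == "breath" && ev$fish_id[j] != f,
        own_attack = ev$behaviour[j] == "attack" && ev$fish_id[j] == f,
        being_attacked = ev$behaviour[j] == "attack" &&
          !is.na(ev$target_id[j]) && ev$target_id[j] == f,
        own_avoid = ev$behaviour[j] == "avoid" && ev$fish_id[j] == f,
        any_interaction = ev$behaviour[j] %in% c("attack", "push", "avoid") &&
          (ev$fish_id[j] == f ||
             (!is.na(ev$target_id[j]) && ev$target_id[j] == f))
      )
      if (isTRUE(hit)) { qual <- TRUE; break }
    }
    if (qual) n_qual <- n_qual + 1L
  }
  n_qual / length(br)
}

# random small trial over a 4-fish roster
random_small_trial <- function(n_events = 25, duration = 120) {
  roster <- c("A", "B", "C", "D")
  beh <- sample(c("breath", "attack", "push", "avoid"), n_events,
                replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1))
  fish <- sample(roster, n_events, replace = TRUE)
  target <- rep(NA_character_, n_events)
  need_t <- beh %in% c("attack", "push")
  for (i in which(need_t)) target[i] <- sample(setdiff(roster, fish[i]), 1)
  trial(
    data.frame(time = round(runif(n_events, 0, duration), 2),
               fish_id = fish, behaviour = beh, target_id = target,
               stringsAsFactors = FALSE),
    group_id = "G", oxygen_level = 100, duration = duration, roster = roster
  )
}
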