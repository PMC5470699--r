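# Brute-force day-by-day episode simulator, independent of the package's
# gap scan: walks the calendar one day at a time with a permissible-time
# counter (supply + grace) that each purchase re-arms, provided the counter
# has not expired. Purchases arriving after expiry are outside the episode.
oracle_episode <- function(day, supply, grace, followup_days) {
  stopifnot(day[1] == 0, !is.unsorted(day))
  horizon <- max(day)
  purch_at <- integer(horizon + 1L)
  purch_at[day + 1L] <- seq_along(day)
  counter <- supply[1] + grace[1]
  last <- 1L
  stopped <- FALSE
  if (horizon >= 1) {
    for (d in seq_len(horizon)) {
      counter <- counter - 1L
      k <- purch_at[d + 1L]
      if (k > 0L && !stopped) {
        if (counter >= 0L) {
          last <- k
          counter <- supply[k] + grace[k]
        } else {
          stopped <- TRUE
        }
      }
    }
  }
  t_disc <- day[last] + supply[last]
  if (t_disc >= followup_days) {
    list(time = as.numeric(followup_days), event = 0L, mode = "none",
         last = last)
  } else {
    list(time = as.numeric(t_disc), event = 1L,
         mode = if (stopped) "interruption" else "complete_stop", last = last)
  }
}
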