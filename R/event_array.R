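#' Construct an event array
#'
#' Detected (or planted) slow-wave events as onset/duration pairs in seconds
#' within a session of known length.  Events must be strictly increasing and
#' non-overlapping.
#'
#' @param onsets_s Event onsets in seconds.
#' @param durations_s Event durations in seconds (same length).
#' @param session_duration_s Total session length in seconds.
#' @return An object of class `event_array`.
#' @export
event_array <- function(onsets_s, durations_s, session_duration_s) {
  onsets_s <- as.numeric(onsets_s)
  durations_s <- as.numeric(durations_s)
  if (length(onsets_s) != length(durations_s))
    stop("onsets and durations must have equal length")
  if (length(onsets_s)) {
    if (is.unsorted(onsets_s, strictly = TRUE))
      stop("onsets must be strictly increasing")
    if (any(onsets_s < 0) ||
        any(onsets_s + durations_s > session_duration_s + 1e-9))
      stop("events must lie within [0, session_duration_s]")
    if (any(durations_s < 0)) stop("durations must be non-negative")
    if (length(onsets_s) > 1L) {
      ends <- onsets_s + durations_s
      if (any(ends[-length(ends)] > onsets_s[-1L] + 1e-9))
        stop("events must not overlap")
    }
  }
  structure(list(onsets_s = onsets_s, durations_s = durations_s,
                 session_duration_s = as.numeric(session_duration_s)),
            class = "event_array")
}

#' @export
print.event_array <- function(x, ...) {
  cat(sprintf("<event_array> %d events in %.1f s (%.2f events/min)\n",
              length(x$onsets_s), x$session_duration_s,
              60 * length(x$onsets_s) / x$session_duration_s))
  invisible(x)
}

#' Number of events
#' @param events An `event_array`.
#' @return Integer event count.
#' @export
n_events <- function(events) length(events$onsets_s)

#' Binarize events to scan-volume resolution
#'
#' The slow-wave vector marks volume v with 1 iff the half-open volume
#' interval `[v*tr, (v+1)*tr)` overlaps any event interval
#' `[onset, onset + duration)`.
#'
#' @param events An `event_array`.
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of volumes in the paired BOLD session.
#' @return A `slow_wave_vector`: list with `bins` (0/1 per volume) and `tr_s`.
#' @export
binarize_to_tr <- function(events, tr_s, n_volumes) {
  if (length(events$onsets_s) &&
      any(events$onsets_s + events$durations_s > n_volumes * tr_s + 1e-9))
    stop("events extend beyond n_volumes * tr_s")
  bins <- integer(n_volumes)
  for (i in seq_along(events$onsets_s)) {
    a <- events$onsets_s[i]
    b <- a + events$durations_s[i]
    v0 <- floor(a / tr_s)
    # half-open event interval: an event ending exactly at a volume boundary
    # does not mark that volume
    v1 <- ceiling(b / tr_s) - 1
    if (b <= a) v1 <- v0
    v0 <- max(0, v0); v1 <- min(n_volumes - 1, v1)
    if (v1 >= v0) bins[(v0:v1) + 1L] <- 1L
  }
  structure(list(bins = bins, tr_s = tr_s), class = "slow_wave_vector")
}

#' Onset volumes of events
#'
#' Volume indices (1-based) containing each event onset; used to anchor the
#' FIR design.
#'
#' @param events An `event_array`.
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of volumes.
#' @return Integer vector of onset volume indices.
#' @export
onset_volumes <- function(events, tr_s, n_volumes) {
  v <- floor(events$onsets_s / tr_s) + 1L
  v[v >= 1L & v <= n_volumes]
}

#' Onset-impulse vector at scan-volume resolution
#'
#' Like [binarize_to_tr()] but marks only the volume containing each event
#' onset, for analyses that model the response to the wave onset rather
#' than a duration boxcar.
#'
#' @param events An `event_array`.
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of volumes.
#' @return A `slow_wave_vector` with a single 1 per event.
#' @export
onset_vector <- function(events, tr_s, n_volumes) {
  bins <- integer(n_volumes)
  bins[onset_volumes(events, tr_s, n_volumes)] <- 1L
  structure(list(bins = bins, tr_s = tr_s), class = "slow_wave_vector")
}

#' Per-bin event frequency
#'
#' Counts events (by onset) in consecutive complete bins of `bin_s` seconds
#' and converts to Hz; the session mean is also reported in events/min.
#'
#' @param events An `event_array`.
#' @param bin_s Bin width in seconds (default 100).
#' @return List with `bin_hz` (per-bin frequency, Hz), `mean_hz`, and
#'   `events_per_min`.
#' @export
event_frequency <- function(events, bin_s = 100) {
  nb <- floor(events$session_duration_s / bin_s)
  if (nb < 1L) stop("session shorter than one bin")
  counts <- integer(nb)
  if (length(events$onsets_s)) {
    b <- floor(events$onsets_s / bin_s) + 1L
    b <- b[b <= nb]  # onsets in the trailing partial bin are ignored
    tb <- table(b)
    counts[as.integer(names(tb))] <- as.integer(tb)
  }
  hz <- counts / bin_s
  list(bin_hz = hz, mean_hz = mean(hz), events_per_min = mean(hz) * 60)
}

#' Time-mirror an event array
#'
#' Control transform: each event (onset o, duration d) maps to
#' (T - o - d, d) with T the session duration, preserving the number of
#' events, their durations and the inter-event interval distribution while
#' destroying their timing relative to the BOLD signal.
#'
#' @param events An `event_array`.
#' @return The mirrored `event_array`.
#' @export
mirror_events <- function(events) {
  T <- events$session_duration_s
  o <- T - events$onsets_s - events$durations_s
  ord <- order(o)
  event_array(o[ord], events$durations_s[ord], T)
}

#' Transplant events from another session
#'
#' Control transform: re-use the event array of a different recording against
#' this session's BOLD data.  Events are clipped to the target session
#' length; events starting beyond it are dropped with a warning.
#'
#' @param events An `event_array` from the donor session.
#' @param target_session_length_s Length of the target session in seconds.
#' @return An `event_array` valid for the target session.
#' @export
swap_events <- function(events, target_session_length_s) {
  o <- events$onsets_s
  d <- events$durations_s
  keep <- o < target_session_length_s
  if (!any(keep)) stop("all donor events lie beyond the target session")
  if (!all(keep)) warning(sprintf("%d donor event(s) beyond target session dropped",
                                  sum(!keep)))
  o <- o[keep]; d <- d[keep]
  over <- o + d > target_session_length_s
  if (any(over)) {
    warning(sprintf("%d donor event(s) clipped at target session end", sum(over)))
    d[over] <- target_session_length_s - o[over]
  }
  event_array(o, d, target_session_length_s)
}
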