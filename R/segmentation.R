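#' Detect screams in a recording by amplitude gating
#'
#' Short-window RMS energy is gated at `threshold_db` relative to the
#' clip's peak frame. Active regions shorter than `min_dur` are dropped.
#' Two temporal thresholds then structure the result: silences of at
#' most `unit_gap` (default 0.03 s) are bridged inside a single vocal
#' unit, and regions closer than `scream_gap` (default 0.3 s) belong to
#' the same scream utterance (a scream spans its first unit's onset to
#' its last unit's offset); gaps of `scream_gap` or more separate
#' distinct screams.
#'
#' @param clip An [audio_clip()] (mono).
#' @param threshold_db Gate threshold in dB relative to the peak frame
#'   RMS.
#' @param min_dur Minimum raw region duration in seconds.
#' @param unit_gap,scream_gap The two silence thresholds in seconds.
#' @param frame_len,hop Analysis frame length and hop in seconds; the
#'   hop sets the timing resolution.
#' @return A `data.frame` with one row per scream: `onset`, `offset`
#'   (s), `n_units`; a silent clip yields zero rows.
#' @export
detect_screams <- function(clip, threshold_db = -25, min_dur = 0.05,
                           unit_gap = 0.03, scream_gap = 0.3,
                           frame_len = 0.005, hop = 0.0025) {
  stopifnot(is_audio_clip(clip))
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      n_units = integer(0))
  nf <- max(1L, round(frame_len * clip$rate))
  nh <- max(1L, round(hop * clip$rate))
  n <- length(clip$samples)
  if (n < nf) return(empty)
  nframes <- (n - nf) %/% nh + 1L
  starts <- (seq_len(nframes) - 1L) * nh
  idx <- outer(seq_len(nf), starts, "+")
  rms <- sqrt(colMeans(matrix(clip$samples[idx]^2, nrow = nf)))
  peak <- max(rms)
  if (peak <= 0) return(empty)
  active <- rms > peak * 10^(threshold_db / 20)
  if (!any(active)) return(empty)

  r <- rle(active)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  on_i <- which(r$values)
  regions <- data.frame(
    onset = starts[begs[on_i]] / clip$rate,
    offset = (starts[ends[on_i]] + nf) / clip$rate)
  regions <- regions[regions$offset - regions$onset >= min_dur, ,
                     drop = FALSE]
  if (!nrow(regions)) return(empty)

  # merge regions separated by < scream_gap into screams; count units
  # (sub-regions separated by more than unit_gap) within each scream
  gaps <- regions$onset[-1L] - regions$offset[-nrow(regions)]
  scream_id <- cumsum(c(1L, as.integer(gaps >= scream_gap)))
  out <- do.call(rbind, lapply(split(regions, scream_id), function(rg) {
    g <- rg$onset[-1L] - rg$offset[-nrow(rg)]
    data.frame(onset = rg$onset[1L], offset = rg$offset[nrow(rg)],
               n_units = 1L + sum(g > unit_gap))
  }))
  rownames(out) <- NULL
  out
}

#' Group labelled screams into bouts
#'
#' A bout is a conflict stage with constant signaller role and conflict
#' severity: within each event and caller, a new bout starts at the
#' first scream whose `role` or `severity` differs from the previous
#' scream's.
#'
#' @param segments `data.frame` with `event_id`, `caller_id`, `role`,
#'   `severity` and `onset` (time order); unlabelled rows are an error.
#' @return `segments` with a `bout_id` column added
#'   (`"<event>_b<k>"`).
#' @export
group_bouts <- function(segments) {
  need <- c("event_id", "caller_id", "role", "severity", "onset")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segments lack column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("role", "severity")) {
    bad <- which(is.na(segments[[col]]))
    if (length(bad))
      stop("unlabelled segment(s) (missing `", col, "`) at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  segments <- segments[order(segments$event_id, segments$onset), ,
                       drop = FALSE]
  segments$bout_id <- NA_character_
  for (ev in unique(segments$event_id)) {
    for (cl in unique(segments$caller_id[segments$event_id == ev])) {
      i <- which(segments$event_id == ev & segments$caller_id == cl)
      key <- paste(segments$role[i], segments$severity[i])
      newb <- c(TRUE, key[-1L] != key[-length(key)])
      segments$bout_id[i] <- sprintf("%s_b%d", ev, cumsum(newb))
    }
  }
  rownames(segments) <- NULL
  segments
}

#' Group bouts into agonistic events
#'
#' Time-ordered bouts are assigned to the same event unless they are
#' separated by at least `event_gap` seconds without agonistic activity
#' or the pair of interacting individuals changes.
#'
#' @param bouts `data.frame` with `start`, `end` (s, absolute within a
#'   session) and optionally `caller_id`/`opponent_id` (the partner
#'   pair).
#' @param event_gap Silence threshold in seconds (default 30).
#' @return `bouts` with an `event_id` column (`"E<k>"`) added.
#' @export
group_events <- function(bouts, event_gap = 30) {
  stopifnot(all(c("start", "end") %in% names(bouts)))
  bouts <- bouts[order(bouts$start), , drop = FALSE]
  n <- nrow(bouts)
  if (!n) { bouts$event_id <- character(0); return(bouts) }
  pair <- if (all(c("caller_id", "opponent_id") %in% names(bouts))) {
    apply(cbind(bouts$caller_id, bouts$opponent_id), 1L,
          function(x) paste(sort(x), collapse = "|"))
  } else rep("", n)
  new_ev <- c(TRUE, (bouts$start[-1L] - bouts$end[-n] >= event_gap) |
                (pair[-1L] != pair[-n]))
  bouts$event_id <- sprintf("E%d", cumsum(new_ev))
  rownames(bouts) <- NULL
  bouts
}

#' Bout-level features
#'
#' The six bout-level parameters: bout duration (first scream onset to
#' last scream offset), number of screams, average scream duration, mean
#' inter-scream interval, scream rate (screams per second of bout), and
#' the percentage of screams carrying at least one non-linear
#' phenomenon.
#'
#' @param segments `data.frame` of this bout's screams with `onset`,
#'   `offset` (s); at least one row.
#' @param nlp_flags Logical vector, one per scream: any NLP present.
#' @return Named list of the six features.
#' @export
bout_features <- function(segments, nlp_flags = NULL) {
  if (!nrow(segments)) stop("empty bout: at least one scream required")
  segments <- segments[order(segments$onset), , drop = FALSE]
  n <- nrow(segments)
  bd <- segments$offset[n] - segments$onset[1L]
  iv <- if (n > 1L) mean(segments$onset[-1L] - segments$offset[-n])
  else NA_real_
  list(bout_duration = bd,
       n_screams = n,
       avg_scream_duration = mean(segments$offset - segments$onset),
       scream_intervals = iv,
       scream_rate = n / bd,
       pct_nlp = if (is.null(nlp_flags)) NA_real_
       else 100 * mean(nlp_flags, na.rm = TRUE))
}
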