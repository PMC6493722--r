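#' Annotation table schema
#'
#' The pipeline uses one documented CSV dialect for scream annotations.
#' Required columns:
#'
#' * `event_id`, `bout_id`, `caller_id` — identifiers (character or integer);
#'   a bout belongs to exactly one event.
#' * `role` — `"aggressor"` or `"victim"`; constant within a bout.
#' * `severity` — `"mild"` or `"severe"`; constant within a bout.
#' * `quality` — `"good"` or `"poor"` (recording quality label; quality is
#'   an input judgement, not computed from audio).
#'
#' Optional columns: `context` (`"observation"`/`"experiment"`),
#' `support_context` (four-level production context used by the support
#' model), `support` (`"yes"`/`"no"`, per bout), `opponent_id`, `wav`
#' (source file), and `onset`/`offset` in seconds from the start of the
#' event recording (half-open interval `[onset, offset)`); when present,
#' `offset > onset` is required and amplitude-based detection can be
#' skipped ("annotation-trusting" mode).
#'
#' @name annotation_schema
NULL

.required_cols <- c("event_id", "bout_id", "caller_id", "role", "severity",
                    "quality")

#' Read and validate a scream annotation CSV
#'
#' @param path CSV path (UTF-8, header as in [annotation_schema]).
#' @return A validated `data.frame` of annotations.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(tab)
}

#' Validate an annotation table against the schema invariants
#'
#' Checks required columns, categorical levels, interval sanity
#' (`offset > onset`), bout-in-event nesting, and the bout-definition rule
#' that social role and conflict severity are constant within a bout.
#' Violations are reported with row numbers or bout ids.
#'
#' @param tab A `data.frame` of annotations.
#' @return `tab`, invisibly classed as validated.
#' @export
validate_annotations <- function(tab) {
  stopifnot(is.data.frame(tab))
  missing_cols <- setdiff(.required_cols, names(tab))
  if (length(missing_cols))
    stop("annotation table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_lvl <- function(col, levels) {
    bad <- which(!tab[[col]] %in% levels)
    if (length(bad))
      stop(sprintf("invalid `%s` value(s) at row(s) %s (allowed: %s)",
                   col, paste(utils::head(bad, 5L), collapse = ", "),
                   paste(levels, collapse = "/")))
  }
  bad_lvl("role", c("aggressor", "victim"))
  bad_lvl("severity", c("mild", "severe"))
  bad_lvl("quality", c("good", "poor"))
  if ("support" %in% names(tab)) bad_lvl("support", c("yes", "no"))

  if (all(c("onset", "offset") %in% names(tab))) {
    both <- !is.na(tab$onset) & !is.na(tab$offset)
    bad <- which(both & tab$offset <= tab$onset)
    if (length(bad))
      stop("offset <= onset at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }

  # bout nested in exactly one event
  n_ev <- tapply(tab$event_id, tab$bout_id, function(x) length(unique(x)))
  if (any(n_ev > 1L))
    stop("bout(s) spanning multiple events: ",
         paste(names(n_ev)[n_ev > 1L], collapse = ", "))

  # role and severity constant within a bout (the bout definition: a bout
  # ends when either changes)
  for (col in c("role", "severity")) {
    n_lvl <- tapply(tab[[col]], tab$bout_id, function(x) length(unique(x)))
    if (any(n_lvl > 1L))
      stop(sprintf(
        "`%s` changes within bout(s) %s: a bout is a conflict stage with constant social role and severity",
        col, paste(names(n_lvl)[n_lvl > 1L], collapse = ", ")))
  }
  invisible(tab)
}

#' Write an annotation table to CSV
#' @param tab Annotation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Drop poor-quality screams
#'
#' Retains only rows labelled `quality == "good"`, mirroring the manual
#' screening step in which recordings with background noise, clipping or
#' reverberation are excluded before feature extraction. The exclusion
#' count is reported via `message()`.
#'
#' @param tab Annotation `data.frame` with a `quality` column.
#' @return The filtered table.
#' @export
filter_quality <- function(tab) {
  if (!"quality" %in% names(tab)) stop("no `quality` column present")
  keep <- tab$quality == "good"
  message(sprintf("filter_quality: excluded %d of %d rows (%.1f%%) as poor quality",
                  sum(!keep), nrow(tab), 100 * mean(!keep)))
  if (!any(keep)) warning("all rows marked poor quality; returning empty table")
  tab[keep, , drop = FALSE]
}

#' Read a Praat TextGrid interval tier as scream segments
#'
#' Parses long-format TextGrids. Non-empty labelled intervals of the
#' chosen tier become segments with onsets/offsets in seconds.
#'
#' @param path TextGrid path.
#' @param tier Tier name or index (default: first interval tier).
#' @return A `data.frame` with columns `onset`, `offset`, `label`.
#' @export
read_textgrid <- function(path, tier = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("ooTextFile", lines)))
    stop("not a Praat TextGrid (missing ooTextFile header): ", path)
  num <- function(l) as.numeric(sub(".*=\\s*", "", l))
  chr <- function(l) gsub("^\\s*.*=\\s*\"(.*)\"\\s*$", "\\1", l)

  item_starts <- grep("^\\s*item\\s*\\[", lines)
  if (!length(item_starts)) stop("TextGrid has no tiers: ", path)
  tiers <- list()
  for (i in seq_along(item_starts)) {
    from <- item_starts[i]
    to <- if (i < length(item_starts)) item_starts[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    cls <- chr(grep("class\\s*=", block, value = TRUE)[1L])
    nm <- chr(grep("name\\s*=", block, value = TRUE)[1L])
    if (!identical(cls, "IntervalTier")) next
    xmins <- num(grep("^\\s*xmin\\s*=", block, value = TRUE))
    xmaxs <- num(grep("^\\s*xmax\\s*=", block, value = TRUE))
    texts <- chr(grep("^\\s*text\\s*=", block, value = TRUE))
    # first xmin/xmax pair is the tier extent
    tiers[[length(tiers) + 1L]] <- list(
      name = nm,
      intervals = data.frame(onset = xmins[-1L], offset = xmaxs[-1L],
                             label = texts, stringsAsFactors = FALSE))
  }
  if (!length(tiers)) stop("TextGrid has no interval tiers: ", path)
  sel <- if (is.character(tier)) {
    idx <- which(vapply(tiers, `[[`, "", "name") == tier)
    if (!length(idx)) stop("no interval tier named \"", tier, "\"")
    idx[1L]
  } else as.integer(tier)
  iv <- tiers[[sel]]$intervals
  iv <- iv[nzchar(iv$label), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Write segments to a Praat TextGrid (long format, one interval tier)
#'
#' @param segments `data.frame` with `onset`, `offset`, `label`.
#' @param path Output path.
#' @param tier_name Name of the interval tier.
#' @param xmax Total duration; defaults to the last offset.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(segments, path, tier_name = "screams",
                           xmax = NULL) {
  stopifnot(all(c("onset", "offset", "label") %in% names(segments)))
  segments <- segments[order(segments$onset), , drop = FALSE]
  if (is.null(xmax)) xmax <- if (nrow(segments)) max(segments$offset) else 1
  # fill gaps with empty intervals so boundaries round-trip exactly
  bounds <- c(0, as.vector(rbind(segments$onset, segments$offset)), xmax)
  labs <- c(as.vector(rbind("", segments$label)), "")
  keep <- diff(bounds) > 0
  iv_on <- bounds[-length(bounds)][keep]
  iv_off <- bounds[-1L][keep]
  iv_lab <- labs[keep]
  out <- c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    "xmin = 0",
    sprintf("xmax = %.6f", xmax),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    "        class = \"IntervalTier\"",
    sprintf("        name = \"%s\"", tier_name),
    "        xmin = 0",
    sprintf("        xmax = %.6f", xmax),
    sprintf("        intervals: size = %d", length(iv_lab)))
  for (i in seq_along(iv_lab)) {
    out <- c(out,
             sprintf("        intervals [%d]:", i),
             sprintf("            xmin = %.6f", iv_on[i]),
             sprintf("            xmax = %.6f", iv_off[i]),
             sprintf("            text = \"%s\"", iv_lab[i]))
  }
  writeLines(out, path)
  invisible(path)
}
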