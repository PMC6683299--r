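# Canonical factor levels used throughout the package.
CONDITIONS <- c("history", "no_history")
ORDER_GROUPS <- c("history_first", "history_last")

#' Column dialect for fixation tables
#'
#' Eye-tracker exports differ in column naming, delimiter and decimal mark.
#' A dialect maps the canonical fields used by this package onto the columns
#' of a concrete export. The default matches a tab-separated table with
#' columns `participant`, `stimulus`, `condition`, `fix_index`, `x`, `y`,
#' `duration_ms`, `onset_ms` and (optionally) `order_group`.
#'
#' @param participant,stimulus,condition,fix_index,x,y,duration,onset,order_group
#'   column names in the file for each canonical field.
#' @param sep field delimiter.
#' @param dec decimal mark.
#' @return a named list of class `gaze_dialect`.
#' @export
fixation_dialect <- function(participant = "participant", stimulus = "stimulus",
                             condition = "condition", fix_index = "fix_index",
                             x = "x", y = "y", duration = "duration_ms",
                             onset = "onset_ms", order_group = "order_group",
                             sep = "\t", dec = ".") {
  structure(list(participant = participant, stimulus = stimulus,
                 condition = condition, fix_index = fix_index, x = x, y = y,
                 duration = duration, onset = onset, order_group = order_group,
                 sep = sep, dec = dec),
            class = "gaze_dialect")
}

#' Construct a stimulus layout
#'
#' A layout names the axis-aligned rectangles of the semantic regions of one
#' stimulus (for a 12-lead ECG, the leads and optionally a rhythm strip).
#' Rectangles are half-open `[x0, x1) x [y0, y1)` in screen pixels with the
#' origin at the top-left corner and y increasing downward.
#'
#' @param stimulus_id identifier of the stimulus.
#' @param width,height canvas size in pixels.
#' @param regions data.frame with columns `name`, `x0`, `y0`, `x1`, `y1`.
#'   May have zero rows (flagged with a warning).
#' @return an object of class `stimulus_layout`.
#' @export
stimulus_layout <- function(stimulus_id, width, height, regions) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  if (is.null(regions)) {
    regions <- data.frame(name = character(), x0 = numeric(), y0 = numeric(),
                          x1 = numeric(), y1 = numeric())
  }
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  req <- c("name", "x0", "y0", "x1", "y1")
  if (!all(req %in% names(regions))) {
    stop("layout regions need columns: ", paste(req, collapse = ", "))
  }
  regions <- regions[, req]
  if (anyDuplicated(regions$name)) stop("duplicate region names in layout")
  if (nrow(regions) > 0) {
    bad <- regions$x0 < 0 | regions$y0 < 0 | regions$x1 > width |
      regions$y1 > height | regions$x0 >= regions$x1 | regions$y0 >= regions$y1
    if (any(bad)) {
      stop("region(s) outside canvas or empty: ",
           paste(regions$name[bad], collapse = ", "))
    }
    if (nrow(regions) > 1 && .any_rect_overlap(regions)) {
      warning("layout '", stimulus_id, "' has overlapping regions")
    }
  } else {
    warning("layout '", stimulus_id, "' has no regions")
  }
  structure(list(stimulus_id = as.character(stimulus_id),
                 width = as.numeric(width), height = as.numeric(height),
                 regions = regions),
            class = "stimulus_layout")
}

.any_rect_overlap <- function(r) {
  n <- nrow(r)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    if (any(r$x0[i] < r$x1[j] & r$x1[i] > r$x0[j] &
            r$y0[i] < r$y1[j] & r$y1[i] > r$y0[j])) return(TRUE)
  }
  FALSE
}

#' Read a stimulus layout from a JSON file
#'
#' Expected shape: `{"stimulus_id": ..., "width": ..., "height": ...,
#' "regions": {"I": [x0, y0, x1, y1], ...}}`.
#'
#' @param path file path.
#' @return a [stimulus_layout()].
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  regs <- j$regions
  if (is.null(regs) || length(regs) == 0) {
    regions <- NULL
  } else {
    m <- do.call(rbind, lapply(regs, function(v) {
      v <- as.numeric(v)
      if (length(v) != 4 || anyNA(v) || any(v < 0)) {
        stop("each region must be four non-negative numbers [x0, y0, x1, y1]")
      }
      v
    }))
    regions <- data.frame(name = names(regs), x0 = m[, 1], y0 = m[, 2],
                          x1 = m[, 3], y1 = m[, 4])
  }
  stimulus_layout(j$stimulus_id, j$width, j$height, regions)
}

#' Read an answer key from a JSON file
#'
#' Shape: `{"<stimulus>": {"canonical": "...", "accepted": ["...", ...]}}`.
#' The canonical term is always included in the accepted set.
#'
#' @param path file path.
#' @return named list of class `answer_key`; each entry has `canonical` and
#'   `accepted`.
#' @export
read_answer_key <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  answer_key(j)
}

#' @rdname read_answer_key
#' @param entries named list of entries (`canonical`, `accepted`).
#' @export
answer_key <- function(entries) {
  out <- lapply(entries, function(e) {
    canonical <- as.character(e$canonical)
    accepted <- unique(c(canonical, as.character(e$accepted)))
    list(canonical = canonical, accepted = accepted)
  })
  structure(out, class = "answer_key")
}

#' Assemble and validate a study dataset
#'
#' The central container: a fixation table covering every trial (one trial =
#' one participant viewing one stimulus in one condition), optional free-text
#' interpretation responses, and the participant roster with presentation
#' order groups.
#'
#' @param fixations data.frame with columns `participant`, `stimulus`,
#'   `condition` (`"history"`/`"no_history"`), `order_group`
#'   (`"history_first"`/`"history_last"`), `fix_index` (1-based, strictly
#'   increasing per trial), `x`, `y` (pixels), `duration_ms` (> 0),
#'   `onset_ms`.
#' @param responses optional data.frame with `participant`, `stimulus`,
#'   `condition`, `response`.
#' @param participants optional data.frame with `participant`, `order_group`;
#'   derived from `fixations` when absent.
#' @return object of class `study_dataset` with elements `fixations`,
#'   `responses`, `participants`.
#' @export
study_dataset <- function(fixations, responses = NULL, participants = NULL) {
  fx <- as.data.frame(fixations, stringsAsFactors = FALSE)
  req <- c("participant", "stimulus", "condition", "order_group", "fix_index",
           "x", "y", "duration_ms", "onset_ms")
  miss <- setdiff(req, names(fx))
  if (length(miss)) stop("fixation table missing column(s): ",
                         paste(miss, collapse = ", "))
  fx <- fx[, req]
  fx$participant <- as.character(fx$participant)
  fx$stimulus <- as.character(fx$stimulus)
  if (!all(fx$condition %in% CONDITIONS)) {
    stop("condition must be one of: ", paste(CONDITIONS, collapse = ", "))
  }
  if (!all(fx$order_group %in% ORDER_GROUPS)) {
    stop("order_group must be one of: ", paste(ORDER_GROUPS, collapse = ", "))
  }
  if (any(fx$duration_ms <= 0)) stop("fixation durations must be positive")
  key <- paste(fx$participant, fx$stimulus, fx$condition, sep = "\r")
  if (anyDuplicated(paste(key, fx$fix_index, sep = "\r"))) {
    stop("integrity error: duplicate (participant, stimulus, condition, fix_index)")
  }
  # per-trial ordering: index strictly increasing, and agreeing with onset
  ord <- order(key, fx$fix_index)
  fx <- fx[ord, , drop = FALSE]
  key <- key[ord]
  same_trial <- duplicated(key)
  if (any(same_trial & c(FALSE, diff(fx$fix_index) <= 0))) {
    stop("integrity error: fix_index not strictly increasing within a trial")
  }
  if (any(same_trial & c(FALSE, diff(fx$onset_ms) < 0))) {
    stop("integrity error: onset order disagrees with fix_index order")
  }
  pg <- unique(fx[, c("participant", "order_group")])
  if (anyDuplicated(pg$participant)) {
    stop("a participant appears in more than one order_group")
  }
  if (is.null(participants)) {
    participants <- pg[order(pg$participant), ]
  } else {
    participants <- as.data.frame(participants, stringsAsFactors = FALSE)
    stopifnot(all(c("participant", "order_group") %in% names(participants)))
    if (anyDuplicated(participants$participant)) {
      stop("a participant appears in more than one order_group")
    }
  }
  rownames(fx) <- NULL
  rownames(participants) <- NULL
  if (!is.null(responses)) {
    responses <- as.data.frame(responses, stringsAsFactors = FALSE)
    stopifnot(all(c("participant", "stimulus", "condition", "response") %in%
                    names(responses)))
  }
  structure(list(fixations = fx, responses = responses,
                 participants = participants),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset:", nrow(x$fixations), "fixations,",
      nrow(x$participants), "participants,",
      length(unique(x$fixations$stimulus)), "stimuli\n")
  invisible(x)
}

#' Read a fixation table into a study dataset
#'
#' Parses a delimited fixation-level export, validates it, and optionally
#' applies stimulus-bound checks. Rows whose coordinates fall outside the
#' stimulus canvas are dropped (default) or clamped to the canvas; the count
#' of affected rows is recorded in `attr(, "n_dropped")` /
#' `attr(, "n_clamped")` and reported via a message.
#'
#' @param path file path.
#' @param layouts optional named list of [stimulus_layout()] (names =
#'   stimulus ids) enabling the bounds check.
#' @param dialect a [fixation_dialect()].
#' @param oob out-of-bounds policy: `"drop"`, `"clamp"` or `"keep"`.
#' @param responses optional responses data.frame passed through to the
#'   dataset.
#' @return a validated [study_dataset()].
#' @export
read_fixation_table <- function(path, layouts = NULL,
                                dialect = fixation_dialect(),
                                oob = c("drop", "clamp", "keep"),
                                responses = NULL) {
  oob <- match.arg(oob)
  if (!file.exists(path)) stop("fixation file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           dec = dialect$dec, stringsAsFactors = FALSE,
                           check.names = FALSE)
  cols <- c(participant = dialect$participant, stimulus = dialect$stimulus,
            condition = dialect$condition, fix_index = dialect$fix_index,
            x = dialect$x, y = dialect$y, duration_ms = dialect$duration,
            onset_ms = dialect$onset)
  miss <- cols[!cols %in% names(raw)]
  if (length(miss)) {
    stop("format error: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  fx <- stats::setNames(raw[, cols, drop = FALSE], names(cols))
  if (dialect$order_group %in% names(raw)) {
    fx$order_group <- raw[[dialect$order_group]]
  } else {
    stop("format error: missing required column(s): ", dialect$order_group)
  }
  n_dropped <- 0L; n_clamped <- 0L
  if (!is.null(layouts) && oob != "keep") {
    w <- vapply(layouts, function(l) l$width, numeric(1))[fx$stimulus]
    h <- vapply(layouts, function(l) l$height, numeric(1))[fx$stimulus]
    out <- !is.na(w) & (fx$x < 0 | fx$y < 0 | fx$x >= w | fx$y >= h)
    if (oob == "drop") {
      n_dropped <- sum(out)
      fx <- fx[!out, , drop = FALSE]
    } else {
      n_clamped <- sum(out)
      fx$x <- pmin(pmax(fx$x, 0), w - 1e-9)
      fx$y <- pmin(pmax(fx$y, 0), h - 1e-9)
    }
    if (n_dropped + n_clamped > 0) {
      message(n_dropped + n_clamped, " out-of-bounds fixation(s) ", oob, "ped")
    }
  }
  ds <- study_dataset(fx, responses = responses)
  attr(ds, "n_dropped") <- n_dropped
  attr(ds, "n_clamped") <- n_clamped
  ds
}

#' Write a study dataset's fixation table
#'
#' Inverse of [read_fixation_table()]: emits a delimited table in the given
#' dialect, so that reading it back reproduces the dataset.
#'
#' @param dataset a [study_dataset()].
#' @param path output file path.
#' @param dialect a [fixation_dialect()].
#' @export
write_fixation_table <- function(dataset, path,
                                 dialect = fixation_dialect()) {
  fx <- dataset$fixations
  out <- stats::setNames(
    fx[, c("participant", "stimulus", "condition", "fix_index", "x", "y",
           "duration_ms", "onset_ms", "order_group")],
    c(dialect$participant, dialect$stimulus, dialect$condition,
      dialect$fix_index, dialect$x, dialect$y, dialect$duration,
      dialect$onset, dialect$order_group))
  utils::write.table(out, path, sep = dialect$sep, dec = dialect$dec,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table as CSV
#'
#' Deterministic column order (as given), header always present, no row
#' names. An empty result set yields a header-only file.
#'
#' @param rows data.frame of results.
#' @param path output file path.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(rows, path, sep = ",", row.names = FALSE, qmethod = "double")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
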