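#' Construct a respirometry trace
#'
#' A `resp_trace` holds one animal's full trial: a time series of oxygen
#' concentration with phase labels and loop indices. Invariants checked:
#' strictly increasing time, non-negative oxygen, non-decreasing loop
#' index, phase labels in FLUSH/WAIT/MEASURE.
#'
#' @param fish_id,chamber_id Identifiers.
#' @param time_s Seconds from trial start (strictly increasing).
#' @param o2 Oxygen concentration, mg O2 per litre.
#' @param phase Character, one of FLUSH/WAIT/MEASURE per point.
#' @param loop_index Integer loop counter, non-decreasing, starts at 0.
#' @param temp_c Water temperature per point (degrees C); recycled.
#' @return An object of class `resp_trace` with a `data` data frame.
#' @export
resp_trace <- function(fish_id, chamber_id = fish_id, time_s, o2, phase,
                       loop_index, temp_c = 18) {
  n <- length(time_s)
  stopifnot(length(o2) == n, length(phase) == n, length(loop_index) == n)
  if (n == 0L) stop("empty trace for fish ", fish_id)
  if (any(diff(time_s) <= 0)) {
    stop("time must be strictly increasing in trace for fish ", fish_id)
  }
  if (any(!is.finite(o2)) || any(o2 < 0)) {
    stop("o2 must be finite and non-negative in trace for fish ", fish_id)
  }
  bad <- setdiff(unique(phase), c("FLUSH", "WAIT", "MEASURE"))
  if (length(bad)) stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  if (any(diff(loop_index) < 0)) stop("loop_index must be non-decreasing")
  structure(
    list(
      fish_id = as.character(fish_id),
      chamber_id = as.character(chamber_id),
      data = data.frame(
        time_s = as.numeric(time_s), o2 = as.numeric(o2),
        phase = as.character(phase),
        loop_index = as.integer(loop_index),
        temp_c = rep_len(as.numeric(temp_c), n)
      )
    ),
    class = "resp_trace"
  )
}

#' @export
print.resp_trace <- function(x, ...) {
  d <- x$data
  cat("<resp_trace> fish ", x$fish_id, ", ", nrow(d), " points, ",
      length(unique(d$loop_index[d$phase == "MEASURE"])),
      " measurement loops, ",
      sprintf("%.1f", max(d$time_s) / 3600), " h\n", sep = "")
  invisible(x)
}

#' Construct a background (empty-chamber) trace
#'
#' Background respiration is microbial oxygen consumption in the empty
#' system, measured immediately before (`PRE`) and after (`POST`) each
#' trial and later subtracted from the animal's oxygen uptake.
#'
#' @param trial_id Identifier of the trial this background belongs to.
#' @param when `"PRE"` or `"POST"`.
#' @param time_s,o2 Sealed-chamber time series (seconds on the trial
#'   clock; `PRE` times are typically negative or near zero, `POST`
#'   times near the trial end).
#' @param temp_c Temperature per point; recycled.
#' @return An object of class `background_trace`.
#' @export
background_trace <- function(trial_id, when, time_s, o2, temp_c = 18) {
  when <- match.arg(when, c("PRE", "POST"))
  n <- length(time_s)
  stopifnot(length(o2) == n, n >= 3)
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  structure(
    list(
      trial_id = as.character(trial_id), when = when,
      data = data.frame(time_s = as.numeric(time_s), o2 = as.numeric(o2),
                        temp_c = rep_len(as.numeric(temp_c), n))
    ),
    class = "background_trace"
  )
}

#' Read a respirometry trace from CSV
#'
#' The native dialect is a headered CSV with columns `fish_id`, `time_s`,
#' `phase`, `o2_mg_l`, `temp_c`. Vendor exports (e.g. AutoResp-style
#' files) are read through `column_map`, which maps the native names to
#' the file's column names. When the file has no phase column, phase
#' labels are inferred from time modulo the loop period using
#' `protocol`, and the loop index from integer division by the period.
#'
#' @param path CSV file path.
#' @param column_map Named list mapping native names (`fish_id`,
#'   `time_s`, `phase`, `o2`, `temp_c`) to the file's column names.
#'   `phase`, `temp_c` and `fish_id` are optional.
#' @param protocol A [protocol_config()] used for phase inference and
#'   loop indexing.
#' @param fish_id Fallback fish id when the file carries none; defaults
#'   to the file name without extension.
#' @return A validated [resp_trace()].
#' @export
read_trace_csv <- function(path,
                           column_map = list(fish_id = "fish_id",
                                             time_s = "time_s",
                                             phase = "phase",
                                             o2 = "o2_mg_l",
                                             temp_c = "temp_c"),
                           protocol = protocol_config(),
                           fish_id = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "o2")
  for (k in need) {
    col <- column_map[[k]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("trace file ", basename(path), " is missing required column '",
           if (is.null(col)) k else col, "'")
    }
  }
  time_s <- raw[[column_map$time_s]]
  if (any(diff(time_s) <= 0)) {
    stop("non-monotone time in trace file ", basename(path))
  }
  o2 <- raw[[column_map$o2]]
  phase_col <- column_map$phase
  if (!is.null(phase_col) && phase_col %in% names(raw)) {
    phase <- toupper(raw[[phase_col]])
  } else {
    phase <- infer_phases(time_s, protocol)
  }
  loop_index <- as.integer(time_s %/% protocol$loop_s)
  id_col <- column_map$fish_id
  id <- if (!is.null(id_col) && id_col %in% names(raw)) {
    as.character(raw[[id_col]][1])
  } else if (!is.null(fish_id)) {
    fish_id
  } else {
    sub("\\.[^.]*$", "", basename(path))
  }
  temp_col <- column_map$temp_c
  temp_c <- if (!is.null(temp_col) && temp_col %in% names(raw)) {
    raw[[temp_col]]
  } else {
    protocol$temp_c
  }
  resp_trace(id, time_s = time_s, o2 = o2, phase = phase,
             loop_index = loop_index, temp_c = temp_c)
}

#' Write a respirometry trace to CSV (native dialect)
#'
#' @param trace A [resp_trace()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "resp_trace"))
  d <- trace$data
  out <- data.frame(fish_id = trace$fish_id, time_s = d$time_s,
                    phase = d$phase, o2_mg_l = d$o2, temp_c = d$temp_c)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
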