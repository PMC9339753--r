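#' Intermittent-flow protocol configuration
#'
#' Describes one measurement loop of an intermittent-flow respirometry
#' system: a flush phase (chamber re-oxygenated), a short wait phase, and
#' a sealed measurement phase during which oxygen declines. Loops repeat
#' with period `flush_s + wait_s + measure_s`. Phase intervals are
#' half-open `[start, end)`: a point at the exact end of a phase belongs
#' to the next phase.
#'
#' The default loop is 180 s flush, 30 s wait, 210 s measurement at
#' 18 degrees C, repeated for at least 121 loops (an overnight trial of
#' just over 14 h). `start_phase` fixes which phase begins at `t = 0`;
#' the default `"WAIT"` reflects a post-chase trial in which the animal
#' is placed in the chamber during the wait phase so that the first
#' measurement phase is usable (the trial starts at maximum metabolic
#' rate).
#'
#' @param flush_s,wait_s,measure_s Phase durations in seconds.
#' @param temp_c Nominal water temperature (degrees C).
#' @param min_loops Minimum number of measurement loops expected in a
#'   full trial.
#' @param start_phase Phase occupying `[0, duration)`; one of
#'   `"FLUSH"`, `"WAIT"`, `"MEASURE"`.
#' @return An object of class `protocol_config`.
#' @examples
#' p <- protocol_config()
#' p$loop_s  # 420
#' @export
protocol_config <- function(flush_s = 180, wait_s = 30, measure_s = 210,
                            temp_c = 18, min_loops = 121,
                            start_phase = "WAIT") {
  stopifnot(flush_s > 0, wait_s >= 0, measure_s > 0, min_loops >= 1)
  start_phase <- match.arg(start_phase, c("FLUSH", "WAIT", "MEASURE"))
  order <- switch(start_phase,
    FLUSH   = c("FLUSH", "WAIT", "MEASURE"),
    WAIT    = c("WAIT", "MEASURE", "FLUSH"),
    MEASURE = c("MEASURE", "FLUSH", "WAIT")
  )
  dur <- c(FLUSH = flush_s, WAIT = wait_s, MEASURE = measure_s)[order]
  structure(
    list(
      flush_s = flush_s, wait_s = wait_s, measure_s = measure_s,
      loop_s = flush_s + wait_s + measure_s,
      temp_c = temp_c, min_loops = min_loops,
      phase_order = order,
      phase_start = stats::setNames(cumsum(c(0, dur[-3])), order),
      phase_end = stats::setNames(cumsum(dur), order)
    ),
    class = "protocol_config"
  )
}

#' Read a protocol configuration from a YAML file
#'
#' Recognised keys: `flush_s`, `wait_s`, `measure_s`, `temp_c`,
#' `min_loops`, `start_phase`. Missing keys fall back to the defaults of
#' [protocol_config()].
#'
#' @param path Path to a YAML file.
#' @return A `protocol_config`.
#' @export
read_protocol_yaml <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("flush_s", "wait_s", "measure_s", "temp_c", "min_loops",
             "start_phase")
  cfg <- cfg[intersect(names(cfg), known)]
  do.call(protocol_config, cfg)
}

#' Infer phase labels from time within the loop cycle
#'
#' Maps each timestamp to FLUSH/WAIT/MEASURE using time modulo the loop
#' period and the protocol's phase boundaries (half-open intervals).
#'
#' @param time_s Numeric vector, seconds from trial start.
#' @param protocol A `protocol_config`.
#' @return Character vector of phase labels.
#' @export
infer_phases <- function(time_s, protocol = protocol_config()) {
  tmod <- time_s %% protocol$loop_s
  out <- character(length(time_s))
  for (ph in protocol$phase_order) {
    out[tmod >= protocol$phase_start[[ph]] & tmod < protocol$phase_end[[ph]]] <- ph
  }
  out
}
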