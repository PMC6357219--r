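#' Construct an annotated beat series
#'
#' @param times Strictly increasing beat times in seconds.
#' @param labels Beat labels, \code{"NORMAL"}/\code{"PVC"} (the shorthand
#'   \code{"N"}/\code{"V"} is accepted).
#' @param vfIntervals \code{data.frame} with columns \code{start_s},
#'   \code{end_s} of annotated fibrillation episodes (non-overlapping, inside
#'   the window), or \code{NULL}.
#' @param window Analysis window \code{c(start, end)} in seconds; the default
#'   0--600 s is the 10-min ischemic episode.
#'
#' @return A [BeatSeries].
#' @examples
#' b <- beatSeries(c(0.5, 1.0, 1.5), c("N", "V", "N"))
#' @export
beatSeries <- function(times, labels, vfIntervals = NULL,
                       window = c(0, 600)) {
  labels <- toupper(as.character(labels))
  bad <- !labels %in% c("NORMAL", "PVC", "N", "V")
  if (any(bad))
    stop("unknown beat label(s): ", paste(unique(labels[bad]), collapse = ", "))
  labels[labels == "N"] <- "NORMAL"
  labels[labels == "V"] <- "PVC"
  if (is.null(vfIntervals))
    vfIntervals <- data.frame(start_s = numeric(0), end_s = numeric(0))
  methods::new("BeatSeries", timesS = as.numeric(times), labels = labels,
               vfIntervals = vfIntervals, window = as.numeric(window))
}

#' Read an annotated beat series from CSV
#'
#' The beats file must have columns \code{time_s,label}; an optional sidecar
#' gives fibrillation intervals as \code{start_s,end_s}. Non-increasing
#' times, unknown labels and malformed or overlapping intervals are rejected
#' with the offending row named.
#'
#' @param path Beats CSV path.
#' @param vfPath Optional VF-interval CSV path.
#' @param window Analysis window in seconds.
#'
#' @return A [BeatSeries].
#' @export
readBeats <- function(path, vfPath = NULL, window = c(0, 600)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "label") %in% names(df)))
    stop("beats CSV must have columns time_s,label: ", path)
  if (nrow(df) > 1) {
    bad <- which(diff(df$time_s) <= 0)
    if (length(bad))
      stop("beat times not strictly increasing at row ", bad[1] + 2,
           " of ", path, " (counting the header)")
  }
  vf <- NULL
  if (!is.null(vfPath)) {
    vf <- utils::read.csv(vfPath, stringsAsFactors = FALSE)
    if (!all(c("start_s", "end_s") %in% names(vf)))
      stop("VF CSV must have columns start_s,end_s: ", vfPath)
    bad <- which(!is.finite(vf$start_s) | !is.finite(vf$end_s) |
                 vf$start_s >= vf$end_s)
    if (length(bad))
      stop("malformed VF interval at row ", bad[1], " of ", vfPath)
  }
  beatSeries(df$time_s, df$label, vf, window)
}

#' Classify PVC runs into singles, salvos and tachycardia
#'
#' Scans the beats inside the analysis window for maximal runs of
#' consecutive PVC labels and categorizes each: length 1 = \code{SINGLE},
#' length 2--3 = \code{SALVO}, length >= 4 = \code{TACHYCARDIA} (a run of 4
#' or more consecutive PVCs).
#'
#' @param beats A [BeatSeries].
#'
#' @return \code{data.frame} with one row per run: \code{start_index} (index
#'   into the window-restricted series), \code{length} and \code{category}.
#'   An empty series yields zero rows.
#' @examples
#' classifyPvcRuns(beatSeries(1:6 / 2, c("N", "V", "V", "V", "V", "N")))
#' @export
classifyPvcRuns <- function(beats) {
  inWin <- beats@timesS >= beats@window[1] & beats@timesS <= beats@window[2]
  lab <- beats@labels[inWin]
  empty <- data.frame(start_index = integer(0), length = integer(0),
                      category = character(0), stringsAsFactors = FALSE)
  if (length(lab) == 0L) return(empty)
  r <- rle(lab == "PVC")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pv <- which(r$values)
  if (length(pv) == 0L) return(empty)
  len <- r$lengths[pv]
  data.frame(start_index = starts[pv], length = len,
             category = ifelse(len >= 4L, "TACHYCARDIA",
                        ifelse(len >= 2L, "SALVO", "SINGLE")),
             stringsAsFactors = FALSE)
}

#' Summarize arrhythmias over the analysis window
#'
#' Counts PVC runs per category and measures tachyarrhythmia burden. A
#' tachycardia episode's duration is the time from its first to its last
#' beat plus one median inter-beat interval of the window (the closure
#' convention, so a hypothetical one-beat episode still has nonzero length);
#' episodes reaching past the window end are truncated there (with a
#' message). Fibrillation episode durations are taken from the annotated
#' intervals. Incidence is \code{TRUE} when any tachycardia run or VF
#' interval occurred.
#'
#' @param beats A [BeatSeries].
#'
#' @return An [EcgSummary].
#' @examples
#' b <- beatSeries(c(1:5 / 5, 10 + 0:4 / 5, 12), c(rep("N", 5), rep("V", 5), "N"))
#' summarizeBeats(b)
#' @export
summarizeBeats <- function(beats) {
  inWin <- beats@timesS >= beats@window[1] & beats@timesS <= beats@window[2]
  times <- beats@timesS[inWin]
  runs <- classifyPvcRuns(beats)
  nS <- sum(runs$category == "SINGLE")
  nSa <- sum(runs$category == "SALVO")
  tach <- runs[runs$category == "TACHYCARDIA", , drop = FALSE]
  closure <- if (length(times) >= 2) stats::median(diff(times)) else 0
  tachDur <- 0
  if (nrow(tach) > 0) {
    for (i in seq_len(nrow(tach))) {
      t0 <- times[tach$start_index[i]]
      t1 <- times[tach$start_index[i] + tach$length[i] - 1L]
      dur <- (t1 - t0) + closure
      if (t0 + dur > beats@window[2]) {
        dur <- beats@window[2] - t0
        message("summarizeBeats: tachycardia episode truncated at window end")
      }
      tachDur <- tachDur + dur
    }
  }
  vf <- beats@vfIntervals
  vfDur <- if (nrow(vf) > 0) sum(vf$end_s - vf$start_s) else 0
  methods::new("EcgSummary",
    nSingles = as.integer(nS), nSalvos = as.integer(nSa),
    nTachEpisodes = nrow(tach), totalPvcs = as.integer(sum(runs$length)),
    tachDurationS = tachDur, vfDurationS = vfDur,
    tachyarrhythmiaDurationS = tachDur + vfDur,
    incidence = nrow(tach) > 0 || nrow(vf) > 0, runs = runs)
}
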