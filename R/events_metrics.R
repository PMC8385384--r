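#' Fraction of active pixels per frame
#'
#' A pixel is active at a frame when its value exceeds its own temporal mean
#' by more than one temporal standard deviation; the trace is the fraction of
#' ROI pixels active at each frame, bounded in `[0, 1]`.
#'
#' @param dff a dF/F [frame_stack()].
#' @param roi optional logical ROI mask (default: all pixels).
#' @return A data frame with columns `frame`, `time_s`, `value` and an
#'   attribute `kind = "active_fraction"`.
#' @export
active_fraction_trace <- function(dff, roi = NULL) {
  stopifnot(inherits(dff, "frame_stack"))
  if (!dff$is_dff) stop("active fraction is defined on dF/F data")
  d <- dim(dff$data)
  if (is.null(roi)) roi <- matrix(TRUE, d[1], d[2])
  if (!any(roi)) stop("empty ROI")
  x <- matrix(dff$data, d[1] * d[2], d[3])[which(roi), , drop = FALSE]
  keep <- rowSums(!is.finite(x)) == 0
  x <- x[keep, , drop = FALSE]
  if (nrow(x) == 0) stop("no finite ROI pixels")
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (d[3] - 1L))
  active <- x > (mu + sdv)
  make_trace(colMeans(active), dff$dt, "active_fraction")
}

make_trace <- function(values, dt, kind) {
  out <- data.frame(
    frame = seq_along(values),
    time_s = (seq_along(values) - 1) * dt,
    value = as.numeric(values)
  )
  attr(out, "kind") <- kind
  attr(out, "dt") <- dt
  out
}

#' Segment pan-cortical wave events from an active-fraction trace
#'
#' A wave event is detected whenever the trace crosses `high` (default 50%
#' of pixels active) upward; the event spans from the nearest preceding
#' upward crossing of `low` (default 10%) to the nearest following downward
#' crossing of `low`. Overlapping events are merged into a single
#' pan-cortical wave, and events shorter than `min_len` frames (the FTLE
#' integration length plus the flow-scaling delay, in practice) are
#' discarded. Intervals are half-open `[start, end)` in 1-based frame
#' indices: the event contains frames `start .. end - 1`, all of which have
#' `trace >= low`.
#'
#' @param trace a trace data frame (e.g. [active_fraction_trace()]) or a
#'   numeric vector.
#' @param high upper threshold defining a wave (default 0.5).
#' @param low bounding threshold delimiting the event (default 0.1).
#' @param min_len minimum event length in frames (default 1).
#' @return Data frame with columns `start`, `end`, `kind`.
#' @export
segment_pan_cortical_waves <- function(trace, high = 0.5, low = 0.1, min_len = 1L) {
  v <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
  if (!(low > 0 && low < high && high < 1)) stop("need 0 < low < high < 1")
  n <- length(v)
  above_low <- v >= low
  events <- list()
  high_idx <- which(v >= high & c(-Inf, v[-n]) < high)  # upward crossings of high
  for (h in high_idx) {
    s <- h
    while (s > 1 && above_low[s - 1]) s <- s - 1
    e <- h
    while (e < n && above_low[e + 1]) e <- e + 1
    if (e == n && above_low[n]) {
      warning("trace never fell below the low threshold; event closed at the recording end")
    }
    events[[length(events) + 1L]] <- c(s, e + 1L)  # half-open [s, e + 1)
  }
  if (length(events) == 0)
    return(data.frame(start = integer(), end = integer(), kind = character()))
  ev <- unique(do.call(rbind, events))
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  # merge overlapping/adjacent-by-construction intervals
  merged <- ev[1, , drop = FALSE]
  for (i in seq_len(nrow(ev))[-1]) {
    last <- nrow(merged)
    if (ev[i, 1] <= merged[last, 2] - 1L) {
      merged[last, 2] <- max(merged[last, 2], ev[i, 2])
    } else {
      merged <- rbind(merged, ev[i, ])
    }
  }
  keep <- (merged[, 2] - merged[, 1]) >= min_len
  merged <- merged[keep, , drop = FALSE]
  data.frame(start = as.integer(merged[, 1]), end = as.integer(merged[, 2]),
             kind = rep("pan_cortical_wave", nrow(merged)))
}

#' Movement score from a behaviour video
#'
#' Per-frame total absolute pixel difference to the previous frame (or next
#' frame with `difference = "forward"`), normalized by the maximum over the
#' recording so the score lies in `[0, 1]`; the first (resp. last) frame
#' scores 0, and a static video scores 0 everywhere.
#'
#' @param video a [frame_stack()] of the behaviour camera.
#' @param difference `"backward"` (default, current minus previous) or
#'   `"forward"` (next minus current).
#' @return A trace data frame (see [active_fraction_trace()]).
#' @export
movement_score_trace <- function(video, difference = c("backward", "forward")) {
  stopifnot(inherits(video, "frame_stack"))
  difference <- match.arg(difference)
  d <- dim(video$data)
  if (d[3] < 2) stop("need at least 2 frames")
  x <- matrix(video$data, d[1] * d[2], d[3])
  dif <- colSums(abs(x[, -1, drop = FALSE] - x[, -d[3], drop = FALSE]))
  score <- if (difference == "backward") c(0, dif) else c(dif, 0)
  mx <- max(score)
  if (mx > 0) score <- score / mx
  make_trace(score, video$dt, "movement_score")
}

#' FTLE intensity trace
#'
#' Per base time, the sum of the (non-negative) FTLE values over the ROI,
#' normalized by the maximum over base times. Indicates how much Lagrangian
#' stretching ("flow") is present around each time point.
#'
#' @param series an `ftle_series`.
#' @return A trace data frame with one row per base time (`frame` holds the
#'   base time).
#' @export
ftle_intensity_trace <- function(series) {
  stopifnot(inherits(series, "ftle_series"))
  if (length(series$fields) == 0) stop("empty FTLE series")
  sums <- vapply(series$fields, function(f) sum(f$sigma, na.rm = TRUE), numeric(1))
  mx <- max(sums)
  if (mx > 0) sums <- sums / mx
  out <- make_trace(sums, series$dt,
                    paste0("ftle_intensity_", substr(series$direction, 1, 3)))
  out$frame <- series$t0s
  out$time_s <- (series$t0s - 1) * series$dt
  out
}

#' Ridge count score of a FLOW portrait
#'
#' Number of disconnected (8-connected) ridges divided by the total ridge
#' area in pixels. High scores mean many small fragmented ridges; low scores
#' mean few consolidated ridges. An empty mask scores 0 by convention; the
#' score never exceeds 1.
#'
#' @param portrait a `flow_portrait` (or a logical mask).
#' @param direction `"forward"`, `"backward"` or `"combined"` (union of both).
#' @return A list with `n_ridges`, `ridge_area`, `score`, `direction`.
#' @export
ridge_count_score <- function(portrait, direction = c("forward", "backward", "combined")) {
  direction <- match.arg(direction)
  mask <- if (is.matrix(portrait) && is.logical(portrait)) portrait
  else switch(direction,
    forward = portrait$forward,
    backward = portrait$backward,
    combined = portrait$forward | portrait$backward
  )
  area <- sum(mask)
  n <- if (area == 0) 0L else label_components(mask)$n
  list(n_ridges = n, ridge_area = area,
       score = if (area == 0) 0 else n / area,
       direction = direction)
}

#' Paired comparison of ridge count scores
#'
#' Two-sided paired t-test on the difference of means between two
#' equal-length groups of scores (e.g. per-animal means over early versus
#' late developmental days). Degenerate inputs are handled explicitly:
#' identical groups give `t = 0, p = 1`; a constant non-zero difference with
#' zero variance is reported with `p = 0` and `degenerate = TRUE`.
#'
#' @param group_a,group_b numeric vectors of paired scores (same length,
#'   >= 2 pairs).
#' @return A list with `t`, `p_value`, `mean_a`, `mean_b`, `n`, `degenerate`.
#' @export
compare_ridge_scores <- function(group_a, group_b) {
  if (length(group_a) != length(group_b))
    stop("paired comparison requires equal-length groups")
  n <- length(group_a)
  if (n < 2) stop("need at least 2 pairs")
  d <- group_a - group_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p_value = 1, mean_a = mean(group_a),
                  mean_b = mean(group_b), n = n, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p_value = 0, mean_a = mean(group_a),
                mean_b = mean(group_b), n = n, degenerate = TRUE))
  }
  ht <- stats::t.test(group_a, group_b, paired = TRUE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       mean_a = mean(group_a), mean_b = mean(group_b), n = n,
       degenerate = FALSE)
}

#' Export a trace to CSV
#'
#' @param trace a trace data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Export event intervals as a BED-like TSV
#'
#' @param events data frame from [segment_pan_cortical_waves()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
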