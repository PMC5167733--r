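#' Peri-stimulus analysis window
#'
#' @param start Window start, ms post stimulus onset (>= 0).
#' @param length Window length, ms; `start + length` must not exceed 300 ms.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(start, length) {
  if (start < 0) stop("window start must be >= 0 ms")
  if (length <= 0) stop("window length must be > 0")
  if (start + length > 300) stop("window must end by 300 ms post onset")
  structure(list(start = as.numeric(start), length = as.numeric(length)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window> [%g, %g] ms\n", x$start, x$start + x$length))
  invisible(x)
}

#' Incremental (growing) windows anchored at 1 ms
#'
#' `n` windows all starting at `start` ms with lengths evenly spaced from
#' `min_len` to `max_len`, snapped to the 2-ms sample grid of 500-Hz data.
#' The defaults give the 18 segments from 40 ms to 260 ms beginning at 1 ms.
#'
#' @param n Number of windows (>= 2).
#' @param min_len,max_len Shortest/longest window length, ms.
#' @param start Common window start, ms.
#' @param grid_ms Sample grid to snap lengths to, ms.
#' @return List of [window_spec()]s, sorted by length.
#' @export
incremental_windows <- function(n = 18, min_len = 40, max_len = 260,
                                start = 1, grid_ms = 2) {
  if (n < 2) stop("n must be >= 2")
  if (min_len >= max_len) stop("min_len must be < max_len")
  lens <- seq(min_len, max_len, length.out = n)
  lens <- round(lens / grid_ms) * grid_ms
  lapply(lens, function(L) window_spec(start, L))
}

#' Fixed-length sliding windows
#'
#' Windows of constant `length` stepped across `span`.
#'
#' @param length Window length, ms (default 60).
#' @param step Start increment, ms (> 0).
#' @param span Two-vector, the interval covered, ms post onset.
#' @return List of [window_spec()]s, sorted by start.
#' @export
fixed_windows <- function(length = 60, step = 30, span = c(0, 300)) {
  if (step <= 0) stop("step must be > 0")
  if (length > diff(span)) stop("window length exceeds the span")
  starts <- seq(span[1], span[2] - length, by = step)
  lapply(starts, function(s) window_spec(s, length))
}

#' Analysis plan: competing models plus window scheme
#'
#' Two complementary analyses are supported.  `"full_dual_input"` compares
#' the four dual-input architectures A-D over the whole peri-stimulus time;
#' `"initiation"` compares single-input serial vs parallel models over short
#' windows, probing only the start of the stimulus response.
#'
#' @param analysis `"full_dual_input"` or `"initiation"`.
#' @param windows Optional list of [window_spec()]s; defaults to the 18
#'   incremental windows (full analysis) or 10 incremental windows
#'   (initiation).
#' @param mode `"incremental"` or `"fixed"`, recorded for bookkeeping.
#' @return Object of class `analysis_plan` with fields `models` (labels),
#'   `windows`, `mode`, `analysis`.
#' @export
build_plan <- function(analysis = c("full_dual_input", "initiation"),
                       windows = NULL, mode = "incremental") {
  analysis <- match.arg(analysis)
  models <- switch(analysis,
    full_dual_input = c("A", "B", "C", "D"),
    initiation = c("serial", "parallel"))
  if (is.null(windows)) {
    windows <- switch(analysis,
      full_dual_input = incremental_windows(18),
      initiation = incremental_windows(10))
  }
  if (length(windows) == 0) stop("windows must be non-empty")
  structure(list(analysis = analysis, models = models, windows = windows,
                 mode = mode),
            class = "analysis_plan")
}

#' @export
print.analysis_plan <- function(x, ...) {
  cat(sprintf("<analysis_plan> %s: %d models {%s}, %d %s windows\n",
              x$analysis, length(x$models), paste(x$models, collapse = ","),
              length(x$windows), x$mode))
  invisible(x)
}
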