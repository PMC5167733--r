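#' Gaussian thalamic input component
#'
#' One Gaussian bump of thalamic drive.  The evoked-response model splits the
#' thalamic input into a *phasic* component encoding the onset of a new
#' stimulus (mean 30 ms, SD 16 ms) and a *sustained* component modeling the
#' drive during ongoing stimulation (mean 170 ms, SD 70 ms).  Which cortical
#' nodes a component reaches encodes the serial/parallel routing hypothesis.
#'
#' @param onset_mean Gaussian mean, ms post stimulus onset.
#' @param onset_sd Gaussian standard deviation, ms; must be positive.
#' @param amplitude Dimensionless drive gain, non-negative.
#' @param targets Character vector of node identifiers receiving the drive.
#' @param label Optional component label (e.g. `"phasic"`).
#' @return An object of class `input_component`.
#' @examples
#' phasic <- input_component(30, 16, 1, "SIc", label = "phasic")
#' gaussian_input(30, phasic)  # 1: the peak
#' @export
input_component <- function(onset_mean, onset_sd, amplitude = 1,
                            targets = "SIc", label = NULL) {
  stopifnot(is.numeric(onset_mean), length(onset_mean) == 1L)
  if (!is.numeric(onset_sd) || onset_sd <= 0)
    stop("onset_sd must be > 0")
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("amplitude must be >= 0")
  if (length(targets) == 0L)
    stop("targets must be non-empty")
  structure(
    list(onset_mean = as.numeric(onset_mean),
         onset_sd = as.numeric(onset_sd),
         amplitude = as.numeric(amplitude),
         targets = as.character(targets),
         label = label),
    class = "input_component")
}

#' Evaluate a Gaussian input component
#'
#' Returns `amplitude * exp(-(t - onset_mean)^2 / (2 * onset_sd^2))`:
#' a smooth, non-negative drive level.
#'
#' @param t Time(s) in ms (vectorized).
#' @param comp An [input_component()].
#' @return Numeric vector of drive levels.
#' @export
gaussian_input <- function(t, comp) {
  stopifnot(inherits(comp, "input_component"))
  comp$amplitude * exp(-(t - comp$onset_mean)^2 / (2 * comp$onset_sd^2))
}

#' Default phasic and sustained thalamic components
#'
#' Phasic: mean 30 ms, SD 16 ms.  Sustained: mean 170 ms, SD 70 ms.
#' Targets are filled in by [build_model()] according to the architecture.
#' The default amplitude of 30 drives the network to sub-millivolt pyramidal
#' deflections, the physiological regime of evoked-response mass models with
#' the standard coupling constants.
#'
#' @param phasic_amplitude,sustained_amplitude Drive gains.
#' @return Named list with elements `phasic` and `sustained`.
#' @export
default_components <- function(phasic_amplitude = 30, sustained_amplitude = 30) {
  list(
    phasic = input_component(30, 16, phasic_amplitude, "SIc", label = "phasic"),
    sustained = input_component(170, 70, sustained_amplitude, "SIc",
                                label = "sustained"))
}

#' @export
print.input_component <- function(x, ...) {
  cat(sprintf("<input_component%s> mean %g ms, sd %g ms, amplitude %g -> {%s}\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$onset_mean, x$onset_sd, x$amplitude,
              paste(x$targets, collapse = ", ")))
  invisible(x)
}
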