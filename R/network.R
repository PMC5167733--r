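#' Node dynamics parameters for the evoked-response neural mass model
#'
#' Each cortical node contains three coupled subpopulations (spiny stellate,
#' pyramidal, inhibitory interneurons) with second-order synaptic kernels
#' `v'' = (H/tau) s(t) - (2/tau) v' - v/tau^2`.  Defaults are the standard
#' prior means for this model family; all gains are re-estimated during
#' inversion as log-scaling coefficients.
#'
#' @param H_e,H_i Excitatory/inhibitory synaptic gains, mV.
#' @param tau_e,tau_i Excitatory/inhibitory synaptic time constants, ms.
#' @param gamma Intrinsic coupling constants, length 4
#'   (pyramidal->stellate, stellate->pyramidal, pyramidal->interneuron,
#'   interneuron->pyramidal).
#' @param sigmoid_slope Slope of the centred firing sigmoid
#'   `S(v) = 1/(1+exp(-r v)) - 1/2`.
#' @param extrinsic_delay,intrinsic_delay Conduction delays, ms.
#' @return Object of class `node_dynamics_params`.
#' @export
node_dynamics_params <- function(H_e = 3.25, H_i = 29.4,
                                 tau_e = 10, tau_i = 16,
                                 gamma = c(50, 40, 12, 12),
                                 sigmoid_slope = 0.56,
                                 extrinsic_delay = 16, intrinsic_delay = 2) {
  if (any(c(H_e, H_i, tau_e, tau_i) <= 0))
    stop("synaptic gains and time constants must be > 0")
  if (any(c(extrinsic_delay, intrinsic_delay) <= 0))
    stop("delays must be > 0")
  stopifnot(length(gamma) == 4, all(gamma >= 0), sigmoid_slope > 0)
  structure(
    list(H_e = H_e, H_i = H_i, tau_e = tau_e, tau_i = tau_i,
         gamma = as.numeric(gamma), sigmoid_slope = sigmoid_slope,
         extrinsic_delay = extrinsic_delay, intrinsic_delay = intrinsic_delay),
    class = "node_dynamics_params")
}

#' Node identifiers of the somatosensory network
#' @export
NODE_IDS <- c("SIc", "SIIc", "SIIi")

# default extrinsic coupling strengths at the prior mean (dimensionless gains
# on presynaptic firing); forward stronger than backward, as is conventional
.FWD_STRENGTH <- 128
.BWD_STRENGTH <- 64

#' Construct a somatosensory network model
#'
#' Three nodes (contralateral SI, contralateral and ipsilateral SII) with
#' bidirectional extrinsic connections SIc<->SIIc and SIIc<->SIIi, intrinsic
#' self-connections on every node, and a set of Gaussian thalamic input
#' components gated onto nodes.  Only those two edge pairs may be non-zero.
#'
#' @param forward,backward `[3 x 3]` non-negative matrices, entry `[i, j]`
#'   is the coupling from node `j` onto node `i`.  Forward connections enter
#'   the granular (stellate) population, backward connections the pyramidal
#'   and inhibitory populations.
#' @param lateral Reserved; must currently be all zero.
#' @param self Length-3 vector of log self-connection gains (0 = prior mean);
#'   multiplies each node's intrinsic couplings by `exp(self)`.
#' @param inputs List of entries `list(component =, gains =)` where `gains`
#'   is a named non-negative vector over the component's target nodes.
#' @param params A [node_dynamics_params()].
#' @param architecture Optional architecture label carried for bookkeeping.
#' @return Object of class `network_model`.
#' @export
network_model <- function(forward, backward, lateral = NULL,
                          self = c(0, 0, 0), inputs, params = node_dynamics_params(),
                          architecture = NA_character_) {
  n <- length(NODE_IDS)
  if (is.null(lateral)) lateral <- matrix(0, n, n)
  for (m in list(forward, backward, lateral)) {
    stopifnot(is.matrix(m), all(dim(m) == n), all(is.finite(m)), all(m >= 0))
    if (any(diag(m) != 0)) stop("connection matrices must have zero diagonal")
  }
  allowed <- matrix(FALSE, n, n, dimnames = list(NODE_IDS, NODE_IDS))
  allowed["SIc", "SIIc"] <- allowed["SIIc", "SIc"] <- TRUE
  allowed["SIIc", "SIIi"] <- allowed["SIIi", "SIIc"] <- TRUE
  if (any((forward + backward + lateral)[!allowed] != 0))
    stop("only edges SIc<->SIIc and SIIc<->SIIi may be non-zero")
  if (length(self) != n) stop("self must have one entry per node")
  if (length(inputs) == 0L) stop("at least one input component is required")
  got_si <- FALSE
  for (entry in inputs) {
    stopifnot(inherits(entry$component, "input_component"),
              is.numeric(entry$gains), !is.null(names(entry$gains)))
    if (!all(names(entry$gains) %in% NODE_IDS))
      stop("input gains must be named by node id")
    if ("SIc" %in% names(entry$gains)) got_si <- TRUE
  }
  if (!got_si) stop("every admissible model must have an input targeting SIc")
  dimnames(forward) <- dimnames(backward) <- dimnames(lateral) <-
    list(NODE_IDS, NODE_IDS)
  structure(
    list(node_ids = NODE_IDS, forward = forward, backward = backward,
         lateral = lateral, self = as.numeric(self), inputs = inputs,
         params = params, architecture = architecture),
    class = "network_model")
}

#' Build one of the competing routing architectures
#'
#' The four dual-input hypotheses differ only in which nodes the phasic and
#' sustained thalamic components reach:
#' \describe{
#'   \item{A}{permanent serial: both components target SIc only.}
#'   \item{B}{serial then parallel: phasic to SIc; sustained to SIc and SIIc.}
#'   \item{C}{parallel then serial: phasic to SIc and SIIc; sustained to SIc.}
#'   \item{D}{permanent parallel: both components target SIc and SIIc.}
#' }
#' The single-input initiation models `"serial"` and `"parallel"` keep only
#' the phasic component (to SIc, or to SIc and SIIc respectively).  The
#' connectivity skeleton (SIc<->SIIc, SIIc<->SIIi, self-connections) is
#' identical across all architectures; the ipsilateral SII never receives
#' direct thalamic input.
#'
#' @param architecture One of `"A"`, `"B"`, `"C"`, `"D"`, `"serial"`,
#'   `"parallel"`.
#' @param params A [node_dynamics_params()].
#' @param components Named list with `phasic` and `sustained`
#'   [input_component()]s (see [default_components()]); target sets are
#'   overridden by the architecture.
#' @return A [network_model()].
#' @export
build_model <- function(architecture, params = node_dynamics_params(),
                        components = default_components()) {
  serial <- "SIc"
  parallel <- c("SIc", "SIIc")
  gating <- switch(architecture,
    A = list(phasic = serial, sustained = serial),
    B = list(phasic = serial, sustained = parallel),
    C = list(phasic = parallel, sustained = serial),
    D = list(phasic = parallel, sustained = parallel),
    serial = list(phasic = serial),
    parallel = list(phasic = parallel),
    stop("unknown architecture label: ", architecture))

  n <- length(NODE_IDS)
  fwd <- bwd <- matrix(0, n, n, dimnames = list(NODE_IDS, NODE_IDS))
  fwd["SIIc", "SIc"] <- fwd["SIIi", "SIIc"] <- .FWD_STRENGTH
  bwd["SIc", "SIIc"] <- bwd["SIIc", "SIIi"] <- .BWD_STRENGTH

  inputs <- lapply(names(gating), function(nm) {
    comp <- components[[nm]]
    if (is.null(comp)) stop("missing input component: ", nm)
    comp$targets <- gating[[nm]]
    comp$label <- nm
    gains <- rep(1, length(gating[[nm]]))
    names(gains) <- gating[[nm]]
    list(component = comp, gains = gains)
  })
  names(inputs) <- names(gating)
  network_model(fwd, bwd, self = c(0, 0, 0), inputs = inputs,
                params = params, architecture = architecture)
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> architecture %s, nodes: %s\n",
              x$architecture, paste(x$node_ids, collapse = ", ")))
  for (entry in x$inputs)
    cat(sprintf("  input %-9s -> {%s}\n", entry$component$label,
                paste(names(entry$gains), collapse = ", ")))
  invisible(x)
}

#' Serialize / restore a network model
#'
#' Plain-JSON round trip with full numeric precision; `read_model()` on the
#' written file reproduces the model exactly.
#'
#' @param model A [network_model()].
#' @param path File path.
#' @return `read_model()` returns the restored [network_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  lst <- list(
    architecture = model$architecture,
    node_ids = model$node_ids,
    forward = model$forward, backward = model$backward,
    lateral = model$lateral, self = model$self,
    params = unclass(model$params),
    inputs = lapply(model$inputs, function(e) list(
      component = unclass(e$component), gains = as.list(e$gains))))
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lst$params
  params <- node_dynamics_params(p$H_e, p$H_i, p$tau_e, p$tau_i, p$gamma,
                                 p$sigmoid_slope, p$extrinsic_delay,
                                 p$intrinsic_delay)
  inputs <- lapply(lst$inputs, function(e) {
    comp <- input_component(e$component$onset_mean, e$component$onset_sd,
                            e$component$amplitude, e$component$targets,
                            label = e$component$label)
    list(component = comp, gains = unlist(e$gains))
  })
  as_mat <- function(m) matrix(as.numeric(as.matrix(m)), length(lst$node_ids))
  network_model(as_mat(lst$forward), as_mat(lst$backward), as_mat(lst$lateral),
                self = lst$self, inputs = inputs, params = params,
                architecture = if (is.null(lst$architecture)) NA_character_
                               else lst$architecture)
}
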