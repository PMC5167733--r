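# run expr with a temporary RNG state seeded by `seed` (global state restored)
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  force(expr)
}

#' Free parameters of a network model
#'
#' Enumerates the parameters estimated during inversion: log-scaling
#' coefficients on the non-zero extrinsic connections, additive log gains on
#' the self-connections, log-scalings of each input amplitude (per component
#' and target), an additive shift of each component's onset mean (ms) and a
#' log-scaling of its width.  Prior means are all zero (the model as built);
#' prior SDs follow the conventions of this model family and can be
#' overridden.
#'
#' @param model A [network_model()].
#' @param sd_extrinsic,sd_self,sd_amplitude Log-scale prior SDs.
#' @param sd_onset_frac Prior SD of the onset-mean shift, as a fraction of
#'   the component's own SD (default 1/2: e.g. 8 ms for the phasic input).
#' @param sd_width Log-scale prior SD of the component width.
#' @return Data frame with columns `name`, `sd`.
#' @export
model_parameters <- function(model, sd_extrinsic = 0.25, sd_self = 0.125,
                             sd_amplitude = 0.5, sd_onset_frac = 0.5,
                             sd_width = 0.25) {
  stopifnot(inherits(model, "network_model"))
  nm <- character(0); sds <- numeric(0)
  add <- function(n, s) { nm <<- c(nm, n); sds <<- c(sds, s) }
  for (m in c("forward", "backward")) {
    idx <- which(model[[m]] != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      add(sprintf("%s_%s_%s", substr(m, 1, 3),
                  model$node_ids[idx[r, 1]], model$node_ids[idx[r, 2]]),
          sd_extrinsic)
  }
  for (i in seq_along(model$node_ids))
    add(paste0("self_", model$node_ids[i]), sd_self)
  for (entry in model$inputs) {
    lab <- entry$component$label
    for (tg in names(entry$gains))
      add(sprintf("amp_%s_%s", lab, tg), sd_amplitude)
    add(paste0("mu_", lab), sd_onset_frac * entry$component$onset_sd)
    add(paste0("sigma_", lab), sd_width)
  }
  data.frame(name = nm, sd = sds, stringsAsFactors = FALSE)
}

#' Apply a parameter vector to a network model
#'
#' @param model A [network_model()].
#' @param theta Named numeric vector over [model_parameters()] names.
#' @return The perturbed [network_model()].
#' @export
apply_parameters <- function(model, theta) {
  m <- model
  for (nm in names(theta)) {
    v <- theta[[nm]]
    parts <- strsplit(nm, "_")[[1]]
    kind <- parts[1]
    if (kind %in% c("for", "bac")) {
      slot <- if (kind == "for") "forward" else "backward"
      m[[slot]][parts[2], parts[3]] <- m[[slot]][parts[2], parts[3]] * exp(v)
    } else if (kind == "self") {
      i <- match(parts[2], m$node_ids)
      m$self[i] <- m$self[i] + v
    } else if (kind == "amp") {
      lab <- parts[2]; tg <- parts[3]
      m$inputs[[lab]]$gains[tg] <- m$inputs[[lab]]$gains[tg] * exp(v)
    } else if (kind == "mu") {
      m$inputs[[parts[2]]]$component$onset_mean <-
        m$inputs[[parts[2]]]$component$onset_mean + v
    } else if (kind == "sigma") {
      m$inputs[[parts[2]]]$component$onset_sd <-
        m$inputs[[parts[2]]]$component$onset_sd * exp(v)
    } else stop("unknown parameter: ", nm)
  }
  m
}

#' Default prior density for a model's parameters
#'
#' Independent Gaussian priors centred on zero (the model as built) with the
#' SDs of [model_parameters()], plus a weak Gaussian hyperprior on the log
#' noise precision of each spatial mode.
#'
#' @param model A [network_model()].
#' @param noise_hyperprior Two-vector `(mean, variance)` of the log noise
#'   precision hyperprior.
#' @param ... Passed to [model_parameters()].
#' @return Object of class `prior_density`: `mean`, `cov` (diagonal),
#'   `noise_hyperprior`, `table`.
#' @export
default_priors <- function(model, noise_hyperprior = c(0, 16), ...) {
  tab <- model_parameters(model, ...)
  mu <- stats::setNames(rep(0, nrow(tab)), tab$name)
  structure(list(mean = mu, cov = diag(tab$sd^2, nrow(tab)),
                 noise_hyperprior = noise_hyperprior, table = tab),
            class = "prior_density")
}

#' Window and reduce an ERF for inversion
#'
#' Restricts the trial-averaged data to the closed peri-stimulus interval
#' `[start, start + length]` ms, then projects onto the leading spatial
#' modes of the windowed data (computed per subject and window).
#'
#' @param erf An [average_erf()] result.
#' @param window A [window_spec()].
#' @param n_modes Number of spatial modes (default 7).
#' @return Object of class `reduced_data`: `Y` (`[modes x samples]`),
#'   `basis` (`[channels x modes]`), `times` (ms), `window`.
#' @export
window_data <- function(erf, window, n_modes = 7) {
  stopifnot(inherits(erf, "erf"), inherits(window, "window_spec"))
  lo <- window$start; hi <- window$start + window$length
  if (lo < min(erf$times) - 1e-9 || hi > max(erf$times) + 1e-9)
    stop("window outside the epoch time range")
  idx <- which(erf$times >= lo - 1e-9 & erf$times <= hi + 1e-9)
  Yf <- erf$data[, idx, drop = FALSE]
  n_modes <- min(n_modes, nrow(Yf), length(idx))
  modes <- compute_modes(Yf, n_modes)
  structure(list(Y = crossprod(modes$basis, Yf), basis = modes$basis,
                 times = erf$times[idx], window = window),
            class = "reduced_data")
}

# numeric forward-difference Jacobian of vec(f) wrt theta
.num_jacobian <- function(f, theta, f0, h) {
  p <- length(theta)
  J <- matrix(0, length(f0), p)
  for (i in seq_len(p)) {
    th <- theta
    th[i] <- th[i] + h[i]
    J[, i] <- (as.numeric(f(th)) - f0) / h[i]
  }
  J
}

#' Variational Laplace inversion of a (possibly nonlinear) forward model
#'
#' Fits a Gaussian posterior `q(theta)` maximizing the free energy
#' `F = <log p(y|theta)>_q - KL(q || prior)` with a Gauss-Newton outer loop
#' (Levenberg-Marquardt damping on rejected steps) and a 1-D Newton update
#' of the log noise precision per spatial mode (Gaussian hyperprior,
#' MAP point estimate).  `F` never decreases over accepted iterations;
#' convergence when the F increment falls below `tol` nats.  Observation
#' noise is IID in time with one precision per mode row of `y`.
#'
#' @param y `[modes x samples]` data matrix.
#' @param f Forward function: named parameter vector -> prediction matrix
#'   of the same shape as `y`.
#' @param prior A `prior_density` (see [default_priors()]).
#' @param settings List; recognized fields `maxit` (128), `tol` (0.01 nats),
#'   `update_noise` (TRUE), `lambda0` (initial log precision per mode;
#'   default from the data scale).
#' @return List with `posterior` (`mean`, `cov`, `noise` = per-mode log
#'   precision and its hyperprior), `evidence` (`free_energy`, `accuracy`,
#'   `complexity`; `free_energy = accuracy - complexity`), `F_trace`
#'   (accepted iterations), `converged`, `iterations`.
#' @export
variational_laplace <- function(y, f, prior, settings = list()) {
  stopifnot(is.matrix(y))
  maxit <- settings$maxit %||% 128L
  tol <- settings$tol %||% 0.01
  update_noise <- settings$update_noise %||% TRUE
  M <- nrow(y); Tn <- ncol(y)
  p <- length(prior$mean)
  mode_of <- rep(seq_len(M), times = Tn)  # row-major index of vec(y)

  ipC <- solve(prior$cov)
  ldCp <- determinant(prior$cov, logarithm = TRUE)$modulus[1]
  h0 <- prior$noise_hyperprior[1]; v0 <- prior$noise_hyperprior[2]

  lam <- settings$lambda0 %||%
    (if (update_noise) stats::setNames(log(Tn / pmax(rowSums(y^2), 1e-12)), NULL)
     else rep(h0, M))
  if (length(lam) == 1L) lam <- rep(lam, M)

  hstep <- 1e-3 * sqrt(diag(prior$cov))
  theta <- prior$mean

  free_energy <- function(r, J, Sq, lam, e) {
    W <- exp(lam)
    rr <- rowSums(r^2)                       # per mode
    JSJt_diag <- rowSums((J %*% Sq) * J)     # diag of J Sq J'
    tr_m <- vapply(seq_len(M), function(m)
      sum(JSJt_diag[mode_of == m]), numeric(1))
    acc <- sum(Tn / 2 * (lam - log(2 * pi)) - W / 2 * (rr + tr_m))
    ldSq <- determinant(Sq, logarithm = TRUE)$modulus[1]
    kl <- 0.5 * (ldCp - ldSq + sum(diag(ipC %*% Sq)) +
                   drop(t(e) %*% ipC %*% e) - p)
    hyp <- sum((lam - h0)^2) / (2 * v0)
    list(F = acc - kl - hyp, accuracy = acc, complexity = kl + hyp)
  }

  # full state at theta: prediction, Jacobian, curvature, Sq, F
  eval_state <- function(theta, lam) {
    f0 <- as.numeric(f(theta))
    if (!all(is.finite(f0))) return(NULL)
    J <- .num_jacobian(f, theta, f0, hstep)
    if (!all(is.finite(J))) return(NULL)
    r <- matrix(as.numeric(y) - f0, M, Tn)
    W <- exp(lam)[mode_of]
    H <- crossprod(J * W, J) + ipC
    Sq <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Sq)) {
      H <- H + diag(1e-6 * mean(diag(H)), p)
      Sq <- solve(H)
      warning("singular curvature: ridge-regularized")
    }
    e <- theta - prior$mean
    fe <- free_energy(r, J, Sq, lam, e)
    list(theta = theta, f0 = f0, J = J, r = r, H = H, Sq = Sq,
         fe = fe, lam = lam)
  }

  st <- eval_state(theta, lam)
  if (is.null(st)) stop("forward model not finite at the prior mean")
  F_trace <- st$fe$F
  damp <- 1 / 16
  converged <- FALSE
  it <- 0L

  while (it < maxit) {
    it <- it + 1L
    # noise precision update (concave 1-D Newton per mode), revert on F loss
    if (update_noise) {
      JSJt_diag <- rowSums((st$J %*% st$Sq) * st$J)
      lam_new <- st$lam
      for (m in seq_len(M)) {
        S_m <- sum(st$r[m, ]^2) + sum(JSJt_diag[mode_of == m])
        l <- lam_new[m]
        for (k in 1:8) {
          g1 <- Tn / 2 - exp(l) * S_m / 2 - (l - h0) / v0
          g2 <- -exp(l) * S_m / 2 - 1 / v0
          step <- g1 / g2
          l <- l - max(min(step, 4), -4)
          if (abs(step) < 1e-8) break
        }
        lam_new[m] <- l
      }
      cand <- eval_state(st$theta, lam_new)
      if (!is.null(cand) && cand$fe$F >= st$fe$F - 1e-9) st <- cand
    }
    # Gauss-Newton / LM parameter step
    W <- exp(st$lam)[mode_of]
    g <- crossprod(st$J * W, as.numeric(st$r)) -
      ipC %*% (st$theta - prior$mean)
    accepted <- FALSE
    for (k in 1:6) {
      Hd <- st$H + damp * diag(diag(st$H), p)
      dth <- drop(solve(Hd, g))
      cand <- eval_state(st$theta + dth, st$lam)
      if (!is.null(cand) && cand$fe$F > st$fe$F) {
        dF <- cand$fe$F - st$fe$F
        st <- cand
        F_trace <- c(F_trace, st$fe$F)
        damp <- max(damp / 2, 1e-8)
        accepted <- TRUE
        if (dF < tol) converged <- TRUE
        break
      }
      damp <- damp * 8
    }
    if (!accepted) { converged <- TRUE }  # no improving step found
    if (converged) break
  }

  names(st$theta) <- names(prior$mean)
  dimnames(st$Sq) <- list(names(prior$mean), names(prior$mean))
  list(
    posterior = list(mean = st$theta, cov = st$Sq,
                     noise = list(log_precision = st$lam,
                                  hyperprior = prior$noise_hyperprior)),
    evidence = list(free_energy = st$fe$F, accuracy = st$fe$accuracy,
                    complexity = st$fe$complexity),
    F_trace = F_trace, converged = converged, iterations = it)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Invert a network model against reduced sensor data
#'
#' Wraps [variational_laplace()] with the neural-mass forward model: source
#' simulation from -50 ms (quiescent spin-up) to the window end, projection
#' through the gain matrix and onto the window's spatial modes.
#'
#' @param model A [network_model()] (at its prior mean).
#' @param rdata A [window_data()] result.
#' @param gain A `gain_matrix` (assumed known).
#' @param prior Optional `prior_density`; defaults to
#'   [default_priors()] on `model`.
#' @param settings Passed to [variational_laplace()].
#' @return As [variational_laplace()], with `posterior$input_strengths`
#'   added: the posterior mean log input strength per target node
#'   (log amplitude x gain, averaged over components reaching the target).
#' @export
invert <- function(model, rdata, gain, prior = NULL, settings = list()) {
  stopifnot(inherits(model, "network_model"), inherits(rdata, "reduced_data"))
  if (is.null(prior)) prior <- default_priors(model)
  G <- if (inherits(gain, "gain_matrix")) gain$values else gain
  step <- diff(rdata$times[1:2])
  sim_times <- seq(-50, max(rdata$times), by = step)
  idx <- match(round(rdata$times / step), round(sim_times / step))
  if (any(is.na(idx))) stop("window times not on the simulation grid")
  U <- rdata$basis

  fwd <- function(theta) {
    names(theta) <- names(prior$mean)
    m <- apply_parameters(model, theta)
    src <- simulate_sources(m, sim_times)
    crossprod(U, G %*% src$values[, idx, drop = FALSE])
  }
  res <- variational_laplace(rdata$Y, fwd, prior, settings)
  res$posterior$input_strengths <- .input_strengths(model, res$posterior$mean)
  res
}

# posterior mean log input strength per target node
.input_strengths <- function(model, theta) {
  out <- list()
  for (entry in model$inputs) {
    lab <- entry$component$label
    for (tg in names(entry$gains)) {
      nm <- sprintf("amp_%s_%s", lab, tg)
      base <- log(entry$component$amplitude * entry$gains[[tg]])
      val <- base + if (nm %in% names(theta)) theta[[nm]] else 0
      out[[tg]] <- c(out[[tg]], val)
    }
  }
  vapply(out, mean, numeric(1))
}
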