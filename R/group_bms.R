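#' Evidence table over subjects and models
#'
#' @param values `[subjects x models]` matrix of free energies (nats).
#' @param subject_ids,model_labels Optional row/column labels.
#' @param window Optional [window_spec()] the evidences refer to.
#' @return Object of class `evidence_table`.
#' @export
evidence_table <- function(values, subject_ids = NULL, model_labels = NULL,
                           window = NULL) {
  stopifnot(is.matrix(values))
  if (ncol(values) < 2) stop("at least 2 models are required")
  if (!all(is.finite(values))) stop("evidence values must be finite")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(model_labels)) model_labels <- colnames(values) %||%
      paste0("M", seq_len(ncol(values)))
  dimnames(values) <- list(subject_ids, model_labels)
  structure(list(values = values, subject_ids = subject_ids,
                 model_labels = model_labels, window = window),
            class = "evidence_table")
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over model frequencies: iterate
#' `u_nk = exp(F_nk + psi(alpha_k) - psi(sum(alpha)))`, normalize per
#' subject, `alpha = alpha0 + colSums(g)`, until the alpha update is below
#' `1e-6`.  Per-subject free energies are shifted by their row maximum
#' before exponentiation (the posterior is invariant to such shifts).
#'
#' @param ev An [evidence_table()] (or bare `[subjects x models]` matrix).
#' @param alpha0 Dirichlet prior counts (scalar or per-model vector);
#'   default 1 (uniform).
#' @param exceedance_samples Monte-Carlo samples for the exceedance
#'   probabilities (used when more than 2 models).
#' @param seed Seed for the Monte-Carlo exceedance draw.
#' @return Object of class `dirichlet_posterior`: `alpha`, `expected_freq`,
#'   `exceedance`, `model_labels`, `g` (posterior model assignment per
#'   subject).
#' @export
rfx_bms <- function(ev, alpha0 = 1, exceedance_samples = 1e6, seed = 1L) {
  Fm <- if (inherits(ev, "evidence_table")) ev$values else ev
  stopifnot(is.matrix(Fm), all(is.finite(Fm)))
  K <- ncol(Fm)
  labels <- colnames(Fm) %||% paste0("M", seq_len(K))
  if (length(alpha0) == 1L) alpha0 <- rep(alpha0, K)
  stopifnot(all(alpha0 > 0), length(alpha0) == K)
  Fc <- Fm - apply(Fm, 1, max)
  alpha <- alpha0 + nrow(Fm) / K
  for (i in 1:500) {
    lu <- sweep(Fc, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    g <- exp(lu)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (sum(abs(alpha_new - alpha)) < 1e-6) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  ex <- exceedance_prob(alpha, n_samples = exceedance_samples, seed = seed)
  structure(list(alpha = stats::setNames(alpha, labels),
                 expected_freq = stats::setNames(alpha / sum(alpha), labels),
                 exceedance = stats::setNames(ex, labels),
                 model_labels = labels, g = g),
            class = "dirichlet_posterior")
}

#' @export
print.dirichlet_posterior <- function(x, ...) {
  cat("<dirichlet_posterior>\n")
  print(round(rbind(alpha = x$alpha, expected_freq = x$expected_freq,
                    exceedance = x$exceedance), 4))
  invisible(x)
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' `P(r_k > r_j for all j != k)` under `Dirichlet(alpha)`.  For two models
#' the exact Beta closed form `1 - pbeta(0.5, alpha_k, alpha_j)` is used
#' (method `"auto"`); otherwise a seeded Monte-Carlo estimate whose argmax
#' partition makes the vector sum to 1 exactly.
#'
#' @param alpha Positive Dirichlet parameter vector.
#' @param n_samples Monte-Carlo sample count (default 1e6).
#' @param seed Integer seed for the draw.
#' @param method `"auto"`, `"beta"` (2 models only) or `"mc"`.
#' @return Exceedance probability vector (sums to 1).
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = 1L,
                            method = c("auto", "beta", "mc")) {
  method <- match.arg(method)
  if (any(alpha <= 0) || !all(is.finite(alpha))) stop("alpha must be > 0")
  K <- length(alpha)
  if (method == "beta" && K != 2)
    stop("the Beta closed form applies to 2 models only")
  if (method == "auto") method <- if (K == 2) "beta" else "mc"
  if (method == "beta") {
    p2 <- stats::pbeta(0.5, alpha[1], alpha[2])  # P(r1 < 1/2) = P(r2 > r1)
    return(c(1 - p2, p2))
  }
  .with_seed(seed, {
    idx <- integer(K)
    draws <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha,
      each = n_samples)), n_samples, K)
    win <- max.col(draws, ties.method = "first")
    tabulate(win, nbins = K) / n_samples
  })
}

#' Paired t-test (two-sided)
#'
#' Thin wrapper around [stats::t.test()] returning the statistic,
#' degrees of freedom (`n - 1`) and p-value.
#'
#' @param x,y Paired measurement vectors.
#' @return List `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x - y) == 0) {
    return(list(t = 0, df = length(x) - 1L, p = 1,
                mean_diff = mean(x - y)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Bayesian model averaging of thalamic input strengths
#'
#' Per subject, model weights are either a one-hot on the group winning
#' model (`"winner"`, the conventional restriction) or the softmax of the
#' subject's free energies over the model set (`"softmax"`).  Per-target
#' log input strengths are averaged with these weights over the models that
#' contain the target, and the SI-vs-SII contrast is a paired t-test of the
#' per-subject SIc vs SIIc strengths.
#'
#' @param ev An [evidence_table()].
#' @param posteriors List (subjects) of lists (models) of `invert()`
#'   posteriors (each carrying `input_strengths`).
#' @param mode `"winner"` or `"softmax"`.
#' @return Object of class `group_result`: `weights`
#'   (`[subjects x models]`), `strengths` (`[subjects x targets]`, log
#'   scale), `contrast` (`t`, `df`, `p`, `mean_diff` for SIc - SIIc),
#'   `summary` (per-target mean and SD), `winning_model`.
#' @export
bma_inputs <- function(ev, posteriors, mode = c("winner", "softmax")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ev, "evidence_table"))
  Fm <- ev$values
  n <- nrow(Fm); K <- ncol(Fm)
  if (n < 2) stop("at least 2 subjects are required for the group contrast")
  stopifnot(length(posteriors) == n)
  if (mode == "winner") {
    win <- which.max(colSums(Fm))
    Wt <- matrix(0, n, K); Wt[, win] <- 1
  } else {
    Fc <- Fm - apply(Fm, 1, max)
    Wt <- exp(Fc) / rowSums(exp(Fc))
    win <- which.max(colSums(Fm))
  }
  dimnames(Wt) <- dimnames(Fm)

  targets <- unique(unlist(lapply(posteriors, function(ps)
    lapply(ps, function(p) names(p$input_strengths)))))
  S <- matrix(NA_real_, n, length(targets),
              dimnames = list(ev$subject_ids, targets))
  for (i in seq_len(n)) {
    for (tg in targets) {
      num <- 0; den <- 0
      for (k in seq_len(K)) {
        s <- posteriors[[i]][[k]]$input_strengths
        if (is.null(s)) s <- posteriors[[i]][[k]]$posterior$input_strengths
        if (!is.null(s) && tg %in% names(s) && Wt[i, k] > 0) {
          num <- num + Wt[i, k] * s[[tg]]
          den <- den + Wt[i, k]
        }
      }
      if (den > 0) S[i, tg] <- num / den
    }
  }
  contrast <- if (all(c("SIc", "SIIc") %in% targets) &&
                  !anyNA(S[, c("SIc", "SIIc")])) {
    paired_t(S[, "SIc"], S[, "SIIc"])
  } else NULL
  structure(list(weights = Wt, strengths = S,
                 contrast = contrast,
                 summary = data.frame(
                   target = targets,
                   mean = colMeans(S, na.rm = TRUE),
                   sd = apply(S, 2, stats::sd, na.rm = TRUE)),
                 winning_model = ev$model_labels[win]),
            class = "group_result")
}

#' Windowed random-effects model-selection sweep
#'
#' For each window of the plan: reduce each subject's ERF with
#' [window_data()], invert every competing model, assemble the evidence
#' table and run [rfx_bms()].  A failed inversion is recorded as `NA` and
#' the affected subject is excluded from that window's BMS with a warning;
#' the sweep itself continues.
#'
#' @param plan An [build_plan()] result.
#' @param erfs List of [average_erf()] objects, one per subject.
#' @param gain The (known) `gain_matrix`.
#' @param priors Optional named list of `prior_density` per model label.
#' @param settings Inversion settings (see [variational_laplace()]).
#' @param n_modes Spatial modes per window.
#' @param onset_prior `"stimulus"`: component onset priors stay
#'   stimulus-locked; `"window"`: for windows starting after 0 ms, the
#'   input onset prior is re-centred at the window start, so the
#'   single-input initiation models can explain late segments (the synaptic
#'   kernel's ~25 ms latency then places the modeled response, and its
#'   serially lagged SII counterpart, inside a 60 ms window).
#' @param store_posteriors Keep per-cell posteriors (needed for
#'   [bma_inputs()]).
#' @param components Input components handed to [build_model()].
#' @return Object of class `bms_sweep`: per window a list with `window`,
#'   `bms` (`dirichlet_posterior`), `evidence` (`evidence_table`), and
#'   optionally `posteriors`.
#' @export
bms_sweep <- function(plan, erfs, gain, priors = NULL, settings = list(),
                      n_modes = 7, onset_prior = c("stimulus", "window"),
                      store_posteriors = FALSE,
                      components = default_components()) {
  onset_prior <- match.arg(onset_prior)
  stopifnot(inherits(plan, "analysis_plan"), length(erfs) >= 2)
  out <- vector("list", length(plan$windows))
  for (w in seq_along(plan$windows)) {
    win <- plan$windows[[w]]
    comps <- components
    if (onset_prior == "window" && win$start > 0) {
      comps$phasic$onset_mean <- win$start
    }
    models <- lapply(plan$models, build_model, components = comps)
    names(models) <- plan$models
    Fm <- matrix(NA_real_, length(erfs), length(models),
                 dimnames = list(paste0("S", seq_along(erfs)), plan$models))
    posts <- if (store_posteriors)
      rep(list(stats::setNames(vector("list", length(models)), plan$models)),
          length(erfs))
    for (i in seq_along(erfs)) {
      rdata <- window_data(erfs[[i]], win, n_modes = n_modes)
      for (k in seq_along(models)) {
        fit <- tryCatch({
          pr <- if (!is.null(priors)) priors[[plan$models[k]]] else NULL
          invert(models[[k]], rdata, gain, prior = pr, settings = settings)
        }, error = function(e) {
          warning(sprintf("inversion failed (subject %d, model %s, window %g-%g ms): %s",
                          i, plan$models[k], win$start,
                          win$start + win$length, conditionMessage(e)))
          NULL
        })
        if (!is.null(fit)) {
          Fm[i, k] <- fit$evidence$free_energy
          if (store_posteriors) posts[[i]][[k]] <- fit$posterior
        }
      }
    }
    ok <- stats::complete.cases(Fm)
    if (!all(ok))
      warning(sum(!ok), " subject(s) excluded from window ", w,
              " due to failed inversions")
    ev <- evidence_table(Fm[ok, , drop = FALSE],
                         subject_ids = rownames(Fm)[ok],
                         model_labels = plan$models, window = win)
    out[[w]] <- list(window = win, bms = rfx_bms(ev), evidence = ev,
                     posteriors = if (store_posteriors) posts[ok])
  }
  structure(list(results = out, plan = plan), class = "bms_sweep")
}

#' Exceedance-probability table of a sweep
#'
#' @param x A [bms_sweep()] result.
#' @return Data frame: window start/length and EP per model.
#' @export
ep_table <- function(x) {
  stopifnot(inherits(x, "bms_sweep"))
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(window_start = r$window$start,
               window_length = r$window$length,
               t(r$bms$exceedance))
  }))
}

#' @export
print.bms_sweep <- function(x, ...) {
  cat(sprintf("<bms_sweep> %s, %d windows\n", x$plan$analysis,
              length(x$results)))
  print(round(as.matrix(ep_table(x)), 3))
  invisible(x)
}
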