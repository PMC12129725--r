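#' @useDynLib banditrl, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm qnorm dnorm rnorm runif sd var cor quantile
#'   optim setNames simulate coef logLik predict residuals acf density
#'   integrate
#' @importFrom utils read.csv write.csv write.table head modifyList
#'   packageVersion
NULL

# Canonical internal parameter order; matches src/bandit.cpp.
.param_names <- c("R", "P", "lr_r", "lr_p", "d", "xi")

#' Model specification for the five bandit learning models
#'
#' The model family tracks separate reward and punishment action values
#' (`Qr`, `Qp`) for the four cues. Prediction errors are scaled by
#' sensitivities `R` and `P`; the chosen cue's values are updated with
#' learning rates that are either coupled (`alpha + beta` for rewards,
#' `alpha - beta` for punishments; models 1-2) or independent (`alpha_r`,
#' `alpha_p`; models 3-5). Models 1 and 3 add a decay (forgetting) rate `d`
#' applied to all cues each trial; models 1-4 mix a lapse probability `xi`
#' into the softmax policy.
#'
#' @param model_id Integer in 1..5.
#' @return An object of class `bandit_model` with fields `model_id`,
#'   `coupled_learning_rates`, `has_decay`, `has_lapse`, `active`
#'   (logical mask over the canonical parameter vector) and `n_params`.
#' @examples
#' bandit_model(1)
#' @export
bandit_model <- function(model_id) {
  if (length(model_id) != 1L || !model_id %in% 1:5)
    stop("`model_id` must be a single integer in 1..5")
  model_id <- as.integer(model_id)
  has_decay <- model_id %in% c(1L, 3L)
  has_lapse <- model_id %in% 1:4
  active <- c(TRUE, TRUE, TRUE, TRUE, has_decay, has_lapse)
  names(active) <- .param_names
  structure(
    list(model_id = model_id,
         coupled_learning_rates = model_id %in% c(1L, 2L),
         has_decay = has_decay,
         has_lapse = has_lapse,
         active = active,
         n_params = sum(active)),
    class = "bandit_model")
}

#' @export
print.bandit_model <- function(x, ...) {
  lr <- if (x$coupled_learning_rates) "coupled (alpha +/- beta)"
        else "independent (alpha_r, alpha_p)"
  cat(sprintf("Bandit learning model %d: sensitivities R, P; %s; decay: %s; lapse: %s\n",
              x$model_id, lr,
              if (x$has_decay) "yes" else "no",
              if (x$has_lapse) "yes" else "no"))
  invisible(x)
}

#' Subject-level parameter vector
#'
#' Builds and validates the canonical six-element parameter vector
#' `(R, P, lr_r, lr_p, d, xi)`. For coupled models supply either
#' `lr_r`/`lr_p` directly or `alpha`/`beta` (then `lr_r = alpha + beta`,
#' `lr_p = alpha - beta`; both composites must lie in `[0, 1]`).
#' Parameters inactive under `model` are pinned to their neutral value
#' (`d = 0`, `xi = 0`).
#'
#' @param model A `bandit_model`.
#' @param R,P Non-negative sensitivities (at most `sens_ub`).
#' @param lr_r,lr_p Learning rates in `[0, 1]`.
#' @param alpha,beta Alternative coupled parameterization.
#' @param d Decay rate in `[0, 1]` (models 1, 3).
#' @param xi Lapse probability in `[0, 1]` (models 1-4).
#' @param sens_ub Upper bound for sensitivities (default 30).
#' @return Named numeric vector of class `bandit_params`.
#' @examples
#' bandit_params(bandit_model(1), R = 12.75, P = 9.95, alpha = 0.58,
#'               beta = 0.11, d = 0.6, xi = 0.1)
#' @export
bandit_params <- function(model, R, P, lr_r = NULL, lr_p = NULL,
                          alpha = NULL, beta = NULL, d = 0, xi = 0,
                          sens_ub = 30) {
  stopifnot(inherits(model, "bandit_model"))
  if (!is.null(alpha)) {
    if (is.null(beta)) beta <- 0
    lr_r <- alpha + beta
    lr_p <- alpha - beta
  }
  if (is.null(lr_r) || is.null(lr_p))
    stop("supply either lr_r/lr_p or alpha/beta")
  th <- c(R = R, P = P, lr_r = lr_r, lr_p = lr_p, d = d, xi = xi)
  if (!model$has_decay && d != 0)
    stop("decay is inactive in model ", model$model_id, "; d must be 0")
  if (!model$has_lapse && xi != 0)
    stop("lapse is inactive in model ", model$model_id, "; xi must be 0")
  validate_params(th, sens_ub = sens_ub)
  structure(th, class = "bandit_params", model_id = model$model_id)
}

validate_params <- function(th, sens_ub = 30) {
  if (any(!is.finite(th))) stop("non-finite parameter value")
  if (th[["R"]] < 0 || th[["P"]] < 0 || th[["R"]] > sens_ub || th[["P"]] > sens_ub)
    stop("sensitivities must lie in [0, ", sens_ub, "]")
  unit <- th[c("lr_r", "lr_p", "d", "xi")]
  if (any(unit < 0 | unit > 1))
    stop("learning rates, decay and lapse must lie in [0, 1]")
  invisible(th)
}

# Coerce a bandit_params / named vector to the canonical 6-vector.
as_theta <- function(params) {
  th <- rep(0, 6)
  names(th) <- .param_names
  th[names(params)[names(params) %in% .param_names]] <-
    params[names(params) %in% .param_names]
  th
}

#' Sensitivity-scaled prediction errors for one trial
#'
#' The reward prediction error is `R * win - Qr[chosen]` and the punishment
#' prediction error `P * loss - Qp[chosen]`: the sensitivities scale the
#' outcome value entering the comparison with the tracked (already scaled)
#' expectation, the convention of this model family's fitting toolchains.
#' Both are computed for the chosen cue only.
#'
#' @param params `bandit_params` or named vector with `R`, `P`.
#' @param q_reward,q_punish Length-4 value vectors.
#' @param choice Chosen cue, 1..4.
#' @param win Reward outcome, 0 or 1.
#' @param loss Punishment outcome, 0 or -1.
#' @return List with `delta_r` and `delta_p`.
#' @export
scaled_prediction_errors <- function(params, q_reward, q_punish, choice,
                                     win, loss) {
  check_obs(choice, win, loss)
  if (any(!is.finite(q_reward)) || any(!is.finite(q_punish)))
    stop("non-finite Q state")
  th <- as_theta(params)
  list(delta_r = th[["R"]] * win - q_reward[choice],
       delta_p = th[["P"]] * loss - q_punish[choice])
}

check_obs <- function(choice, win, loss) {
  if (!all(choice %in% 1:4)) stop("choice must be coded 1..4")
  if (!all(win %in% c(0, 1))) stop("win must be coded {0, 1}")
  if (!all(loss %in% c(0, -1))) stop("loss must be coded {0, -1}")
  invisible(TRUE)
}

#' Delta-rule value update for the chosen cue
#'
#' Adds `lr_r * delta_r` to the chosen cue's reward value and
#' `lr_p * delta_p` to its punishment value, where the learning rates are
#' `alpha +/- beta` for coupled models and `alpha_r`, `alpha_p` otherwise
#' (both covered by the canonical `lr_r`, `lr_p` slots). Other cues are
#' untouched.
#'
#' @inheritParams scaled_prediction_errors
#' @param delta_r,delta_p Scaled prediction errors for this trial.
#' @return List with updated `q_reward`, `q_punish`.
#' @export
update_values <- function(params, q_reward, q_punish, choice,
                          delta_r, delta_p) {
  th <- as_theta(params)
  if (th[["lr_r"]] < 0 || th[["lr_r"]] > 1 || th[["lr_p"]] < 0 || th[["lr_p"]] > 1)
    stop("learning rates must lie in [0, 1]")
  q_reward[choice] <- q_reward[choice] + th[["lr_r"]] * delta_r
  q_punish[choice] <- q_punish[choice] + th[["lr_p"]] * delta_p
  list(q_reward = q_reward, q_punish = q_punish)
}

#' Multiplicative forgetting of all tracked values
#'
#' Every entry of both value vectors is shrunk towards zero by `1 - d`.
#'
#' @inheritParams scaled_prediction_errors
#' @return List with decayed `q_reward`, `q_punish`.
#' @export
apply_decay <- function(params, q_reward, q_punish) {
  th <- as_theta(params)
  d <- th[["d"]]
  if (d < 0 || d > 1) stop("decay rate must lie in [0, 1]")
  list(q_reward = (1 - d) * q_reward, q_punish = (1 - d) * q_punish)
}

#' Softmax choice probabilities with optional lapse
#'
#' `p(i) = exp(Qr_i + Qp_i) / sum_j exp(Qr_j + Qp_j)`, stabilized by
#' max-subtraction; when the model has a lapse term the policy becomes
#' `p * (1 - xi) + xi / 4`.
#'
#' @param model A `bandit_model`.
#' @inheritParams scaled_prediction_errors
#' @return Length-4 probability vector summing to 1.
#' @export
choice_probabilities <- function(model, params, q_reward, q_punish) {
  if (any(!is.finite(q_reward)) || any(!is.finite(q_punish)))
    stop("non-finite Q state")
  th <- as_theta(params)
  v <- q_reward + q_punish
  e <- exp(v - max(v))
  p <- e / sum(e)
  if (model$has_lapse) p <- p * (1 - th[["xi"]]) + th[["xi"]] / 4
  p
}

#' Run a learning model through an observed choice sequence
#'
#' Applies the per-trial order decay -> policy -> prediction errors ->
#' update to every trial of a subject's dataset and records the full latent
#' trace. The Q-state starts at zero and, by default, is carried across run
#' boundaries (the four runs are contiguous blocks of one session); set
#' `reset_runs = TRUE` to re-initialize at each run start.
#'
#' @param model A `bandit_model`.
#' @param params `bandit_params` (or named vector).
#' @param subject A single-subject record as produced by [bandit_data()]
#'   (list with `trials` data frame), or a data frame of trials with
#'   columns `choice`, `win`, `loss` and optionally `run`.
#' @param reset_runs Reset the Q-state at every run boundary?
#' @return A `bandit_trace`: data frame with per-trial `choice`, `win`,
#'   `loss`, `delta_r`, `delta_p`, `log_lik`, policy probabilities
#'   `p1..p4` and pre-update values `qr1..qr4`, `qp1..qp4`; total
#'   log-likelihood in `attr(, "loglik")`.
#' @export
run_trials <- function(model, params, subject, reset_runs = FALSE) {
  trials <- subject_trials(subject)
  if (nrow(trials) == 0L) stop("empty dataset")
  check_obs(trials$choice, trials$win, trials$loss)
  th <- as_theta(params)
  validate_params(th, sens_ub = Inf)
  reset <- reset_vector(trials, reset_runs)
  tr <- cpp_subject_trace(unname(th), as.integer(trials$choice) - 1L,
                          as.numeric(trials$win), as.numeric(trials$loss),
                          reset, model$has_decay, model$has_lapse)
  out <- data.frame(trial = seq_len(nrow(trials)),
                    choice = trials$choice, win = trials$win,
                    loss = trials$loss,
                    delta_r = tr$delta_r, delta_p = tr$delta_p,
                    log_lik = tr$loglik)
  colnames(tr$choice_probs) <- paste0("p", 1:4)
  colnames(tr$q_reward) <- paste0("qr", 1:4)
  colnames(tr$q_punish) <- paste0("qp", 1:4)
  out <- cbind(out, tr$choice_probs, tr$q_reward, tr$q_punish)
  if (!is.null(trials$run)) out$run <- trials$run
  for (nm in c("cue_onset", "outcome_onset", "keypress_time"))
    if (!is.null(trials[[nm]])) out[[nm]] <- trials[[nm]]
  structure(out, loglik = tr$total, class = c("bandit_trace", "data.frame"))
}

subject_trials <- function(subject) {
  if (is.data.frame(subject)) subject
  else if (is.list(subject) && is.data.frame(subject$trials)) subject$trials
  else stop("`subject` must be a data frame of trials or a subject record")
}

reset_vector <- function(trials, reset_runs) {
  reset <- integer(nrow(trials))
  reset[1L] <- 1L
  if (reset_runs && !is.null(trials$run)) {
    r <- trials$run
    reset[which(r[-1L] != r[-length(r)]) + 1L] <- 1L
  }
  reset
}

#' Negative log-likelihood of a subject's choices under a model
#'
#' @inheritParams run_trials
#' @return Scalar negative log-likelihood with the per-trial log-likelihood
#'   vector (the leave-one-out unit) in `attr(, "pointwise")`.
#' @export
negative_log_likelihood <- function(model, params, subject,
                                    reset_runs = FALSE) {
  tr <- run_trials(model, params, subject, reset_runs = reset_runs)
  structure(-attr(tr, "loglik"), pointwise = tr$log_lik)
}

#' Export model-derived event regressors
#'
#' Builds the six FSL-style 3-column event tables per run: reward outcome,
#' punishment outcome, reward prediction error and punishment prediction
#' error at the outcome onset, plus cue-onset and keypress tables of no
#' interest (value 1). Traces are typically computed with group-mean fitted
#' parameters.
#'
#' @param trace A `bandit_trace` from [run_trials()] whose source dataset
#'   carried `outcome_onset` (and optionally `cue_onset`, `keypress_time`).
#' @param duration Constant event duration in seconds (default 0).
#' @param subject_id Identifier used in error messages.
#' @return Named list (one element per run) of named lists of data frames
#'   with columns `onset`, `duration`, `value`.
#' @export
export_regressors <- function(trace, duration = 0, subject_id = "subject") {
  if (is.null(trace$outcome_onset) || any(!is.finite(trace$outcome_onset)))
    stop("missing outcome onsets for ", subject_id,
         if (!is.null(trace$run)) paste0(" (runs ",
           paste(unique(trace$run[!is.finite(trace$outcome_onset %||% NA)]),
                 collapse = ", "), ")") else "")
  run <- if (is.null(trace$run)) rep(1L, nrow(trace)) else trace$run
  ev <- function(onset, value) data.frame(onset = onset, duration = duration,
                                          value = value)
  out <- lapply(split(seq_len(nrow(trace)), run), function(idx) {
    tt <- trace[idx, ]
    tabs <- list(
      reward_outcome     = ev(tt$outcome_onset, tt$win),
      punishment_outcome = ev(tt$outcome_onset, tt$loss),
      rpe                = ev(tt$outcome_onset, tt$delta_r),
      ppe                = ev(tt$outcome_onset, tt$delta_p))
    if (!is.null(tt$cue_onset))
      tabs$cue <- ev(tt$cue_onset, rep(1, nrow(tt)))
    if (!is.null(tt$keypress_time))
      tabs$keypress <- ev(tt$keypress_time, rep(1, nrow(tt)))
    tabs
  })
  names(out) <- paste0("run", names(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
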