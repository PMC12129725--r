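# Synthetic-data module: task schedules (reflected Gaussian random walks),
# outcome sampling, simulated agents and cohorts with known parameters,
# parcel time series with a planted hub, and clinical scores with planted
# correlations. Named RNG streams (derived from one seed per purpose) keep
# the components independently reproducible.

derive_seed <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Configuration of the task's probability random walks
#'
#' Win and loss probabilities of the four cues drift slowly across trials
#' as independent Gaussian random walks, reflected at the bounds.
#'
#' @param n_trials Total trials (default 240).
#' @param n_runs Number of runs the trials divide into (default 4).
#' @param step_sd Per-trial Gaussian step SD (default 0.02).
#' @param bounds Reflecting bounds within (0, 1) (default `c(0.2, 0.8)`).
#' @param init `"uniform"` (uniform within bounds) or a fixed length-4
#'   vector reused for both walk sets.
#' @param seed Integer seed.
#' @return A `walk_config` list.
#' @export
walk_config <- function(n_trials = 240, n_runs = 4, step_sd = 0.02,
                        bounds = c(0.2, 0.8), init = "uniform", seed = 1) {
  if (step_sd < 0) stop("step_sd must be >= 0")
  if (bounds[1] >= bounds[2] || bounds[1] <= 0 || bounds[2] >= 1)
    stop("bounds must satisfy 0 < low < high < 1")
  structure(list(n_trials = n_trials, n_runs = n_runs, n_cues = 4L,
                 step_sd = step_sd, bounds = bounds, init = init,
                 seed = seed),
            class = "walk_config")
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Generate a task schedule of win/loss probabilities
#'
#' Eight independent reflected Gaussian walks: win and loss probability per
#' cue, drawn from separate RNG streams so the two walk sets are
#' statistically independent.
#'
#' @param cfg A [walk_config()].
#' @return A `task_schedule`: list with `p_win` and `p_loss` (trials x 4
#'   matrices within bounds), `n_runs`, `run` (run index per trial).
#' @export
generate_schedule <- function(cfg = walk_config()) {
  stopifnot(inherits(cfg, "walk_config"))
  lo <- cfg$bounds[1]; hi <- cfg$bounds[2]
  one_set <- function(stream) {
    set.seed(derive_seed(cfg$seed, stream))
    p0 <- if (identical(cfg$init, "uniform")) runif(4, lo, hi)
          else rep_len(cfg$init, 4)
    steps <- matrix(rnorm(cfg$n_trials * 4, 0, cfg$step_sd), cfg$n_trials, 4)
    steps[1, ] <- 0
    reflect_into(apply(steps, 2, cumsum) + rep(p0, each = cfg$n_trials),
                 lo, hi)
  }
  run <- sort(rep_len(seq_len(cfg$n_runs), cfg$n_trials))
  structure(list(p_win = one_set("walk-win"), p_loss = one_set("walk-loss"),
                 n_runs = cfg$n_runs, run = run, config = cfg),
            class = "task_schedule")
}

#' Sample one trial's outcome from the schedule
#'
#' Win ~ Bernoulli(p_win), coded \{0, 1\}; loss ~ Bernoulli(p_loss), coded
#' \{0, -1\}; the draws are independent, so both-token and no-token
#' outcomes arise naturally.
#'
#' @param schedule A `task_schedule`.
#' @param trial Trial index.
#' @param choice Chosen cue 1..4.
#' @return List with `choice`, `win`, `loss`.
#' @export
sample_outcomes <- function(schedule, trial, choice) {
  if (trial < 1 || trial > nrow(schedule$p_win)) stop("trial out of range")
  if (!choice %in% 1:4) stop("choice out of range")
  list(choice = choice,
       win = as.numeric(runif(1) < schedule$p_win[trial, choice]),
       loss = -as.numeric(runif(1) < schedule$p_loss[trial, choice]))
}

#' Simulate one agent playing the bandit task
#'
#' Forward run of the learning model: per trial decay (if active), choice
#' sampled from the softmax/lapse policy, outcome sampled from the
#' schedule, then prediction-error update. Event onsets are synthesized on
#' a fixed trial grid so regressor export can be exercised.
#'
#' @param model A `bandit_model`.
#' @param params `bandit_params` or named parameter vector.
#' @param schedule A `task_schedule`.
#' @param seed Integer seed (separate streams for choices and outcomes).
#' @param trial_spacing Seconds between trials for synthetic onsets.
#' @param reset_runs Reset Q-values at run starts.
#' @return Long-format data frame (one row per trial) with columns
#'   `subject`, `run`, `trial`, `choice`, `win`, `loss`, `cue_onset`,
#'   `outcome_onset`, `keypress_time`.
#' @export
simulate_agent <- function(model, params, schedule, seed = 1,
                           trial_spacing = 6, reset_runs = FALSE) {
  stopifnot(inherits(model, "bandit_model"), inherits(schedule, "task_schedule"))
  th <- as_theta(params)
  validate_params(th, sens_ub = Inf)
  n <- nrow(schedule$p_win)
  run <- schedule$run
  set.seed(derive_seed(seed, "agent-choices"))
  u_choice <- runif(n)
  u_win <- runif(n)
  u_loss <- runif(n)
  qr <- qp <- rep(0, 4)
  choice <- integer(n); win <- numeric(n); loss <- numeric(n)
  for (t in seq_len(n)) {
    if (t > 1 && reset_runs && run[t] != run[t - 1]) qr <- qp <- rep(0, 4)
    if (model$has_decay) {
      dec <- apply_decay(th, qr, qp)
      qr <- dec$q_reward; qp <- dec$q_punish
    }
    p <- choice_probabilities(model, th, qr, qp)
    choice[t] <- findInterval(u_choice[t], cumsum(p)) + 1L
    choice[t] <- min(choice[t], 4L)
    win[t] <- as.numeric(u_win[t] < schedule$p_win[t, choice[t]])
    loss[t] <- -as.numeric(u_loss[t] < schedule$p_loss[t, choice[t]])
    pe <- scaled_prediction_errors(th, qr, qp, choice[t], win[t], loss[t])
    up <- update_values(th, qr, qp, choice[t], pe$delta_r, pe$delta_p)
    qr <- up$q_reward; qp <- up$q_punish
  }
  cue_onset <- (seq_len(n) - 1) * trial_spacing
  data.frame(subject = "agent", run = run, trial = seq_len(n),
             choice = choice, win = win, loss = loss,
             cue_onset = cue_onset,
             outcome_onset = cue_onset + trial_spacing / 2,
             keypress_time = cue_onset + trial_spacing / 4)
}

#' Group-level defaults for simulated cohorts
#'
#' Constrained-scale hypermeans and hyper-SDs per parameter for two
#' emulated groups, matching the magnitude of group-level estimates
#' reported for chronic-arthritis patients and healthy controls in this
#' task (punishment-sensitivity gap 9.953 - 5.778 = 4.175). For
#' independent-rate models the composite learning-rate rows stand in for
#' `lr_r`/`lr_p`.
#'
#' @param group `"arthritis"` or `"control"`.
#' @return Named list of `c(mean, sd)` pairs.
#' @export
cohort_defaults <- function(group = c("arthritis", "control")) {
  group <- match.arg(group)
  if (group == "arthritis")
    list(R = c(12.750, 5.911), P = c(9.953, 2.577),
         lr_r = c(0.679, 0.069), lr_p = c(0.547, 0.074),
         d = c(0.603, 0.311), xi = c(0.105, 0.043))
  else
    list(R = c(9.417, 5.031), P = c(5.778, 3.715),
         lr_r = c(0.590, 0.043), lr_p = c(0.570, 0.047),
         d = c(0.469, 0.261), xi = c(0.026, 0.003))
}

#' Simulate a cohort of agents with known group-level parameters
#'
#' Subject parameters are drawn from independent normals per parameter
#' (constrained scale), rejection-resampled into the admissible ranges,
#' then each subject plays the task on its own schedule.
#'
#' @param model A `bandit_model` or id.
#' @param n_subjects Cohort size (>= 2).
#' @param hyper Named list of `c(mean, sd)` per active parameter; defaults
#'   to [cohort_defaults()] for `group`.
#' @param group Group label (also selects defaults).
#' @param seed Integer seed.
#' @param walk Passed to [walk_config()] (list of overrides).
#' @param sens_ub Admissible sensitivity range upper bound.
#' @return List with `data` (a `bandit_data`), `true_params` (subjects x
#'   parameters matrix), `hyper` (the generating list).
#' @export
simulate_cohort <- function(model = 1, n_subjects = 12, hyper = NULL,
                            group = "arthritis", seed = 1, walk = list(),
                            sens_ub = 30) {
  if (!inherits(model, "bandit_model")) model <- bandit_model(model)
  if (n_subjects < 2L) stop("need >= 2 subjects")
  if (is.null(hyper)) {
    if (!group %in% c("arthritis", "control"))
      stop("no default hyperparameters for group '", group,
           "'; supply `hyper`")
    hyper <- cohort_defaults(group)
  }
  pn <- .param_names[model$active]
  miss <- setdiff(pn, names(hyper))
  if (length(miss)) stop("hyper lacks parameters: ",
                         paste(miss, collapse = ", "))
  ub <- c(R = sens_ub, P = sens_ub, lr_r = 1, lr_p = 1, d = 1, xi = 1)
  set.seed(derive_seed(seed, "cohort-params"))
  true_params <- sapply(pn, function(p) {
    m <- hyper[[p]][1]; s <- hyper[[p]][2]
    x <- rnorm(n_subjects, m, s)
    bad <- x < 0 | x > ub[[p]]
    while (any(bad)) {   # rejection resampling into the admissible range
      x[bad] <- rnorm(sum(bad), m, s)
      bad <- x < 0 | x > ub[[p]]
    }
    x
  })
  true_params <- matrix(true_params, nrow = n_subjects,
                        dimnames = list(sprintf("s%02d", seq_len(n_subjects)),
                                        pn))
  dfs <- lapply(seq_len(n_subjects), function(j) {
    th <- setNames(rep(0, 6), .param_names)
    th[pn] <- true_params[j, ]
    wcfg <- do.call(walk_config,
                    modifyList(list(seed = derive_seed(seed, paste0("walk", j))),
                               walk))
    agent <- simulate_agent(model, th, generate_schedule(wcfg),
                            seed = derive_seed(seed, paste0("agent", j)))
    agent$subject <- sprintf("s%02d", j)
    agent
  })
  data <- bandit_data(do.call(rbind, dfs), group = group)
  list(data = data, true_params = true_params, hyper = hyper,
       model = model)
}

#' Parcel time series with a planted hub
#'
#' Every parcel is idiosyncratic Gaussian noise; parcels linked to the hub
#' (including the hub itself) additionally carry `hub_strength` times a
#' shared signal, creating a block of correlated nodes centred on the hub.
#'
#' @param n_parcels,n_volumes Matrix dimensions.
#' @param hub_node Hub parcel index.
#' @param hub_strength Shared-signal loading (>= 0).
#' @param n_linked Number of parcels (besides the hub) carrying the shared
#'   signal (default 30).
#' @param seed Integer seed.
#' @return List with `ts` (parcels x volumes matrix, rows named
#'   `parcel###`), `hub_node`, `linked`.
#' @export
generate_parcel_timeseries <- function(n_parcels = 180, n_volumes = 260,
                                       hub_node = 1, hub_strength = 1,
                                       n_linked = 30, seed = 1) {
  if (hub_strength < 0) stop("hub_strength must be >= 0")
  if (hub_node > n_parcels) stop("hub_node out of range")
  set.seed(derive_seed(seed, "parcel-ts"))
  ts <- matrix(rnorm(n_parcels * n_volumes), n_parcels, n_volumes)
  shared <- rnorm(n_volumes)
  linked <- setdiff(seq_len(n_parcels), hub_node)
  linked <- linked[seq_len(min(n_linked, length(linked)))]
  # hub loads on the shared signal more strongly than its partners, so the
  # planted block centres on the hub
  ts[hub_node, ] <- ts[hub_node, ] + 1.5 * hub_strength * shared
  for (i in linked) ts[i, ] <- ts[i, ] + hub_strength * rnorm(1, 1, 0.1) * shared
  rownames(ts) <- sprintf("parcel%03d", seq_len(n_parcels))
  list(ts = ts, hub_node = hub_node, linked = linked)
}

#' Clinical scores with a planted correlation to a centrality vector
#'
#' `score = z(centrality) * target_r + noise * sqrt(1 - target_r^2)`, so
#' the sample correlation converges to `target_r` as n grows.
#'
#' @param centrality Numeric vector (non-constant).
#' @param target_r Target correlation in (-1, 1).
#' @param seed Integer seed.
#' @return Numeric score vector of the same length.
#' @export
generate_clinical_scores <- function(centrality, target_r = 0.6, seed = 1) {
  if (sd(centrality) == 0) stop("constant centrality vector")
  if (abs(target_r) >= 1) stop("target_r must lie in (-1, 1)")
  set.seed(derive_seed(seed, "clinical"))
  z <- as.numeric(scale(centrality))
  z * target_r + rnorm(length(z)) * sqrt(1 - target_r^2)
}
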