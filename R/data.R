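#' Assemble a cohort of bandit choice data
#'
#' Validates the task coding (choice 1..4, win in \{0, 1\}, loss in
#' \{0, -1\}) and splits a long-format table into per-subject records,
#' preserving trial order within subject.
#'
#' @param df Data frame with columns `subject`, `choice`, `win`, `loss` and
#'   optionally `group`, `run`, `trial`, `cue_onset`, `outcome_onset`,
#'   `keypress_time`.
#' @param group Optional group label; defaults to the table's `group`
#'   column (which must then be constant) or `"all"`.
#' @return A `bandit_data` object: list with `subjects` (named list of
#'   records, each holding `subject_id` and a `trials` data frame),
#'   `group`, `n_subjects`, `n_trials`.
#' @examples
#' sched <- generate_schedule(walk_config(n_trials = 40, n_runs = 2, seed = 1))
#' agent <- simulate_agent(bandit_model(5),
#'                         bandit_params(bandit_model(5), R = 6, P = 6,
#'                                       lr_r = 0.6, lr_p = 0.5),
#'                         sched, seed = 2)
#' bandit_data(agent)
#' @export
bandit_data <- function(df, group = NULL) {
  if (inherits(df, "bandit_data")) return(df)
  need <- c("subject", "choice", "win", "loss")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(df$choice %in% 1:4) | !(df$win %in% c(0, 1)) |
               !(df$loss %in% c(0, -1)))
  if (length(bad))
    stop("invalid task coding (choice 1..4, win {0,1}, loss {0,-1}) in rows: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  if (is.null(group)) {
    if (!is.null(df$group)) {
      g <- unique(as.character(df$group))
      if (length(g) > 1)
        stop("multiple groups present (", paste(g, collapse = ", "),
             "); split before calling bandit_data()")
      group <- g
    } else group <- "all"
  }
  keep <- intersect(c("run", "trial", "choice", "win", "loss",
                      "cue_onset", "outcome_onset", "keypress_time"),
                    names(df))
  subjects <- lapply(split(df[keep], df$subject), function(tt) {
    rownames(tt) <- NULL
    list(subject_id = NA_character_, trials = tt)
  })
  for (i in seq_along(subjects))
    subjects[[i]]$subject_id <- names(subjects)[i]
  structure(list(subjects = subjects, group = group,
                 n_subjects = length(subjects),
                 n_trials = vapply(subjects, function(s) nrow(s$trials), 0L)),
            class = "bandit_data")
}

#' @export
print.bandit_data <- function(x, ...) {
  cat(sprintf("Bandit choice data: %d subjects (group '%s'), %s trials each\n",
              x$n_subjects, x$group,
              paste(unique(x$n_trials), collapse = "/")))
  invisible(x)
}

#' Read behavioural choice data from a delimited file
#'
#' Expects columns `subject, group, run, trial, choice, win, loss` (onsets
#' optional) with the task coding choice 1..4, win \{0, 1\}, loss
#' \{0, -1\}; rows violating the coding are reported by number.
#'
#' @param path CSV (or TSV, by extension) file path.
#' @return A data frame; pass through [bandit_data()] per group to fit.
#' @export
read_behaviour <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject", "choice", "win", "loss")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  bad <- which(!(df$choice %in% 1:4) | !(df$win %in% c(0, 1)) |
               !(df$loss %in% c(0, -1)))
  if (length(bad))
    stop("invalid task coding in ", path, ", rows: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  df
}

#' Write behavioural choice data as CSV
#'
#' Inverse of [read_behaviour()]: a cohort is flattened to long format so
#' that `read_behaviour(write_behaviour(x, f))` round-trips.
#'
#' @param data A `bandit_data` object or long-format data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_behaviour <- function(data, path) {
  df <- if (inherits(data, "bandit_data")) {
    do.call(rbind, lapply(data$subjects, function(s) {
      cbind(subject = s$subject_id, group = data$group, s$trials,
            row.names = NULL)
    }))
  } else data
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write FSL-style 3-column EV files
#'
#' One whitespace-delimited text file (onset, duration, value; no header)
#' per regressor per run.
#'
#' @param regs Output of [export_regressors()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, typically the subject id.
#' @return Character vector of files written, invisibly.
#' @export
write_regressors <- function(regs, dir, prefix = "subject") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (run in names(regs)) {
    for (nm in names(regs[[run]])) {
      f <- file.path(dir, sprintf("%s_%s_%s.txt", prefix, run, nm))
      tab <- regs[[run]][[nm]]
      write.table(format(tab, trim = TRUE, scientific = FALSE), f,
                  row.names = FALSE, col.names = FALSE, quote = FALSE,
                  sep = " ")
      files <- c(files, f)
    }
  }
  invisible(files)
}
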