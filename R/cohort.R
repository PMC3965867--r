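#' Baseline covariates for one subject
#'
#' Covariate coding follows the study convention: `male` (1 = male,
#' 0 = female), `single` (1 = single, 0 = married), `skin_phenotype`
#' (1 = skin lesions, 0 = mucosal lesions). `age` is years at diagnosis,
#' `lymphocyte` the baseline lymphocyte laboratory value, and `follow_up`
#' the administrative follow-up time in months.
#'
#' @param age Age at diagnosis, years.
#' @param male,single,skin_phenotype Indicator variables, exactly 0 or 1.
#' @param lymphocyte Baseline lymphocyte value (laboratory units).
#' @param follow_up Follow-up duration in months, `> 0`.
#' @return A list of class `jm_covariates`.
#' @export
subject_covariates <- function(age, male, single, skin_phenotype,
                               lymphocyte, follow_up) {
  stopifnot(is.numeric(age), is.numeric(lymphocyte),
            is.numeric(follow_up), length(follow_up) == 1L)
  for (nm in c("male", "single", "skin_phenotype")) {
    v <- get(nm)
    if (!(length(v) == 1L && v %in% c(0, 1))) {
      stop("`", nm, "` must be exactly 0 or 1", call. = FALSE)
    }
  }
  if (!is.finite(follow_up) || follow_up <= 0) {
    stop("`follow_up` must be a positive number of months", call. = FALSE)
  }
  structure(list(age = as.numeric(age), male = as.numeric(male),
                 single = as.numeric(single),
                 skin_phenotype = as.numeric(skin_phenotype),
                 lymphocyte = as.numeric(lymphocyte),
                 follow_up = as.numeric(follow_up)),
            class = "jm_covariates")
}

#' Assemble the data for one subject
#'
#' Bundles baseline covariates, longitudinal titer measurements and the
#' episode (gap-time) history of a single subject. The transformed
#' response `y = ln(1 + titer)` is computed from `titer` when not supplied.
#'
#' @param subject_id Identifier, coerced to character.
#' @param covariates A [subject_covariates()] object.
#' @param observations Data frame with columns `t` (months since disease
#'   onset, `>= 0`) and `titer` (raw titer, `>= 0`); may have zero rows.
#' @param episodes Data frame with columns `k` (episode index, 1..K),
#'   `w` (gap time in months, `> 0`) and `delta` (1 = recurrence observed,
#'   0 = censored), e.g. as returned by [build_gap_times()].
#' @return A list of class `jm_subject`.
#' @export
subject_data <- function(subject_id, covariates, observations, episodes) {
  stopifnot(inherits(covariates, "jm_covariates"),
            is.data.frame(observations), is.data.frame(episodes))
  if (nrow(observations) > 0L) {
    if (!all(c("t", "titer") %in% names(observations))) {
      stop("`observations` needs columns `t` and `titer`", call. = FALSE)
    }
    observations$y <- transform_titer(observations$titer)
    observations <- observations[order(observations$t),
                                 c("t", "titer", "y"), drop = FALSE]
  } else {
    observations <- data.frame(t = numeric(0), titer = numeric(0),
                               y = numeric(0))
  }
  if (!all(c("k", "w", "delta") %in% names(episodes))) {
    stop("`episodes` needs columns `k`, `w` and `delta`", call. = FALSE)
  }
  episodes <- episodes[order(episodes$k), c("k", "w", "delta"), drop = FALSE]
  rownames(observations) <- rownames(episodes) <- NULL
  structure(list(subject_id = as.character(subject_id),
                 covariates = covariates,
                 observations = observations,
                 episodes = episodes),
            class = "jm_subject")
}

#' Construct a cohort from per-subject data
#'
#' @param subjects List of [subject_data()] objects with unique ids.
#' @param metadata Provenance list (source files, or generator seed and
#'   truth parameters).
#' @return A list of class `jm_cohort` with elements `subjects` (named by
#'   subject id) and `metadata`.
#' @export
new_cohort <- function(subjects, metadata = list()) {
  stopifnot(is.list(subjects), length(subjects) > 0L)
  ok <- vapply(subjects, inherits, logical(1), what = "jm_subject")
  if (!all(ok)) stop("all elements must be `jm_subject` objects", call. = FALSE)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(subjects) <- ids
  structure(list(subjects = subjects, metadata = metadata),
            class = "jm_cohort")
}

#' @export
print.jm_cohort <- function(x, ...) {
  n_obs <- sum(vapply(x$subjects, function(s) nrow(s$observations), integer(1)))
  epi <- lapply(x$subjects, function(s) s$episodes)
  n_epi <- sum(vapply(epi, nrow, integer(1)))
  n_ev <- sum(vapply(epi, function(e) sum(e$delta), numeric(1)))
  cat("Joint-model cohort: ", length(x$subjects), " subjects, ",
      n_obs, " titer measurements, ", n_epi, " episodes (",
      n_ev, " recurrences)\n", sep = "")
  invisible(x)
}

#' Convert calendar event times to gap-time episodes
#'
#' Recurrence times are recorded on the calendar scale with disease onset
#' at time 0; the hazard model works on gap times
#' `w_k = t_k - t_{k-1}`. Each observed recurrence yields an event episode
#' (`delta = 1`); if follow-up extends beyond the last event, the
#' remaining time becomes a final censored episode (`delta = 0`). The
#' returned gap times always sum exactly to `follow_up`.
#'
#' @param event_times Strictly increasing calendar times in months; the
#'   first element must be 0 (disease onset). Later elements are observed
#'   recurrence times.
#' @param follow_up End of follow-up in months, `>=` the last event time.
#' @return Data frame with columns `k`, `w`, `delta`.
#' @examples
#' build_gap_times(c(0, 3, 7), follow_up = 12)  # gaps 3, 4 and censored 5
#' @export
build_gap_times <- function(event_times, follow_up) {
  stopifnot(is.numeric(event_times), length(event_times) >= 1L,
            is.numeric(follow_up), length(follow_up) == 1L)
  if (event_times[1L] != 0) {
    stop("first event time must be 0 (disease onset)", call. = FALSE)
  }
  if (any(diff(event_times) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  last <- event_times[length(event_times)]
  if (!is.finite(follow_up) || follow_up < last) {
    stop("`follow_up` (", follow_up, ") is before the last event time (",
         last, ")", call. = FALSE)
  }
  w <- diff(event_times)
  delta <- rep(1, length(w))
  if (follow_up > last) {
    w <- c(w, follow_up - last)
    delta <- c(delta, 0)
  }
  if (length(w) == 0L) {
    stop("no episodes: a subject needs positive follow-up", call. = FALSE)
  }
  # force exact conservation against accumulated rounding in diff()
  w[length(w)] <- follow_up - sum(w[-length(w)])
  data.frame(k = seq_along(w), w = w, delta = delta)
}

#' Validate a cohort against the model's data invariants
#'
#' Collects (rather than throws on) every violation of the domain
#' invariants: transformed responses must equal `ln(1 + titer)`,
#' observation times must be finite, non-negative and within follow-up,
#' episodes must be consecutively indexed with positive gap times summing
#' to at most follow-up, censoring may occur only in a subject's last
#' episode, and indicators must be 0/1. The input is never modified.
#'
#' @param cohort A `jm_cohort`.
#' @param tol Numerical slack for time comparisons (months).
#' @param stop_on_error If `TRUE`, raise an error when any violation is
#'   found instead of returning the report.
#' @return Data frame of class `jm_validation` with columns `subject_id`,
#'   `rule`, `message`; zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort, tol = 1e-6, stop_on_error = FALSE) {
  stopifnot(inherits(cohort, "jm_cohort"))
  bad <- list()
  note <- function(id, rule, msg) {
    bad[[length(bad) + 1L]] <<- data.frame(subject_id = id, rule = rule,
                                           message = msg)
  }
  ids <- vapply(cohort$subjects, function(s) s$subject_id, character(1))
  if (length(ids) == 0L) note(NA_character_, "cohort_nonempty", "cohort has no subjects")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) note(d, "unique_subject_id", "duplicated subject_id")

  for (s in cohort$subjects) {
    id <- s$subject_id
    cv <- s$covariates
    for (nm in c("male", "single", "skin_phenotype")) {
      if (!cv[[nm]] %in% c(0, 1)) {
        note(id, "indicator_coding", paste0("`", nm, "` = ", cv[[nm]],
                                            " is not 0/1"))
      }
    }
    if (!is.finite(cv$follow_up) || cv$follow_up <= 0) {
      note(id, "follow_up_positive", paste("follow_up =", cv$follow_up))
    }
    ob <- s$observations
    if (nrow(ob) > 0L) {
      if (any(!is.finite(ob$t) | ob$t < 0)) {
        note(id, "time_nonnegative", "observation time negative or non-finite")
      }
      if (any(ob$t > cv$follow_up + tol)) {
        note(id, "time_within_follow_up",
             "observation time exceeds follow_up")
      }
      if (any(!is.finite(ob$titer) | ob$titer < 0)) {
        note(id, "titer_nonnegative", "titer negative or non-finite")
      }
      if (any(abs(ob$y - log1p(pmax(ob$titer, 0))) > 1e-8)) {
        note(id, "transform_consistency", "y != ln(1 + titer)")
      }
    }
    ep <- s$episodes
    if (nrow(ep) == 0L) {
      note(id, "episode_present", "subject has no episodes")
      next
    }
    if (!identical(as.numeric(ep$k), as.numeric(seq_len(nrow(ep))))) {
      note(id, "episode_indexing", "episode indices are not consecutive 1..K")
    }
    if (any(!is.finite(ep$w) | ep$w <= 0)) {
      note(id, "gap_positive", "gap time not strictly positive")
    }
    if (!all(ep$delta %in% c(0, 1))) {
      note(id, "event_indicator", "delta not 0/1")
    }
    cens <- which(ep$delta == 0)
    if (length(cens) > 1L || (length(cens) == 1L && cens != nrow(ep))) {
      note(id, "censoring_terminal",
           "censored episode (delta = 0) not in last position")
    }
    if (sum(ep$w) > cv$follow_up + tol) {
      note(id, "gap_sum_within_follow_up",
           sprintf("sum of gaps %.6f exceeds follow_up %.6f",
                   sum(ep$w), cv$follow_up))
    }
  }
  rep <- if (length(bad)) do.call(rbind, bad) else
    data.frame(subject_id = character(0), rule = character(0),
               message = character(0))
  rownames(rep) <- NULL
  class(rep) <- c("jm_validation", "data.frame")
  if (stop_on_error && nrow(rep) > 0L) {
    stop("invalid cohort: ", nrow(rep), " violation(s); first: [",
         rep$subject_id[1L], "] ", rep$rule[1L], " - ", rep$message[1L],
         call. = FALSE)
  }
  rep
}

#' @export
print.jm_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Cohort validation: no violations\n")
  } else {
    cat("Cohort validation: ", nrow(x), " violation(s)\n", sep = "")
    print.data.frame(x, ...)
  }
  invisible(x)
}
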