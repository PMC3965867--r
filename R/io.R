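# Flat-file interface: two CSV tables joined on subject_id.
#
# Longitudinal table: subject_id, time_months, igg_titer, age, male,
#   single, skin_phenotype, lymphocyte (baseline covariates repeated on
#   every row). Episode table: subject_id, episode, gap_months, event.
# Follow-up is not stored explicitly; it is the sum of a subject's gap
# times (the gap construction conserves total follow-up by design).

long_cols <- c("subject_id", "time_months", "igg_titer", "age", "male",
               "single", "skin_phenotype", "lymphocyte")
epi_cols <- c("subject_id", "episode", "gap_months", "event")

#' Read a cohort from the two CSV tables
#'
#' Parses, joins on `subject_id`, reconstructs follow-up as the sum of
#' each subject's gap times, recomputes `y = ln(1 + titer)`, and
#' validates the result (raising on any invariant violation).
#'
#' @param longitudinal_path CSV with columns `subject_id, time_months,
#'   igg_titer, age, male, single, skin_phenotype, lymphocyte`.
#' @param episodes_path CSV with columns `subject_id, episode,
#'   gap_months, event`.
#' @return A `jm_cohort`.
#' @export
read_cohort <- function(longitudinal_path, episodes_path) {
  for (p in c(longitudinal_path, episodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  lng <- read.csv(longitudinal_path, stringsAsFactors = FALSE)
  epi <- read.csv(episodes_path, stringsAsFactors = FALSE)
  miss <- setdiff(long_cols, names(lng))
  if (length(miss)) {
    stop(longitudinal_path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(epi_cols, names(epi))
  if (length(miss)) {
    stop(episodes_path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(lng) == 0L || nrow(epi) == 0L) {
    stop("empty cohort: both CSV files need at least one data row",
         call. = FALSE)
  }
  lng$subject_id <- as.character(lng$subject_id)
  epi$subject_id <- as.character(epi$subject_id)
  unknown <- setdiff(unique(epi$subject_id), unique(lng$subject_id))
  if (length(unknown)) {
    stop(episodes_path, ": subject_id without longitudinal rows: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  subjects <- lapply(unique(lng$subject_id), function(id) {
    li <- lng[lng$subject_id == id, , drop = FALSE]
    ei <- epi[epi$subject_id == id, , drop = FALSE]
    if (nrow(ei) == 0L) {
      stop("subject ", id, " has longitudinal rows but no episodes",
           call. = FALSE)
    }
    ei <- ei[order(ei$episode), , drop = FALSE]
    covs <- subject_covariates(age = li$age[1L], male = li$male[1L],
                               single = li$single[1L],
                               skin_phenotype = li$skin_phenotype[1L],
                               lymphocyte = li$lymphocyte[1L],
                               follow_up = sum(ei$gap_months))
    subject_data(id, covs,
                 data.frame(t = li$time_months, titer = li$igg_titer),
                 data.frame(k = ei$episode, w = ei$gap_months,
                            delta = ei$event))
  })
  cohort <- new_cohort(subjects,
                       metadata = list(longitudinal = longitudinal_path,
                                       episodes = episodes_path))
  validate_cohort(cohort, stop_on_error = TRUE)
  cohort
}

#' Write a cohort to the two CSV tables (plus a truth manifest)
#'
#' Inverse of [read_cohort()]. When the cohort metadata carries a
#' generator seed/truth (as cohorts from [simulate_cohort()] do) a
#' `manifest.json` with that provenance is written alongside.
#'
#' @param cohort A `jm_cohort`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"cohort"`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "jm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lng <- do.call(rbind, lapply(cohort$subjects, function(s) {
    if (nrow(s$observations) == 0L) return(NULL)
    cv <- s$covariates
    data.frame(subject_id = s$subject_id, time_months = s$observations$t,
               igg_titer = s$observations$titer, age = cv$age,
               male = cv$male, single = cv$single,
               skin_phenotype = cv$skin_phenotype,
               lymphocyte = cv$lymphocyte)
  }))
  epi <- do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, episode = s$episodes$k,
               gap_months = s$episodes$w, event = s$episodes$delta)
  }))
  paths <- c(longitudinal = file.path(dir, paste0(prefix, "_longitudinal.csv")),
             episodes = file.path(dir, paste0(prefix, "_episodes.csv")))
  # 17 significant digits so numeric values round-trip exactly
  fmt <- function(df) {
    df[] <- lapply(df, function(v) {
      if (is.numeric(v)) format(v, digits = 17, scientific = FALSE,
                                trim = TRUE) else v
    })
    df
  }
  write.csv(fmt(lng), paths[["longitudinal"]], row.names = FALSE,
            quote = FALSE)
  write.csv(fmt(epi), paths[["episodes"]], row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$metadata$truth)) {
    manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
    jsonlite::write_json(cohort$metadata, manifest, auto_unbox = TRUE,
                         digits = NA, null = "null")
    paths <- c(paths, manifest = manifest)
  }
  invisible(paths)
}
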