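#' Read a clinical table
#'
#' Tab-separated file with columns `sample_id`, `recurrence_status`
#' (`yes`/`no`/`unknown`), `time_to_recurrence_months` (present iff status is
#' `yes`; empty or NA otherwise) and `followup_months`.
#'
#' @param path Path to the clinical TSV.
#' @return A data.frame in the clinical record layout.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "recurrence_status", "time_to_recurrence_months",
              "followup_months")
  if (!all(needed %in% names(tab))) {
    stop("clinical table must have columns: ", paste(needed, collapse = ", "))
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab[, needed]
}

validate_clinical <- function(records) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$sample_id)) {
    stop("duplicate sample_id in clinical records: ",
         paste(unique(records$sample_id[duplicated(records$sample_id)]),
               collapse = ", "))
  }
  if (!all(records$recurrence_status %in% c("yes", "no", "unknown"))) {
    stop("recurrence_status must be one of 'yes', 'no', 'unknown'")
  }
  yes <- records$recurrence_status == "yes"
  if (anyNA(records$time_to_recurrence_months[yes])) {
    stop("time_to_recurrence_months required when recurrence_status is 'yes'")
  }
  times <- c(records$time_to_recurrence_months[yes], records$followup_months)
  if (any(stats::na.omit(times) < 0)) stop("negative time in clinical records")
  if (anyNA(records$followup_months)) stop("followup_months must be present")
  bad <- yes & records$time_to_recurrence_months > records$followup_months
  if (any(bad)) {
    stop("time_to_recurrence exceeds follow-up time for: ",
         paste(records$sample_id[bad], collapse = ", "))
  }
  invisible(records)
}

#' Label a cohort for classification and survival analysis
#'
#' Converts clinical records into the class labels used for classifier
#' training/evaluation, and into the event/censoring records used for
#' Kaplan-Meier analysis. The inclusion windows are:
#'
#' * positive (recurrence class): recurrence diagnosed within
#'   `recurrence_window` months (default 36, i.e. 3 years);
#' * negative (event-free class): no diagnosed recurrence and follow-up of at
#'   least `followup_min` months (default 48, i.e. 4 years);
#' * excluded from classification with a reason code: unknown recurrence
#'   status (`unknown_status`); any usable time of at most `early_exclusion`
#'   months (`first_month`); recurrence after the window (`late_recurrence`);
#'   no recurrence with follow-up short of `followup_min` (`short_followup`).
#'
#' Late recurrences and short-follow-up patients are excluded from
#' classification but kept in the survival records (as events and censored
#' observations, respectively), so that Kaplan-Meier curves can be computed on
#' the complete cohort. First-month and unknown-status patients are excluded
#' everywhere.
#'
#' Boundary semantics are frozen as: recurrence time <= `early_exclusion`
#' excluded; recurrence time <= `recurrence_window` positive; follow-up >=
#' `followup_min` negative.
#'
#' @param records Clinical data.frame (see [read_clinical()]).
#' @param recurrence_window Months; recurrences up to this time are positives.
#' @param followup_min Months; event-free follow-up needed for a negative.
#' @param early_exclusion Months; records with usable time at or below this
#'   are excluded entirely.
#' @return An object of class `cohort_labeling`: a list with `positives`,
#'   `negatives` (character vectors of sample ids), `excluded` (data.frame
#'   `sample_id`, `reason`) and `km` (data.frame `sample_id`, `event`, `time`
#'   of all samples usable for survival analysis).
#' @export
label_cohort <- function(records, recurrence_window = 36, followup_min = 48,
                         early_exclusion = 1) {
  validate_clinical(records)
  n <- nrow(records)
  status <- records$recurrence_status
  ttr <- records$time_to_recurrence_months
  fu <- records$followup_months
  usable_time <- ifelse(status == "yes", ttr, fu)

  category <- character(n)
  category[status == "unknown"] <- "unknown_status"
  early <- status != "unknown" & usable_time <= early_exclusion
  category[early] <- "first_month"
  rest <- category == ""
  category[rest & status == "yes" & ttr <= recurrence_window] <- "positive"
  category[rest & status == "yes" & ttr > recurrence_window] <- "late_recurrence"
  category[rest & status == "no" & fu >= followup_min] <- "negative"
  category[rest & status == "no" & fu < followup_min] <- "short_followup"

  in_km <- category %in% c("positive", "negative", "late_recurrence",
                           "short_followup")
  km <- data.frame(sample_id = records$sample_id[in_km],
                   event = status[in_km] == "yes",
                   time = usable_time[in_km],
                   stringsAsFactors = FALSE)
  excl <- !(category %in% c("positive", "negative"))
  structure(list(
    positives = records$sample_id[category == "positive"],
    negatives = records$sample_id[category == "negative"],
    excluded = data.frame(sample_id = records$sample_id[excl],
                          reason = category[excl], stringsAsFactors = FALSE),
    km = km,
    n_input = n
  ), class = "cohort_labeling")
}

#' @export
print.cohort_labeling <- function(x, ...) {
  cat(sprintf(
    "cohort_labeling: %d samples; %d positive, %d negative, %d excluded (%d in KM population)\n",
    x$n_input, length(x$positives), length(x$negatives), nrow(x$excluded),
    nrow(x$km)))
  invisible(x)
}

#' Survival records of a labeled cohort
#'
#' Returns the event/censoring table of every sample with a usable time:
#' the classification-included positives and negatives plus late recurrences
#' (events after the recurrence window) and short-follow-up censored samples.
#' `event` is `TRUE` iff a recurrence was ever diagnosed; `time` is the time
#' to recurrence for events and the follow-up time otherwise (months).
#'
#' @param labeling A `cohort_labeling` from [label_cohort()].
#' @return data.frame with columns `sample_id`, `event`, `time`.
#' @export
km_population <- function(labeling) {
  stopifnot(inherits(labeling, "cohort_labeling"))
  labeling$km
}

#' Per-cohort patient counts
#'
#' Summarizes labeled cohorts in the customary layout for multi-cohort
#' prognostic studies: total patients, event-free patients with at least the
#' minimum follow-up, and patients with recurrence within the window.
#'
#' @param labelings Named list of `cohort_labeling` objects (name = cohort).
#' @return data.frame with columns `cohort`, `n_total`,
#'   `n_no_recurrence_min_followup`, `n_recurrence_within_window`.
#' @export
cohort_summary <- function(labelings) {
  stopifnot(is.list(labelings), length(names(labelings)) == length(labelings))
  data.frame(
    cohort = names(labelings),
    n_total = vapply(labelings, function(l) l$n_input, integer(1L)),
    n_no_recurrence_min_followup =
      vapply(labelings, function(l) length(l$negatives), integer(1L)),
    n_recurrence_within_window =
      vapply(labelings, function(l) length(l$positives), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
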