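#' Lifespan cohort
#'
#' A cohort is a validated table of one record per animal (`animal_id`,
#' `group`, `age_months`, `event`) plus the age at which the intervention
#' (first injection) started.  Events are:
#' \describe{
#'   \item{`natural`}{death from natural causes at `age_months`.}
#'   \item{`embolic`}{death during an intravenous injection; the study's
#'     inclusion policy relabels these as natural deaths.}
#'   \item{`sacrificed`}{animal removed for tissue sampling; excluded from
#'     all survival statistics by the policy.}
#'   \item{`alive`}{right-censored at `age_months` (still alive when last
#'     observed).}
#' }
#'
#' @param records Data frame with columns `animal_id` (unique strings),
#'   `group` (`"control"` or `"experimental"`), `age_months` (nonnegative),
#'   `event` (one of the four labels above).
#' @param t_intervention Age in months at the first injection (default 15,
#'   the age at which about half the population has died).
#' @return An object of class `cohort`.
#' @export
cohort <- function(records, t_intervention = 15) {
  stopifnot(is.data.frame(records))
  required <- c("animal_id", "group", "age_months", "event")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[required]
  records$animal_id <- as.character(records$animal_id)
  records$group <- as.character(records$group)
  records$event <- as.character(records$event)
  stopifnot(is.numeric(t_intervention), t_intervention >= 0)
  validate_records(records)
  structure(list(records = records,
                 t_intervention = as.numeric(t_intervention)),
            class = "cohort")
}

validate_records <- function(records) {
  bad <- which(!records$group %in% c("control", "experimental"))
  if (length(bad))
    stop(sprintf("row %d (animal '%s'): unknown group '%s'", bad[1],
                 records$animal_id[bad[1]], records$group[bad[1]]))
  bad <- which(!records$event %in% c("natural", "embolic", "sacrificed",
                                     "alive"))
  if (length(bad))
    stop(sprintf("row %d (animal '%s'): unknown event '%s'", bad[1],
                 records$animal_id[bad[1]], records$event[bad[1]]))
  bad <- which(!is.finite(records$age_months) | records$age_months < 0)
  if (length(bad))
    stop(sprintf("row %d (animal '%s'): negative or missing age_months",
                 bad[1], records$animal_id[bad[1]]))
  dup <- duplicated(records$animal_id)
  if (any(dup))
    stop(sprintf("row %d: duplicate animal_id '%s'",
                 which(dup)[1], records$animal_id[which(dup)[1]]))
  invisible(records)
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$records$group, x$records$event)
  cat(sprintf("Cohort of %d animals (intervention at %g months)\n",
              nrow(x$records), x$t_intervention))
  print(tab)
  invisible(x)
}

#' Apply the study's mortality inclusion policy
#'
#' Removes sacrificed animals from the cohort (they are excluded from all
#' survival statistics) and relabels embolic deaths as natural deaths at
#' the recorded injection-day age.  All other records are unchanged; the
#' input cohort is not modified.  Idempotent.
#'
#' @param x A [cohort()].
#' @return A new `cohort` with the policy applied.
#' @export
apply_mortality_policy <- function(x) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  if (nrow(rec) == 0L) stop("empty cohort")
  rec <- rec[rec$event != "sacrificed", , drop = FALSE]
  rec$event[rec$event == "embolic"] <- "natural"
  rownames(rec) <- NULL
  cohort(rec, x$t_intervention)
}

#' Empirical survival step curve
#'
#' Builds the empirical fraction-surviving step function of a cohort:
#' starting from 1.0 at age 0, the curve drops by 1/n at every death age
#' (k/n for k tied deaths), where n counts all animals in the cohort.
#' `alive` records contribute to n but never drop the curve (simple right
#' censoring at last observation; no Kaplan--Meier reweighting).
#'
#' @param x A [cohort()] with the mortality policy already applied (an
#'   error is raised if sacrificed records remain) and at least one death.
#' @return A [step_curve()].
#' @export
empirical_survival <- function(x) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  if (any(rec$event == "sacrificed"))
    stop("sacrificed records present; run apply_mortality_policy() first")
  n <- nrow(rec)
  death_ages <- rec$age_months[rec$event %in% c("natural", "embolic")]
  if (length(death_ages) == 0L) stop("no events")
  tab <- table(sort(death_ages))
  ages <- as.numeric(names(tab))
  drops <- as.integer(tab)
  frac <- 1 - cumsum(drops) / n
  step_curve(c(0, ages), c(1, frac))
}

#' Empirical survival step curve container
#'
#' A right-continuous, nonincreasing step function of fraction surviving
#' versus age, stored as breakpoints `(age_months, fraction_surviving)`:
#' each row gives the fraction holding at and after that age, and the
#' first row is the anchor (0, 1).
#'
#' @param age_months Increasing breakpoint ages, starting at 0.
#' @param fraction_surviving Fractions in `[0, 1]`, nonincreasing,
#'   starting at 1.
#' @return An object of class `step_curve`.
#' @export
step_curve <- function(age_months, fraction_surviving) {
  stopifnot(length(age_months) == length(fraction_surviving),
            length(age_months) >= 1L)
  if (age_months[1] != 0 || fraction_surviving[1] != 1)
    stop("step curve must start at (age 0, fraction 1)")
  if (is.unsorted(age_months, strictly = TRUE))
    stop("breakpoint ages must be strictly increasing")
  if (any(diff(fraction_surviving) > 0))
    stop("fraction_surviving must be nonincreasing")
  if (any(fraction_surviving < 0 | fraction_surviving > 1))
    stop("fractions must lie in [0, 1]")
  structure(list(breakpoints = data.frame(
    age_months = as.numeric(age_months),
    fraction_surviving = as.numeric(fraction_surviving))),
    class = "step_curve")
}

#' @export
print.step_curve <- function(x, ...) {
  bp <- x$breakpoints
  cat(sprintf("Survival step curve: %d breakpoints, final fraction %.4g\n",
              nrow(bp), bp$fraction_surviving[nrow(bp)]))
  invisible(x)
}

#' Evaluate a step curve at given ages
#'
#' @param curve A [step_curve()].
#' @param t Ages in months (vectorized).
#' @return Fraction surviving at each age (right-continuous convention).
#' @export
step_at <- function(curve, t) {
  stopifnot(inherits(curve, "step_curve"), all(t >= 0))
  bp <- curve$breakpoints
  idx <- findInterval(t, bp$age_months)
  bp$fraction_surviving[idx]
}

#' Read / write a cohort lifespan table as CSV
#'
#' The CSV dialect is fixed: comma separator, dot decimal, UTF-8, and a
#' required header with the exact columns `animal_id`, `group`,
#' `age_months`, `event`.  Reading validates every row and reports the
#' offending data row (header = row 1) on failure; write-then-read is the
#' identity on valid cohorts.
#'
#' @param path CSV file path.
#' @param t_intervention Intervention age attached to the cohort on read.
#' @param x A [cohort()] to write.
#' @return `read_cohort_csv` returns a `cohort`; `write_cohort_csv`
#'   invisibly returns `path`.
#' @export
read_cohort_csv <- function(path, t_intervention = 15) {
  raw <- utils::read.csv(path, colClasses = c(animal_id = "character"),
                         fileEncoding = "UTF-8")
  required <- c("animal_id", "group", "age_months", "event")
  if (!identical(sort(names(raw)), sort(required)))
    stop("CSV header must contain exactly: ", paste(required, collapse = ", "))
  raw <- raw[required]
  out <- tryCatch(cohort(raw, t_intervention), error = function(e) {
    # validation indexes data rows from 1; report the file row (header = 1)
    msg <- sub("^row (\\d+)", "", conditionMessage(e))
    m <- regmatches(conditionMessage(e),
                    regexec("^row (\\d+)", conditionMessage(e)))[[1]]
    if (length(m) == 2L)
      stop(sprintf("%s: file row %d%s", path, as.integer(m[2]) + 1L, msg),
           call. = FALSE)
    stop(conditionMessage(e), call. = FALSE)
  })
  out
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(x$records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a step curve as CSV (columns age_months, fraction_surviving)
#'
#' @param curve A [step_curve()].
#' @param path CSV file path.
#' @export
write_step_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "step_curve"))
  utils::write.csv(curve$breakpoints, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
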