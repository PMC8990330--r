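#' Write a cohort to tidy CSV exchange files
#'
#' Emits three files into `dir`: `activity.csv` (long format:
#' participant_id, minute_index, intensity, reliability_flag),
#' `medications.csv` (participant_id, generic_name) and
#' `participants.csv` (demographics plus PHQ-9; missing PHQ-9 is an empty
#' field). The write -> read round trip is lossless: activity, labels
#' (re-derived from the medication table), demographics and PHQ-9 all
#' survive bitwise.
#'
#' @param cohort an `ssri_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ssri_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(cohort$activity)
  ids <- rownames(cohort$activity)
  act <- tibble::tibble(
    participant_id = rep(ids, each = MINUTES_PER_WEEK),
    minute_index = rep(0:(MINUTES_PER_WEEK - 1L), times = n),
    intensity = as.vector(t(cohort$activity)),
    reliability_flag = TRUE
  )
  readr::write_csv(act, file.path(dir, "activity.csv"), progress = FALSE)
  readr::write_csv(cohort$medications, file.path(dir, "medications.csv"),
                   progress = FALSE)
  part <- dplyr::mutate(cohort$demographics, phq9 = cohort$phq9)
  readr::write_csv(part, file.path(dir, "participants.csv"), progress = FALSE,
                   na = "")
  invisible(dir)
}

#' Read minute-level activity records into a cohort matrix
#'
#' Accepts a long-format table (data frame or CSV path) with columns
#' `participant_id`, `minute_index` (0-10,079), `intensity` (counts/min)
#' and optionally `reliability_flag`. Malformed rows (missing fields,
#' negative intensity, out-of-range or duplicated minute index) are dropped
#' and reported. Participants are then screened by the completeness policy:
#' `"strict-drop"` keeps only participants with all 10,080 minutes present
#' and every reliability flag true; `"zero-pad"` fills absent minutes with
#' zero counts.
#'
#' @param source data frame or path to a CSV file.
#' @param completeness_policy `"strict-drop"` (default) or `"zero-pad"`.
#' @return A participants x 10,080 numeric matrix (rownames = participant
#'   ids) with attributes `excluded` (ids dropped by the policy) and
#'   `row_errors` (tibble describing rejected rows).
#' @export
read_activity_records <- function(source,
                                  completeness_policy = c("strict-drop", "zero-pad")) {
  completeness_policy <- match.arg(completeness_policy)
  df <- if (is.character(source)) {
    readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  } else tibble::as_tibble(source)
  required <- c("participant_id", "minute_index", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("activity table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"reliability_flag" %in% names(df)) df$reliability_flag <- TRUE

  bad <- is.na(df$participant_id) | is.na(df$minute_index) | is.na(df$intensity) |
    df$intensity < 0 | df$minute_index < 0 | df$minute_index >= MINUTES_PER_WEEK
  row_errors <- tibble::tibble(row = which(bad),
                               reason = "missing field, negative intensity, or minute_index out of range")
  df <- df[!bad, , drop = FALSE]
  dup <- duplicated(df[c("participant_id", "minute_index")])
  if (any(dup)) {
    row_errors <- dplyr::bind_rows(
      row_errors, tibble::tibble(row = which(dup), reason = "duplicate minute_index"))
    df <- df[!dup, , drop = FALSE]
  }

  ids <- unique(df$participant_id)
  per <- split(df, factor(df$participant_id, levels = ids))
  excluded <- character(0)
  rows <- list()
  for (id in ids) {
    d <- per[[id]]
    complete <- nrow(d) == MINUTES_PER_WEEK && all(d$reliability_flag)
    if (completeness_policy == "strict-drop" && !complete) {
      excluded <- c(excluded, id)
      next
    }
    week <- numeric(MINUTES_PER_WEEK)
    week[d$minute_index + 1L] <- d$intensity
    rows[[id]] <- week
  }
  if (length(excluded))
    message(length(excluded), " participant(s) excluded by completeness policy '",
            completeness_policy, "'")
  if (!length(rows))
    stop("no participants survived the completeness policy", call. = FALSE)
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  attr(mat, "excluded") <- excluded
  attr(mat, "row_errors") <- row_errors
  mat
}

#' Derive the SSRI exposure label from a medication table
#'
#' A participant is labelled exposed iff any reported generic name contains
#' one of the five SSRI stems (SERTRALINE, ESCITALOPRAM, FLUOXETINE,
#' PAROXETINE, CITALOPRAM) after uppercasing, so salt suffixes
#' ("... HYDROCHLORIDE", "... OXALATE") match. Matching is stem-based,
#' order-independent and idempotent. Participants listed in
#' `participant_ids` but absent from the medication table are labelled
#' unexposed (no reported medications).
#'
#' @param meds data frame with `participant_id` and `generic_name`.
#' @param participant_ids optional character vector fixing the output rows
#'   and their order (e.g. the rownames of an activity matrix).
#' @return Tibble with `participant_id` and logical `ssri`.
#' @examples
#' classify_ssri(data.frame(participant_id = "a",
#'                          generic_name = "SERTRALINE HYDROCHLORIDE"))
#' @export
classify_ssri <- function(meds, participant_ids = NULL) {
  meds <- tibble::as_tibble(meds)
  stopifnot(all(c("participant_id", "generic_name") %in% names(meds)))
  if (any(!nzchar(meds$generic_name) | is.na(meds$generic_name)))
    stop("medication table contains empty generic names", call. = FALSE)
  nm <- toupper(meds$generic_name)
  hit <- Reduce(`|`, lapply(SSRI_STEMS, function(s) grepl(s, nm, fixed = TRUE)))
  pos <- unique(meds$participant_id[hit])
  if (is.null(participant_ids)) participant_ids <- unique(meds$participant_id)
  absent <- setdiff(participant_ids, meds$participant_id)
  if (length(absent))
    message(length(absent), " participant(s) absent from the medication table; labelled unexposed")
  tibble::tibble(participant_id = participant_ids,
                 ssri = participant_ids %in% pos)
}

#' Read PHQ-9 depression scores
#'
#' Accepts a data frame or CSV path with `participant_id` and `phq9`
#' (integer 0-27; empty field / NA = missing). Missing values are preserved
#' as explicit `NA`, never silently zeroed. Rows with scores outside
#' `[0, 27]` are rejected and reported via the `rejected` attribute.
#'
#' @param source data frame or CSV path.
#' @return Tibble with `participant_id` and numeric `phq9` (NA = missing),
#'   with attribute `rejected`.
#' @export
read_phq9 <- function(source) {
  df <- if (is.character(source)) {
    readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  } else tibble::as_tibble(source)
  stopifnot(all(c("participant_id", "phq9") %in% names(df)))
  bad <- !is.na(df$phq9) & (df$phq9 < 0 | df$phq9 > 27)
  rejected <- df[bad, , drop = FALSE]
  if (nrow(rejected))
    warning(nrow(rejected), " PHQ-9 row(s) outside [0, 27] rejected", call. = FALSE)
  out <- tibble::as_tibble(df[!bad, c("participant_id", "phq9")])
  attr(out, "rejected") <- rejected
  out
}

#' Read a cohort back from the tidy CSV exchange files
#'
#' Inverse of [write_cohort()]: reconstructs the activity matrix, re-derives
#' exposure labels from the medication table via [classify_ssri()], and
#' reads demographics and PHQ-9.
#'
#' @param dir directory produced by [write_cohort()].
#' @param completeness_policy passed to [read_activity_records()].
#' @return An `ssri_cohort` (without a generator config).
#' @export
read_cohort <- function(dir, completeness_policy = "strict-drop") {
  activity <- read_activity_records(file.path(dir, "activity.csv"),
                                    completeness_policy)
  meds <- readr::read_csv(file.path(dir, "medications.csv"),
                          show_col_types = FALSE, progress = FALSE)
  labels <- classify_ssri(meds, participant_ids = rownames(activity))
  part <- readr::read_csv(file.path(dir, "participants.csv"),
                          show_col_types = FALSE, progress = FALSE)
  part <- part[match(rownames(activity), part$participant_id), , drop = FALSE]
  phq <- read_phq9(part[c("participant_id", "phq9")])
  structure(
    list(activity = activity, labels = as.integer(labels$ssri),
         demographics = tibble::as_tibble(part[c("participant_id", "age", "sex", "race")]),
         phq9 = phq$phq9,
         medications = tibble::as_tibble(meds), config = NULL),
    class = "ssri_cohort"
  )
}

# ---- NHANES-format converters -----------------------------------------------
# These map raw NHANES 2005-2006 table layouts (as read from SAS transport
# files) onto the internal tidy formats. They accept plain data frames so the
# mapping is testable without transport files; read_nhanes_cohort() wires them
# to foreign::read.xport for real ingestion.

#' Convert an NHANES physical-activity-monitor table to activity records
#'
#' Maps PAXRAW-style columns (`SEQN`, `PAXN` 1-10,080 minute counter,
#' `PAXINTEN` device intensity, `PAXSTAT`/`PAXCAL` status and calibration
#' flags) to the internal long format; the reliability flag is true where
#' both status flags equal 1.
#'
#' @param df data frame in PAXRAW layout.
#' @return Tibble in the [read_activity_records()] input format.
#' @export
nhanes_activity_records <- function(df) {
  stopifnot(all(c("SEQN", "PAXN", "PAXINTEN") %in% names(df)))
  stat <- if ("PAXSTAT" %in% names(df)) df$PAXSTAT == 1 else TRUE
  cal <- if ("PAXCAL" %in% names(df)) df$PAXCAL == 1 else TRUE
  tibble::tibble(participant_id = as.character(df$SEQN),
                 minute_index = as.integer(df$PAXN) - 1L,
                 intensity = as.numeric(df$PAXINTEN),
                 reliability_flag = stat & cal)
}

#' Convert an NHANES prescription-medication table to a medication table
#'
#' Maps RXQ_RX-style columns (`SEQN`, `RXDDRUG` generic drug name) to the
#' internal medication format, dropping refusal/unknown sentinel rows.
#'
#' @param df data frame in RXQ_RX layout.
#' @return Tibble in the [classify_ssri()] input format.
#' @export
nhanes_medication_table <- function(df) {
  stopifnot(all(c("SEQN", "RXDDRUG") %in% names(df)))
  nm <- toupper(trimws(as.character(df$RXDDRUG)))
  keep <- !is.na(nm) & nzchar(nm) & !nm %in% c("77777", "99999", "REFUSED", "DON'T KNOW")
  tibble::tibble(participant_id = as.character(df$SEQN[keep]),
                 generic_name = nm[keep])
}

#' Convert an NHANES depression-screener table to PHQ-9 scores
#'
#' Sums the nine DPQ items (`DPQ010`-`DPQ090`, each 0-3; 7 = refused and
#' 9 = don't know are treated as missing). A participant's total is missing
#' if any item is missing.
#'
#' @param df data frame in DPQ layout.
#' @return Tibble in the [read_phq9()] input format.
#' @export
nhanes_phq9_scores <- function(df) {
  items <- sprintf("DPQ0%d0", 1:9)
  stopifnot("SEQN" %in% names(df), all(items %in% names(df)))
  m <- as.matrix(df[items])
  m[m %in% c(7, 9)] <- NA
  total <- rowSums(m)
  tibble::tibble(participant_id = as.character(df$SEQN), phq9 = as.numeric(total))
}

#' Read a cohort from NHANES SAS transport files
#'
#' Optional real-data ingestion path: reads PAXRAW, RXQ_RX, DPQ and DEMO
#' transport (XPT) files with `foreign::read.xport()` and assembles an
#' `ssri_cohort` via the converters above.
#'
#' @param paxraw,rxq,dpq,demo paths to the four transport files.
#' @param completeness_policy passed to [read_activity_records()].
#' @return An `ssri_cohort`.
#' @export
read_nhanes_cohort <- function(paxraw, rxq, dpq, demo,
                               completeness_policy = "strict-drop") {
  if (!requireNamespace("foreign", quietly = TRUE))
    stop("package 'foreign' is required to read SAS transport files", call. = FALSE)
  activity <- read_activity_records(
    nhanes_activity_records(foreign::read.xport(paxraw)), completeness_policy)
  meds <- nhanes_medication_table(foreign::read.xport(rxq))
  labels <- classify_ssri(meds, participant_ids = rownames(activity))
  phq <- read_phq9(nhanes_phq9_scores(foreign::read.xport(dpq)))
  demo_df <- foreign::read.xport(demo)
  demographics <- tibble::tibble(
    participant_id = as.character(demo_df$SEQN),
    age = as.numeric(demo_df$RIDAGEYR),
    sex = ifelse(demo_df$RIAGENDR == 2, "female", "male"),
    race = c("Mexican American", "Other Hispanic", "White", "Black",
             "Other")[demo_df$RIDRETH1]
  )
  ids <- rownames(activity)
  structure(
    list(activity = activity, labels = as.integer(labels$ssri),
         demographics = demographics[match(ids, demographics$participant_id), ],
         phq9 = phq$phq9[match(ids, phq$participant_id)],
         medications = meds, config = NULL),
    class = "ssri_cohort"
  )
}
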