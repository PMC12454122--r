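# Reading and writing the survey tables.

RESPONDENT_COLUMNS <- c("id", "age", "gender", "education", "zone",
                        "community_role", "religion", "pref_daughter",
                        "pref_daughter_in_law", "is_reporter",
                        "empirical_expectation_men",
                        "empirical_expectation_women",
                        "normative_expectation")

NOMINATION_COLUMNS <- c("ego", "generator", "alter", "kin", "relationship")

EDUCATION_LEVELS <- c("none", "some_primary", "completed_primary",
                      "some_secondary_plus")
NORMATIVE_LEVELS <- c("approve", "disapprove", "none_of_their_business")

#' Read respondent and nomination tables
#'
#' Reads the two delimited survey tables: one row per respondent (covariates,
#' preference answers, norm-expectation answers, network-reporter flag) and
#' one row per nomination (ego, name generator, matched alter id or
#' `UNMATCHED`, kin flag, relationship label).  Unmatched alters are retained
#' and flagged, mirroring survey practice where a named alter could not be
#' assigned a census id.
#'
#' @param respondent_path,nomination_path paths to UTF-8 CSV files with
#'   header rows.
#' @return list with data frames `respondents` and `nominations`; the
#'   nomination table gains a logical `unmatched` column.
#' @export
read_tables <- function(respondent_path, nomination_path) {
  resp <- read.csv(respondent_path, stringsAsFactors = FALSE,
                   colClasses = c(id = "character"))
  missing_cols <- setdiff(RESPONDENT_COLUMNS, names(resp))
  if (length(missing_cols)) {
    stop("respondent table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(resp$id)) {
    stop("duplicate respondent id: ", resp$id[duplicated(resp$id)][1L])
  }
  bad_age <- which(!is.na(resp$age) & resp$age < 15)
  if (length(bad_age)) {
    warning("age below 15 at data row(s) ",
            paste(head(bad_age, 5L), collapse = ", "))
  }
  dec <- c("empirical_expectation_men", "empirical_expectation_women")
  for (col in dec) {
    bad <- which(!is.na(resp[[col]]) &
                   (resp[[col]] %% 10 != 0 | resp[[col]] < 0 | resp[[col]] > 100))
    if (length(bad)) {
      stop("column ", col, " must hold deciles 0..100; bad data row(s): ",
           paste(head(bad, 5L), collapse = ", "))
    }
  }
  resp$is_reporter <- as.logical(resp$is_reporter)

  nom <- read.csv(nomination_path, stringsAsFactors = FALSE,
                  colClasses = c(ego = "character", alter = "character"))
  missing_cols <- setdiff(NOMINATION_COLUMNS, names(nom))
  if (length(missing_cols)) {
    stop("nomination table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_gen <- which(!nom$generator %in% GENERATORS)
  if (length(bad_gen)) {
    stop("unknown generator label at nomination row(s): ",
         paste(head(bad_gen, 5L), collapse = ", "))
  }
  nom$kin <- as.logical(nom$kin)
  nom$unmatched <- is.na(nom$alter) | nom$alter == UNMATCHED
  non_rep <- setdiff(unique(nom$ego), resp$id[resp$is_reporter])
  if (length(non_rep)) {
    warning("nominations by non-reporter or unknown ego(s): ",
            paste(head(non_rep, 5L), collapse = ", "))
  }
  cap_tab <- table(nom$ego, nom$generator)
  if (any(cap_tab > 10L)) {
    warning("more than 10 nominations for some (ego, generator) pairs")
  }
  list(respondents = resp, nominations = nom)
}

#' Write respondent and nomination tables
#'
#' Writes the same CSV schema [read_tables()] consumes, so that a write/read
#' round trip returns identical records.
#'
#' @param respondents,nominations data frames in the package schema.
#' @param respondent_path,nomination_path output paths.
#' @export
write_tables <- function(respondents, nominations,
                         respondent_path, nomination_path) {
  write.csv(respondents[RESPONDENT_COLUMNS], respondent_path,
            row.names = FALSE)
  write.csv(nominations[NOMINATION_COLUMNS], nomination_path,
            row.names = FALSE)
  invisible(c(respondent_path, nomination_path))
}

#' Classify practice preference from the two survey answers
#'
#' A respondent is classified `pro` if they answered yes to wanting the
#' practice for either a (hypothetical) daughter or daughter-in-law, and
#' `anti` only if they answered no to both.  Vectorized; a missing answer
#' yields `NA` (callers exclude and log such records).
#'
#' @param pref_daughter,pref_daughter_in_law character vectors of
#'   `"yes"`/`"no"` answers.
#' @return factor with levels `anti`, `pro`.
#' @export
classify_preference <- function(pref_daughter, pref_daughter_in_law) {
  chk <- function(x) {
    x <- tolower(as.character(x))
    x[!x %in% c("yes", "no")] <- NA
    x
  }
  d <- chk(pref_daughter)
  dl <- chk(pref_daughter_in_law)
  out <- ifelse(is.na(d) | is.na(dl), NA_character_,
                ifelse(d == "yes" | dl == "yes", "pro", "anti"))
  n_missing <- sum(is.na(out))
  if (n_missing) {
    message(n_missing, " record(s) with missing preference answers -> NA")
  }
  factor(out, levels = c("anti", "pro"))
}

#' Binary preference vector aligned to a roster
#'
#' @param respondents respondent data frame.
#' @param roster ids defining vector order (default: respondent row order).
#' @return integer 0/1 vector (1 = pro); `NA` where unclassifiable.
#' @export
preference_vector <- function(respondents, roster = respondents$id) {
  idx <- match(as.character(roster), respondents$id)
  if (anyNA(idx)) stop("roster id absent from respondent table")
  pref <- classify_preference(respondents$pref_daughter[idx],
                              respondents$pref_daughter_in_law[idx])
  as.integer(pref == "pro")
}

#' Assemble the raw reports for a double-sampled generator
#'
#' @param nominations nomination data frame.
#' @param pair `"money"` (borrow_out / borrow_in) or `"advice"`.
#' @param reporter_set ids of respondents who were asked network questions.
#' @return object of class `double_sampled_reports` holding the out-side and
#'   in-side nomination tables and the reporter set.
#' @export
double_sampled_reports <- function(nominations, pair = c("money", "advice"),
                                   reporter_set) {
  pair <- match.arg(pair)
  gens <- if (pair == "money") c("borrow_out", "borrow_in")
          else c("advice_out", "advice_in")
  out_reports <- nominations[nominations$generator == gens[1L], , drop = FALSE]
  in_reports <- nominations[nominations$generator == gens[2L], , drop = FALSE]
  reporter_set <- as.character(reporter_set)
  bad <- setdiff(c(out_reports$ego, in_reports$ego), reporter_set)
  if (length(bad)) {
    stop("report by ego outside the reporter set: ", bad[1L])
  }
  structure(list(out_reports = out_reports, in_reports = in_reports,
                 reporter_set = reporter_set, pair = pair,
                 generators = gens),
            class = "double_sampled_reports")
}

#' @export
print.double_sampled_reports <- function(x, ...) {
  cat(sprintf(
    "<double_sampled_reports '%s': %d out-reports, %d in-reports, %d reporters>\n",
    x$pair, nrow(x$out_reports), nrow(x$in_reports), length(x$reporter_set)))
  invisible(x)
}
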