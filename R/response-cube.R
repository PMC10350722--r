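#' Construct a response cube
#'
#' The central data container: patient x item x timepoint ordinal responses
#' with arm assignment and optional treatment-expectancy ratings. Stored in
#' long form with integer scores on each instrument's native scale; all
#' rescaling happens downstream so that raw provenance stays auditable.
#'
#' @param responses `data.frame` with columns `patient_id`, `timepoint`,
#'   `item_id`, `score` (integer, on the item's native scale).
#' @param arms `data.frame` with columns `patient_id`, `arm` (`"PT"` or
#'   `"ET"`); must cover every patient appearing in `responses`.
#' @param expectancy Optional `data.frame` with columns `patient_id`,
#'   `expectancy_pt`, `expectancy_et` (0-100 ratings; `NA` allowed).
#' @param scales Named list of [scale_definition()]s the responses are
#'   validated against.
#' @param timepoints Ordered character vector of assessment occasions;
#'   defaults to the occasions present, ordered
#'   baseline < week5 < week6 < (others).
#' @return An object of class `response_cube` with elements `responses`,
#'   `arms` (named character vector), `expectancy`, `scales`, `timepoints`,
#'   `patients`, and `items` (the flat [item_table()]).
#' @details Validation is total: every response is checked against its
#'   item's admissible range, duplicates and unknown item ids are rejected,
#'   and arm labels must partition the patients. Missing responses are
#'   simply absent rows (the trial design measures only the QIDS at week 5).
#' @export
response_cube <- function(responses, arms, expectancy = NULL,
                          scales = builtin_scales(), timepoints = NULL) {
  req <- c("patient_id", "timepoint", "item_id", "score")
  if (!all(req %in% names(responses)))
    stop("responses must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  responses <- responses[req]
  responses$patient_id <- as.character(responses$patient_id)
  responses$timepoint <- as.character(responses$timepoint)
  responses$item_id <- as.character(responses$item_id)
  responses$score <- as.integer(responses$score)

  if (!all(c("patient_id", "arm") %in% names(arms)))
    stop("arms must have columns patient_id, arm", call. = FALSE)
  arm_vec <- as.character(arms$arm)
  names(arm_vec) <- as.character(arms$patient_id)
  bad_arm <- setdiff(unique(arm_vec), c("PT", "ET"))
  if (length(bad_arm))
    stop("arm labels must be 'PT' or 'ET'; found: ",
         paste(bad_arm, collapse = ", "), call. = FALSE)

  items <- item_table(scales)
  patients <- unique(responses$patient_id)
  missing_arm <- setdiff(patients, names(arm_vec))
  if (length(missing_arm))
    stop("no arm assignment for patient(s): ",
         paste(missing_arm, collapse = ", "), call. = FALSE)

  if (is.null(timepoints)) {
    tp <- unique(responses$timepoint)
    canon <- c("baseline", "week5", "week6")
    timepoints <- c(intersect(canon, tp), setdiff(tp, canon))
  }

  if (!is.null(expectancy)) {
    reqe <- c("patient_id", "expectancy_pt", "expectancy_et")
    if (!all(reqe %in% names(expectancy)))
      stop("expectancy must have columns ", paste(reqe, collapse = ", "),
           call. = FALSE)
    expectancy <- expectancy[reqe]
    expectancy$patient_id <- as.character(expectancy$patient_id)
    for (col in c("expectancy_pt", "expectancy_et")) {
      v <- expectancy[[col]]
      if (any(!is.na(v) & (v < 0 | v > 100)))
        stop(col, " must lie in [0, 100]", call. = FALSE)
    }
  }

  cube <- structure(
    list(responses = responses, arms = arm_vec, expectancy = expectancy,
         scales = scales, timepoints = timepoints, patients = patients,
         items = items),
    class = "response_cube")
  validate_cube(cube)
  cube
}

#' Validate a response cube
#'
#' Re-runs all container invariants: known item ids, in-range scores
#' (errors name the offending patient/item/timepoint), no duplicated
#' (patient, item, timepoint) cells, complete arm assignment.
#'
#' @param cube A [response_cube()].
#' @return `cube`, invisibly, if valid; otherwise an error.
#' @export
validate_cube <- function(cube) {
  stopifnot(inherits(cube, "response_cube"))
  r <- cube$responses
  it <- cube$items

  unknown <- setdiff(unique(r$item_id), it$item_id)
  if (length(unknown))
    stop("unknown item id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  idx <- match(r$item_id, it$item_id)
  bad <- which(is.na(r$score) | r$score < it$min_score[idx] |
                 r$score > it$max_score[idx])
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf(
      "score %s out of range [%d, %d] for patient '%s', item '%s', timepoint '%s' (%d offending cell(s))",
      r$score[b], it$min_score[idx[b]], it$max_score[idx[b]],
      r$patient_id[b], r$item_id[b], r$timepoint[b], length(bad)),
      call. = FALSE)
  }

  key <- paste(r$patient_id, r$item_id, r$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    d <- r[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "duplicate response for patient '%s', item '%s', timepoint '%s'",
      d$patient_id, d$item_id, d$timepoint), call. = FALSE)
  }

  if (length(setdiff(cube$patients, names(cube$arms))))
    stop("arm labels do not cover all patients", call. = FALSE)
  invisible(cube)
}

#' @export
print.response_cube <- function(x, ...) {
  cat("<response_cube> ", length(x$patients), " patients (",
      sum(x$arms[x$patients] == "PT"), " PT / ",
      sum(x$arms[x$patients] == "ET"), " ET), ",
      nrow(x$responses), " responses, timepoints: ",
      paste(x$timepoints, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-patient relative treatment expectancy
#'
#' PT expectancy minus ET expectancy, on the 100-point rating scale; `NA`
#' where either rating is missing. A positive value means the patient
#' predicted more improvement under psilocybin therapy than escitalopram.
#'
#' @param cube A [response_cube()] carrying expectancy ratings.
#' @return Named numeric vector (one element per patient in the cube).
#' @export
relative_expectancy <- function(cube) {
  out <- rep(NA_real_, length(cube$patients))
  names(out) <- cube$patients
  ex <- cube$expectancy
  if (!is.null(ex)) {
    idx <- match(cube$patients, ex$patient_id)
    out[] <- ex$expectancy_pt[idx] - ex$expectancy_et[idx]
  }
  out
}

#' Extract a patients x items score matrix at one timepoint
#'
#' @param cube A [response_cube()].
#' @param item_ids Character vector of items (columns, in this order).
#' @param timepoint Single timepoint.
#' @param patients Optional subset of patients (rows); default all.
#' @return Numeric matrix with `NA` for absent responses, dimnames
#'   patients x items.
#' @export
score_matrix <- function(cube, item_ids, timepoint, patients = NULL) {
  if (is.null(patients)) patients <- cube$patients
  r <- cube$responses[cube$responses$timepoint == timepoint &
                        cube$responses$item_id %in% item_ids &
                        cube$responses$patient_id %in% patients, ]
  m <- matrix(NA_real_, length(patients), length(item_ids),
              dimnames = list(patients, item_ids))
  m[cbind(match(r$patient_id, patients), match(r$item_id, item_ids))] <- r$score
  m
}

#' Read item-level responses from CSV
#'
#' Two layouts are supported. Long: one row per response with columns
#' `patient_id, arm, timepoint, item_id, score`. Wide: one row per patient
#' with `patient_id, arm` followed by one `<item_id>@<timepoint>` column per
#' measured cell (empty cells = missing). An optional companion CSV supplies
#' expectancy ratings (`patient_id, expectancy_pt, expectancy_et`).
#'
#' @param path CSV file path.
#' @param format `"long_csv"` or `"wide_csv"`.
#' @param expectancy_path Optional expectancy CSV path.
#' @param scales Scale definitions used for validation.
#' @return A validated [response_cube()].
#' @export
load_responses <- function(path, format = c("long_csv", "wide_csv"),
                           expectancy_path = NULL,
                           scales = builtin_scales()) {
  format <- match.arg(format)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (format == "long_csv") {
    req <- c("patient_id", "arm", "timepoint", "item_id", "score")
    if (!all(req %in% names(raw)))
      stop("long CSV must have columns ", paste(req, collapse = ", "),
           call. = FALSE)
    responses <- raw[c("patient_id", "timepoint", "item_id", "score")]
    arms <- unique(raw[c("patient_id", "arm")])
    if (anyDuplicated(arms$patient_id))
      stop("inconsistent arm labels within a patient", call. = FALSE)
  } else {
    if (!all(c("patient_id", "arm") %in% names(raw)))
      stop("wide CSV must start with patient_id, arm", call. = FALSE)
    cell_cols <- setdiff(names(raw), c("patient_id", "arm"))
    bad <- cell_cols[!grepl("@", cell_cols, fixed = TRUE)]
    if (length(bad))
      stop("wide CSV columns must be <item_id>@<timepoint>; offending: ",
           paste(bad, collapse = ", "), call. = FALSE)
    parts <- strsplit(cell_cols, "@", fixed = TRUE)
    long <- do.call(rbind, lapply(seq_along(cell_cols), function(i) {
      data.frame(patient_id = as.character(raw$patient_id),
                 timepoint = parts[[i]][2L], item_id = parts[[i]][1L],
                 score = raw[[cell_cols[i]]])
    }))
    responses <- long[!is.na(long$score), ]
    arms <- raw[c("patient_id", "arm")]
  }
  expectancy <- if (!is.null(expectancy_path))
    utils::read.csv(expectancy_path, stringsAsFactors = FALSE)
  response_cube(responses, arms, expectancy = expectancy, scales = scales)
}

#' Write a response cube to long CSV
#'
#' Inverse of [load_responses()] (long layout): round-tripping preserves
#' every response, arm label and expectancy rating exactly.
#'
#' @param cube A [response_cube()].
#' @param path Output CSV path.
#' @param expectancy_path Optional path for the expectancy companion CSV.
#' @return `path`, invisibly.
#' @export
write_responses <- function(cube, path, expectancy_path = NULL) {
  r <- cube$responses
  out <- data.frame(patient_id = r$patient_id,
                    arm = unname(cube$arms[r$patient_id]),
                    timepoint = r$timepoint, item_id = r$item_id,
                    score = r$score)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(expectancy_path) && !is.null(cube$expectancy))
    utils::write.csv(cube$expectancy, expectancy_path, row.names = FALSE)
  invisible(path)
}
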