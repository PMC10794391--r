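#' Read and write item-level response tables
#'
#' The item-level CSV schema has one row per participant with columns
#' `participant_id`, `device` (`headphones` or `loudspeakers`),
#' `self_report`, and 0/1 trial outcome columns `testA_1..testA_6`,
#' `testB_1..testB_6`, `testC_1..testC_6` (tests may be absent).
#'
#' @param path File path.
#' @return `read_responses()` returns the responses tibble.
#' @export
read_responses <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(out) == 0) stop_input("responses file is empty.")
  if (!"device" %in% names(out)) stop_input("responses need a `device` column.")
  bad <- setdiff(unique(out$device), c("headphones", "loudspeakers"))
  if (length(bad) > 0) {
    stop_input(sprintf("unknown device label(s): %s.", paste(bad, collapse = ", ")))
  }
  out
}

#' @rdname read_responses
#' @param responses A responses tibble (e.g. from [simulate_cohort()]).
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(responses, path)
  invisible(path)
}

#' Read and write characteristics tables
#'
#' A characteristics table maps each test and threshold to its sensitivity
#' and specificity (proportions) with group sizes: columns `test`,
#' `threshold`, `sen`, `spe`, `n_pos`, `n_neg`; extra columns (confidence
#' bounds, counts) are preserved. Written and re-read tables are
#' identical.
#'
#' @param path File path.
#' @return `read_characteristics()` returns the table as a tibble.
#' @export
read_characteristics <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("test", "threshold", "sen", "spe")
  if (!all(need %in% names(out))) {
    stop_input(sprintf("characteristics table needs columns %s.",
                       paste(need, collapse = ", ")))
  }
  check_prob(out$sen, "sen"); check_prob(out$spe, "spe")
  out
}

#' @rdname read_characteristics
#' @param chars A characteristics tibble.
#' @export
write_characteristics <- function(chars, path) {
  readr::write_csv(chars, path)
  invisible(path)
}

#' Format and parse procedure spec strings
#'
#' A procedure is written `"EK<ek>:<slot><threshold>,..."`, e.g.
#' `"EK11:A5,B5,C6"` for the majority vote of Test A at threshold 5,
#' Test B at 5 and Test C at 6. Slots without a threshold are omitted.
#'
#' @param ek Evaluation key(s).
#' @param thr_a,thr_b,thr_c Thresholds (NA for uninvolved slots).
#' @return `format_procedure()` a character vector; `parse_procedure()` a
#'   tibble with columns `ek`, `thr_a`, `thr_b`, `thr_c`.
#' @examples
#' format_procedure(11, 5, 5, 6)
#' parse_procedure("EK12:A6,B2,C6")
#' @export
format_procedure <- function(ek, thr_a = NA, thr_b = NA, thr_c = NA) {
  mapply(function(ek, a, b, c) {
    parts <- c(
      if (!is.na(a)) paste0("A", a),
      if (!is.na(b)) paste0("B", b),
      if (!is.na(c)) paste0("C", c)
    )
    paste0("EK", ek, ":", paste(parts, collapse = ","))
  }, ek, thr_a, thr_b, thr_c, USE.NAMES = FALSE)
}

#' @rdname format_procedure
#' @param spec Procedure spec string(s).
#' @export
parse_procedure <- function(spec) {
  purrr::map(spec, function(s) {
    m <- regmatches(s, regexec("^EK([0-9]+):([ABC][0-9](,[ABC][0-9])*)$", s))[[1]]
    if (length(m) == 0) stop_input(sprintf("malformed procedure spec `%s`.", s))
    ek <- as.integer(m[2])
    thr <- c(A = NA_integer_, B = NA_integer_, C = NA_integer_)
    for (part in strsplit(m[3], ",")[[1]]) {
      thr[substr(part, 1, 1)] <- as.integer(substr(part, 2, nchar(part)))
    }
    tibble(ek = ek, thr_a = thr[["A"]], thr_b = thr[["B"]], thr_c = thr[["C"]])
  }) |> bind_rows()
}

#' Write a screening plan report as JSON
#'
#' Serialises a [plan_screening()] result to JSON with the ranked
#' candidate table, the planning parameters, and a provenance block
#' (package version, seed, characteristics source) so planning decisions
#' are auditable. With `timestamp = FALSE` identical inputs produce
#' byte-identical reports.
#'
#' @param plan A `screening_plan`.
#' @param path Output path.
#' @param seed Seed used to produce candidate characteristics, if any.
#' @param source Free-text provenance of the candidate characteristics
#'   (e.g. `"fixture:mainstudy"` or `"simulation"`).
#' @param timestamp Include a timestamp field (default TRUE).
#' @return The path, invisibly.
#' @export
write_plan_report <- function(plan, path, seed = NULL,
                              source = "user-supplied", timestamp = TRUE) {
  stopifnot(inherits(plan, "screening_plan"))
  report <- list(
    parameters = list(
      strategy = plan$strategy, criterion = plan$criterion, k = plan$k,
      theta = plan$theta, pi_hat = plan$pi_hat, sigma_hat = plan$sigma_hat,
      utilities = as.list(unclass(plan$weights))
    ),
    selected = as.list(tidy(plan)[1, ]),
    candidates = tidy(plan),
    provenance = c(
      list(package = "screenplan",
           version = as.character(utils::packageVersion("screenplan")),
           characteristics_source = source, seed = seed),
      if (timestamp) list(timestamp = format(Sys.time(), tz = "UTC"))
    )
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
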