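#' The NERVE-ML reporting checklist schema
#'
#' Loads the bundled machine-readable transcription of the NERVE-ML
#' (neural engineering reproducibility and validity essentials for machine
#' learning) checklist: five categories -- data and train/test definition,
#' parameter and hyperparameter selection, performance metrics, scientific
#' conclusions, and future use of results -- each a set of yes/no/unclear/
#' not-applicable items. The schema ships as a versioned data file so
#' wording updates do not require code changes.
#'
#' @return A list with `name`, `schema_version`, `answers`, and
#'   `categories` (each with `id`, `title`, optional `note`, and `items`).
#' @export
nerve_checklist <- function() {
  path <- system.file("extdata", "nerve_ml_checklist.json",
                      package = "nerveaudit")
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
}

checklist_item_ids <- function(schema = nerve_checklist()) {
  unlist(lapply(schema$categories, function(cat)
    vapply(cat$items, `[[`, character(1), "id")))
}

#' Validate a set of checklist responses
#'
#' Responses reference items by id and answer with one of the four printed
#' options (`Yes`, `No`, `Unclear`, `N/A`), optionally with a free-text
#' note. The verdict lists unanswered items; a rendering groups answered
#' items under the five category headers.
#'
#' @param responses a data frame with columns `id`, `answer`, and
#'   optionally `note`; or a named list/vector mapping item id to answer.
#' @return A list of class `checklist_verdict`: `complete` (logical),
#'   `missing` (unanswered item ids), `responses` (normalized data frame),
#'   `rendered` (markdown text).
#' @export
checklist_validate <- function(responses) {
  schema <- nerve_checklist()
  ids <- checklist_item_ids(schema)
  if (!is.data.frame(responses)) {
    responses <- data.frame(id = names(responses),
                            answer = unlist(lapply(responses, function(r)
                              if (is.list(r)) r$answer else r)),
                            stringsAsFactors = FALSE)
  }
  assert_that(all(c("id", "answer") %in% names(responses)),
              "responses need 'id' and 'answer' columns")
  if (!"note" %in% names(responses)) responses$note <- ""
  unknown <- setdiff(responses$id, ids)
  if (length(unknown))
    fail("unknown checklist item id(s): ", paste(unknown, collapse = ", "))
  bad <- setdiff(unique(responses$answer), schema$answers)
  if (length(bad))
    fail("invalid answer(s) ", paste(bad, collapse = ", "),
         "; must be one of ", paste(schema$answers, collapse = ", "))
  dup <- responses$id[duplicated(responses$id)]
  if (length(dup))
    fail("duplicated response(s) for item(s): ", paste(dup, collapse = ", "))
  missing <- setdiff(ids, responses$id)
  structure(list(complete = length(missing) == 0,
                 missing = missing,
                 responses = responses,
                 rendered = render_checklist(responses, schema)),
            class = "checklist_verdict")
}

render_checklist <- function(responses = NULL, schema = nerve_checklist()) {
  ans_of <- if (is.null(responses)) character() else
    stats::setNames(responses$answer, responses$id)
  note_of <- if (is.null(responses)) character() else
    stats::setNames(responses$note, responses$id)
  lines <- c(paste0("# ", schema$name),
             paste0("Schema version ", schema$schema_version), "")
  for (cat in schema$categories) {
    lines <- c(lines, paste0("## ", cat$title), "")
    if (!is.null(cat$note)) lines <- c(lines, paste0("_", cat$note, "_"), "")
    lines <- c(lines, "| Question | Answer | Note |", "|---|---|---|")
    for (item in cat$items) {
      ans <- if (item$id %in% names(ans_of)) ans_of[[item$id]] else ""
      note <- if (item$id %in% names(note_of)) note_of[[item$id]] else ""
      lines <- c(lines, paste0("| ", item$question, " | ", ans, " | ",
                               note, " |"))
    }
    lines <- c(lines, "")
  }
  paste(lines, collapse = "\n")
}

#' @export
print.checklist_verdict <- function(x, ...) {
  if (x$complete) cat("checklist complete:", nrow(x$responses), "items\n")
  else cat("checklist incomplete; missing:",
           paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
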