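#' Construct a cohort table
#'
#' A cohort table holds one row per participant: a unique `participant_id`,
#' one `item_<id>` column per checklist item coded 0 (absent), 1 (present) or
#' `NA` (missing), a binary `outcome` column (1 = prospective event, never
#' missing), and any number of additional subgroup label columns.
#'
#' @param data `data.frame` in the layout above.
#' @param definition Optional [checklist_definition()]; when supplied, a
#'   response column is required for every item of the definition.
#' @return `data` with class `cohort_table` prepended.
#' @export
cohort_table <- function(data, definition = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(data)) {
    stop("cohort lacks a `participant_id` column", call. = FALSE)
  }
  if (anyDuplicated(data$participant_id)) {
    stop("participant_id values must be unique", call. = FALSE)
  }
  if (!"outcome" %in% names(data)) {
    stop("cohort lacks an `outcome` column", call. = FALSE)
  }
  if (anyNA(data$outcome)) {
    stop("`outcome` must never be missing", call. = FALSE)
  }
  if (!is_binary01(data$outcome)) {
    stop("`outcome` must be coded 0/1", call. = FALSE)
  }
  item_cols <- grep("^item_", names(data), value = TRUE)
  if (length(item_cols) == 0L) {
    stop("cohort has no `item_<id>` response columns", call. = FALSE)
  }
  for (col in item_cols) {
    v <- data[[col]]
    if (!all(v %in% c(0, 1) | is.na(v))) {
      stop("column `", col, "` must be coded 0/1/NA", call. = FALSE)
    }
  }
  if (!is.null(definition)) {
    stopifnot(inherits(definition, "checklist_definition"))
    need <- paste0("item_", definition$items$id)
    miss <- setdiff(need, item_cols)
    if (length(miss)) {
      stop("cohort lacks response columns for definition items: ",
           paste(sub("^item_", "", miss), collapse = ", "), call. = FALSE)
    }
  }
  class(data) <- unique(c("cohort_table", class(data)))
  data
}

#' Read a cohort from CSV/TSV
#'
#' Expects a header row with columns `participant_id`, `item_<id>` in
#' \{0, 1, NA\}, `outcome` in \{0, 1\}, plus optional subgroup columns.
#' `NA` (or an empty field) means a missing item response.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param definition Optional [checklist_definition()] to validate coverage.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, definition = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  data <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  data$participant_id <- as.character(data$participant_id)
  cohort_table(data, definition)
}

#' Write a cohort to CSV
#'
#' @param cohort A [cohort_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "NA")
  invisible(path)
}

# item response columns present in a cohort
cohort_item_ids <- function(cohort) {
  sub("^item_", "", grep("^item_", names(cohort), value = TRUE))
}
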