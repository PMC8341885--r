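#' Construct a checklist definition
#'
#' A checklist definition is the scoring rule itself: a set of dichotomous
#' items with positive integer weights, a contiguous set of named risk bands
#' over the integer score range, and the missing-data policy. The total score
#' of a participant is the sum of weights of the items marked present;
#' missing responses contribute nothing (the `"absent_as_zero"` policy, the
#' only one supported, mirrors how such checklists are scored at the bedside).
#'
#' @param name Checklist name.
#' @param version Free-text version label.
#' @param items `data.frame` with columns `id` (unique character), `label`
#'   (character) and `weight` (positive integer).
#' @param bands `data.frame` with columns `name`, `lower`, `upper`. Bands must
#'   be sorted, non-overlapping, contiguous from 0, and the last band must be
#'   unbounded above (`upper = NA`).
#' @param missing_policy Only `"absent_as_zero"` is supported.
#'
#' @return An object of class `checklist_definition`.
#' @seealso [load_definition()], [drs_definition()], [sad_persons_definition()]
#' @export
checklist_definition <- function(name, version, items, bands,
                                 missing_policy = "absent_as_zero") {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  bands <- as.data.frame(bands, stringsAsFactors = FALSE)
  for (col in c("id", "label", "weight")) {
    if (!col %in% names(items)) {
      stop("definition items lack required field `", col, "`", call. = FALSE)
    }
  }
  for (col in c("name", "lower", "upper")) {
    if (!col %in% names(bands)) {
      stop("definition bands lack required field `", col, "`", call. = FALSE)
    }
  }
  if (anyDuplicated(items$id)) {
    dup <- items$id[duplicated(items$id)][1L]
    stop("duplicate item id in field `items.id`: '", dup, "'", call. = FALSE)
  }
  w <- items$weight
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 1) || any(w != round(w))) {
    stop("field `items.weight` must contain positive integers", call. = FALSE)
  }
  items$weight <- as.integer(w)
  missing_policy <- match.arg(missing_policy, "absent_as_zero")

  bands$lower <- as.integer(bands$lower)
  bands$upper <- suppressWarnings(as.integer(bands$upper))
  n_bands <- nrow(bands)
  if (n_bands < 1L) stop("at least one band is required", call. = FALSE)
  if (bands$lower[1L] != 0L) {
    stop("field `bands`: first band must start at 0", call. = FALSE)
  }
  if (!is.na(bands$upper[n_bands])) {
    stop("field `bands`: last band must be unbounded above (upper = null)",
         call. = FALSE)
  }
  if (n_bands > 1L) {
    up <- bands$upper[-n_bands]
    lo <- bands$lower[-1L]
    if (anyNA(up)) {
      stop("field `bands`: only the last band may be unbounded", call. = FALSE)
    }
    if (any(lo != up + 1L)) {
      bad <- which(lo != up + 1L)[1L]
      stop("field `bands`: gap or overlap between band '",
           bands$name[bad], "' and band '", bands$name[bad + 1L], "'",
           call. = FALSE)
    }
    if (any(bands$upper[-n_bands] < bands$lower[-n_bands])) {
      stop("field `bands`: band upper bound below lower bound", call. = FALSE)
    }
  }

  structure(
    list(name = as.character(name), version = as.character(version),
         items = items[, c("id", "label", "weight")],
         bands = bands[, c("name", "lower", "upper")],
         missing_policy = missing_policy),
    class = "checklist_definition"
  )
}

#' Maximum attainable checklist score
#'
#' @param definition A [checklist_definition()].
#' @return Integer: the sum of all item weights.
#' @export
max_score <- function(definition) {
  stopifnot(inherits(definition, "checklist_definition"))
  sum(definition$items$weight)
}

#' @export
print.checklist_definition <- function(x, ...) {
  cat("<checklist_definition> ", x$name, " (", x$version, ")\n", sep = "")
  n_dbl <- sum(x$items$weight > 1L)
  cat("  ", nrow(x$items), " items (", n_dbl, " with weight > 1), max score ",
      max_score(x), "\n", sep = "")
  rng <- ifelse(is.na(x$bands$upper),
                paste0(">=", x$bands$lower),
                paste0(x$bands$lower, "-", x$bands$upper))
  cat("  bands: ", paste0(x$bands$name, " [", rng, "]", collapse = ", "),
      "\n", sep = "")
  cat("  missing policy:", x$missing_policy, "\n")
  invisible(x)
}

#' Load a checklist definition from JSON or YAML
#'
#' The document must carry fields `name`, `version`,
#' `items[{id,label,weight}]`, `bands[{name,lower,upper|null}]` and
#' `missing_policy`. JSON is the canonical format; YAML is accepted.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [checklist_definition()].
#' @export
load_definition <- function(path) {
  if (!file.exists(path)) stop("definition file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported definition format: .", ext, call. = FALSE)
  )
  for (fld in c("name", "version", "items", "bands")) {
    if (is.null(doc[[fld]])) {
      stop("definition document lacks field `", fld, "`", call. = FALSE)
    }
  }
  items <- doc$items
  bands <- doc$bands
  if (!is.data.frame(items)) {
    items <- do.call(rbind, lapply(items, function(it) {
      data.frame(id = it$id, label = it$label %||% it$id,
                 weight = it$weight, stringsAsFactors = FALSE)
    }))
  }
  if (!is.data.frame(bands)) {
    bands <- do.call(rbind, lapply(bands, function(b) {
      data.frame(name = b$name, lower = b$lower,
                 upper = if (is.null(b$upper)) NA_integer_ else b$upper,
                 stringsAsFactors = FALSE)
    }))
  }
  checklist_definition(
    name = doc$name, version = doc$version, items = items, bands = bands,
    missing_policy = doc$missing_policy %||% "absent_as_zero"
  )
}

#' Write a checklist definition to JSON
#'
#' @param definition A [checklist_definition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_definition <- function(definition, path) {
  stopifnot(inherits(definition, "checklist_definition"))
  doc <- list(
    name = definition$name, version = definition$version,
    items = definition$items, bands = definition$bands,
    missing_policy = definition$missing_policy
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}

#' The packaged 23-item risk checklist definition
#'
#' The default checklist: 23 dichotomous risk-factor items, four of them
#' double-weighted (lifetime suicide attempt, lifetime psychiatric
#' hospitalization, lifetime nonsuicidal self-injury, lifetime borderline
#' personality disorder), for a maximum attainable score of 27, and six named
#' risk bands (0-2 lowest through >=15 highest).
#'
#' @return A [checklist_definition()].
#' @export
drs_definition <- function() {
  load_definition(system.file("extdata", "drs_checklist.json",
                              package = "checkrisk", mustWork = TRUE))
}

#' The packaged SAD PERSONS checklist definition
#'
#' The classic 10-item mnemonic screen, every item weight 1 (maximum score
#' 10), included as a comparison checklist configuration.
#'
#' @return A [checklist_definition()].
#' @export
sad_persons_definition <- function() {
  load_definition(system.file("extdata", "sad_persons.json",
                              package = "checkrisk", mustWork = TRUE))
}
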