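#' Read volunteer classifications
#'
#' Reads a table of volunteer classifications in either of two dialects and
#' returns the canonical in-memory form: a data frame with one row per point
#' mark and one (mark-less) row per classification without marks.
#'
#' The canonical columns are `classification_id`, `volunteer_id`,
#' `anonymous`, `image_id`, `presence_answer` (`"yes"`/`"no"`),
#' `mark_index`, `category`, `x`, `y`. Mark fields are `NA` on mark-less
#' rows. Coordinates are continuous pixels with the origin at the top-left
#' corner (x rightward, y downward).
#'
#' Rows are de-duplicated on (`volunteer_id`, `image_id`), keeping the
#' classification with the earliest `classification_id` (first-submission
#' semantics). A volunteer is anonymous if an explicit `anonymous` column
#' says so or if the id carries the platform prefix `"not-logged-in"`.
#'
#' @param path Path to a CSV file.
#' @param dialect `"flat_csv"` (the canonical layout above, one row per
#'   mark) or `"zooniverse_export"` (platform export with a JSON
#'   `annotations` payload column).
#' @param mapping For the export dialect, a list mapping payload fields to
#'   the canonical form; see [zooniverse_mapping()].
#' @return Classifications data frame as described above.
#' @seealso [write_classifications()], [read_gold_standard()]
#' @export
read_classifications <- function(path,
                                 dialect = c("flat_csv", "zooniverse_export"),
                                 mapping = zooniverse_mapping()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) return(empty_classifications())
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (dialect == "flat_csv") {
    cls <- parse_flat_csv(raw)
  } else {
    cls <- parse_zooniverse_export(raw, mapping)
  }
  validate_classifications(cls)
  dedup_classifications(cls)
}

flat_csv_columns <- c("classification_id", "volunteer_id", "anonymous",
                      "image_id", "presence_answer", "mark_index",
                      "category", "x", "y")

parse_flat_csv <- function(raw) {
  missing <- setdiff(flat_csv_columns, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_classifications())
  data.frame(
    classification_id = raw$classification_id,
    volunteer_id      = raw$volunteer_id,
    anonymous         = parse_anonymous(raw$anonymous, raw$volunteer_id),
    image_id          = raw$image_id,
    presence_answer   = tolower(raw$presence_answer),
    mark_index        = suppressWarnings(as.integer(raw$mark_index)),
    category          = ifelse(raw$category == "" | is.na(raw$category),
                               NA_character_, raw$category),
    x                 = suppressWarnings(as.numeric(raw$x)),
    y                 = suppressWarnings(as.numeric(raw$y)),
    stringsAsFactors  = FALSE
  )
}

parse_anonymous <- function(flag, volunteer_id) {
  anon <- tolower(trimws(flag)) %in% c("true", "t", "1", "yes")
  anon | startsWith(volunteer_id, "not-logged-in")
}

empty_classifications <- function() {
  data.frame(classification_id = character(), volunteer_id = character(),
             anonymous = logical(), image_id = character(),
             presence_answer = character(), mark_index = integer(),
             category = character(), x = numeric(), y = numeric(),
             stringsAsFactors = FALSE)
}

validate_classifications <- function(cls) {
  bad <- !is.na(cls$category) & !(cls$category %in% MARK_CATEGORIES)
  if (any(bad)) {
    stop("unknown mark category label(s): ",
         paste(unique(cls$category[bad]), collapse = ", "), call. = FALSE)
  }
  if (!all(cls$presence_answer %in% c("yes", "no"))) {
    stop("presence_answer must be 'yes' or 'no'", call. = FALSE)
  }
  marked_no <- cls$presence_answer == "no" & !is.na(cls$mark_index)
  if (any(marked_no)) {
    stop("classification(s) answering 'no' carry marks: ",
         paste(unique(cls$classification_id[marked_no]), collapse = ", "),
         call. = FALSE)
  }
  invisible(cls)
}

# keep, for each (volunteer_id, image_id), the classification with the
# earliest classification_id; idempotent
dedup_classifications <- function(cls) {
  if (nrow(cls) == 0) return(cls)
  ids <- unique(cls$classification_id)
  ids <- ids[order_ids(ids)]
  first <- !duplicated(cls[match(ids, cls$classification_id),
                           c("volunteer_id", "image_id")])
  keep <- ids[first]
  out <- cls[cls$classification_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write volunteer classifications
#'
#' Writes the canonical classifications data frame to disk in either
#' dialect. Writing then reading back is lossless in both dialects.
#'
#' @inheritParams read_classifications
#' @param cls Classifications data frame (see [read_classifications()]).
#' @return `path`, invisibly.
#' @export
write_classifications <- function(cls, path,
                                  dialect = c("flat_csv", "zooniverse_export"),
                                  mapping = zooniverse_mapping()) {
  dialect <- match.arg(dialect)
  if (dialect == "flat_csv") {
    out <- cls
    out$anonymous <- ifelse(out$anonymous, "true", "false")
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    write_zooniverse_export(cls, path, mapping)
  }
  invisible(path)
}

#' Zooniverse export mapping
#'
#' Field mapping for the platform-export dialect: the presence question is a
#' question-type task and the marks a point-type task whose tool labels are
#' translated to the canonical categories.
#'
#' @param classification_id,volunteer,image,annotations Column names in the
#'   export CSV.
#' @param presence_task,marks_task Task keys inside the annotation payload.
#' @param yes_value Payload value meaning "present".
#' @param tool_labels Named character vector translating tool labels to
#'   canonical categories.
#' @return A named list used by [read_classifications()].
#' @export
zooniverse_mapping <- function(classification_id = "classification_id",
                               volunteer = "user_name",
                               image = "subject_ids",
                               annotations = "annotations",
                               presence_task = "T0",
                               marks_task = "T1",
                               yes_value = "Yes",
                               tool_labels = c("Adult male" = "adult_male",
                                               "Other" = "other",
                                               "Lek" = "lek",
                                               "Partial iguana" = "partial")) {
  list(classification_id = classification_id, volunteer = volunteer,
       image = image, annotations = annotations,
       presence_task = presence_task, marks_task = marks_task,
       yes_value = yes_value, tool_labels = tool_labels)
}

parse_zooniverse_export <- function(raw, mapping) {
  need <- unlist(mapping[c("classification_id", "volunteer", "image",
                           "annotations")])
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_classifications())
  label_to_cat <- mapping$tool_labels
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    ann <- tryCatch(
      jsonlite::fromJSON(raw[[mapping$annotations]][i],
                         simplifyVector = FALSE),
      error = function(e) NULL)
    if (is.null(ann)) {
      stop("malformed annotation payload in row ", i, call. = FALSE)
    }
    tasks <- vapply(ann, function(a) a$task %||% "", character(1))
    pres <- ann[[match(mapping$presence_task, tasks)]]
    if (is.null(pres)) {
      stop("malformed annotation payload in row ", i,
           ": no presence task", call. = FALSE)
    }
    presence <- if (identical(pres$value, mapping$yes_value)) "yes" else "no"
    marks <- list()
    mt <- match(mapping$marks_task, tasks)
    if (!is.na(mt)) marks <- ann[[mt]]$value
    n <- length(marks)
    base <- data.frame(
      classification_id = raw[[mapping$classification_id]][i],
      volunteer_id = raw[[mapping$volunteer]][i],
      anonymous = startsWith(raw[[mapping$volunteer]][i], "not-logged-in"),
      image_id = raw[[mapping$image]][i],
      presence_answer = presence,
      mark_index = if (n) seq_len(n) else NA_integer_,
      category = NA_character_, x = NA_real_, y = NA_real_,
      stringsAsFactors = FALSE
    )
    if (n) {
      base$x <- vapply(marks, function(m) as.numeric(m$x), numeric(1))
      base$y <- vapply(marks, function(m) as.numeric(m$y), numeric(1))
      lab <- vapply(marks, function(m) as.character(m$tool_label), character(1))
      cat <- unname(label_to_cat[lab])
      if (anyNA(cat)) {
        stop("unknown mark category label(s): ",
             paste(unique(lab[is.na(cat)]), collapse = ", "), call. = FALSE)
      }
      base$category <- cat
    }
    rows[[i]] <- base
  }
  do.call(rbind, rows)
}

write_zooniverse_export <- function(cls, path, mapping) {
  label_of <- stats::setNames(names(mapping$tool_labels),
                              mapping$tool_labels)
  ids <- unique(cls$classification_id)
  out <- data.frame(classification_id = ids, user_name = "",
                    subject_ids = "", annotations = "",
                    stringsAsFactors = FALSE)
  names(out) <- c(mapping$classification_id, mapping$volunteer,
                  mapping$image, mapping$annotations)
  for (j in seq_along(ids)) {
    rows <- cls[cls$classification_id == ids[j], , drop = FALSE]
    out[[mapping$volunteer]][j] <- rows$volunteer_id[1]
    out[[mapping$image]][j] <- rows$image_id[1]
    pres <- list(task = mapping$presence_task,
                 value = if (rows$presence_answer[1] == "yes")
                   mapping$yes_value else "No")
    tasks <- list(pres)
    marked <- rows[!is.na(rows$mark_index), , drop = FALSE]
    if (nrow(marked)) {
      marked <- marked[order(marked$mark_index), , drop = FALSE]
      pts <- lapply(seq_len(nrow(marked)), function(k) {
        list(x = marked$x[k], y = marked$y[k],
             tool_label = unname(label_of[marked$category[k]]))
      })
      tasks <- c(tasks, list(list(task = mapping$marks_task, value = pts)))
    }
    out[[mapping$annotations]][j] <-
      as.character(jsonlite::toJSON(tasks, auto_unbox = TRUE, digits = NA))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an expert gold-standard table
#'
#' Reads the expert consensus truth, one row per image: phase, expert count
#' and an image-quality judgement (`good`/`bad`). Presence and the abundance
#' category (`absent`/`low`/`medium`/`high`) are derived, so the invariant
#' "present iff count > 0" holds by construction.
#'
#' @param path CSV with columns `image_id,phase,expert_count,quality`.
#' @return Data frame with columns `image_id`, `phase`, `expert_count`,
#'   `quality`, `expert_present`, `abundance_category`.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("image_id", "phase", "expert_count", "quality")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gold <- data.frame(
    image_id = raw$image_id,
    phase = as.integer(raw$phase),
    expert_count = suppressWarnings(as.integer(raw$expert_count)),
    quality = tolower(raw$quality),
    stringsAsFactors = FALSE
  )
  as_gold_standard(gold)
}

#' Construct/validate a gold-standard table
#'
#' @param gold Data frame with `image_id`, `phase`, `expert_count`,
#'   `quality`.
#' @return Validated table with derived `expert_present` and
#'   `abundance_category` columns.
#' @export
as_gold_standard <- function(gold) {
  if (anyNA(gold$expert_count) || any(gold$expert_count < 0)) {
    stop("expert_count must be a non-negative integer", call. = FALSE)
  }
  if (!all(gold$quality %in% c("good", "bad"))) {
    stop("unknown quality label(s): ",
         paste(setdiff(unique(gold$quality), c("good", "bad")),
               collapse = ", "), call. = FALSE)
  }
  gold$expert_present <- gold$expert_count > 0
  gold$abundance_category <- abundance_category(gold$expert_count)
  rownames(gold) <- NULL
  gold
}

#' Write a gold-standard table
#'
#' @param gold Gold-standard data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  utils::write.csv(gold[, c("image_id", "phase", "expert_count", "quality")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Summarise volunteer activity
#'
#' One profile row per distinct volunteer with their classification tally;
#' the tallies sum to the total number of classifications (conservation).
#'
#' @param cls Classifications data frame.
#' @return Data frame `volunteer_id`, `anonymous`, `n_classifications`,
#'   sorted by decreasing activity.
#' @export
profile_volunteers <- function(cls) {
  if (nrow(cls) == 0) {
    return(data.frame(volunteer_id = character(), anonymous = logical(),
                      n_classifications = integer(),
                      stringsAsFactors = FALSE))
  }
  one <- cls[!duplicated(cls$classification_id),
             c("volunteer_id", "anonymous")]
  tab <- table(one$volunteer_id)
  prof <- data.frame(volunteer_id = names(tab),
                     n_classifications = as.integer(tab),
                     stringsAsFactors = FALSE)
  prof$anonymous <- one$anonymous[match(prof$volunteer_id, one$volunteer_id)]
  prof <- prof[order(-prof$n_classifications, prof$volunteer_id),
               c("volunteer_id", "anonymous", "n_classifications")]
  rownames(prof) <- NULL
  prof
}
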