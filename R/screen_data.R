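#' @title Screen data model and delimited-text I/O
#' @name screen_data
#' @description
#' A behavioral screen is stored as a `screen_table`: one row per larva
#' (plate, well, replicate index, group, drug, alive flag, distance traveled
#' in one hour) plus a drug annotation table. Groups are `WT_CONTROL`
#' (noninjected wild type, positive control), `MO_CONTROL` (morphant,
#' negative control) and `TREATED`. Control wells are identified by the
#' `group` column, not by plate position; the column-1/12 placement used on
#' the physical plates is a layout convention checked by [validate_layout()].
NULL

SCREEN_GROUPS <- c("WT_CONTROL", "MO_CONTROL", "TREATED")

SCREEN_COLUMNS <- c("plate", "row", "column", "fish_index", "group",
                    "drug_id", "alive", "distance_m")

#' Construct and validate a screen table
#'
#' @param observations data.frame with columns `plate` (integer >= 1), `row`
#'   (letter A-H), `column` (integer 1-12), `fish_index` (integer, 1-based
#'   replicate index within a drug's quadruplicate), `group` (one of
#'   `WT_CONTROL`, `MO_CONTROL`, `TREATED`), `drug_id` (character, `NA` for
#'   controls), `alive` (logical) and `distance_m` (non-negative meters
#'   traveled in 1 h). An optional logical `excluded` column marks wells
#'   manually removed from analysis (e.g. tracking artifacts); extra columns
#'   are preserved.
#' @param drugs data.frame of drug annotations with at least a unique
#'   `drug_id` column; defaults to the distinct treated drug ids.
#' @param replicate_count designed number of larvae per drug (default 4).
#' @return an object of class `screen_table`.
#' @details Invariants enforced: distances are non-negative; `group ==
#'   "TREATED"` exactly when `drug_id` is present; dead fish carry
#'   `distance_m = 0`; every treated drug appears in `drugs`.
#' @export
screen_table <- function(observations, drugs = NULL, replicate_count = 4) {
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SCREEN_COLUMNS, names(obs))
  if (length(missing_cols) > 0) {
    stage_error("screen_data", paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  obs$plate <- as.integer(obs$plate)
  obs$column <- as.integer(obs$column)
  obs$fish_index <- as.integer(obs$fish_index)
  obs$row <- as.character(obs$row)
  obs$group <- as.character(obs$group)
  obs$drug_id <- as.character(obs$drug_id)
  obs$drug_id[!is.na(obs$drug_id) & obs$drug_id == ""] <- NA_character_
  obs$alive <- as.logical(obs$alive)
  obs$distance_m <- as.numeric(obs$distance_m)
  if (!"excluded" %in% names(obs)) obs$excluded <- logical(nrow(obs))
  obs$excluded <- as.logical(obs$excluded)

  if (nrow(obs) > 0) {
    if (any(is.na(obs$plate)) || any(obs$plate < 1)) {
      stage_error("screen_data", "plate indices must be integers >= 1")
    }
    bad_row <- !obs$row %in% LETTERS[1:8]
    if (any(bad_row)) {
      stage_error("screen_data", sprintf(
        "row must be a letter A-H (first offending row number: %d)",
        which(bad_row)[1]))
    }
    if (any(is.na(obs$column)) || any(obs$column < 1 | obs$column > 12)) {
      stage_error("screen_data", "well column must be an integer in 1..12")
    }
    bad_group <- !obs$group %in% SCREEN_GROUPS
    if (any(bad_group)) {
      stage_error("screen_data", sprintf(
        "unknown group '%s' (row %d)", obs$group[which(bad_group)[1]],
        which(bad_group)[1]))
    }
    neg <- is.na(obs$distance_m) | obs$distance_m < 0
    if (any(neg)) {
      stage_error("screen_data", sprintf(
        "distance_m must be non-negative (row %d)", which(neg)[1]))
    }
    treated <- obs$group == "TREATED"
    orphan <- treated & is.na(obs$drug_id)
    if (any(orphan)) {
      stage_error("screen_data", sprintf(
        "TREATED observation without drug_id (row %d)", which(orphan)[1]))
    }
    mislabeled <- !treated & !is.na(obs$drug_id)
    if (any(mislabeled)) {
      stage_error("screen_data", sprintf(
        "control observation carries a drug_id (row %d)",
        which(mislabeled)[1]))
    }
    dead_moving <- !obs$alive & obs$distance_m != 0
    if (any(dead_moving)) {
      stage_error("screen_data", sprintf(
        "dead fish must carry distance_m = 0 (row %d)",
        which(dead_moving)[1]))
    }
  }

  treated_ids <- unique(obs$drug_id[obs$group == "TREATED"])
  if (is.null(drugs)) {
    drugs <- data.frame(drug_id = treated_ids, stringsAsFactors = FALSE)
  }
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  if (nrow(drugs) > 0 || length(treated_ids) > 0) {
    if (!"drug_id" %in% names(drugs)) {
      stage_error("screen_data", "drugs table must have a drug_id column")
    }
    if (anyDuplicated(drugs$drug_id)) {
      stage_error("screen_data", "drug_id must be unique within a library")
    }
    unknown <- setdiff(treated_ids, drugs$drug_id)
    if (length(unknown) > 0) {
      stage_error("screen_data", paste0(
        "treated drug id(s) absent from the drug table: ",
        paste(unknown, collapse = ", ")))
    }
  }

  structure(
    list(observations = obs, drugs = drugs,
         replicate_count = as.integer(replicate_count)),
    class = "screen_table")
}

#' @export
print.screen_table <- function(x, ...) {
  counts <- table(factor(x$observations$group, levels = SCREEN_GROUPS))
  cat(sprintf(
    "screen_table: %d observations on %d plate(s) | WT %d, MO %d, treated %d | %d drug(s)\n",
    nrow(x$observations), length(unique(x$observations$plate)),
    counts[["WT_CONTROL"]], counts[["MO_CONTROL"]], counts[["TREATED"]],
    nrow(x$drugs)))
  invisible(x)
}

#' Read a screen table from CSV
#'
#' The interchange dialect is comma-separated UTF-8 with a mandatory header
#' naming at least the columns `plate,row,column,fish_index,group,drug_id,
#' alive,distance_m`. Empty `drug_id` fields are read as absent. Unknown
#' columns are preserved. Parsing is order-independent: rows may appear in
#' any order.
#'
#' @param path CSV file path.
#' @param replicate_count designed larvae per drug (default 4).
#' @return a validated [screen_table()].
#' @export
read_screen_table <- function(path, replicate_count = 4) {
  if (!file.exists(path)) {
    stage_error("screen_data", paste0("file not found: ", path))
  }
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(drug_id = "character"))
  if (nrow(raw) == 0 && !all(SCREEN_COLUMNS %in% names(raw))) {
    # header-only file written by write_screen_table for an empty table
    raw <- raw[SCREEN_COLUMNS]
  }
  screen_table(raw, replicate_count = replicate_count)
}

#' Write a screen table to CSV
#'
#' Inverse of [read_screen_table()]: `read_screen_table(write_screen_table(t))`
#' reproduces `t` field for field. Absent drug ids are written as empty
#' fields.
#'
#' @param table a [screen_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(table, path) {
  stopifnot(inherits(table, "screen_table"))
  obs <- table$observations
  obs$drug_id[is.na(obs$drug_id)] <- ""
  # full-precision distances so read . write is the exact identity
  obs$distance_m <- sprintf("%.17g", obs$distance_m)
  ok <- tryCatch({
    write.csv(obs, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stage_error("screen_data", paste0("cannot write ", path, ": ",
                                      conditionMessage(ok)))
  }
  invisible(path)
}

#' Validate the plate layout of a screen table
#'
#' Report-only check of the assay-plate conventions: each plate carries both
#' control groups; each drug has exactly `replicate_count` larvae; no two
#' observations share a (plate, row, column, fish_index) address. Never
#' mutates the data.
#'
#' @param table a [screen_table()].
#' @return a `layout_report` list with elements `plate_controls` (per-plate
#'   WT/MO counts with missing flags), `bad_replicates` (drugs whose larvae
#'   count differs from `replicate_count`), `duplicate_addresses`, and
#'   `clean` (`TRUE` when nothing was flagged). Serialize with
#'   [write_layout_report()].
#' @export
validate_layout <- function(table) {
  stopifnot(inherits(table, "screen_table"))
  obs <- table$observations
  plates <- sort(unique(obs$plate))
  plate_controls <- data.frame(
    plate = plates,
    n_wt = vapply(plates, function(p)
      sum(obs$plate == p & obs$group == "WT_CONTROL"), integer(1)),
    n_mo = vapply(plates, function(p)
      sum(obs$plate == p & obs$group == "MO_CONTROL"), integer(1)))
  plate_controls$missing_wt <- plate_controls$n_wt == 0
  plate_controls$missing_mo <- plate_controls$n_mo == 0

  treated <- obs[obs$group == "TREATED", , drop = FALSE]
  rep_counts <- if (nrow(treated) > 0) {
    tab <- table(treated$drug_id)
    data.frame(drug_id = names(tab), n_fish = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(drug_id = character(0), n_fish = integer(0))
  }
  bad_replicates <- rep_counts[rep_counts$n_fish != table$replicate_count, ,
                               drop = FALSE]

  addr <- paste(obs$plate, obs$row, obs$column, obs$fish_index, sep = "/")
  dup <- unique(addr[duplicated(addr)])

  rep <- list(
    plate_controls = plate_controls,
    bad_replicates = bad_replicates,
    duplicate_addresses = dup,
    clean = !any(plate_controls$missing_wt) &&
      !any(plate_controls$missing_mo) &&
      nrow(bad_replicates) == 0 && length(dup) == 0)
  class(rep) <- "layout_report"
  rep
}

#' @export
print.layout_report <- function(x, ...) {
  cat(if (x$clean) "layout_report: clean\n" else "layout_report: issues found\n")
  if (any(x$plate_controls$missing_wt) || any(x$plate_controls$missing_mo)) {
    bad <- x$plate_controls[x$plate_controls$missing_wt |
                              x$plate_controls$missing_mo, ]
    cat("  plates missing controls:", paste(bad$plate, collapse = ", "), "\n")
  }
  if (nrow(x$bad_replicates) > 0) {
    cat("  drugs with wrong replicate count:",
        paste(x$bad_replicates$drug_id, collapse = ", "), "\n")
  }
  if (length(x$duplicate_addresses) > 0) {
    cat("  duplicate addresses:",
        paste(x$duplicate_addresses, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a layout report to JSON
#'
#' @param report a `layout_report` from [validate_layout()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_layout_report <- function(report, path) {
  stopifnot(inherits(report, "layout_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}
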