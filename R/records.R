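#' Construct a validated score sheet
#'
#' A score sheet holds one elephant-session's item scores: one value in
#' {0, 1, 2} (or `NA` for explicitly unscored) per codebook item. Missing is
#' distinct from 0 -- a 0 is a meaningful grade ("Welfare concern" /
#' "High-risk"), not an absent one.
#'
#' @param elephant_id,camp_id,rater_id Identifiers (character scalars).
#' @param cb The active `ewat_codebook`.
#' @param scores Named numeric vector; names are item keys
#'   (`"<measure_id>:<condition>"`). Items absent from `scores` are `NA`.
#' @param date ISO-8601 date string.
#' @param occasion Assessment occasion, integer >= 1 (used for test-retest).
#' @param notes Free-text note.
#' @return An object of class `ewat_sheet`.
#' @export
new_sheet <- function(elephant_id, cb, scores = numeric(0), camp_id = "camp1",
                      rater_id = "rater1", date = NA_character_,
                      occasion = 1L, notes = "") {
  keys <- cb$items$key
  full <- stats::setNames(rep(NA_real_, length(keys)), keys)
  if (length(scores)) {
    if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
      stop_ewat("scores must be named by item key", "ewat_usage_error")
    }
    unknown <- setdiff(names(scores), keys)
    if (length(unknown)) {
      stop_ewat(sprintf("unknown item key(s): %s",
                        paste(unknown, collapse = ", ")),
                "ewat_validation_error")
    }
    bad <- names(scores)[!is.na(scores) & !scores %in% c(0, 1, 2)]
    if (length(bad)) {
      stop_ewat(sprintf("score out of range {0,1,2} for item(s): %s",
                        paste(bad, collapse = ", ")),
                "ewat_validation_error")
    }
    full[names(scores)] <- as.numeric(scores)
  }
  occasion <- as.integer(occasion)
  if (is.na(occasion) || occasion < 1L) {
    stop_ewat("occasion must be an integer >= 1", "ewat_validation_error")
  }
  structure(
    list(elephant_id = as.character(elephant_id),
         camp_id = as.character(camp_id),
         rater_id = as.character(rater_id),
         date = as.character(date), occasion = occasion,
         scores = full, notes = as.character(notes)),
    class = "ewat_sheet"
  )
}

sheet_columns <- c("camp_id", "elephant_id", "rater_id", "date", "occasion",
                   "measure_id", "condition", "score", "note")

#' Read assessment score sheets from a long-format CSV
#'
#' The file format is long (tidy): one row per scored item, columns
#' `camp_id, elephant_id, rater_id, date, occasion, measure_id, condition,
#' score, note`, header mandatory. Scores are 0, 1, 2 or the literal token
#' `NA` for explicitly-unscored items. Rows are grouped into one sheet per
#' (camp, elephant, rater, date, occasion) session.
#'
#' @param path CSV file path.
#' @param cb The active `ewat_codebook`; every (measure_id, condition) must be
#'   one of its items.
#' @return List of `ewat_sheet` objects, in first-appearance order.
#' @export
read_sheets <- function(path, cb) {
  if (!file.exists(path)) {
    stop_ewat(sprintf("score-sheet file not found: %s", path), "ewat_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                        strip.white = TRUE)
  missing_cols <- setdiff(sheet_columns, names(df))
  if (length(missing_cols)) {
    stop_ewat(sprintf("score-sheet file lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "ewat_parse_error")
  }
  validate_rows(df, cb)
  split_key <- paste(df$camp_id, df$elephant_id, df$rater_id, df$date,
                     df$occasion, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(split_key, levels = unique(split_key)))
  lapply(groups, function(idx) {
    g <- df[idx, , drop = FALSE]
    sc <- suppressWarnings(as.numeric(g$score))  # "NA" token -> NA
    names(sc) <- item_key(g$measure_id, g$condition)
    note <- paste(unique(g$note[nzchar(g$note)]), collapse = "; ")
    new_sheet(elephant_id = g$elephant_id[1], cb = cb, scores = sc,
              camp_id = g$camp_id[1], rater_id = g$rater_id[1],
              date = g$date[1], occasion = as.integer(g$occasion[1]),
              notes = note)
  })
}

# Row-level validation with row numbers in every message (header = line 1).
validate_rows <- function(df, cb) {
  keys <- cb$items$key
  row_key <- item_key(df$measure_id, df$condition)
  unknown <- which(!row_key %in% keys)
  if (length(unknown)) {
    stop_ewat(sprintf("row %d: unknown item '%s' for the active codebook",
                      unknown[1] + 1L, row_key[unknown[1]]),
              "ewat_validation_error")
  }
  ok_score <- df$score %in% c("0", "1", "2", "NA")
  if (any(!ok_score)) {
    i <- which(!ok_score)[1]
    stop_ewat(sprintf("row %d: score '%s' not in {0,1,2,NA}", i + 1L,
                      df$score[i]),
              "ewat_validation_error")
  }
  dup_key <- paste(df$camp_id, df$elephant_id, df$rater_id, df$occasion,
                   row_key, sep = "\r")
  dups <- which(duplicated(dup_key))
  if (length(dups)) {
    stop_ewat(sprintf(
      "row %d: duplicate score for elephant '%s', rater '%s', occasion %s, item '%s'",
      dups[1] + 1L, df$elephant_id[dups[1]], df$rater_id[dups[1]],
      df$occasion[dups[1]], row_key[dups[1]]),
      "ewat_validation_error")
  }
  invisible(df)
}

#' Write score sheets to the long CSV format
#'
#' Inverse of [read_sheets()]: `read_sheets(write_sheets(x))` round-trips
#' validated data. Unscored items are written with the explicit `NA` token.
#'
#' @param sheets List of `ewat_sheet` objects.
#' @param path Output CSV path.
#' @param cb The active codebook.
#' @return `path`, invisibly.
#' @export
write_sheets <- function(sheets, path, cb) {
  items <- cb$items
  rows <- lapply(sheets, function(s) {
    data.frame(camp_id = s$camp_id, elephant_id = s$elephant_id,
               rater_id = s$rater_id, date = s$date, occasion = s$occasion,
               measure_id = items$measure_id, condition = items$condition,
               score = ifelse(is.na(s$scores[items$key]), "NA",
                              format(s$scores[items$key], trim = TRUE)),
               note = s$notes, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Fraction of codebook items scored on a sheet
#'
#' @param sheet An `ewat_sheet`.
#' @param cb The active codebook.
#' @return Fraction in [0, 1]: non-missing items / total items.
#' @export
completeness <- function(sheet, cb) {
  keys <- cb$items$key
  if (length(keys) == 0L) return(0)
  mean(!is.na(sheet$scores[keys]))
}

#' Camp roster
#'
#' Lightweight container tying elephant ids (with optional age/sex metadata)
#' to a camp.
#'
#' @param camp_id Camp identifier.
#' @param elephant_id Character vector of unique elephant ids.
#' @param age,sex Optional per-elephant metadata.
#' @return An object of class `ewat_roster` (a data.frame).
#' @export
camp_roster <- function(camp_id, elephant_id, age = NA_real_, sex = NA_character_) {
  if (anyDuplicated(elephant_id)) {
    stop_ewat("elephant ids must be unique within a camp",
              "ewat_validation_error")
  }
  structure(
    data.frame(camp_id = camp_id, elephant_id = elephant_id,
               age = age, sex = sex, stringsAsFactors = FALSE),
    class = c("ewat_roster", "data.frame")
  )
}

#' @export
print.ewat_sheet <- function(x, ...) {
  n <- length(x$scores)
  cat(sprintf(
    "<ewat_sheet> elephant=%s camp=%s rater=%s occasion=%d: %d/%d items scored\n",
    x$elephant_id, x$camp_id, x$rater_id, x$occasion,
    sum(!is.na(x$scores)), n))
  invisible(x)
}
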