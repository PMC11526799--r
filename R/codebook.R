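#' Path to the shipped instrument codebook
#'
#' The package ships the full instrument definition (measure names, Five
#' Domains assignment, animal/resource basis, day/night conditions,
#' data-collection methods and the 0-2 scoring rubric for every measure) as a
#' single versioned DCF text file. Records carry a `versions` tag so both the
#' initial 39-measure draft and the final 36-measure tool load from one file.
#'
#' @return Path to the codebook (or protocol metadata) file installed with the
#'   package.
#' @export
ewat_codebook_file <- function() {
  system.file("extdata", "ewat_codebook.dcf", package = "ewat", mustWork = TRUE)
}

#' @rdname ewat_codebook_file
#' @export
ewat_protocol_file <- function() {
  system.file("extdata", "ewat_protocol.dcf", package = "ewat", mustWork = TRUE)
}

.domains <- c("Nutrition", "Environment", "Health", "BehaviorMental")
.bases <- c("animal", "resource")
.conditions <- c("none", "daytime", "nighttime", "restricted", "unrestricted")
.methods <- c("interview", "observation", "physical_exam")

# Expected counts for the two shipped instrument versions; checked whenever a
# preset version is requested so the data file cannot silently drift.
.version_spec <- list(
  final_36 = list(
    n_measures = 36L, n_items = 42L,
    basis = c(animal = 18L, resource = 18L),
    domain = c(Nutrition = 5L, Environment = 11L, Health = 10L,
               BehaviorMental = 10L)
  ),
  initial_39 = list(
    n_measures = 39L, n_items = 45L,
    basis = c(animal = 18L, resource = 21L),
    domain = c(Nutrition = 5L, Environment = 14L, Health = 10L,
               BehaviorMental = 10L)
  )
)

split_list_field <- function(x) {
  lapply(strsplit(x, ","), function(v) trimws(v))
}

#' Load and validate an instrument codebook
#'
#' Reads a codebook file (DCF, one record per measure), optionally filters to
#' an instrument version, validates every measure record, and derives the
#' ordered list of scoring items: one item per (measure, condition), with
#' daytime before nighttime for the six dual-condition measures.
#'
#' @param path Codebook file; defaults to the shipped instrument.
#' @param version `"final_36"` (default), `"initial_39"`, or `NULL` to take
#'   every record in the file without preset count checks (useful for toy
#'   codebooks in examples and tests).
#' @return An object of class `ewat_codebook`: a list with `measures`
#'   (data.frame, one row per measure, list-columns `conditions`, `method`,
#'   `rubric`), `items` (data.frame `measure_id`, `condition`, `key`), and
#'   `version`.
#' @examples
#' cb <- load_codebook()
#' nrow(cb$measures)   # 36
#' nrow(cb$items)      # 42
#' @export
load_codebook <- function(path = ewat_codebook_file(), version = "final_36") {
  if (!file.exists(path)) {
    stop_ewat(sprintf("codebook file not found: %s", path), "ewat_io_error")
  }
  empty <- all(!nzchar(trimws(readLines(path, warn = FALSE))))
  raw <- if (empty) {
    as.data.frame(stats::setNames(
      rep(list(character(0)), 9),
      c("id", "name", "domain", "basis", "conditions", "method",
        paste0("score", 0:2))))
  } else {
    tryCatch(
      read.dcf(path, all = TRUE),
      error = function(e) stop_ewat(
        sprintf("cannot parse codebook file '%s': %s", path,
                conditionMessage(e)),
        "ewat_parse_error")
    )
  }
  required <- c("id", "name", "domain", "basis", "conditions", "method",
                paste0("score", 0:2))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_ewat(sprintf("codebook file lacks field(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "ewat_parse_error")
  }
  for (f in required) {
    bad <- which(is.na(raw[[f]]) | !nzchar(trimws(as.character(raw[[f]]))))
    if (length(bad)) {
      stop_ewat(sprintf("codebook record %d ('%s') has empty field '%s'",
                        bad[1], raw$id[bad[1]] %||% "?", f),
                "ewat_validation_error")
    }
  }
  measures <- data.frame(
    id = trimws(raw$id),
    name = trimws(raw$name),
    domain = trimws(raw$domain),
    basis = trimws(raw$basis),
    stringsAsFactors = FALSE
  )
  measures$conditions <- split_list_field(raw$conditions)
  measures$method <- split_list_field(raw$method)
  measures$rubric <- lapply(seq_len(nrow(raw)), function(i) {
    stats::setNames(trimws(c(raw$score0[i], raw$score1[i], raw$score2[i])),
                    c("0", "1", "2"))
  })
  versions_field <- if ("versions" %in% names(raw)) {
    split_list_field(ifelse(is.na(raw$versions), "", raw$versions))
  } else {
    rep(list(character(0)), nrow(raw))
  }

  if (!is.null(version)) {
    version <- match.arg(version, names(.version_spec))
    keep <- vapply(versions_field, function(v) {
      length(v) == 0L || version %in% v
    }, logical(1))
    measures <- measures[keep, , drop = FALSE]
    rownames(measures) <- NULL
  }

  cb <- structure(
    list(measures = measures, items = NULL, version = version, path = path),
    class = "ewat_codebook"
  )
  cb$items <- expand_items(cb)
  validate_codebook(cb)
  cb
}

#' Validate codebook invariants
#'
#' Checks every measure record (known domain/basis/condition/method values,
#' complete three-entry rubric, unique ids, dual-condition measures are
#' exactly daytime+nighttime) and, when the codebook carries a preset version,
#' the published counts for that version: final_36 has 36 measures (18
#' animal-, 18 resource-based; Nutrition 5, Environment 11, Health 10,
#' Behavior and Mental State 10) expanding to 42 items; initial_39 has 39
#' measures and 45 items.
#'
#' @param cb An `ewat_codebook`.
#' @return `cb`, invisibly; signals a classed validation error otherwise.
#' @export
validate_codebook <- function(cb) {
  m <- cb$measures
  if (anyDuplicated(m$id)) {
    stop_ewat(sprintf("duplicate measure id(s): %s",
                      paste(unique(m$id[duplicated(m$id)]), collapse = ", ")),
              "ewat_validation_error")
  }
  for (i in seq_len(nrow(m))) {
    id <- m$id[i]
    if (!m$domain[i] %in% .domains) {
      stop_ewat(sprintf("measure '%s': unknown domain '%s'", id, m$domain[i]),
                "ewat_validation_error")
    }
    if (!m$basis[i] %in% .bases) {
      stop_ewat(sprintf("measure '%s': unknown basis '%s'", id, m$basis[i]),
                "ewat_validation_error")
    }
    cond <- m$conditions[[i]]
    if (length(cond) == 0L || !all(cond %in% .conditions)) {
      stop_ewat(sprintf("measure '%s': conditions must be a non-empty subset of {%s}",
                        id, paste(.conditions, collapse = ", ")),
                "ewat_validation_error")
    }
    if (length(cond) > 1L && !setequal(cond, c("daytime", "nighttime"))) {
      stop_ewat(sprintf(
        "measure '%s': multi-condition measures must be exactly daytime+nighttime",
        id), "ewat_validation_error")
    }
    if (!all(m$method[[i]] %in% .methods)) {
      stop_ewat(sprintf("measure '%s': unknown data-collection method", id),
                "ewat_validation_error")
    }
    rub <- m$rubric[[i]]
    if (length(rub) != 3L || !identical(names(rub), c("0", "1", "2")) ||
        any(!nzchar(rub))) {
      stop_ewat(sprintf("measure '%s': rubric must have descriptors for scores 0, 1 and 2",
                        id), "ewat_validation_error")
    }
  }
  if (!is.null(cb$version)) {
    spec <- .version_spec[[cb$version]]
    counts <- codebook_counts(cb)
    fails <- character(0)
    if (counts$n_measures != spec$n_measures) {
      fails <- c(fails, sprintf("measures %d != %d", counts$n_measures,
                                spec$n_measures))
    }
    if (counts$n_items != spec$n_items) {
      fails <- c(fails, sprintf("items %d != %d", counts$n_items, spec$n_items))
    }
    for (b in names(spec$basis)) {
      if (counts$basis[[b]] != spec$basis[[b]]) {
        fails <- c(fails, sprintf("%s-based %d != %d", b, counts$basis[[b]],
                                  spec$basis[[b]]))
      }
    }
    for (d in names(spec$domain)) {
      if (counts$domain[[d]] != spec$domain[[d]]) {
        fails <- c(fails, sprintf("%s %d != %d", d, counts$domain[[d]],
                                  spec$domain[[d]]))
      }
    }
    if (length(fails)) {
      stop_ewat(sprintf("codebook does not satisfy version '%s': %s",
                        cb$version, paste(fails, collapse = "; ")),
                "ewat_validation_error")
    }
  }
  invisible(cb)
}

#' Expand measures into scoring items
#'
#' One scoring item per (measure, condition), in codebook order with daytime
#' before nighttime. The final instrument's 36 measures expand to 42 items
#' because six environment measures (chain length/enclosure space, shade,
#' hygiene, noise type, substrate, access to social interaction) are scored
#' separately for day and night.
#'
#' @param cb An `ewat_codebook`.
#' @return data.frame with columns `measure_id`, `condition`, `key`
#'   (`"<measure_id>:<condition>"`), `domain`, `basis`.
#' @export
expand_items <- function(cb) {
  m <- cb$measures
  rows <- lapply(seq_len(nrow(m)), function(i) {
    cond <- m$conditions[[i]]
    if (setequal(cond, c("daytime", "nighttime"))) {
      cond <- c("daytime", "nighttime")
    }
    data.frame(measure_id = m$id[i], condition = cond,
               domain = m$domain[i], basis = m$basis[i],
               stringsAsFactors = FALSE)
  })
  items <- do.call(rbind, rows)
  if (is.null(items)) {
    items <- data.frame(measure_id = character(0), condition = character(0),
                        domain = character(0), basis = character(0))
  }
  items$key <- item_key(items$measure_id, items$condition)
  rownames(items) <- NULL
  items[, c("measure_id", "condition", "key", "domain", "basis")]
}

#' @rdname expand_items
#' @param measure_id,condition Vectors defining items.
#' @export
item_key <- function(measure_id, condition) {
  paste(measure_id, condition, sep = ":")
}

#' Summary counts for a codebook
#'
#' @param cb An `ewat_codebook`.
#' @return List with `n_measures`, `n_items`, `domain` (named integer vector
#'   over all four domains), `basis` (animal/resource), and `n_dual`
#'   (measures scored under both day and night).
#' @export
codebook_counts <- function(cb) {
  m <- cb$measures
  domain <- vapply(.domains, function(d) sum(m$domain == d), integer(1))
  basis <- vapply(.bases, function(b) sum(m$basis == b), integer(1))
  dual <- sum(vapply(m$conditions, function(cond) {
    setequal(cond, c("daytime", "nighttime"))
  }, logical(1)))
  list(n_measures = nrow(m), n_items = nrow(cb$items),
       domain = domain, basis = basis, n_dual = dual)
}

#' Welfare grade semantics
#'
#' The instrument's 0-2 Likert scores carry different labels for animal-based
#' measures (read directly off the elephant) and resource-based measures
#' (provision/management): 0 is "Welfare concern (Not adequate)" vs
#' "High-risk", 1 "Potential welfare concern (Needs improvement)" vs
#' "Moderate-risk", 2 "No welfare concern (Adequate)" vs "Low-risk".
#'
#' @return data.frame with columns `basis`, `score`, `label`.
#' @export
grade_semantics <- function() {
  data.frame(
    basis = rep(c("animal", "resource"), each = 3L),
    score = rep(0:2, times = 2L),
    label = c("Welfare concern (Not adequate)",
              "Potential welfare concern (Needs improvement)",
              "No welfare concern (Adequate)",
              "High-risk", "Moderate-risk", "Low-risk"),
    stringsAsFactors = FALSE
  )
}

#' @rdname grade_semantics
#' @param basis `"animal"` or `"resource"` (vectorised).
#' @param score Integer score(s) in 0..2.
#' @export
grade_label <- function(basis, score) {
  sem <- grade_semantics()
  idx <- match(paste(basis, score), paste(sem$basis, sem$score))
  if (anyNA(idx)) {
    stop_ewat("grade_label: basis must be animal/resource and score in 0..2",
              "ewat_usage_error")
  }
  sem$label[idx]
}

#' Data-collection protocol metadata
#'
#' Step timings of the assessment visit (about 1.5 h per elephant) and the
#' behavioural-observation protocol (two 15-min observations, restrained and
#' unrestrained, at least 1 h apart). Stored as documentation metadata; the
#' package does not schedule visits.
#'
#' @return data.frame with columns `step`, `minutes`, `note`.
#' @export
protocol_steps <- function() {
  raw <- read.dcf(ewat_protocol_file(), all = TRUE)
  data.frame(step = raw$step,
             minutes = as.integer(raw$minutes),
             note = if ("note" %in% names(raw)) {
               ifelse(is.na(raw$note), "", raw$note)
             } else "",
             stringsAsFactors = FALSE)
}

#' @export
print.ewat_codebook <- function(x, ...) {
  cts <- codebook_counts(x)
  cat(sprintf("<ewat_codebook> version=%s: %d measures, %d items\n",
              x$version %||% "(custom)", cts$n_measures, cts$n_items))
  cat(sprintf("  domains: %s\n",
              paste(sprintf("%s %d", names(cts$domain), cts$domain),
                    collapse = ", ")))
  cat(sprintf("  basis: animal %d, resource %d; dual-condition measures: %d\n",
              cts$basis[["animal"]], cts$basis[["resource"]], cts$n_dual))
  invisible(x)
}
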