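new_score <- function(level, value, n_items, n_missing, n = NULL) {
  structure(
    list(level = level, value = value, n_items = n_items,
         n_missing = n_missing, n = n),
    class = "ewat_score"
  )
}

#' Overall welfare score for one elephant
#'
#' Averages the 0-2 item scores of a sheet. Two weightings are offered
#' because the instrument's six dual-condition measures contribute two data
#' points each: `per_item` (default) gives each of the 42 items equal weight;
#' `per_measure` first averages within a measure (so day+night count once),
#' then averages across measures.
#'
#' @param sheet An `ewat_sheet`.
#' @param cb The active codebook.
#' @param weighting `"per_item"` or `"per_measure"`.
#' @param min_completeness Minimum fraction of scored items (default 0.8)
#'   below which no overall score is issued.
#' @return An `ewat_score` with `value` in [0, 2].
#' @export
elephant_score <- function(sheet, cb, weighting = c("per_item", "per_measure"),
                           min_completeness = 0.8) {
  weighting <- match.arg(weighting)
  comp <- completeness(sheet, cb)
  if (comp < min_completeness) {
    stop_ewat(sprintf(
      "insufficient data: completeness %.2f below minimum %.2f for elephant '%s'",
      comp, min_completeness, sheet$elephant_id),
      "ewat_insufficient_data_error")
  }
  sc <- sheet$scores[cb$items$key]
  n_missing <- sum(is.na(sc))
  value <- if (weighting == "per_item") {
    mean(sc, na.rm = TRUE)
  } else {
    per_measure <- tapply(sc, factor(cb$items$measure_id,
                                     levels = unique(cb$items$measure_id)),
                          mean, na.rm = TRUE)
    mean(per_measure, na.rm = TRUE)
  }
  new_score("elephant", value, n_items = sum(!is.na(sc)),
            n_missing = n_missing)
}

#' Per-domain welfare scores for one elephant
#'
#' Mean of the non-missing items within each of the four domains. A domain
#' with no scored items yields `NA` (reported as missing, not zero).
#'
#' @inheritParams elephant_score
#' @return data.frame with one row per domain: `domain`, `value`, `n_items`,
#'   `n_missing`.
#' @export
domain_scores <- function(sheet, cb) {
  sc <- sheet$scores[cb$items$key]
  out <- lapply(.domains, function(d) {
    idx <- cb$items$domain == d
    v <- sc[idx]
    data.frame(domain = d,
               value = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
               n_items = sum(!is.na(v)), n_missing = sum(is.na(v)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Camp-level welfare score
#'
#' Unweighted mean of per-elephant overall scores. If an elephant has several
#' sheets (e.g. several raters), its sheets are averaged first so each
#' elephant counts once.
#'
#' @param sheets List of `ewat_sheet` objects (one camp).
#' @inheritParams elephant_score
#' @return An `ewat_score` with `n` = number of scorable elephants.
#' @export
camp_score <- function(sheets, cb, weighting = c("per_item", "per_measure"),
                       min_completeness = 0.8) {
  weighting <- match.arg(weighting)
  if (length(sheets) == 0L) {
    stop_ewat("insufficient data: no score sheets supplied",
              "ewat_insufficient_data_error")
  }
  ids <- vapply(sheets, function(s) s$elephant_id, character(1))
  per_elephant <- tapply(seq_along(sheets), factor(ids, levels = unique(ids)),
    function(idx) {
      vals <- vapply(sheets[idx], function(s) {
        elephant_score(s, cb, weighting, min_completeness)$value
      }, numeric(1))
      mean(vals)
    })
  new_score("camp", mean(per_elephant),
            n_items = sum(vapply(sheets, function(s) sum(!is.na(s$scores)),
                                 integer(1))),
            n_missing = sum(vapply(sheets, function(s) sum(is.na(s$scores)),
                                   integer(1))),
            n = length(per_elephant))
}

#' Flag welfare concerns on a sheet
#'
#' Lists every item scored 0 with the basis-appropriate label ("Welfare
#' concern (Not adequate)" for animal-based measures, "High-risk" for
#' resource-based ones); optionally also items scored 1 with the intermediate
#' label.
#'
#' @inheritParams elephant_score
#' @param include_potential Also list items scored 1.
#' @return data.frame: `key`, `measure_id`, `condition`, `measure`, `domain`,
#'   `basis`, `score`, `label`, ordered as in the codebook.
#' @export
flag_concerns <- function(sheet, cb, include_potential = FALSE) {
  items <- cb$items
  sc <- sheet$scores[items$key]
  flag_scores <- if (include_potential) c(0, 1) else 0
  idx <- which(!is.na(sc) & sc %in% flag_scores)
  out <- data.frame(
    key = items$key[idx], measure_id = items$measure_id[idx],
    condition = items$condition[idx],
    measure = cb$measures$name[match(items$measure_id[idx], cb$measures$id)],
    domain = items$domain[idx], basis = items$basis[idx],
    score = as.integer(sc[idx]), stringsAsFactors = FALSE
  )
  out$label <- if (nrow(out)) grade_label(out$basis, out$score) else character(0)
  rownames(out) <- NULL
  out
}

#' Tabular welfare report
#'
#' One row per elephant: overall score under the chosen weighting, the four
#' domain means, completeness, and the number of flagged welfare concerns
#' (items scored 0). `camp_report()` aggregates to one row per camp.
#'
#' @inheritParams camp_score
#' @return data.frame.
#' @export
elephant_report <- function(sheets, cb, weighting = c("per_item", "per_measure"),
                            min_completeness = 0.8) {
  weighting <- match.arg(weighting)
  rows <- lapply(sheets, function(s) {
    ds <- domain_scores(s, cb)
    data.frame(
      camp_id = s$camp_id, elephant_id = s$elephant_id, rater_id = s$rater_id,
      occasion = s$occasion,
      overall = elephant_score(s, cb, weighting, min_completeness)$value,
      Nutrition = ds$value[ds$domain == "Nutrition"],
      Environment = ds$value[ds$domain == "Environment"],
      Health = ds$value[ds$domain == "Health"],
      BehaviorMental = ds$value[ds$domain == "BehaviorMental"],
      completeness = completeness(s, cb),
      n_concerns = nrow(flag_concerns(s, cb)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname elephant_report
#' @export
camp_report <- function(sheets, cb, weighting = c("per_item", "per_measure"),
                        min_completeness = 0.8) {
  weighting <- match.arg(weighting)
  camps <- vapply(sheets, function(s) s$camp_id, character(1))
  rows <- lapply(split(sheets, factor(camps, levels = unique(camps))),
    function(group) {
      cs <- camp_score(group, cb, weighting, min_completeness)
      data.frame(camp_id = group[[1]]$camp_id, n_elephants = cs$n,
                 camp_score = cs$value,
                 n_concerns = sum(vapply(group, function(s) {
                   nrow(flag_concerns(s, cb))
                 }, integer(1))),
                 stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ewat_score <- function(x, ...) {
  cat(sprintf("<ewat_score> %s: %.2f (0-2 scale; %d items scored, %d missing%s)\n",
              x$level, x$value, x$n_items, x$n_missing,
              if (!is.null(x$n)) sprintf(", n=%d", x$n) else ""))
  invisible(x)
}
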