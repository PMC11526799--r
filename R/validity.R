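#' Construct an expert relevance panel
#'
#' Content validation asks a panel of experts to rate every instrument
#' measure's relevance on a 4-point ordinal scale (1 not relevant .. 4 very
#' relevant). A panel is complete: every expert rates every item.
#'
#' @param ratings Numeric matrix, items x experts, all values in {1,2,3,4};
#'   rownames are measure ids, colnames expert ids (defaults supplied).
#' @return An object of class `ewat_panel` (the validated matrix).
#' @export
ewat_panel <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 1L || ncol(ratings) < 2L) {
    stop_ewat("panel needs at least 1 item and 2 experts", "ewat_validation_error")
  }
  if (anyNA(ratings)) {
    stop_ewat("panel is incomplete: every expert must rate every item",
              "ewat_validation_error")
  }
  if (!all(ratings %in% 1:4)) {
    stop_ewat("panel ratings must be on the 4-point ordinal scale {1,2,3,4}",
              "ewat_validation_error")
  }
  if (is.null(rownames(ratings))) {
    rownames(ratings) <- sprintf("item%02d", seq_len(nrow(ratings)))
  }
  if (is.null(colnames(ratings))) {
    colnames(ratings) <- sprintf("expert%d", seq_len(ncol(ratings)))
  }
  structure(ratings, class = c("ewat_panel", class(ratings)))
}

#' Read / write an expert panel file
#'
#' Delimited text: first column `measure_id`, remaining columns one per
#' expert, cells 1-4.
#'
#' @param path CSV file path.
#' @return `read_panel()`: an `ewat_panel`; `write_panel()`: `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    stop_ewat(sprintf("panel file not found: %s", path), "ewat_io_error")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L || names(df)[1] != "measure_id") {
    stop_ewat("panel file must have a 'measure_id' column then one column per expert",
              "ewat_parse_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$measure_id
  ewat_panel(m)
}

#' @rdname read_panel
#' @param panel An `ewat_panel`.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(measure_id = rownames(panel),
                   unclass(panel)[, , drop = FALSE], check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dichotomise ordinal relevance ratings
#'
#' Ratings of 3 or 4 count as "relevant" (1), ratings of 1 or 2 as "not
#' relevant" (0). All content-validity indices are computed on this
#' dichotomisation, so relabelling within {3,4} or within {1,2} never changes
#' any index.
#'
#' @param rating Numeric vector/matrix with values in {1,2,3,4}.
#' @return Same shape, values in {0,1}.
#' @export
dichotomize <- function(rating) {
  if (anyNA(rating) || !all(rating %in% 1:4)) {
    stop_ewat("ratings must be in {1,2,3,4}", "ewat_validation_error")
  }
  out <- ifelse(rating >= 3, 1L, 0L)
  if (is.matrix(rating)) {
    out <- matrix(out, nrow(rating), dimnames = dimnames(rating))
  }
  out
}

#' Item-level content validity index
#'
#' For each item, the number of experts in agreement (rating it relevant) and
#' I-CVI = agreement / number of experts. With 6 experts, 5/6 relevant gives
#' 0.83, 4/6 gives 0.67, 3/6 gives 0.50 at the conventional two-decimal
#' presentation; full precision is retained in `i_cvi`.
#'
#' @param panel An `ewat_panel` (or item x expert rating matrix).
#' @param item Optional measure id(s) to restrict to.
#' @return data.frame: `item`, `n_agree`, `i_cvi` (full precision),
#'   `i_cvi_2dp` (half-up rounded), `ua` (1 iff all experts agree relevant).
#' @export
item_cvi <- function(panel, item = NULL) {
  panel <- ewat_panel(panel)
  rel <- dichotomize(unclass(panel))
  n_exp <- ncol(rel)
  out <- data.frame(
    item = rownames(rel),
    n_agree = as.integer(rowSums(rel)),
    stringsAsFactors = FALSE
  )
  out$i_cvi <- out$n_agree / n_exp
  out$i_cvi_2dp <- round_half_up(out$i_cvi, 2)
  out$ua <- as.integer(out$n_agree == n_exp)
  if (!is.null(item)) {
    unknown <- setdiff(item, out$item)
    if (length(unknown)) {
      stop_ewat(sprintf("item(s) not in panel: %s",
                        paste(unknown, collapse = ", ")),
                "ewat_usage_error")
    }
    out <- out[match(item, out$item), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Scale-level content validity indices
#'
#' S-CVI/Average is the mean of the item I-CVIs; S-CVI/UA is the proportion
#' of items on which 100% of experts agree (universal agreement). Since an
#' item's UA indicator never exceeds its I-CVI, S-CVI/UA <= S-CVI/Average for
#' every panel.
#'
#' @inheritParams item_cvi
#' @return List with `s_cvi_ua`, `s_cvi_avg`, `n_items`, `n_experts`.
#' @export
scale_cvi <- function(panel) {
  icvi <- item_cvi(panel)
  list(s_cvi_ua = mean(icvi$ua), s_cvi_avg = mean(icvi$i_cvi),
       n_items = nrow(icvi), n_experts = ncol(panel))
}

#' Full content-validity pipeline
#'
#' Dichotomises the panel, computes per-item agreement, I-CVI and universal
#' agreement, the scale indices, and applies the retention rule: an item is
#' removed iff its unrounded I-CVI falls below `threshold` (with a small
#' epsilon so 5/6 = 0.8333 passes a 0.83 threshold). Scale indices are
#' reported both for the full panel and recomputed over the retained items.
#'
#' @inheritParams item_cvi
#' @param threshold Retention threshold on I-CVI (default 0.83).
#' @return An object of class `ewat_cvi`: list with `items` (per-item table),
#'   `s_cvi_ua`, `s_cvi_avg`, `retained`, `removed` (ordered by ascending
#'   I-CVI), `retained_scale` (scale indices over retained items only),
#'   `threshold`, `n_experts`.
#' @export
cvi <- function(panel, threshold = 0.83) {
  panel <- ewat_panel(panel)
  items <- item_cvi(panel)
  sc <- scale_cvi(panel)
  ret <- apply_retention(items, threshold)
  retained_scale <- if (length(ret$retained)) {
    sub <- items[items$item %in% ret$retained, , drop = FALSE]
    list(s_cvi_ua = mean(sub$ua), s_cvi_avg = mean(sub$i_cvi))
  } else {
    list(s_cvi_ua = NA_real_, s_cvi_avg = NA_real_)
  }
  structure(
    list(items = items, s_cvi_ua = sc$s_cvi_ua, s_cvi_avg = sc$s_cvi_avg,
         retained = ret$retained, removed = ret$removed,
         retained_scale = retained_scale,
         threshold = threshold, n_experts = sc$n_experts),
    class = "ewat_cvi"
  )
}

#' Apply the I-CVI retention rule
#'
#' Items whose unrounded I-CVI is below the threshold (minus epsilon 1e-9)
#' are removed; the removed list is ordered by ascending I-CVI.
#'
#' @param x An `ewat_cvi` result or the per-item table from [item_cvi()].
#' @param threshold Retention threshold (default 0.83).
#' @return List with character vectors `retained` and `removed`.
#' @export
apply_retention <- function(x, threshold = 0.83) {
  items <- if (inherits(x, "ewat_cvi")) x$items else x
  drop <- items$i_cvi < threshold - 1e-9
  removed <- items[drop, , drop = FALSE]
  removed <- removed[order(removed$i_cvi, removed$item), , drop = FALSE]
  list(retained = items$item[!drop], removed = removed$item)
}

#' @export
print.ewat_cvi <- function(x, ...) {
  cat(sprintf("<ewat_cvi> %d items x %d experts\n", nrow(x$items), x$n_experts))
  cat(sprintf("  S-CVI/UA = %.2f, S-CVI/Average = %.2f (all items)\n",
              round_half_up(x$s_cvi_ua, 2), round_half_up(x$s_cvi_avg, 2)))
  cat(sprintf("  retention (I-CVI >= %.2f): %d retained, %d removed\n",
              x$threshold, length(x$retained), length(x$removed)))
  if (length(x$removed)) {
    cat(sprintf("  removed: %s\n", paste(x$removed, collapse = ", ")))
  }
  cat(sprintf("  S-CVI/UA = %.2f, S-CVI/Average = %.2f (retained items)\n",
              round_half_up(x$retained_scale$s_cvi_ua, 2),
              round_half_up(x$retained_scale$s_cvi_avg, 2)))
  invisible(x)
}
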