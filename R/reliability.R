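#' Construct a subjects x raters ratings matrix
#'
#' Container for reliability analyses: rows are subjects (elephants), columns
#' raters (inter-rater design) or occasions (test-retest design). Cells are
#' numeric scores at any level of the instrument (item, domain mean, or
#' overall). The two-way model requires a complete matrix with at least two
#' subjects and two raters; there is no imputation (incomplete matrices must
#' be handled upstream, e.g. by listwise subject deletion, which
#' [assemble_ratings()] exposes behind an explicit flag).
#'
#' @param values Numeric matrix or data.frame, subjects x raters.
#' @return An object of class `ewat_ratings` (the validated matrix).
#' @export
ratings_matrix <- function(values) {
  m <- as.matrix(values)
  if (!is.numeric(m)) {
    stop_ewat("ratings must be numeric", "ewat_validation_error")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_ewat("ratings matrix needs >= 2 subjects and >= 2 raters/occasions",
              "ewat_validation_error")
  }
  if (anyNA(m)) {
    stop_ewat("ratings matrix has missing cells; no imputation is performed",
              "ewat_validation_error")
  }
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("R%d", seq_len(ncol(m)))
  structure(m, class = c("ewat_ratings", class(m)))
}

#' Two-way ANOVA mean squares without replication
#'
#' Decomposes a complete subjects x raters matrix into between-subject
#' (rows), between-rater (columns) and residual sums of squares:
#' `SS_rows = k * sum_i (rowmean_i - grand)^2`,
#' `SS_cols = n * sum_j (colmean_j - grand)^2`, and
#' `SS_error = SS_total - SS_rows - SS_cols`, with degrees of freedom n-1,
#' k-1 and (n-1)(k-1). These mean squares parameterise the two-way
#' random-effects intraclass correlation.
#'
#' @param m An `ewat_ratings` matrix (coerced via [ratings_matrix()]).
#' @return An object of class `ewat_anova`: list with `MSR`, `MSC`, `MSE`,
#'   the corresponding `SS*` and `df*`, `n`, `k`, `grand`.
#' @export
anova_mean_squares <- function(m) {
  m <- ratings_matrix(m)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  structure(
    list(MSR = ss_rows / (n - 1), MSC = ss_cols / (k - 1),
         MSE = ss_error / ((n - 1) * (k - 1)),
         SSR = ss_rows, SSC = ss_cols, SSE = ss_error, SST = ss_total,
         df_rows = n - 1L, df_cols = k - 1L, df_error = (n - 1L) * (k - 1L),
         n = n, k = k, grand = grand),
    class = "ewat_anova"
  )
}

#' Absolute-agreement intraclass correlation (two-way random effects)
#'
#' Estimates ICC(A,1) (single rating) or ICC(A,k) (average of the k ratings)
#' under the two-way random-effects model with absolute agreement, from the
#' ANOVA mean squares:
#' \deqn{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' \deqn{ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)}
#' Absolute agreement charges systematic rater level differences (through
#' MSC) against reliability, unlike consistency ICCs. The 95% confidence
#' interval uses the McGraw-Wong F construction with a Satterthwaite
#' approximation for the rater-term degrees of freedom; the average-rating
#' interval is the Spearman-Brown transform of the single-rating one.
#' Estimates can be negative and are never truncated. The p-value tests
#' ICC = 0 via F = MSR/MSE on (n-1, (n-1)(k-1)) df.
#'
#' @param m An `ewat_ratings` matrix.
#' @param unit `"single"` (default: each rating stands alone) or `"average"`.
#' @param alpha Two-sided confidence level is `1 - alpha` (default 0.05).
#' @return An object of class `ewat_icc`: list with `estimate`, `lower`,
#'   `upper`, `unit`, `band` (Koo-Li interpretation), `alpha`, `F`, `p`,
#'   `anova`, `n`, `k`.
#' @export
icc_agreement <- function(m, unit = c("single", "average"), alpha = 0.05) {
  unit <- match.arg(unit)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_ewat("alpha must be in (0, 1)", "ewat_usage_error")
  }
  a <- anova_mean_squares(m)
  n <- a$n; k <- a$k
  msr <- a$MSR; msc <- a$MSC; mse <- a$MSE
  denom_single <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom_single) < 1e-300) {
    stop_ewat(
      "degenerate ratings matrix (no variance anywhere): ICC is undefined (0/0)",
      "ewat_degenerate_error")
  }
  est1 <- (msr - mse) / denom_single

  # CI for ICC(A,1): McGraw & Wong's F-based bounds with Satterthwaite df.
  if (est1 >= 1 - 1e-12 && a$SSE + a$SSC < 1e-12 * max(a$SST, 1)) {
    ci1 <- c(1, 1)  # perfect agreement: interval collapses
    fv <- Inf; p <- 0
  } else {
    aa <- (k * est1) / (n * (1 - est1))
    bb <- 1 + (k * est1 * (n - 1)) / (n * (1 - est1))
    nu <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, nu)
    f_u <- stats::qf(1 - alpha / 2, nu, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci1 <- c(lower, upper)
    fv <- msr / mse
    p <- stats::pf(fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }

  if (unit == "single") {
    est <- est1; ci <- ci1
  } else {
    est <- (msr - mse) / (msr + (msc - mse) / n)
    # Spearman-Brown step-up of the single-rating bounds; below the pole at
    # -1/(k-1) the transform is meaningless and the bound is unbounded below.
    sb <- function(x) {
      ifelse(1 + (k - 1) * x <= 0, -Inf, k * x / (1 + (k - 1) * x))
    }
    ci <- sb(ci1)
  }
  structure(
    list(estimate = est, lower = ci[1], upper = ci[2], unit = unit,
         band = classify_icc(est), alpha = alpha, F = fv, p = p,
         anova = a, n = n, k = k),
    class = "ewat_icc"
  )
}

#' Interpretation band for an ICC estimate
#'
#' Conventional qualitative bands: below 0.5 poor, 0.5 to 0.75 moderate,
#' 0.75 to 0.9 good, 0.90 and above excellent. Values exactly on a boundary
#' fall in the upper band (so 0.75 is "good" and 0.90 "excellent");
#' `right_closed = TRUE` flips that convention. Negative estimates are
#' "poor".
#'
#' @param estimate Finite numeric ICC estimate(s).
#' @param right_closed Boundary convention (default: boundaries belong to the
#'   upper band).
#' @return Character vector of bands.
#' @export
classify_icc <- function(estimate, right_closed = FALSE) {
  if (anyNA(estimate) || any(!is.finite(estimate))) {
    stop_ewat("ICC estimate must be finite to classify", "ewat_usage_error")
  }
  # boundary comparisons at 12 decimals so float noise (0.9 - 2e-16) does not
  # flip a band
  estimate <- round(estimate, 12)
  cut_one <- function(x) {
    if (right_closed) {
      if (x <= 0.5) "poor" else if (x <= 0.75) "moderate"
      else if (x <= 0.9) "good" else "excellent"
    } else {
      if (x < 0.5) "poor" else if (x < 0.75) "moderate"
      else if (x < 0.9) "good" else "excellent"
    }
  }
  vapply(estimate, cut_one, character(1))
}

#' Pooled reliability report over several rating matrices
#'
#' Computes an absolute-agreement ICC per labelled matrix (e.g. one per
#' welfare domain plus the overall score) and pools them in the conventional
#' reporting style: mean, SD, SE (= SD / sqrt(m)) and min-max range of the m
#' estimates. For a test-retest design the columns are two occasions of the
#' same rater, so k must equal 2.
#'
#' @param matrices Named list of `ewat_ratings` matrices (a bare matrix is
#'   accepted). All matrices must cover the same subjects.
#' @param design `"inter_rater"` or `"test_retest"`.
#' @param unit,alpha Passed to [icc_agreement()].
#' @return An object of class `ewat_reliability`: list with `results`
#'   (data.frame label/estimate/lower/upper/band), `mean`, `sd`, `se` (0 for
#'   a single label), `range`, `design`, `unit`, `iccs` (the full
#'   `ewat_icc` objects).
#' @export
reliability_report <- function(matrices, design = c("inter_rater", "test_retest"),
                               unit = c("single", "average"), alpha = 0.05) {
  design <- match.arg(design)
  unit <- match.arg(unit)
  if (inherits(matrices, "ewat_ratings") || is.matrix(matrices)) {
    matrices <- list(overall = matrices)
  }
  if (length(matrices) < 1L) {
    stop_ewat("at least one ratings matrix is required", "ewat_usage_error")
  }
  if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
    names(matrices) <- sprintf("matrix%d", seq_along(matrices))
  }
  matrices <- lapply(matrices, ratings_matrix)
  subj <- lapply(matrices, rownames)
  if (!all(vapply(subj, identical, logical(1), y = subj[[1]]))) {
    stop_ewat("all matrices must cover the same subjects in the same order",
              "ewat_validation_error")
  }
  if (design == "test_retest" &&
      any(vapply(matrices, ncol, integer(1)) != 2L)) {
    stop_ewat("test-retest design requires exactly 2 occasions per matrix",
              "ewat_validation_error")
  }
  iccs <- lapply(matrices, icc_agreement, unit = unit, alpha = alpha)
  est <- vapply(iccs, `[[`, numeric(1), "estimate")
  results <- data.frame(
    label = names(matrices), estimate = est,
    lower = vapply(iccs, `[[`, numeric(1), "lower"),
    upper = vapply(iccs, `[[`, numeric(1), "upper"),
    band = vapply(iccs, `[[`, character(1), "band"),
    p = vapply(iccs, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  rownames(results) <- NULL
  m <- length(est)
  sd_est <- if (m > 1L) stats::sd(est) else 0
  structure(
    list(results = results, mean = mean(est), sd = sd_est,
         se = sd_est / sqrt(m), range = range(est),
         design = design, unit = unit, iccs = iccs),
    class = "ewat_reliability"
  )
}

#' Assemble rating matrices from score sheets
#'
#' Builds subjects x raters (or subjects x occasions) matrices from validated
#' score sheets: rows are elephants, columns the distinct raters (`by =
#' "rater"`) or occasions (`by = "occasion"`), cells the overall or
#' per-domain welfare score. The default grouping -- one matrix per domain
#' plus the overall score -- matches the unit of replication used by
#' [reliability_report()].
#'
#' @param sheets List of `ewat_sheet` objects.
#' @param cb The active codebook.
#' @param level `"domain_overall"` (default), `"overall"`, or `"domain"`.
#' @param by Column dimension: `"rater"` or `"occasion"`.
#' @param weighting Passed to [elephant_score()] for the overall cell values.
#' @param drop_incomplete Listwise-delete elephants not scored by every
#'   rater/occasion (explicit opt-in; default errors instead).
#' @return Named list of `ewat_ratings` matrices.
#' @export
assemble_ratings <- function(sheets, cb,
                             level = c("domain_overall", "overall", "domain"),
                             by = c("rater", "occasion"),
                             weighting = c("per_item", "per_measure"),
                             drop_incomplete = FALSE) {
  level <- match.arg(level)
  by <- match.arg(by)
  weighting <- match.arg(weighting)
  subj <- vapply(sheets, function(s) s$elephant_id, character(1))
  col_id <- if (by == "rater") {
    vapply(sheets, function(s) s$rater_id, character(1))
  } else {
    as.character(vapply(sheets, function(s) s$occasion, integer(1)))
  }
  subjects <- unique(subj)
  columns <- unique(col_id)
  fill <- function(value_fun) {
    m <- matrix(NA_real_, length(subjects), length(columns),
                dimnames = list(subjects, columns))
    for (i in seq_along(sheets)) {
      m[subj[i], col_id[i]] <- value_fun(sheets[[i]])
    }
    if (anyNA(m)) {
      if (drop_incomplete) {
        m <- m[stats::complete.cases(m), , drop = FALSE]
      } else {
        stop_ewat(paste0(
          "not every elephant was scored by every ", by,
          "; set drop_incomplete = TRUE for listwise deletion"),
          "ewat_validation_error")
      }
    }
    ratings_matrix(m)
  }
  out <- list()
  if (level %in% c("domain_overall", "domain")) {
    for (d in .domains) {
      out[[d]] <- fill(function(s) {
        ds <- domain_scores(s, cb)
        ds$value[ds$domain == d]
      })
    }
  }
  if (level %in% c("domain_overall", "overall")) {
    out[["overall"]] <- fill(function(s) {
      elephant_score(s, cb, weighting = weighting)$value
    })
  }
  out
}

#' @export
print.ewat_icc <- function(x, ...) {
  cat(sprintf(
    "<ewat_icc> ICC(A,%s) = %.3f, %d%% CI [%.3f, %.3f], %s reliability (n=%d, k=%d, p=%.3g)\n",
    if (x$unit == "single") "1" else "k", x$estimate,
    round((1 - x$alpha) * 100), x$lower, x$upper, x$band, x$n, x$k, x$p))
  invisible(x)
}

#' @export
print.ewat_reliability <- function(x, ...) {
  cat(sprintf("<ewat_reliability> %s, unit=%s: %d matrices\n",
              x$design, x$unit, nrow(x$results)))
  print(transform(x$results,
                  estimate = round_half_up(estimate, 2),
                  lower = round_half_up(lower, 2),
                  upper = round_half_up(upper, 2)),
        row.names = FALSE)
  cat(sprintf("  pooled: %.2f +/- %.2f SE (SD %.2f; range, %.2f-%.2f)\n",
              round_half_up(x$mean, 2), round_half_up(x$se, 2),
              round_half_up(x$sd, 2),
              round_half_up(x$range[1], 2), round_half_up(x$range[2], 2)))
  invisible(x)
}
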