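# Shared fixtures and independent oracles.

# Write a toy codebook DCF and load it (version = NULL skips preset counts).
toy_codebook <- function(measures) {
  path <- tempfile(fileext = ".dcf")
  recs <- vapply(measures, function(m) {
    paste0(
      "id: ", m$id, "\n",
      "name: ", m$name %||% m$id, "\n",
      "domain: ", m$domain %||% "Health", "\n",
      "basis: ", m$basis %||% "animal", "\n",
      "conditions: ", paste(m$conditions %||% "none", collapse = ", "), "\n",
      "method: ", paste(m$method %||% "observation", collapse = ", "), "\n",
      "score0: ", m$score0 %||% "bad", "\n",
      "score1: ", m$score1 %||% "middling", "\n",
      "score2: ", m$score2 %||% "good", "\n"
    )
  }, character(1))
  writeLines(paste(recs, collapse = "\n"), path)
  load_codebook(path, version = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Three-measure toy: one dual-condition (day/night) resource measure, one
# single resource, one single animal measure -> 4 items.
toy_cb4 <- function() {
  toy_codebook(list(
    list(id = "env.chain", domain = "Environment", basis = "resource",
         conditions = c("daytime", "nighttime")),
    list(id = "env.bath", domain = "Environment", basis = "resource"),
    list(id = "hlt.skin", domain = "Health", basis = "animal")
  ))
}

# Brute-force two-way sum-of-squares decomposition (direct double loops).
oracle_ss <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  rowm <- sapply(seq_len(n), function(i) sum(m[i, ]) / k)
  colm <- sapply(seq_len(k), function(j) sum(m[, j]) / n)
  ss_rows <- 0; ss_cols <- 0; ss_err <- 0; ss_tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ss_tot <- ss_tot + (m[i, j] - grand)^2
      ss_err <- ss_err + (m[i, j] - rowm[i] - colm[j] + grand)^2
    }
  }
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (rowm[i] - grand)^2
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (colm[j] - grand)^2
  list(SSR = ss_rows, SSC = ss_cols, SSE = ss_err, SST = ss_tot,
       MSR = ss_rows / (n - 1), MSC = ss_cols / (k - 1),
       MSE = ss_err / ((n - 1) * (k - 1)))
}

# Variance-component oracle for the single-rating agreement ICC: method-of-
# moments components from the mean squares, then the intraclass ratio.
oracle_icc_vc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  ss <- oracle_ss(m)
  sig_s <- (ss$MSR - ss$MSE) / k
  sig_r <- (ss$MSC - ss$MSE) / n
  sig_e <- ss$MSE
  sig_s / (sig_s + sig_r + sig_e)
}

# Mean squares via stats::aov on the long layout (independent of the
# package's closed-form decomposition).
oracle_ms_aov <- function(m) {
  d <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(y ~ subject + rater, data = d))[[1]]
  list(MSR = tab["subject", "Mean Sq"], MSC = tab["rater", "Mean Sq"],
       MSE = tab["Residuals", "Mean Sq"])
}

# Panel with a prescribed number of relevant ratings per item (6 experts).
panel_with_agreement <- function(n_agree, n_experts = 6L) {
  ratings <- t(vapply(n_agree, function(a) {
    c(rep(4L, a), rep(2L, n_experts - a))
  }, integer(n_experts)))
  rownames(ratings) <- sprintf("item%02d", seq_along(n_agree))
  ewat_panel(ratings)
}

# A complete all-constant sheet on a codebook.
constant_sheet <- function(cb, value, elephant_id = "E01", ...) {
  sc <- stats::setNames(rep(value, nrow(cb$items)), cb$items$key)
  new_sheet(elephant_id, cb, scores = sc, ...)
}
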