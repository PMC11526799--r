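#' Simulate an expert relevance panel
#'
#' Each expert x item cell is drawn "relevant" with the item's probability
#' `p_rel[i]`, in which case the ordinal rating is sampled uniformly from
#' {3, 4}; otherwise from {1, 2}. Since all content-validity indices depend
#' only on the dichotomisation, the within-class choice is cosmetic. The
#' default emulates the validation study's design: 6 experts rating the 39
#' initial measures.
#'
#' @param n_experts Number of experts (>= 2).
#' @param p_rel Per-item probability of a relevant rating; recycled across
#'   `items` if scalar.
#' @param items Item ids (default: the initial 39-measure codebook).
#' @param seed Integer seed; generation is reproducible given (spec, seed).
#' @return An `ewat_panel`.
#' @export
simulate_panel <- function(n_experts = 6L, p_rel = 1,
                           items = load_codebook(version = "initial_39")$measures$id,
                           seed = 1L) {
  if (n_experts < 2L) {
    stop_ewat("need at least 2 experts", "ewat_usage_error")
  }
  if (any(p_rel < 0 | p_rel > 1)) {
    stop_ewat("p_rel must be probabilities in [0, 1]", "ewat_usage_error")
  }
  p_rel <- rep_len(p_rel, length(items))
  with_seed(seed, {
    rel <- matrix(stats::runif(length(items) * n_experts) < p_rel,
                  nrow = length(items))  # p_rel recycles down columns
    ratings <- matrix(0L, length(items), n_experts,
                      dimnames = list(items, sprintf("expert%d", seq_len(n_experts))))
    ratings[rel] <- sample(3:4, sum(rel), replace = TRUE)
    ratings[!rel] <- sample(1:2, sum(!rel), replace = TRUE)
    ewat_panel(ratings)
  })
}

#' Simulate a two-way random-effects ratings matrix
#'
#' Draws `y_ij = mu + s_i + r_j + e_ij` with independent zero-mean normal
#' subject, rater and residual effects of the given variances. The population
#' single-rating agreement ICC is
#' `sigma2_subject / (sigma2_subject + sigma2_rater + sigma2_error)`, which
#' is the recovery target for the estimator. With `discretize = TRUE` the
#' continuous scores are cut at fixed thresholds 0.5 and 1.5 onto the
#' instrument's {0,1,2} scale (the variance-component ground truth is then
#' only approximate).
#'
#' @param n,k Subjects and raters (both >= 2). Defaults emulate the
#'   inter-rater design: 10 elephants x 3 raters.
#' @param sigma2_subject,sigma2_rater,sigma2_error Non-negative variance
#'   components.
#' @param mu Grand mean (default 1, the middle of the 0-2 scale).
#' @param discretize Cut onto {0,1,2}.
#' @param seed Integer seed.
#' @return An `ewat_ratings` matrix with attribute `"population_icc"`.
#' @export
simulate_two_way <- function(n = 10L, k = 3L, sigma2_subject = 1,
                             sigma2_rater = 0.1, sigma2_error = 0.25,
                             mu = 1, discretize = FALSE, seed = 1L) {
  if (n < 2L || k < 2L) {
    stop_ewat("need n >= 2 subjects and k >= 2 raters", "ewat_usage_error")
  }
  if (any(c(sigma2_subject, sigma2_rater, sigma2_error) < 0)) {
    stop_ewat("variance components must be non-negative", "ewat_usage_error")
  }
  with_seed(seed, {
    s <- stats::rnorm(n, 0, sqrt(sigma2_subject))
    r <- stats::rnorm(k, 0, sqrt(sigma2_rater))
    e <- matrix(stats::rnorm(n * k, 0, sqrt(sigma2_error)), n, k)
    y <- mu + outer(s, r, `+`) + e
    if (discretize) {
      y <- matrix(as.numeric(cut(y, c(-Inf, 0.5, 1.5, Inf), labels = FALSE)) - 1,
                  n, k)
    }
    dimnames(y) <- list(sprintf("S%02d", seq_len(n)), sprintf("R%d", seq_len(k)))
    out <- ratings_matrix(y)
    attr(out, "population_icc") <-
      sigma2_subject / (sigma2_subject + sigma2_rater + sigma2_error)
    out
  })
}

#' Simulate score sheets for a camp
#'
#' Each elephant has a latent welfare quality `q` in [0, 2]; every item score
#' is an independent normal draw centred on `q` with standard deviation
#' `noise`, cut at the fixed thresholds 0.5 and 1.5 onto {0,1,2}. As
#' `noise -> 0` every item equals `round(q)` region-wise and the elephant
#' score converges to `q`'s grade; with `q = 1` and symmetric noise the
#' expected score is 1.
#'
#' @param cb The active codebook.
#' @param n_elephants Number of elephants.
#' @param quality Latent quality per elephant in [0, 2]; recycled.
#' @param noise Standard deviation of the latent draw (>= 0).
#' @param camp_id,rater_id,date,occasion Sheet metadata.
#' @param seed Integer seed.
#' @return List of `ewat_sheet` objects.
#' @export
simulate_camp <- function(cb, n_elephants = 10L, quality = 1.5, noise = 0.3,
                          camp_id = "simcamp", rater_id = "rater1",
                          date = NA_character_, occasion = 1L, seed = 1L) {
  if (noise < 0) stop_ewat("noise must be >= 0", "ewat_usage_error")
  quality <- rep_len(quality, n_elephants)
  if (any(quality < 0 | quality > 2)) {
    stop_ewat("quality must be in [0, 2]", "ewat_usage_error")
  }
  n_items <- nrow(cb$items)
  with_seed(seed, {
    lapply(seq_len(n_elephants), function(i) {
      latent <- quality[i] + stats::rnorm(n_items, 0, noise)
      sc <- as.numeric(cut(latent, c(-Inf, 0.5, 1.5, Inf), labels = FALSE)) - 1
      names(sc) <- cb$items$key
      new_sheet(sprintf("E%02d", i), cb, scores = sc, camp_id = camp_id,
                rater_id = rater_id, date = date, occasion = occasion)
    })
  })
}
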