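#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions,
#' computed from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\frac12\left[\sum_i
#' \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right] - E}, \quad
#' E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}.}
#' Equals 1 for identical partitions up to relabelling, is symmetric in
#' its arguments, and is ~0 for independent partitions. Label alphabets
#' are arbitrary (any atomic vector).
#'
#' @param labels_a,labels_b equal-length label vectors, `n >= 2`.
#' @return A single number in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")) # 1
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("partitions have different lengths: ", length(labels_a), " vs ",
         length(labels_b))
  }
  n <- length(labels_a)
  stopifnot(n >= 2)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Chain diagnostics report
#'
#' Posterior summaries and stability checks for a fitted chain: mean and
#' central 95% interval of the beta trace, the distribution of the
#' occupied-cluster count, the exchange acceptance rate, and a split-half
#' stability score (ARI between point clusterings estimated from the two
#' halves of the stored samples).
#'
#' @param fit a `"potts_fit"`.
#' @return A list with `beta_mean`, `beta_ci` (2.5% and 97.5% quantiles),
#'   `k_table` (tibble of occupied-cluster counts), `accept_rate`, and
#'   `split_half_ari` (NA when labels were not stored or fewer than two
#'   samples exist).
#' @export
chain_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "potts_fit"))
  if (length(fit$beta_samples) < 1) stop("empty chain")
  k_tab <- tibble::tibble(K = as.integer(names(table(fit$K_trace))),
                          count = as.integer(table(fit$K_trace)))
  split_half <- NA_real_
  if (!is.null(fit$C_samples) && ncol(fit$C_samples) >= 2) {
    S <- ncol(fit$C_samples)
    half <- function(idx) {
      sub <- fit
      sub$C_samples <- fit$C_samples[, idx, drop = FALSE]
      summarize_labels(sub)$point_labels
    }
    split_half <- adjusted_rand_index(half(seq_len(floor(S / 2))),
                                      half((floor(S / 2) + 1):S))
  }
  list(beta_mean = mean(fit$beta_samples),
       beta_ci = quantile(fit$beta_samples, c(0.025, 0.975), names = FALSE),
       k_table = k_tab,
       k_mode = k_tab$K[which.max(k_tab$count)],
       accept_rate = round(fit$accept_rate, 3),
       split_half_ari = split_half)
}
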