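# Unadjusted (zero-order) correlation screen, pooled across imputations.

#' Zero-order Pearson correlation screen with Rubin pooling
#'
#' For each requested pair, Pearson r is computed in every imputed dataset,
#' carried to the Fisher-z scale, and combined by Rubin's rules (within
#' variance `1/(n-3)`, between variance across the m datasets). The pooled z
#' statistic yields a two-sided p-value (Student-t with the Rubin-Barnard
#' degrees of freedom; normal when the between variance vanishes, e.g. m = 1
#' or complete data). Significance is flagged at the Bonferroni-corrected
#' threshold `alpha / n_tests`; at the study's alpha = 0.05 over the 21
#' trait x depression pairs this is p < 2.38e-3.
#'
#' @param imp an `imputed_set`.
#' @param pairs data.frame with columns `i`, `j`, `pair` (defaults to the 21
#'   trait x depression pairs).
#' @param alpha nominal level in (0, 1).
#' @return data.frame: `pair`, `r_pooled`, `p_pooled`, `significant`, and the
#'   threshold as attribute `threshold`.
#' @export
zero_order_screen <- function(imp, pairs = pair_sets()$trait_depression,
                              alpha = 0.05) {
  stopifnot(inherits(imp, "imputed_set"), alpha > 0, alpha < 1)
  m <- length(imp$datasets)
  n <- nrow(imp$datasets[[1]])
  threshold <- alpha / nrow(pairs)
  out <- pairs
  out$r_pooled <- NA_real_
  out$p_pooled <- NA_real_
  for (row in seq_len(nrow(pairs))) {
    z <- vnapply(imp$datasets, function(d)
      atanh(stats::cor(d[, pairs$i[row]], d[, pairs$j[row]])))
    qbar <- mean(z)
    w <- 1 / (n - 3)                       # within-imputation variance
    b <- if (m > 1) stats::var(z) else 0   # between-imputation variance
    tot <- w + (1 + 1 / m) * b
    stat <- qbar / sqrt(tot)
    p <- if (b > 0) {
      df <- (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
      2 * stats::pt(-abs(stat), df)
    } else {
      2 * stats::pnorm(-abs(stat))
    }
    out$r_pooled[row] <- tanh(qbar)
    out$p_pooled[row] <- p
  }
  out$significant <- out$p_pooled < threshold
  attr(out, "threshold") <- threshold
  out
}

#' Bonferroni-corrected threshold
#' @param alpha nominal level.
#' @param n_tests number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 21L) alpha / n_tests
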