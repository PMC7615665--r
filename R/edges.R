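# Savage-Dickey Bayes factors, edge classification, replication inference,
# and network-level summaries.

BF_FLOOR <- 1e-4
BF_CEILING <- 1e4

#' Savage-Dickey Bayes factor for one edge
#'
#' `BF01 = posterior density of rho at 0 / prior density of rho at 0`. The
#' prior ordinate is the analytic scaled-Beta value from the `prior_spec`;
#' the posterior ordinate is estimated from the pooled draws by a Gaussian
#' kernel density with Silverman bandwidth (`method = "normal"` swaps in a
#' normal approximation as a cross-check). BF values are clamped to
#' `[1e-4, 1e4]`; a clamped value is flagged.
#'
#' @param rho_draws posterior draws of one partial correlation (>= 1000
#'   recommended).
#' @param prior a `prior_spec`.
#' @param method posterior density estimator at 0.
#' @return list: `bf01`, `bf10`, `floored`.
#' @export
savage_dickey_bf <- function(rho_draws, prior,
                             method = c("kde", "normal")) {
  method <- match.arg(method)
  stopifnot(inherits(prior, "prior_spec"))
  if (length(rho_draws) < 1000L)
    warning("fewer than 1,000 posterior draws: BF estimate will be unstable")
  f0_post <- if (method == "kde") {
    bw <- stats::bw.nrd0(rho_draws)
    mean(stats::dnorm(0, mean = rho_draws, sd = bw))
  } else {
    stats::dnorm(0, mean = mean(rho_draws), sd = stats::sd(rho_draws))
  }
  bf01 <- f0_post / prior_density0(prior)
  floored <- bf01 < BF_FLOOR || bf01 > BF_CEILING || !is.finite(bf01)
  bf01 <- min(max(bf01, BF_FLOOR), BF_CEILING)
  list(bf01 = bf01, bf10 = 1 / bf01, floored = floored)
}

#' Three-way Bayes-factor classification of every edge
#'
#' Per pair: BF01/BF10, posterior mean rho, central 95% credible interval,
#' and the status rule `associated` iff `BF10 >= threshold`, `independent`
#' iff `BF01 >= threshold`, otherwise `ambiguous`.
#'
#' @param draws a `posterior_draws`.
#' @param prior a `prior_spec` (defaults to the one carried by `draws`).
#' @param threshold BF cut (> 1; study default 3).
#' @param pairs data.frame `i`, `j` (default all pairs of the draw's nodes).
#' @param method passed to [savage_dickey_bf()].
#' @return data.frame of class `edge_decisions`: `pair`, `i`, `j`, `bf01`,
#'   `bf10`, `rho_mean`, `cri_low`, `cri_high`, `status`.
#' @export
classify_edges <- function(draws, prior = NULL, threshold = 3,
                           pairs = NULL, method = "kde") {
  stopifnot(threshold > 1)
  prior <- prior %||% draws$prior
  if (is.null(pairs)) pairs <- pairs_of(draws$labels)
  out <- data.frame(pair = paste(draws$labels[pairs$i], draws$labels[pairs$j],
                                 sep = "--"),
                    i = pairs$i, j = pairs$j,
                    bf01 = NA_real_, bf10 = NA_real_, rho_mean = NA_real_,
                    cri_low = NA_real_, cri_high = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    rd <- draws$rho[, out$i[r], out$j[r]]
    bf <- savage_dickey_bf(rd, prior, method = method)
    q <- stats::quantile(rd, c(0.025, 0.975))
    out$bf01[r] <- bf$bf01
    out$bf10[r] <- bf$bf10
    out$rho_mean[r] <- mean(rd)
    out$cri_low[r] <- q[[1]]
    out$cri_high[r] <- q[[2]]
  }
  out$status <- ifelse(out$bf10 >= threshold, "associated",
                       ifelse(out$bf01 >= threshold, "independent", "ambiguous"))
  class(out) <- c("edge_decisions", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Cross-cohort replication status per edge
#'
#' Inference is drawn only on findings replicated in both cohorts:
#' `replicated_association` needs `associated` in both with matching sign of
#' the posterior mean; `replicated_independence` needs `independent` in both;
#' `discordant` marks associated-vs-independent conflicts (or sign-conflicting
#' associations); everything else is `unreplicated`.
#'
#' @param decisions_a,decisions_b `edge_decisions` over identical pair sets.
#' @return data.frame of class `replication_summary`: `pair`, `i`, `j`,
#'   `status_a`, `status_b`, `sign_a`, `sign_b`, `rho_mean_a`, `rho_mean_b`,
#'   `replication`.
#' @export
replicate_edges <- function(decisions_a, decisions_b) {
  if (!identical(decisions_a$pair, decisions_b$pair))
    stop("pair sets of the two cohorts do not match")
  sa <- decisions_a$status; sb <- decisions_b$status
  sga <- sign(decisions_a$rho_mean); sgb <- sign(decisions_b$rho_mean)
  repl <- rep("unreplicated", length(sa))
  repl[sa == "associated" & sb == "associated" & sga == sgb] <- "replicated_association"
  repl[sa == "associated" & sb == "associated" & sga != sgb] <- "discordant"
  repl[sa == "independent" & sb == "independent"] <- "replicated_independence"
  repl[(sa == "associated" & sb == "independent") |
       (sa == "independent" & sb == "associated")] <- "discordant"
  out <- data.frame(pair = decisions_a$pair, i = decisions_a$i, j = decisions_a$j,
                    status_a = sa, status_b = sb, sign_a = sga, sign_b = sgb,
                    rho_mean_a = decisions_a$rho_mean,
                    rho_mean_b = decisions_b$rho_mean,
                    replication = repl, stringsAsFactors = FALSE)
  class(out) <- c("replication_summary", class(out))
  out
}

# percentage in the study's mixed reporting style (52%, 9.5%, 22%):
# two significant figures
density_percent <- function(n_supported, n_possible) {
  if (n_possible == 0) return(0)
  signif(100 * n_supported / n_possible, 2)
}

#' Network density over a pair set
#'
#' Counts supported edges (status `associated`, or replication
#' `replicated_association` for replication summaries) relative to the
#' possible edges in the pair set. Percentages follow the study's reporting
#' style (nearest integer, one decimal where the value demands it:
#' 11/21 -> 52, 2/21 -> 9.5).
#'
#' @param decisions an `edge_decisions` or `replication_summary`.
#' @param pair_set data.frame with a `pair` column naming the pairs to count
#'   over (see [pair_sets()]).
#' @param count for replication summaries, which replication status to count
#'   (default `replicated_association`; use `replicated_independence` for the
#'   independence proportions).
#' @return list: `pair_set_n`, `n_supported`, `n_possible`, `density_pct`.
#' @export
network_density <- function(decisions, pair_set,
                            count = "replicated_association") {
  stopifnot(nrow(pair_set) > 0)
  rows <- decisions[decisions$pair %in% pair_set$pair, , drop = FALSE]
  n_possible <- nrow(pair_set)
  n_supported <- if (inherits(decisions, "replication_summary"))
    sum(rows$replication == count)
  else
    sum(rows$status == "associated")
  list(n_supported = n_supported, n_possible = n_possible,
       density_pct = density_percent(n_supported, n_possible))
}

#' Pearson similarity of two cohorts' weighted adjacency matrices
#'
#' Correlates the posterior-mean partial correlations of the two cohorts over
#' a pair set -- by default only pairs replicated as associations, matching
#' the study's comparison of replicated edge magnitudes.
#'
#' @param decisions_a,decisions_b `edge_decisions` over identical pairs.
#' @param pairs optional pair subset (data.frame with `pair`); default all.
#' @param replicated_only restrict to replicated associations?
#' @return Pearson r (errors if fewer than 3 pairs remain).
#' @export
adjacency_similarity <- function(decisions_a, decisions_b, pairs = NULL,
                                 replicated_only = TRUE) {
  if (!identical(decisions_a$pair, decisions_b$pair))
    stop("pair sets of the two cohorts do not match")
  keep <- rep(TRUE, nrow(decisions_a))
  if (!is.null(pairs)) keep <- decisions_a$pair %in% pairs$pair
  if (replicated_only) {
    repl <- replicate_edges(decisions_a, decisions_b)
    keep <- keep & repl$replication == "replicated_association"
  }
  if (sum(keep) < 3L)
    stop("fewer than 3 pairs available for the adjacency similarity")
  stats::cor(decisions_a$rho_mean[keep], decisions_b$rho_mean[keep])
}

#' Posterior index of mediation for an (X, M, Y) triple
#'
#' Per posterior draw, `ab_cs = beta(M <- X) * beta(Y <- M)` from the
#' GGM-converted standardized coefficients; summarised by the posterior mean
#' and central 95% credible interval.
#'
#' @param beta a `beta_draws` object (see [beta_from_draws()]).
#' @param x,m,y node labels or indices: exposure, mediator, outcome
#'   (distinct).
#' @return list of class `mediation_estimate`: `triple`, `ab_mean`, `ab_cri`,
#'   `ab_draws`.
#' @export
mediation_index <- function(beta, x, m, y) {
  idx <- function(v) if (is.character(v)) match(v, beta$labels) else v
  x <- idx(x); m <- idx(m); y <- idx(y)
  if (anyNA(c(x, m, y))) stop("unknown node label in mediation triple")
  if (length(unique(c(x, m, y))) != 3L) stop("x, m, y must be distinct nodes")
  ab <- beta$beta[, m, x] * beta$beta[, y, m]
  structure(list(triple = paste(beta$labels[c(x, m, y)], collapse = " -> "),
                 ab_mean = mean(ab),
                 ab_cri = unname(stats::quantile(ab, c(0.025, 0.975))),
                 ab_draws = ab),
            class = "mediation_estimate")
}

#' @export
print.mediation_estimate <- function(x, ...) {
  cat(sprintf("%s: ab_cs = %.3f (95%% CrI %.3f, %.3f)\n",
              x$triple, x$ab_mean, x$ab_cri[1], x$ab_cri[2]))
  invisible(x)
}

#' Write edge decisions or replication summaries as TSV
#' @param x an `edge_decisions` or `replication_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
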