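# Canonical variable schema and pair sets.
#
# Thirteen prorated scale scores per individual: seven neurodevelopmental
# traits, emotional dysregulation plus two social-environmental stressors, and
# depressive symptoms (sMFQ) at ages 12, 16 and 21. Two cohort presets carry
# the same canonical variable names but instrument-specific score ranges and
# collection ages, mirroring two near-but-not-identical UK cohorts.

#' Canonical order of the 13 network variables
#' @return character vector of length 13.
#' @export
ndnet_variables <- function() {
  c("autistic", "hyperactive_impulsive", "inattentive", "general_cognitive",
    "speech_syntax", "pragmatic", "learning",
    "dysregulation", "peer_problems", "academic",
    "dep_12", "dep_16", "dep_21")
}

#' Variable schema for a cohort preset
#'
#' Returns the 13-variable schema: block membership, instrument score bounds,
#' nominal collection age, and the marginal skew parameter used by the
#' synthetic generator (positive = right skew, negative = left skew, magnitude
#' = degree of the exponential-quantile warp).
#'
#' @param cohort `"cohort_A"` (the smaller cohort, CAST/CPRS-style bounds) or
#'   `"cohort_B"` (the larger cohort, SCDC/DAWBA-style bounds).
#' @return a `data.frame` with one row per variable and columns `name`,
#'   `block`, `score_min`, `score_max`, `timepoint`, `skew_target`.
#' @export
ndnet_schema <- function(cohort = c("cohort_A", "cohort_B")) {
  cohort <- match.arg(cohort)
  name <- ndnet_variables()
  block <- c(rep("trait", 7L), rep("stressor_dysregulation", 3L), rep("depression", 3L))
  skew <- c(2.5, 2.5, 2.5, 0.2, -1.5, -1.5, -0.8, 2.5, 2.5, -1.2, 3, 3, 3)
  if (cohort == "cohort_A") {
    score_min <- c(0, 0, 0, -3, 0, 0, 0, 0, 0, 9, 0, 0, 0)
    score_max <- c(31, 27, 27, 3, 16, 8, 82, 10, 10, 45, 26, 26, 16)
    timepoint <- c(8, 8, 8, 9, 9, 9, 10, 9, 9, 10, 12, 16, 21)
  } else {
    score_min <- c(0, 0, 0, 45, 45, 96, 0, 0, 0, 0, 0, 0, 0)
    score_max <- c(24, 18, 18, 151, 70, 162, 50, 10, 10, 99, 26, 26, 26)
    timepoint <- c(7.58, 7.58, 7.58, 8.5, 9.58, 9.58, 7.5, 9.58, 9.58, 11, 12, 16, 21)
  }
  out <- data.frame(name = name, block = block, score_min = score_min,
                    score_max = score_max, timepoint = timepoint,
                    skew_target = skew, stringsAsFactors = FALSE)
  validate_schema(out)
  out
}

validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema),
            all(c("name", "block", "score_min", "score_max",
                  "timepoint", "skew_target") %in% names(schema)))
  if (nrow(schema) != 13L)
    stop("schema must have exactly 13 variables, got ", nrow(schema))
  counts <- table(schema$block)
  if (!identical(as.integer(counts[c("trait", "stressor_dysregulation", "depression")]),
                 c(7L, 3L, 3L)))
    stop("schema blocks must be 7 traits, 3 stressor/dysregulation, 3 depression waves")
  if (any(schema$score_min >= schema$score_max))
    stop("schema score_min must be < score_max for every variable")
  invisible(schema)
}

trait_vars <- function() ndnet_variables()[1:7]
stressor_vars <- function() ndnet_variables()[8:10]
depression_vars <- function() ndnet_variables()[11:13]

#' Canonical pair sets over the 13 network nodes
#'
#' The block-crossing pair sets the analysis reports on: 21 trait-trait pairs,
#' 21 trait x stressor/dysregulation pairs, 21 trait x depression pairs, and 9
#' stressor/dysregulation x depression pairs; `all_pairs` holds all 78
#' unordered pairs (the remaining 6 are within the stressor and depression
#' blocks).
#'
#' @return a list of data.frames, each with integer columns `i`, `j`
#'   (canonical indices, `i < j`) and a `pair` label.
#' @export
pair_sets <- function() {
  vars <- ndnet_variables()
  mk <- function(ii, jj) {
    g <- expand.grid(i = ii, j = jj)
    g <- g[g$i != g$j, , drop = FALSE]
    idx <- cbind(pmin(g$i, g$j), pmax(g$i, g$j))
    idx <- unique(idx[order(idx[, 1], idx[, 2]), , drop = FALSE])
    data.frame(i = idx[, 1], j = idx[, 2],
               pair = paste(vars[idx[, 1]], vars[idx[, 2]], sep = "--"),
               stringsAsFactors = FALSE)
  }
  tt <- mk(1:7, 1:7)
  ts <- mk(1:7, 8:10)
  td <- mk(1:7, 11:13)
  sd_ <- mk(8:10, 11:13)
  ss <- mk(8:10, 8:10)
  dd <- mk(11:13, 11:13)
  all <- mk(1:13, 1:13)
  stopifnot(nrow(tt) == 21L, nrow(ts) == 21L, nrow(td) == 21L,
            nrow(sd_) == 9L, nrow(all) == 78L,
            nrow(tt) + nrow(ts) + nrow(td) + nrow(sd_) + nrow(ss) + nrow(dd) == 78L)
  list(trait_trait = tt, trait_stressor = ts, trait_depression = td,
       stressor_depression = sd_, within_stressor = ss,
       within_depression = dd, all_pairs = all)
}

# pair set over an arbitrary label vector (used for the traits-only 7-node model)
pairs_of <- function(labels) {
  cmb <- utils::combn(length(labels), 2)
  data.frame(i = cmb[1, ], j = cmb[2, ],
             pair = paste(labels[cmb[1, ]], labels[cmb[2, ]], sep = "--"),
             stringsAsFactors = FALSE)
}
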