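#' Unpaired Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test on raw scores. When the pooled sample size is at
#' most `exact_max_n`, the p-value comes from the exact permutation
#' distribution of the Mann-Whitney U statistic (complete enumeration of all
#' group assignments, midranks for ties); otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y Numeric score vectors (each non-empty).
#' @param alternative One of "two.sided", "less", "greater" (x relative to y).
#' @param exact_max_n Largest pooled size for which the exact branch is used.
#' @return p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))  # exact: 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less",
                                                    "greater"),
                              exact_max_n = 20) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2   # Mann-Whitney U for x
  if ((m + n) <= exact_max_n) {
    combos <- utils::combn(m + n, m)
    us <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
    mu <- m * n / 2
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(us - mu) >= abs(u - mu) - eps),
      greater = mean(us >= u - eps),
      less = mean(us <= u + eps))
    return(p)
  }
  nn <- m + n
  tab <- table(r)
  sigma2 <- (m * n / 12) * ((nn + 1) - sum(tab^3 - tab) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(1)  # all observations identical
  mu <- m * n / 2
  cc <- function(z) sign(z) * 0.5               # continuity correction
  p <- switch(alternative,
    two.sided = {
      z <- (u - mu - cc(u - mu)) / sqrt(sigma2)
      min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    },
    greater = stats::pnorm((u - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE),
    less = stats::pnorm((u - mu + 0.5) / sqrt(sigma2)))
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity, capped
#' at 1. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param pvalues p-values in (0, 1]; NA is rejected.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)))
    stop("p-values must be finite (no NA/NaN)")
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-target test of guide fitness against control guides
#'
#' For every target, compares the fitness scores of its guides with the
#' fitness scores of the control guides by a two-sided unpaired Wilcoxon
#' rank-sum test; BH adjustment is applied across all targets (one family per
#' condition).
#'
#' @param guide_fitness data.frame with `guide_id`, `target_id`, `fitness`
#'   for one condition (controls included, labelled in `target_id`).
#' @param control_label Value of `target_id` marking control guides.
#' @return data.frame `target_id`, `n_guides`, `p`, `p_adj`.
#' @export
condition_gene_test <- function(guide_fitness, control_label = "ctrl") {
  ctrl <- guide_fitness$fitness[guide_fitness$target_id == control_label]
  if (length(ctrl) == 0L) stop("no control guides found (label '",
                               control_label, "')")
  targets <- guide_fitness[guide_fitness$target_id != control_label, ,
                           drop = FALSE]
  sp <- split(targets$fitness, targets$target_id)
  p <- vapply(sp, function(f) wilcoxon_rank_sum(f, ctrl), numeric(1))
  data.frame(target_id = names(sp),
             n_guides = vapply(sp, length, integer(1)),
             p = as.numeric(p), p_adj = bh_adjust(as.numeric(p)),
             row.names = NULL)
}

#' Per-target test of guide fitness between two conditions
#'
#' For every target, compares the fitness scores of its guides under
#' condition A with those under condition B (two-sided unpaired Wilcoxon
#' rank-sum); BH adjustment across targets. Scores may be one per guide
#' (replicate-averaged) or one per guide and replicate; pooling per-replicate
#' scores increases the resolution of the exact/normal null and is the
#' default in the full pipeline.
#'
#' @param fitness_a,fitness_b data.frames with `target_id` and `fitness` for
#'   the two conditions.
#' @return data.frame `target_id`, `n_a`, `n_b`, `p`, `p_adj` (targets present
#'   in both conditions).
#' @export
between_condition_test <- function(fitness_a, fitness_b) {
  sa <- split(fitness_a$fitness, fitness_a$target_id)
  sb <- split(fitness_b$fitness, fitness_b$target_id)
  ids <- intersect(names(sa), names(sb))
  p <- vapply(ids, function(id) wilcoxon_rank_sum(sa[[id]], sb[[id]]),
              numeric(1))
  data.frame(target_id = ids,
             n_a = vapply(sa[ids], length, integer(1)),
             n_b = vapply(sb[ids], length, integer(1)),
             p = as.numeric(p), p_adj = bh_adjust(as.numeric(p)),
             row.names = NULL)
}

#' Impact score: distance from the identity line
#'
#' Signed perpendicular distance of the point (fitness under condition A,
#' fitness under condition B) from the identity line y = x:
#' `d = (y0 - x0) / sqrt(2)`. Positive values mean relatively better growth
#' under condition B (the stress condition).
#'
#' @param fitness_a Fitness under condition A (x0, e.g. 4% CO2).
#' @param fitness_b Fitness under condition B (y0, e.g. 30% CO2).
#' @return Impact score d.
#' @examples
#' impact_score(-3.20, 1.95)  # 3.64
#' @export
impact_score <- function(fitness_a, fitness_b) {
  (fitness_b - fitness_a) / sqrt(2)
}

#' Combined score: impact times evidence
#'
#' Product of the impact score and the negative decadic logarithm of the
#' adjusted p-value, mixing effect size and statistical reliability.
#'
#' @param d Impact score.
#' @param p_adj Adjusted p-value in (0, 1].
#' @return Combined score.
#' @export
combined_score <- function(d, p_adj) {
  if (any(p_adj <= 0, na.rm = TRUE))
    stop("p_adj must be > 0; cap underflowed p-values at .Machine$double.xmin")
  if (any(p_adj > 1, na.rm = TRUE)) stop("p_adj must be <= 1")
  d * (-log10(p_adj))
}

#' Classify fitness scores into hit classes
#'
#' Depleted if fitness < -1, enriched if fitness > 1 (strict inequalities),
#' neutral otherwise.
#'
#' @param fitness Fitness score(s).
#' @return Character vector in \{"depleted", "neutral", "enriched"\}.
#' @export
classify_hits <- function(fitness) {
  stopifnot(all(is.finite(fitness)))
  ifelse(fitness < -1, "depleted", ifelse(fitness > 1, "enriched", "neutral"))
}
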