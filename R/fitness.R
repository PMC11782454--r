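#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over guides, of
#' the ratio of the guide's count in that sample to the guide's geometric
#' mean across samples. Only guides with strictly positive counts in every
#' sample enter the reference, which makes the factor track the majority
#' (neutral) guides rather than strongly selected ones. This is the
#' median-of-ratios scheme popularized by count-based differential-abundance
#' tools, re-implemented here without dispersion modelling.
#'
#' @param counts Non-negative count matrix (guides x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- cbind(s1 = c(2, 3, 5), s2 = c(4, 6, 10))
#' size_factors(m)  # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no guide has positive counts in every sample; ",
         "consider adding a pseudocount before normalization")
  logg <- rowMeans(log(counts[pos, , drop = FALSE]))
  f <- apply(counts[pos, , drop = FALSE], 2,
             function(col) exp(stats::median(log(col) - logg)))
  if (any(!is.finite(f) | f <= 0)) stop("non-positive size factor computed")
  f
}

#' Per-guide log2 fold-change profiles versus generation 0
#'
#' Normalizes counts by the supplied size factors, adds a pseudocount, and
#' computes, for every guide and every (condition, replicate), the log2 fold
#' change of each sampled generation relative to that replicate's own
#' generation-0 sample.
#'
#' @param counts Count matrix (guides x samples, rownames = guide ids).
#' @param factors Size factors named by sample (see [size_factors()]).
#' @param sheet Sample sheet data.frame (see [read_sample_sheet()]).
#' @param pseudocount Added to normalized counts before taking logs.
#' @return data.frame with columns `guide_id`, `condition`, `replicate`,
#'   `generation`, `log2fc` (long format; includes the generation-0 rows,
#'   which are identically 0).
#' @export
log2fc_profiles <- function(counts, factors, sheet, pseudocount = 0.5) {
  sheet <- validate_sample_sheet(sheet)
  miss <- setdiff(sheet$sample, colnames(counts))
  if (length(miss)) stop("samples missing from count matrix: ",
                         paste(miss, collapse = ", "))
  norm <- sweep(counts[, sheet$sample, drop = FALSE], 2,
                factors[sheet$sample], "/") + pseudocount
  ln <- log2(norm)
  cr <- unique(sheet[, c("condition", "replicate")])
  out <- vector("list", nrow(cr))
  for (i in seq_len(nrow(cr))) {
    sel <- which(sheet$condition == cr$condition[i] &
                   sheet$replicate == cr$replicate[i])
    gens <- sheet$generation[sel]
    ref <- sel[gens == 0]
    lfc <- ln[, sel, drop = FALSE] - ln[, ref]
    out[[i]] <- data.frame(
      guide_id = rep(rownames(counts), times = length(sel)),
      condition = cr$condition[i], replicate = cr$replicate[i],
      generation = rep(gens, each = nrow(counts)),
      log2fc = as.vector(lfc))
  }
  res <- do.call(rbind, out)
  res[order(res$condition, res$replicate, res$generation, res$guide_id), ,
      drop = FALSE]
}

#' Replicate-mean log2 fold-change profiles
#'
#' Averages per-replicate log2 fold changes within each condition, yielding
#' one profile per guide and condition.
#'
#' @param profiles Long data.frame from [log2fc_profiles()].
#' @return data.frame `guide_id`, `condition`, `generation`, `log2fc`,
#'   `n_replicates`.
#' @export
replicate_mean_profiles <- function(profiles) {
  agg <- stats::aggregate(log2fc ~ guide_id + condition + generation,
                          data = profiles, FUN = mean)
  n <- stats::aggregate(log2fc ~ guide_id + condition + generation,
                        data = profiles, FUN = length)
  agg$n_replicates <- n$log2fc
  agg[order(agg$condition, agg$guide_id, agg$generation), , drop = FALSE]
}

#' Area-under-curve fitness score of one log2 fold-change profile
#'
#' Trapezoidal integral of log2 fold change over the generation axis. With
#' `normalize = TRUE` (default) the area is divided by the final generation,
#' putting the score on the per-generation log2 fold-change scale: a constant
#' post-induction log2FC of c over generations (0, 4, 8, 10) scores 0.8 c.
#'
#' @param generations Sampled generations, must start at 0 and be increasing.
#' @param log2fc Log2 fold changes at those generations (0 at generation 0).
#' @param normalize Divide the raw area by the final generation.
#' @return Fitness score (dimensionless).
#' @examples
#' auc_fitness(c(0, 4, 8, 10), c(0, -2, -4, -5))          # -2.5
#' auc_fitness(c(0, 4, 8, 10), c(0, -2, -4, -5), FALSE)   # -25
#' @export
auc_fitness <- function(generations, log2fc, normalize = TRUE) {
  stopifnot(length(generations) == length(log2fc))
  if (length(generations) < 2)
    stop("need at least 2 points (including generation 0)")
  o <- order(generations)
  g <- generations[o]; y <- log2fc[o]
  if (g[1] != 0) stop("profile must include generation 0")
  area <- sum(diff(g) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (normalize) area / g[length(g)] else area
}

#' Per-guide fitness scores from log2 fold-change profiles
#'
#' Applies [auc_fitness()] to every guide's profile. With
#' `by_replicate = FALSE` the replicate-mean profile is integrated (one score
#' per guide and condition); with `by_replicate = TRUE` each replicate's
#' profile is integrated separately. Because the trapezoid is linear in the
#' profile, the replicate-mean score equals the mean of per-replicate scores
#' when all replicates share the sampled generations.
#'
#' @param profiles Long data.frame from [log2fc_profiles()].
#' @param normalize Passed to [auc_fitness()].
#' @param by_replicate Keep replicates separate.
#' @return data.frame `guide_id`, `condition`, (`replicate`,) `fitness`,
#'   `n_points`.
#' @export
guide_fitness_scores <- function(profiles, normalize = TRUE,
                                 by_replicate = FALSE) {
  if (!by_replicate) profiles <- replicate_mean_profiles(profiles)
  keys <- if (by_replicate) c("guide_id", "condition", "replicate")
          else c("guide_id", "condition")
  sp <- split(profiles, profiles[keys], drop = TRUE)
  out <- lapply(sp, function(b) {
    row <- b[1, keys, drop = FALSE]
    row$fitness <- auc_fitness(b$generation, b$log2fc, normalize)
    row$n_points <- nrow(b)
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation- and efficiency-based guide weights within one target
#'
#' Guides whose replicate-mean profiles do not co-vary with the other guides
#' targeting the same gene are down-weighted: the weight of guide i is
#' proportional to the mean over the other guides of the pairwise Pearson
#' correlation clamped at zero, multiplied by an optional repression
#' efficiency prior. If all raw weights vanish (or a single guide is
#' supplied) the weights fall back to uniform. Weights are normalized to sum
#' to one.
#'
#' @param profile_matrix Numeric matrix, one row per guide, columns =
#'   post-induction generations (replicate-mean log2 fold changes).
#' @param efficiency Per-guide efficiency prior in \[0, 1\] (default 1).
#' @return Numeric weight vector summing to 1.
#' @examples
#' m <- rbind(a = c(-1, -2, -3), b = c(-1, -2, -3), c = c(1, 2, 3))
#' guide_weights(m)  # c(0.5, 0.5, 0): the anti-correlated guide is dropped
#' @export
guide_weights <- function(profile_matrix, efficiency = 1) {
  if (is.null(dim(profile_matrix)))
    profile_matrix <- matrix(profile_matrix, nrow = 1)
  n <- nrow(profile_matrix)
  efficiency <- rep_len(efficiency, n)
  if (n == 1L) return(1)
  cm <- suppressWarnings(stats::cor(t(profile_matrix)))
  cm[!is.finite(cm)] <- 0          # zero-variance profiles carry no signal
  cm[cm < 0] <- 0                  # anti-correlation is evidence against, not for
  diag(cm) <- NA
  raw <- rowMeans(cm, na.rm = TRUE) * efficiency
  raw[!is.finite(raw)] <- 0
  if (sum(raw) <= 0) raw <- rep(1, n)
  raw / sum(raw)
}

#' Weighted gene-level fitness with bootstrap confidence interval
#'
#' The gene score is the weighted mean of its guides' fitness scores; the
#' uncertainty is a percentile bootstrap over guides, resampling guides with
#' probability proportional to their weights.
#'
#' @param fitness Per-guide fitness scores.
#' @param weights Non-negative weights (normalized internally); default
#'   uniform.
#' @param bootstrap_reps Number of bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @return List with `fitness`, `ci_lo`, `ci_hi`, `n_guides`, `weights`.
#' @export
gene_fitness <- function(fitness, weights = NULL, bootstrap_reps = 1000,
                         conf = 0.95, seed = NULL) {
  n <- length(fitness)
  if (n == 0L) stop("empty guide set")
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  est <- sum(w * fitness)
  if (n == 1L) {
    return(list(fitness = est, ci_lo = est, ci_hi = est,
                n_guides = 1L, weights = w))
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * bootstrap_reps, replace = TRUE, prob = w),
                nrow = n)
  boots <- colMeans(matrix(fitness[idx], nrow = n))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(fitness = est, ci_lo = qs[1], ci_hi = qs[2], n_guides = n, weights = w)
}
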