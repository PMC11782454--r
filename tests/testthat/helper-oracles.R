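# Independent oracles and small fixture builders shared across tests.

# Exact two-sided rank-sum p-value by complete enumeration of all
# choose(m+n, m) group assignments (tie-free data assumed).
enumerate_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * n / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Step-up BH oracle written independently of stats::p.adjust.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force per-position maximal-|fitness| coverage oracle.
brute_force_coverage <- function(guides) {
  guides <- guides[stats::complete.cases(
    guides[, c("chrom", "start", "end", "fitness")]), , drop = FALSE]
  out <- list()
  for (ch in sort(unique(guides$chrom))) {
    g <- guides[guides$chrom == ch, , drop = FALSE]
    lo <- min(g$start); hi <- max(g$end)
    val <- rep(NA_real_, hi - lo)
    for (pos in lo:(hi - 1)) {
      cov <- which(g$start <= pos & g$end > pos)
      if (!length(cov)) next
      f <- g$fitness[cov]
      best <- cov[order(-abs(f), -sign(f), g$start[cov])][1]
      val[pos - lo + 1] <- g$fitness[best]
    }
    pos <- lo:(hi - 1)
    covered <- !is.na(val)
    if (!any(covered)) next
    runs <- rle(paste0(covered, "|", val))
    ends <- cumsum(runs$lengths)
    starts <- c(1, head(ends, -1) + 1)
    for (k in seq_along(runs$lengths)) {
      if (!covered[starts[k]]) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = pos[starts[k]], end = pos[ends[k]] + 1,
        value = val[starts[k]])
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Random small guide sets for coverage-rule testing.
random_guide_set <- function(n, max_pos = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample(3:12, n, replace = TRUE)
  data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
             start = start, end = start + width,
             fitness = round(stats::runif(n, -3, 3), 2))
}

# Tiny deterministic two-condition screen fixture built by hand: counts laid
# out so that normalized log2 fold changes are exact round numbers.
tiny_screen_fixture <- function() {
  guides <- c("g1_1", "g1_2", "ctrl_1", "ctrl_2")
  gens <- c(0, 4, 8, 10)
  sheet <- data.frame(
    sample = paste0("A_rep1_gen", gens),
    condition = "A", replicate = 1, generation = gens)
  # guide g1_* halves every generation relative to controls
  counts <- rbind(
    g1_1 = c(1024, 64, 4, 1),
    g1_2 = c(1024, 64, 4, 1),
    ctrl_1 = c(1024, 1024, 1024, 1024),
    ctrl_2 = c(1024, 1024, 1024, 1024))
  colnames(counts) <- sheet$sample
  storage.mode(counts) <- "integer"
  lib <- data.frame(guide_id = guides,
                    target_id = c("gene1", "gene1", "ctrl", "ctrl"))
  list(counts = counts, sheet = sheet, library = lib)
}
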