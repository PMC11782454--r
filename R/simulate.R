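#' Configuration for a simulated turbidostat CRISPRi screen
#'
#' The defaults mirror the study design this package targets: five sgRNAs per
#' target, control guides labelled `"ctrl"`, samples at generations 0, 4, 8
#' and 10 after induction, four replicates in the benign condition and three
#' in the stress condition (one stress culture failed), mean growth rates of
#' 0.058 h-1 and 0.038 h-1 used as wall-clock metadata, and a sequencing
#' depth of two million reads per sample.
#'
#' @param n_genes Number of (non-control) targets.
#' @param guides_per_gene Guides per target.
#' @param n_controls Number of non-targeting control guides.
#' @param conditions Named numeric vector of mean growth rates (h-1); names
#'   are condition labels. The first condition is the benign reference (A),
#'   the second the stress condition (B).
#' @param replicates Integer vector of replicate counts, one per condition.
#' @param generations Sampled population doublings, starting at 0.
#' @param depth Reads per sample.
#' @param dispersion Squared coefficient of variation of the multiplicative
#'   gamma noise applied to expected guide fractions before sequencing
#'   (library-prep overdispersion); 0 disables it. The default 0.004 gives a
#'   null log2FC standard deviation of about 0.2 at the default depth.
#' @param dirichlet_conc Concentration of the symmetric Dirichlet for initial
#'   guide abundances (larger = more even library).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20, guides_per_gene = 5, n_controls = 10,
                       conditions = c(`4pct` = 0.058, `30pct` = 0.038),
                       replicates = c(4, 3),
                       generations = c(0, 4, 8, 10),
                       depth = 2e6, dispersion = 0.004,
                       dirichlet_conc = 5, seed = 1) {
  stopifnot(n_genes > 0, guides_per_gene > 0, n_controls >= 0,
            length(conditions) >= 1, length(replicates) == length(conditions),
            all(replicates >= 1), generations[1] == 0,
            !is.unsorted(generations, strictly = TRUE), depth > 0)
  if (dispersion < 0) stop("dispersion must be non-negative")
  structure(list(n_genes = n_genes, guides_per_gene = guides_per_gene,
                 n_controls = n_controls, conditions = conditions,
                 replicates = replicates, generations = generations,
                 depth = depth, dispersion = dispersion,
                 dirichlet_conc = dirichlet_conc, seed = seed),
            class = "sim_config")
}

#' Expected log2 fold change of a guide under turbidostat selection
#'
#' Selection is modelled per population generation: a guide with relative
#' fitness w doubles `2^w`-fold per population doubling, so in the
#' small-fraction approximation its log2 fold change after g generations is
#' `g * (w - wbar)`, where wbar is the population-mean fitness.
#'
#' @param w Guide relative fitness (1 = neutral).
#' @param g Generations since induction (>= 0).
#' @param wbar Population mean fitness (default 1).
#' @return Expected log2 fold change.
#' @examples
#' expected_log2fc(1.2, 10)  # 2
#' @export
expected_log2fc <- function(w, g, wbar = 1) {
  stopifnot(all(g >= 0))
  g * (w - wbar)
}

#' Exact renormalized log2 fold change of one guide
#'
#' Exact companion of [expected_log2fc()]: given the full initial fraction
#' vector and fitness vector of the library, the log2 fold change of guide i
#' is `g * w_i - log2(sum_j f0_j * 2^(g * w_j))`.
#'
#' @param i Index of the guide of interest.
#' @param g Generations since induction.
#' @param f0 Initial fractions (sum to 1).
#' @param w Relative fitness of every guide.
#' @return Exact expected log2 fold change of guide i.
#' @export
expected_log2fc_exact <- function(i, g, f0, w) {
  stopifnot(length(f0) == length(w), abs(sum(f0) - 1) < 1e-9)
  g * w[i] - log2(sum(f0 * 2^(g * w)))
}

# Deterministic fraction trajectory: f0 * 2^(g*w), renormalized.
guide_fractions <- function(f0, w, g) {
  x <- f0 * 2^(g * (w - max(w)))   # stabilized
  x / sum(x)
}

#' Simulate a pooled CRISPRi screen under turbidostat selection
#'
#' Draws initial guide abundances from a symmetric Dirichlet, propagates them
#' deterministically under per-generation exponential selection with guide
#' relative fitness `w = 1 + s_gene * efficiency`, and samples sequencing
#' counts per sample from a multinomial at the configured depth, optionally
#' with gamma-multiplicative overdispersion of the expected fractions. All
#' replicates share the inoculum; replicate variation comes from the
#' overdispersion and sampling noise. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param truth Optional truth list as returned by this function (fields
#'   `gene` and `guide`, see below); if NULL, a truth is generated: gene
#'   selection coefficients 70% zero / 15% uniform in \[-0.6, -0.1\] / 15%
#'   uniform in \[0.05, 0.3\] shared across conditions, a 5% labelled subset
#'   shifted by +/- 0.3 in the second (stress) condition, and guide
#'   efficiencies drawn from Beta(5, 1).
#' @return List with `counts` (integer matrix), `samples` (sample sheet),
#'   `library` (annotation with coordinates), and `truth`. The truth holds
#'   `gene` (per-gene selection coefficients per condition and a `shifted`
#'   flag) and `guide` (per-guide efficiency; controls have s = 0, e = 0).
#' @export
simulate_screen <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes; gpg <- config$guides_per_gene; nc <- config$n_controls
  genes <- sprintf("gene%04d", seq_len(ng))
  guide_gene <- rep(genes, each = gpg)
  guide_ids <- c(paste0(guide_gene, "_", rep(seq_len(gpg), ng)),
                 if (nc > 0) sprintf("ctrl_%03d", seq_len(nc)))
  target_ids <- c(guide_gene, rep("ctrl", nc))
  n_guides <- length(guide_ids)
  conds <- names(config$conditions)

  if (is.null(truth)) {
    cls <- sample(c("neutral", "depleted", "enriched"), ng, replace = TRUE,
                  prob = c(0.70, 0.15, 0.15))
    s_a <- numeric(ng)
    s_a[cls == "depleted"] <- stats::runif(sum(cls == "depleted"), -0.6, -0.1)
    s_a[cls == "enriched"] <- stats::runif(sum(cls == "enriched"), 0.05, 0.3)
    shifted <- rep(FALSE, ng)
    s <- matrix(s_a, nrow = ng, ncol = length(conds),
                dimnames = list(genes, conds))
    if (length(conds) >= 2) {
      nshift <- max(1L, round(0.05 * ng))
      idx <- sample.int(ng, nshift)
      shifted[idx] <- TRUE
      sgn <- rep_len(c(1, -1), nshift)  # balanced up/down shifts
      s[idx, 2] <- s[idx, 2] + 0.3 * sgn
    }
    eff <- c(stats::rbeta(ng * gpg, 5, 1), rep(0, nc))
    truth <- list(
      gene = data.frame(target_id = genes, s, shifted = shifted,
                        check.names = FALSE, row.names = NULL),
      guide = data.frame(guide_id = guide_ids, target_id = target_ids,
                         efficiency = eff, row.names = NULL))
  }
  smat <- as.matrix(truth$gene[, conds, drop = FALSE])
  rownames(smat) <- truth$gene$target_id
  eff <- truth$guide$efficiency[match(guide_ids, truth$guide$guide_id)]
  miss <- is.na(eff)
  if (any(miss & target_ids != "ctrl"))
    stop("truth$guide lacks efficiencies for non-control guides")
  eff[miss] <- 0  # controls absent from a custom truth are neutral

  f0 <- stats::rgamma(n_guides, shape = config$dirichlet_conc)
  f0 <- f0 / sum(f0)

  # per-condition guide relative fitness
  wmat <- sapply(conds, function(cn) {
    s_all <- c(smat[guide_gene, cn], rep(0, nc))  # controls are neutral
    1 + s_all * eff
  })

  samples <- do.call(rbind, lapply(seq_along(conds), function(ci) {
    expand.grid(replicate = seq_len(config$replicates[ci]),
                generation = config$generations,
                condition = conds[ci], stringsAsFactors = FALSE)
  }))
  samples$sample <- sprintf("%s_rep%d_gen%g", samples$condition,
                            samples$replicate, samples$generation)
  samples <- samples[, c("sample", "condition", "replicate", "generation")]

  counts <- matrix(0L, nrow = n_guides, ncol = nrow(samples),
                   dimnames = list(guide_ids, samples$sample))
  for (k in seq_len(nrow(samples))) {
    w <- wmat[, samples$condition[k]]
    fr <- guide_fractions(f0, w, samples$generation[k])
    if (config$dispersion > 0) {
      shape <- 1 / config$dispersion
      fr <- fr * stats::rgamma(n_guides, shape = shape, rate = shape)
      fr <- fr / sum(fr)
    }
    counts[, k] <- as.integer(stats::rmultinom(1, config$depth, fr))
  }

  # genomic layout: 1 kb per gene locus, 20 nt guides at distinct offsets
  lib <- data.frame(guide_id = guide_ids, target_id = target_ids,
                    stringsAsFactors = FALSE)
  gene_idx <- match(guide_gene, genes)
  within <- rep(seq_len(gpg), ng)
  lib$chrom <- NA_character_; lib$start <- NA_integer_; lib$end <- NA_integer_
  lib$strand <- NA_character_
  ii <- seq_len(ng * gpg)
  lib$chrom[ii] <- "chr"
  lib$start[ii] <- (gene_idx - 1L) * 1000L + (within - 1L) * 60L
  lib$end[ii] <- lib$start[ii] + 20L
  lib$strand[ii] <- rep_len(c("+", "-"), ng * gpg)

  list(counts = counts, samples = samples,
       library = validate_library_annotation(lib), truth = truth)
}

#' Default parameter-recovery scenario
#'
#' The benchmark configuration used for end-to-end validation: 2,000 genes
#' with five guides each plus 500 controls, the two-condition unbalanced
#' replicate design, depth 2e6, and the default truth generator (see
#' [simulate_screen()]). Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @return List with `config` (a [sim_config()]); pass it to
#'   [simulate_screen()] to generate data and truth.
#' @export
default_recovery_scenario <- function(seed = 1) {
  list(config = sim_config(n_genes = 2000, guides_per_gene = 5,
                           n_controls = 500, seed = seed))
}
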