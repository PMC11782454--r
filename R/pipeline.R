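#' Run the full screen fitness analysis
#'
#' Orchestrates the pipeline: size-factor normalization, per-replicate log2
#' fold changes versus generation 0, per-guide AUC fitness, correlation- and
#' efficiency-weighted gene fitness with bootstrap confidence intervals per
#' condition, control-based per-gene tests, the between-condition test, and
#' the impact / combined scores with hit classes.
#'
#' @param counts Count matrix (guides x samples) or path to a count TSV.
#' @param samples Sample sheet data.frame or CSV path.
#' @param library Library annotation data.frame or TSV path.
#' @param condition_a,condition_b Condition labels for the reference (x0,
#'   e.g. 4% CO2) and stress (y0, e.g. 30% CO2) condition. Defaults to the
#'   first two conditions in the sample sheet.
#' @param control_label `target_id` value marking control guides.
#' @param pseudocount Pseudocount for the log2 fold changes.
#' @param normalize_auc Normalize AUC by the final generation.
#' @param between_scores `"replicate"` (default) pools per-guide
#'   per-replicate fitness scores in the between-condition test;
#'   `"guide"` uses one replicate-averaged score per guide.
#' @param efficiency Optional named vector of guide efficiency priors.
#' @param bootstrap_reps Bootstrap replicates for gene confidence intervals.
#' @param seed Integer seed for the bootstrap.
#' @param min_guides Genes with fewer usable guides get `p_adj = NA` (they
#'   are reported, not dropped).
#' @param out_dir Optional output directory; if given, writes
#'   `fitness_A.tsv`, `fitness_B.tsv`, `compare.tsv` and `manifest.json`.
#' @return List with `guide_fitness` (per guide x condition, plus
#'   per-replicate scores in `guide_fitness_rep`), `gene_fitness` (per gene x
#'   condition with CI), `compare` (per gene: fitness in both conditions,
#'   impact, p_adj, combined score, hit classes) and `size_factors`.
#' @export
run_screen_analysis <- function(counts, samples, library,
                                condition_a = NULL, condition_b = NULL,
                                control_label = "ctrl",
                                pseudocount = 0.5, normalize_auc = TRUE,
                                between_scores = c("replicate", "guide"),
                                efficiency = NULL,
                                bootstrap_reps = 1000, seed = NULL,
                                min_guides = 2, out_dir = NULL) {
  between_scores <- match.arg(between_scores)
  if (is.character(counts)) counts <- read_count_table(counts)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  samples <- validate_sample_sheet(samples)
  if (is.character(library)) library <- read_library_annotation(library)
  library <- validate_library_annotation(library)

  conds <- unique(samples$condition)
  if (is.null(condition_a)) condition_a <- conds[1]
  if (is.null(condition_b)) condition_b <- conds[min(2, length(conds))]
  if (!all(c(condition_a, condition_b) %in% conds))
    stop("condition labels not present in the sample sheet")
  if (!is.null(seed)) set.seed(seed)

  sf <- size_factors(counts)
  profiles <- log2fc_profiles(counts, sf, samples, pseudocount)
  guide_fit <- guide_fitness_scores(profiles, normalize = normalize_auc)
  guide_fit_rep <- guide_fitness_scores(profiles, normalize = normalize_auc,
                                        by_replicate = TRUE)
  tmap <- stats::setNames(library$target_id, library$guide_id)
  guide_fit$target_id <- unname(tmap[guide_fit$guide_id])
  guide_fit_rep$target_id <- unname(tmap[guide_fit_rep$guide_id])

  mean_prof <- replicate_mean_profiles(profiles)
  post <- mean_prof[mean_prof$generation > 0, , drop = FALSE]

  gene_fit <- do.call(rbind, lapply(unique(c(condition_a, condition_b)),
                                    function(cond) {
    pc <- post[post$condition == cond, , drop = FALSE]
    gens <- sort(unique(pc$generation))
    pc <- pc[order(pc$guide_id, pc$generation), , drop = FALSE]
    pmat <- matrix(pc$log2fc, ncol = length(gens), byrow = TRUE,
                   dimnames = list(unique(pc$guide_id), gens))
    gf <- guide_fit[guide_fit$condition == cond, , drop = FALSE]
    gf <- gf[gf$target_id != control_label, , drop = FALSE]
    sp <- split(seq_len(nrow(gf)), gf$target_id)
    rows <- lapply(names(sp), function(tid) {
      idx <- sp[[tid]]
      prof <- pmat[gf$guide_id[idx], , drop = FALSE]
      effp <- if (is.null(efficiency)) 1 else
        ifelse(is.na(efficiency[gf$guide_id[idx]]), 1,
               efficiency[gf$guide_id[idx]])
      w <- guide_weights(prof, effp)
      res <- gene_fitness(gf$fitness[idx], w, bootstrap_reps = bootstrap_reps)
      c(res$fitness, res$ci_lo, res$ci_hi, res$n_guides)
    })
    m <- do.call(rbind, rows)
    data.frame(target_id = names(sp), condition = cond, fitness = m[, 1],
               ci_lo = m[, 2], ci_hi = m[, 3], n_guides = as.integer(m[, 4]),
               row.names = NULL)
  }))

  # control-based per-gene tests, one BH family per condition
  ctrl_tests <- lapply(unique(c(condition_a, condition_b)), function(cond) {
    gf <- guide_fit[guide_fit$condition == cond, , drop = FALSE]
    ct <- condition_gene_test(gf, control_label)
    ct$condition <- cond
    ct
  })
  ctrl_tests <- do.call(rbind, ctrl_tests)

  # between-condition test
  bsrc <- if (between_scores == "replicate") guide_fit_rep else guide_fit
  bsrc <- bsrc[bsrc$target_id != control_label, , drop = FALSE]
  bt <- between_condition_test(
    bsrc[bsrc$condition == condition_a, c("target_id", "fitness")],
    bsrc[bsrc$condition == condition_b, c("target_id", "fitness")])

  ga <- gene_fit[gene_fit$condition == condition_a, , drop = FALSE]
  gb <- gene_fit[gene_fit$condition == condition_b, , drop = FALSE]
  ids <- intersect(ga$target_id, gb$target_id)
  ia <- match(ids, ga$target_id); ib <- match(ids, gb$target_id)
  it <- match(ids, bt$target_id)
  compare <- data.frame(
    target_id = ids,
    fitness_a = ga$fitness[ia], fitness_b = gb$fitness[ib],
    impact = impact_score(ga$fitness[ia], gb$fitness[ib]),
    p = bt$p[it], p_adj = bt$p_adj[it])
  usable <- pmin(ga$n_guides[ia], gb$n_guides[ib]) >= min_guides
  compare$p_adj[!usable] <- NA_real_
  compare$combined <- ifelse(is.na(compare$p_adj), NA_real_,
                             combined_score(compare$impact,
                                            pmax(compare$p_adj,
                                                 .Machine$double.xmin)))
  compare$class_a <- classify_hits(compare$fitness_a)
  compare$class_b <- classify_hits(compare$fitness_b)

  result <- list(guide_fitness = guide_fit, guide_fitness_rep = guide_fit_rep,
                 gene_fitness = gene_fit, control_tests = ctrl_tests,
                 compare = compare, size_factors = sf,
                 conditions = c(a = condition_a, b = condition_b))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(ga, "fitness_A.tsv"); wt(gb, "fitness_B.tsv")
    wt(compare, "compare.tsv")
    manifest <- list(package_version = as.character(
                       utils::packageVersion("co2screen")),
                     r_version = R.version.string,
                     seed = if (is.null(seed)) NA else seed,
                     condition_a = condition_a, condition_b = condition_b,
                     n_guides = nrow(counts), n_samples = ncol(counts),
                     n_genes = length(ids))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
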