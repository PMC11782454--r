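#' Read an sgRNA count table
#'
#' Tab-separated file with a header line; first column `guide_id`, remaining
#' columns one sample each, containing non-negative integer read counts.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, guides in rows (rownames = guide ids), samples in
#'   columns.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a guide_id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated guide id(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop(sprintf("non-integer or negative count in column '%s', line %d",
                   colnames(m)[j], bad[1] + 1L))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write an sgRNA count table
#'
#' @param counts Integer matrix with guide ids as rownames.
#' @param path Output TSV path.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  df <- data.frame(guide_id = rownames(counts), counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample`, `condition`, `replicate`, `generation`
#' (population doublings since induction). Validates that
#' (condition, replicate, generation) combinations are unique and that every
#' condition/replicate pair has a generation-0 reference sample.
#'
#' @param path Path to the CSV file.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet data.frame
#'
#' @param df data.frame with `sample`, `condition`, `replicate`, `generation`.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample", "condition", "replicate", "generation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- interaction(df$condition, df$replicate, df$generation, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (condition, replicate, generation) combination")
  cr <- unique(df[, c("condition", "replicate")])
  for (i in seq_len(nrow(cr))) {
    sel <- df$condition == cr$condition[i] & df$replicate == cr$replicate[i]
    if (!any(df$generation[sel] == 0))
      stop(sprintf("condition '%s' replicate %s has no generation-0 sample",
                   cr$condition[i], cr$replicate[i]))
  }
  df
}

#' Write a sample sheet
#' @param sheet data.frame as in [read_sample_sheet()].
#' @param path Output CSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a guide library annotation
#'
#' TSV with columns `guide_id`, `target_id`, and optionally `sequence`,
#' `chrom`, `start`, `end` (0-based half-open) and `strand`. Control guides
#' carry the control label (conventionally `"ctrl"`) in `target_id`.
#'
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
read_library_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_library_annotation(df)
}

#' Validate a guide library annotation
#' @param df data.frame with at least `guide_id` and `target_id`.
#' @return The validated data.frame.
#' @export
validate_library_annotation <- function(df) {
  if (!all(c("guide_id", "target_id") %in% names(df)))
    stop("library annotation needs guide_id and target_id columns")
  dup <- df$guide_id[duplicated(df$guide_id)]
  if (length(dup))
    stop("duplicated guide id(s): ", paste(unique(dup), collapse = ", "))
  if (all(c("start", "end") %in% names(df))) {
    has <- !is.na(df$start) & !is.na(df$end)
    if (any(df$start[has] >= df$end[has]))
      stop("guide coordinates must satisfy start < end (0-based half-open)")
  }
  df
}

#' Write a guide library annotation
#' @param library data.frame as in [read_library_annotation()].
#' @param path Output TSV path.
#' @export
write_library_annotation <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Count guides in a FASTQ file by exact spacer matching
#'
#' A read contributes one count to a guide if the sequence between the first
#' occurrence of `flank5` and the following occurrence of `flank3` equals the
#' guide's spacer exactly. Reads without both flanks, or whose extracted
#' spacer matches no library guide, are tallied as unmatched. This replaces
#' alignment-based counting with a strict exact-match rule.
#'
#' @param path FASTQ file path (may be uncompressed or gzipped).
#' @param library Library annotation with a `sequence` column of spacers.
#' @param flank5 Constant sequence 5' of the spacer.
#' @param flank3 Constant sequence 3' of the spacer.
#' @return List with `counts` (named integer vector over all library guides)
#'   and `unmatched` (number of reads not assigned).
#' @export
count_guides_from_fastq <- function(path, library, flank5, flank3) {
  library <- validate_library_annotation(library)
  if (is.null(library$sequence) || all(is.na(library$sequence)))
    stop("library annotation has no guide sequences")
  reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  counts <- stats::setNames(integer(nrow(library)), library$guide_id)
  p5 <- regexpr(flank5, reads, fixed = TRUE)
  spacer <- rep(NA_character_, length(reads))
  has5 <- p5 > 0
  if (any(has5)) {
    tail5 <- substr(reads[has5], p5[has5] + nchar(flank5), nchar(reads[has5]))
    p3 <- regexpr(flank3, tail5, fixed = TRUE)
    ok <- p3 > 0
    spacer[has5][ok] <- substr(tail5[ok], 1, p3[ok] - 1)
  }
  hit <- match(spacer, library$sequence)
  tab <- table(factor(library$guide_id[hit[!is.na(hit)]],
                      levels = library$guide_id))
  counts[] <- as.integer(tab)
  list(counts = counts, unmatched = sum(is.na(hit)))
}

#' Maximal-|fitness| coverage intervals for a set of guides
#'
#' For every genomic position covered by at least one guide, the reported
#' value is the fitness of the covering guide with the largest absolute
#' fitness. Ties in |fitness| are resolved toward the positive value, then
#' toward the earlier-starting guide. Adjacent intervals with equal value are
#' merged.
#'
#' @param guides data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and `fitness`.
#' @return data.frame with `chrom`, `start`, `end`, `value`, sorted and
#'   non-overlapping.
#' @export
coverage_intervals <- function(guides) {
  stopifnot(all(c("chrom", "start", "end", "fitness") %in% names(guides)))
  keep <- stats::complete.cases(guides[, c("chrom", "start", "end", "fitness")])
  if (!all(keep)) {
    warning(sum(!keep), " guide(s) without coordinates or fitness skipped")
    guides <- guides[keep, , drop = FALSE]
  }
  if (nrow(guides) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  # IRanges is 1-based closed; shift the 0-based half-open starts by one
  gr <- GenomicRanges::GRanges(guides$chrom,
                               IRanges::IRanges(guides$start + 1L, guides$end))
  dj <- GenomicRanges::disjoin(gr)
  ov <- GenomicRanges::findOverlaps(dj, gr)
  pick <- vapply(split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov)),
                 function(idx) {
                   f <- guides$fitness[idx]
                   best <- idx[order(-abs(f), -sign(f), guides$start[idx])][1]
                   guides$fitness[best]
                 }, numeric(1))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(dj)),
                    start = GenomicRanges::start(dj) - 1L,
                    end = GenomicRanges::end(dj),
                    value = as.numeric(pick))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  # merge adjacent runs with equal value
  if (nrow(out) > 1L) {
    same <- with(out, c(FALSE, chrom[-1] == chrom[-nrow(out)] &
                          start[-1] == end[-nrow(out)] &
                          value[-1] == value[-nrow(out)]))
    grp <- cumsum(!same)
    out <- do.call(rbind, lapply(split(out, grp), function(b)
      data.frame(chrom = b$chrom[1], start = b$start[1],
                 end = b$end[nrow(b)], value = b$value[1])))
  }
  rownames(out) <- NULL
  out
}

#' Export guide fitness as a bedGraph coverage track
#'
#' Writes the [coverage_intervals()] of the supplied guides as a bedGraph
#' file (0-based half-open, sorted, non-overlapping), the format used to
#' display per-position fitness in a genome browser.
#'
#' @inheritParams coverage_intervals
#' @param path Output bedGraph path.
#' @param track_name Track name for the header line (NULL for no header).
#' @return Invisibly, the interval data.frame written.
#' @export
export_coverage_track <- function(guides, path, track_name = "fitness") {
  iv <- coverage_intervals(guides)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  if (nrow(iv))
    writeLines(sprintf("%s\t%d\t%d\t%s", iv$chrom, iv$start, iv$end,
                       format(iv$value, trim = TRUE, scientific = FALSE)), con)
  invisible(iv)
}
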