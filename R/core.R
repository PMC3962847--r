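# Core-microbiome delineation. An OTU belongs to the core when it is present
# in every sample above both abundance filters AND its reads are spread
# evenly across samples, measured by a cross-sample Shannon evenness
# ("samples as taxa, reads as individuals").

#' Core-membership criteria
#'
#' Three simultaneously applied filters define the core:
#' * `min_reads_per_sample`: at least this many reads in every sample
#'   (default 3, i.e. OTUs with two or fewer reads in any sample are
#'   eliminated — guarding against reads placed in a sample by chance, e.g.
#'   through a mis-read multiplex identifier);
#' * `min_freq_per_sample`: relative abundance strictly above this fraction
#'   in every sample (default 0.001, i.e. > 0.1%);
#' * `evenness_min`: cross-sample Shannon evenness strictly above this value
#'   (default 0.9).
#'
#' The read-count and frequency conditions are deliberately kept as separate
#' filters: at a depth of, say, 1,500 reads per sample, 0.1% corresponds to
#' 1.5 reads and the two thresholds differ, so applying both is the stricter
#' (and safer) reading of "present at > 0.1% (> 2 reads)".
#'
#' @param evenness_min evenness threshold in `[0, 1]` (strict inequality).
#' @param min_reads_per_sample minimum reads per sample (`>= 1`).
#' @param min_freq_per_sample frequency threshold in `[0, 1)` (strict
#'   inequality).
#' @return a `core_criteria` list.
#' @export
core_criteria <- function(evenness_min = 0.9, min_reads_per_sample = 3,
                          min_freq_per_sample = 0.001) {
  if (!is.numeric(evenness_min) || evenness_min < 0 || evenness_min > 1)
    stop("evenness_min must lie in [0, 1]")
  if (!is.numeric(min_reads_per_sample) || min_reads_per_sample < 1)
    stop("min_reads_per_sample must be >= 1")
  if (!is.numeric(min_freq_per_sample) ||
      min_freq_per_sample < 0 || min_freq_per_sample >= 1)
    stop("min_freq_per_sample must lie in [0, 1)")
  structure(list(evenness_min = evenness_min,
                 min_reads_per_sample = min_reads_per_sample,
                 min_freq_per_sample = min_freq_per_sample),
            class = "core_criteria")
}

#' Cross-sample evenness of one OTU
#'
#' Shannon evenness of an OTU's read distribution across the samples:
#' `E = (-sum(p_j log p_j)) / log(S)` over the samples `j` with reads, where
#' `S` is the number of samples. `E = 1` when the OTU's reads are spread
#' perfectly evenly; values near 0 indicate concentration in one sample.
#'
#' @param per_sample_counts the OTU's read counts across the `S >= 2`
#'   samples; total must be positive.
#' @return evenness in `[0, 1]`.
#' @examples
#' otu_evenness(c(13, 26, 24, 36, 41))  # 0.960
#' @export
otu_evenness <- function(per_sample_counts) {
  if (length(per_sample_counts) < 2L)
    stop("need counts across at least 2 samples")
  if (sum(per_sample_counts) <= 0)
    stop("OTU has zero total reads: evenness undefined")
  shannon_evenness(per_sample_counts,
                   n_categories = length(per_sample_counts))
}

#' Delineate the core microbiome of an OTU table
#'
#' Applies [core_criteria()] to every OTU: core membership is the conjunction
#' of (a) `count >= min_reads_per_sample` in every sample, (b)
#' `count / sample_total > min_freq_per_sample` in every sample, and (c)
#' cross-sample [otu_evenness()] `> evenness_min`. The full per-OTU report is
#' returned, including near-misses (OTUs failing exactly one criterion) for
#' diagnostics. For real-valued (averaged) tables the count filter compares
#' the means against the same thresholds; the report flags that
#' interpretation.
#'
#' OTUs passing both abundance filters whose evenness falls within 0.005 of
#' the threshold are reported in a warning, since their verdict is sensitive
#' to the threshold choice.
#'
#' @param x an [otu_table()] with positive sample totals.
#' @param criteria a [core_criteria()].
#' @param taxonomy optional `taxonomy_table`; adds a consensus lineage
#'   column.
#' @return a `core_report`: data frame with one row per OTU (per-sample
#'   counts, `total`, `evenness`, `pass_reads`, `pass_freq`, `pass_evenness`,
#'   `core`, `near_miss`, optional `taxonomy`), sorted by total descending;
#'   attributes `criteria`, `label`, `averaged`.
#' @examples
#' m <- rbind(c(4, 2, 100), c(3, 5, 3), c(4, 5, 3), c(6, 5, 3), c(6, 5, 3))
#' tab <- otu_table(m, sample_ids = paste0("S", 1:5),
#'                  otu_ids = c("even", "low1", "skew"), label = "0.03")
#' delineate_core(tab)
#' @export
delineate_core <- function(x, criteria = core_criteria(), taxonomy = NULL) {
  stopifnot(inherits(x, "otu_table"))
  if (!inherits(criteria, "core_criteria"))
    criteria <- do.call(core_criteria, as.list(criteria))
  totals <- rowSums(x)
  if (any(totals <= 0))
    stop("all-zero sample(s): ",
         paste(sample_ids(x)[totals <= 0], collapse = ", "))
  m <- unclass(x)
  freq <- sweep(m, 1L, totals, "/")
  pass_reads <- apply(m >= criteria$min_reads_per_sample, 2L, all)
  pass_freq <- apply(freq > criteria$min_freq_per_sample, 2L, all)
  evenness <- apply(m, 2L, otu_evenness)
  pass_even <- evenness > criteria$evenness_min
  core <- pass_reads & pass_freq & pass_even
  fails <- (!pass_reads) + (!pass_freq) + (!pass_even)
  near <- pass_reads & pass_freq &
    abs(evenness - criteria$evenness_min) < 0.005
  if (any(near))
    warning("evenness within 0.005 of threshold for OTU(s): ",
            paste(otu_ids(x)[near], collapse = ", "),
            "; verdicts there are threshold-sensitive")
  rep_df <- data.frame(otu = otu_ids(x), t(m), check.names = FALSE,
                       row.names = NULL)
  rep_df$total <- colSums(m)
  rep_df$evenness <- evenness
  rep_df$pass_reads <- pass_reads
  rep_df$pass_freq <- pass_freq
  rep_df$pass_evenness <- pass_even
  rep_df$core <- core
  rep_df$near_miss <- !core & fails == 1L
  if (!is.null(taxonomy)) {
    lin <- taxonomy$lineages[rep_df$otu]
    rep_df$taxonomy <- vapply(lin, function(l) {
      if (is.null(l)) NA_character_
      else paste0(paste(l, collapse = ";"), ";")
    }, "")
  }
  rep_df <- rep_df[order(-rep_df$total, rep_df$otu), , drop = FALSE]
  rownames(rep_df) <- NULL
  structure(rep_df, criteria = criteria, label = otu_label(x),
            averaged = !is_integer_table(x),
            class = c("core_report", "data.frame"))
}

#' @export
print.core_report <- function(x, ...) {
  cr <- attr(x, "criteria")
  cat("Core microbiome report (label ", attr(x, "label"), "): ",
      sum(x$core), " core OTU(s) of ", nrow(x), "\n", sep = "")
  cat("criteria: >= ", cr$min_reads_per_sample, " reads and > ",
      100 * cr$min_freq_per_sample, "% in every sample; evenness > ",
      cr$evenness_min, "\n", sep = "")
  if (attr(x, "averaged"))
    cat("note: averaged (real-valued) counts; filters applied to means\n")
  cat("near-misses (failed exactly one criterion): ", sum(x$near_miss),
      "\n", sep = "")
  if (sum(x$core)) {
    df <- as.data.frame(x)[x$core, , drop = FALSE]
    df$evenness <- round(df$evenness, 3)
    drop <- intersect(c("pass_reads", "pass_freq", "pass_evenness",
                        "near_miss", "core"), names(df))
    print(df[setdiff(names(df), drop)], row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.core_report <- function(object, ...) {
  cat("OTUs tested:              ", nrow(object), "\n")
  cat("pass read-count filter:   ", sum(object$pass_reads), "\n")
  cat("pass frequency filter:    ", sum(object$pass_freq), "\n")
  cat("pass evenness filter:     ", sum(object$pass_evenness), "\n")
  cat("core (all three):         ", sum(object$core), "\n")
  cat("near-misses:              ", sum(object$near_miss), "\n")
  invisible(object)
}

#' Extract the core OTU identifiers from a report
#'
#' @param report a `core_report`.
#' @return character vector of core OTU ids (sorted by total, descending).
#' @export
core_otus <- function(report) {
  stopifnot(inherits(report, "core_report"))
  report$otu[report$core]
}

#' Majority-rule consensus lineage
#'
#' Per rank, the deepest taxon supported by more than half of the member
#' lineages; at the first rank where no taxon reaches a majority, the
#' consensus stops and the remaining ranks (to the deepest member lineage)
#' are filled with the `"unclassified"` sentinel. A single lineage is its
#' own consensus.
#'
#' @param lineages a list of character vectors (one lineage per member), or
#'   a single character vector.
#' @return the consensus as a semicolon-terminated string.
#' @examples
#' consensus_taxonomy(list(c("Bacteria", "Proteobacteria"),
#'                         c("Bacteria", "Proteobacteria"),
#'                         c("Bacteria", "Acidobacteria")))
#' @export
consensus_taxonomy <- function(lineages) {
  if (is.character(lineages)) lineages <- list(lineages)
  if (length(lineages) == 0L) stop("no lineages supplied")
  if (any(lengths(lineages) == 0L)) stop("empty lineage in input")
  n <- length(lineages)
  depth <- max(lengths(lineages))
  out <- character(0)
  for (k in seq_len(depth)) {
    taxa <- vapply(lineages, function(l)
      if (length(l) >= k) l[[k]] else "unclassified", "")
    tab <- sort(table(taxa), decreasing = TRUE)
    top <- names(tab)[1L]
    if (tab[1L] > n / 2 && top != "unclassified") {
      out <- c(out, top)
    } else {
      out <- c(out, rep("unclassified", depth - k + 1L))
      break
    }
  }
  paste0(paste(out, collapse = ";"), ";")
}

#' Write a core report as TSV
#'
#' Columns mirror the tabular presentation of a core microbiome: OTU id,
#' per-sample read counts, evenness, total, consensus taxonomy and the
#' per-criterion verdicts.
#'
#' @param report a `core_report`.
#' @param path output path.
#' @param comment optional comment lines (prefixed `# `).
#' @return `path`, invisibly.
#' @export
write_core_report <- function(report, path, comment = character()) {
  stopifnot(inherits(report, "core_report"))
  cr <- attr(report, "criteria")
  hdr <- c(sprintf("# core criteria: min_reads=%s min_freq=%s evenness_min=%s",
                   cr$min_reads_per_sample, cr$min_freq_per_sample,
                   cr$evenness_min),
           if (attr(report, "averaged"))
             "# averaged (real-valued) counts; filters applied to means",
           paste0("# ", comment))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(report)
  df$evenness <- sprintf("%.3f", df$evenness)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
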