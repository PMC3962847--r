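# Pairwise community dissimilarities and shared-OTU (Venn) accounting.
# Scalar metric functions implement the defining formulas; the matrix
# builder delegates to vegan::vegdist, and tests assert the two routes agree.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`: the abundance-based form. For the
#' incidence-based relative, see [sorensen()].
#'
#' @param x,y non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  .check_pair(x, y)
  if (sum(x) + sum(y) <= 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / sum(x + y)
}

#' Morisita-Horn dissimilarity between two abundance vectors
#'
#' `1 - 2 sum(x_i y_i) / ((d_x + d_y) X Y)` with `X = sum(x)`, `Y = sum(y)`,
#' `d_x = sum(x^2) / X^2`, `d_y = sum(y^2) / Y^2`. Invariant to rescaling
#' either sample and dominated by the abundant OTUs.
#'
#' @param x,y non-negative numeric vectors of equal length, each with
#'   positive total.
#' @return dissimilarity in `[0, 1]`.
#' @export
morisita_horn <- function(x, y) {
  .check_pair(x, y)
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stop("zero-total vector: Morisita-Horn undefined")
  dx <- sum(x^2) / X^2
  dy <- sum(y^2) / Y^2
  1 - 2 * sum(x * y) / ((dx + dy) * X * Y)
}

#' Sorensen (incidence-based) dissimilarity
#'
#' `1 - 2|A intersect B| / (|A| + |B|)` on the presence/absence reduction of
#' two abundance vectors. Provided as the incidence-based companion to
#' [bray_curtis()].
#'
#' @param x,y non-negative numeric vectors of equal length, each with at
#'   least one positive entry.
#' @return dissimilarity in `[0, 1]`.
#' @export
sorensen <- function(x, y) {
  .check_pair(x, y)
  a <- x > 0; b <- y > 0
  if (!any(a) || !any(b)) stop("empty sample: Sorensen undefined")
  1 - 2 * sum(a & b) / (sum(a) + sum(b))
}

.check_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors differ in length (", length(x), " vs ", length(y), ")")
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0))
    stop("counts must be non-negative and free of missing values")
}

#' All-pairs dissimilarity matrix
#'
#' Computes the chosen metric for every pair of samples of an OTU table,
#' through `vegan::vegdist` (`bray`, `horn`, or binary `bray` for Sorensen).
#' Samples keep the table's order.
#'
#' @param x an [otu_table()] with at least 2 samples, none all-zero.
#' @param metric `"braycurtis"`, `"morisitahorn"` or `"sorensen"`.
#' @return a `dist_matrix`: dense symmetric matrix with zero diagonal,
#'   entries in `[0, 1]`, and a `metric` attribute recording the name
#'   verbatim.
#' @export
dist_matrix <- function(x, metric = c("braycurtis", "morisitahorn",
                                      "sorensen")) {
  stopifnot(inherits(x, "otu_table"))
  metric <- match.arg(metric)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  zero <- rowSums(x) <= 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(sample_ids(x)[zero], collapse = ", "))
  m <- unclass(x)
  d <- switch(metric,
    braycurtis = vegan::vegdist(m, method = "bray"),
    morisitahorn = vegan::vegdist(m, method = "horn"),
    sorensen = vegan::vegdist(m, method = "bray", binary = TRUE))
  dm <- as.matrix(d)
  dimnames(dm) <- list(sample_ids(x), sample_ids(x))
  diag(dm) <- 0
  structure(dm, metric = metric, label = otu_label(x),
            class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, digits = 4, ...) {
  cat("Pairwise dissimilarity (", attr(x, "metric"), "), ",
      nrow(x), " samples\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Write a dissimilarity matrix as a square TSV
#'
#' The metric name is recorded verbatim in a leading comment line.
#'
#' @param x a `dist_matrix`.
#' @param path output path.
#' @param comment optional extra comment lines (each written with `# `).
#' @return `path`, invisibly.
#' @export
write_dist <- function(x, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# metric: ", attr(x, "metric")),
               paste0("# ", comment)[seq_along(comment)]), con)
  writeLines(paste(c("sample", colnames(x)), collapse = "\t"), con)
  for (i in seq_len(nrow(x)))
    writeLines(paste(c(rownames(x)[i], sprintf("%.6f", unclass(x)[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Shared-OTU (Venn) accounting
#'
#' Partitions the OTUs of a table by their support: the exact subset of
#' samples in which they reach `min_count` reads. Cell counts therefore sum
#' to the table's OTU count; for every cell the fraction of the table's total
#' reads carried by its OTUs is also reported. OTUs below `min_count`
#' everywhere (possible when `min_count > 1`) fall into an explicit
#' `"(none)"` cell so the partition stays exhaustive.
#'
#' @param x an [otu_table()].
#' @param min_count presence threshold in reads (default 1; the core
#'   analysis applies stronger filters of its own).
#' @return an `overlap_report`: list with `cells` (data frame: `subset` key
#'   of `&`-joined sample ids, `n_samples`, `n_otus`, `read_fraction`),
#'   `total_otus`, `shared_all_otus`, `shared_all_read_fraction`.
#' @export
overlap_report <- function(x, min_count = 1) {
  stopifnot(inherits(x, "otu_table"))
  if (min_count < 0) stop("min_count must be >= 0")
  m <- unclass(x)
  pres <- m >= min_count
  total_reads <- sum(m)
  key <- apply(pres, 2L, function(col)
    if (!any(col)) "(none)" else paste(sample_ids(x)[col], collapse = "&"))
  cells <- split(seq_len(ncol(m)), key)
  df <- data.frame(
    subset = names(cells),
    n_samples = vapply(names(cells), function(k)
      if (k == "(none)") 0L
      else length(strsplit(k, "&", fixed = TRUE)[[1L]]), 0L),
    n_otus = lengths(cells),
    read_fraction = vapply(cells, function(j) sum(m[, j]) / total_reads, 0),
    row.names = NULL
  )
  df <- df[order(-df$n_samples, df$subset), , drop = FALSE]
  rownames(df) <- NULL
  all_key <- paste(sample_ids(x), collapse = "&")
  i <- match(all_key, df$subset)
  structure(list(
    cells = df,
    total_otus = ncol(m),
    shared_all_otus = if (is.na(i)) 0L else df$n_otus[i],
    shared_all_read_fraction = if (is.na(i)) 0 else df$read_fraction[i],
    min_count = min_count,
    label = otu_label(x)
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Shared-OTU accounting (label ", x$label, ", presence >= ",
      x$min_count, " reads)\n", sep = "")
  cat("OTUs shared by all samples: ", x$shared_all_otus, " (",
      sprintf("%.1f", 100 * x$shared_all_read_fraction),
      "% of reads)\n", sep = "")
  print(x$cells, row.names = FALSE)
  invisible(x)
}
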