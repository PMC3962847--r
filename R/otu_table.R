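#' Construct an OTU count table
#'
#' The central data structure of the package: a samples x OTUs matrix of
#' non-negative read counts (integers for raw tables; reals are permitted so
#' that subsample-averaged tables can be represented) together with a label
#' naming the OTU dissimilarity level at which the table was built (e.g.
#' `"0.03"` for roughly species-level clusters, `"0.10"` for family level).
#'
#' All-zero OTU columns carry no information and are dropped at construction;
#' the drop is reported via [message()].
#'
#' @param counts numeric matrix, rows = samples, columns = OTUs, all entries
#'   `>= 0`. Dimnames are used as identifiers when `sample_ids`/`otu_ids` are
#'   not given.
#' @param sample_ids character vector of unique sample identifiers.
#' @param otu_ids character vector of unique OTU identifiers.
#' @param label clustering-level label stored with the table.
#' @return an object of class `otu_table`: the count matrix with `label`
#'   attribute and identifier dimnames.
#' @examples
#' m <- matrix(c(1, 2, 0, 0, 1, 1), nrow = 2, byrow = TRUE)
#' otu_table(m, sample_ids = c("A", "B"), otu_ids = paste0("Otu", 1:3))
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts), label = "user") {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("Otu", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts))
    stop("sample_ids length does not match number of rows")
  if (length(otu_ids) != ncol(counts))
    stop("otu_ids length does not match number of columns")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stop("duplicate otu_ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of missing values")
  dimnames(counts) <- list(sample_ids, otu_ids)
  zero <- colSums(counts) == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " all-zero OTU column(s): ",
            paste(utils::head(otu_ids[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
    counts <- counts[, !zero, drop = FALSE]
  }
  structure(counts, label = as.character(label),
            class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table (label ", otu_label(x), "): ",
      nrow(x), " samples x ", ncol(x), " OTUs, ",
      if (is_integer_table(x)) "integer" else "real-valued (averaged)",
      " counts\n", sep = "")
  cat("sample totals:\n")
  print(rowSums(unclass(x)))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
otu_label <- function(x) attr(x, "label")

#' @rdname otu_table
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname otu_table
#' @export
otu_ids <- function(x) colnames(x)

#' Does the table hold integer counts?
#'
#' Raw shared tables are integer; replicate-averaged tables are not.
#' Operations that require whole reads (down-sampling) assert this.
#'
#' @param x an `otu_table`.
#' @param tol absolute tolerance for integer-ness.
#' @export
is_integer_table <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) <= tol)
}

.assert_integer_table <- function(x, what) {
  if (!is_integer_table(x))
    stop(what, " requires an integer count table; this table holds ",
         "real-valued (averaged) counts")
}

#' Read a mothur-style shared OTU table
#'
#' Parses the tab-separated `.shared` dialect: a header line
#' `label Group numOtus Otu...` followed by one row per sample per clustering
#' label. Lines starting with `#` are treated as comments (used by
#' [write_shared()] to flag real-valued tables).
#'
#' @param path path to the file.
#' @param label which clustering label to extract. May be omitted when the
#'   file holds a single label; otherwise an error lists the labels present.
#' @return an [otu_table()].
#' @export
read_shared <- function(path, label = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty shared file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 3L ||
      tolower(header[1L]) != "label" ||
      tolower(header[2L]) != "group" ||
      tolower(header[3L]) != "numotus")
    stop("not a shared file (expected header 'label<TAB>Group<TAB>numOtus<TAB>...'): ",
         path)
  otus <- header[-(1:3)]
  width <- length(header)
  body <- fields[-1L]
  ragged <- which(lengths(body) != width)
  if (length(ragged))
    stop("ragged row(s) in ", path, " at line(s) ",
         paste(ragged + 1L, collapse = ", "),
         " (expected ", width, " fields)")
  labels <- vapply(body, `[[`, "", 1L)
  if (is.null(label)) {
    if (length(unique(labels)) > 1L)
      stop("file holds multiple labels {",
           paste(unique(labels), collapse = ", "),
           "}; pass `label` to select one")
    label <- labels[1L]
  }
  label <- as.character(label)
  keep <- labels == label
  if (!any(keep))
    stop("label '", label, "' not present; available: ",
         paste(unique(labels), collapse = ", "))
  body <- body[keep]
  groups <- vapply(body, `[[`, "", 2L)
  numotus <- as.integer(vapply(body, `[[`, "", 3L))
  counts <- t(vapply(body, function(f) as.numeric(f[-(1:3)]),
                     numeric(length(otus))))
  if (anyNA(counts)) stop("non-numeric count field in ", path)
  if (any(numotus != length(otus)))
    stop("numOtus column (", paste(unique(numotus), collapse = ","),
         ") inconsistent with parsed width ", length(otus))
  otu_table(counts, sample_ids = groups, otu_ids = otus, label = label)
}

#' Write an OTU table in the shared dialect
#'
#' Integer tables are written without decimal points. Real-valued (averaged)
#' tables are written at fixed 6-decimal precision, and the fact is flagged in
#' a leading `#` comment line so readers know the counts are means.
#'
#' @param x an [otu_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shared <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  fmt_row <- if (is_integer_table(x)) {
    function(v) format(round(v), scientific = FALSE, trim = TRUE)
  } else {
    function(v) sprintf("%.6f", v)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is_integer_table(x))
    writeLines("# real-valued counts (subsample-averaged table), 6 decimal places",
               con)
  writeLines(paste(c("label", "Group", "numOtus", otu_ids(x)), collapse = "\t"),
             con)
  for (i in seq_len(nrow(x))) {
    writeLines(paste(c(otu_label(x), sample_ids(x)[i], ncol(x),
                       fmt_row(unclass(x)[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read mothur-style consensus taxonomy assignments
#'
#' Expects the constaxonomy layout `OTU<TAB>Size<TAB>Taxonomy` (header
#' optional). Lineages are semicolon-separated, optionally with per-level
#' bootstrap confidence in parentheses, e.g.
#' `Bacteria(100);Proteobacteria(98);`. A trailing semicolon is accepted;
#' an empty lineage is rejected.
#'
#' @param path path to the file.
#' @return a `taxonomy_table`: list with `otu_ids`, `lineages` (named list of
#'   character vectors) and `confidences` (named list of numeric vectors, `NA`
#'   where no bootstrap value was given).
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty taxonomy file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(fields[[1L]][1L]) == "otu") fields <- fields[-1L]
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("malformed taxonomy line(s): ", paste(bad, collapse = ", "))
  otus <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(otus))
    stop("duplicate OTU ids in taxonomy: ",
         paste(unique(otus[duplicated(otus)]), collapse = ", "))
  # taxonomy string is the last field (Size column may be absent)
  tax <- vapply(fields, function(f) f[[length(f)]], "")
  parsed <- lapply(tax, parse_lineage)
  structure(list(
    otu_ids = otus,
    lineages = stats::setNames(lapply(parsed, `[[`, "taxa"), otus),
    confidences = stats::setNames(lapply(parsed, `[[`, "conf"), otus)
  ), class = "taxonomy_table")
}

#' Parse one semicolon-separated lineage string
#'
#' @param s lineage such as `"Bacteria(100);Proteobacteria(98);"`.
#' @return list with `taxa` (character) and `conf` (numeric, `NA` if absent).
#' @export
parse_lineage <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("empty lineage: '", s, "'")
  m <- regmatches(parts, regexec("^(.*?)\\(([0-9.]+)\\)$", parts))
  taxa <- vapply(seq_along(parts), function(i) {
    if (length(m[[i]])) m[[i]][2L] else parts[i]
  }, "")
  conf <- vapply(seq_along(parts), function(i) {
    if (length(m[[i]])) as.numeric(m[[i]][3L]) else NA_real_
  }, 0)
  list(taxa = taxa, conf = conf)
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat("Taxonomy assignments for", length(x$otu_ids), "OTUs\n")
  n <- min(3L, length(x$otu_ids))
  for (i in seq_len(n))
    cat("  ", x$otu_ids[i], ": ",
        paste(x$lineages[[i]], collapse = ";"), ";\n", sep = "")
  if (length(x$otu_ids) > n) cat("  ...\n")
  invisible(x)
}

#' Read a per-sample environment table
#'
#' Tab-separated, one header row; the first column holds sample identifiers,
#' the remaining columns numeric variables (metal concentrations in mg/kg,
#' pH, organic matter in percent, ...).
#'
#' @param path path to the TSV file.
#' @param check_nonnegative require all variables `>= 0` (concentrations,
#'   pH and percentages all are). Default `TRUE`.
#' @return data frame with sample ids as row names, numeric columns.
#' @export
read_env <- function(path, check_nonnegative = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("environment table needs a sample column plus ",
                          "at least one variable: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in environment table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[-1L]
  if (!all(vapply(vals, is.numeric, TRUE)))
    stop("non-numeric environment variable column(s): ",
         paste(names(vals)[!vapply(vals, is.numeric, TRUE)], collapse = ", "))
  if (check_nonnegative && any(unlist(vals) < 0, na.rm = TRUE))
    stop("negative values in environment table")
  rownames(vals) <- ids
  vals
}

#' Read a rooted phylogenetic tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contracts the
#' diversity code relies on: a single rooted tree, unique leaf names and
#' non-negative branch lengths.
#'
#' @param path newick file path.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick tree: ", path)
  if (inherits(tr, "multiPhylo"))
    stop("file contains ", length(tr), " trees; exactly one expected")
  if (!ape::is.rooted(tr)) stop("tree is not rooted: ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("tree has missing or no branch lengths: ", path)
  if (any(tr$edge.length < 0))
    stop("negative branch length(s) in tree: ", path)
  tr
}

#' Check that a table and companion objects cross-reference cleanly
#'
#' Reports (as an error) sample ids or OTU ids that cannot be resolved
#' between an OTU table and an environment table, taxonomy or tree, rather
#' than letting joins silently drop them.
#'
#' @param table an [otu_table()].
#' @param env optional environment data frame (row names = sample ids).
#' @param taxonomy optional `taxonomy_table`.
#' @param tree optional `phylo`; its leaves must cover the table's OTUs.
#' @return `TRUE` invisibly if everything resolves.
#' @export
check_links <- function(table, env = NULL, taxonomy = NULL, tree = NULL) {
  if (!is.null(env)) {
    miss <- setdiff(sample_ids(table), rownames(env))
    extra <- setdiff(rownames(env), sample_ids(table))
    if (length(miss) || length(extra))
      stop("sample-id mismatch with environment table; missing: {",
           paste(miss, collapse = ", "), "}; unmatched: {",
           paste(extra, collapse = ", "), "}")
  }
  if (!is.null(taxonomy)) {
    miss <- setdiff(otu_ids(table), taxonomy$otu_ids)
    if (length(miss))
      stop(length(miss), " OTU(s) lack taxonomy assignments: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) ", ..." else "")
  }
  if (!is.null(tree)) {
    miss <- setdiff(otu_ids(table), tree$tip.label)
    if (length(miss))
      stop(length(miss), " OTU(s) absent from tree leaves: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) ", ..." else "")
  }
  invisible(TRUE)
}
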