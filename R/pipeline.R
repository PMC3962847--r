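# Orchestration: read-accounting arithmetic and the end-to-end driver that
# glues subsampling, alpha and beta diversity, shared-OTU accounting, core
# delineation and environmental correlation into one reproducible run.

#' Sequencing read accounting
#'
#' From per-sample raw, high-quality and chimera read counts, derives the
#' high-quality non-chimeric count (`hqnc = high_quality - chimeras`) and
#' the conventional percentages: high-quality of raw, chimeras of
#' high-quality, and high-quality non-chimeric of raw. A totals row is
#' appended (column sums, with percentages recomputed from the totals).
#' Full precision is retained; the print method displays one decimal.
#'
#' @param samples character vector of sample names.
#' @param raw,high_quality,chimeras integer vectors,
#'   `0 <= chimeras <= high_quality <= raw` per sample.
#' @return a `read_accounting` data frame (samples plus a `Total` row) with
#'   columns `raw`, `high_quality`, `hq_pct`, `chimeras`, `chimera_pct`,
#'   `hqnc`, `hqnc_pct`.
#' @examples
#' read_accounting("A1", raw = 4235, high_quality = 3054, chimeras = 422)
#' @export
read_accounting <- function(samples, raw, high_quality, chimeras) {
  n <- length(samples)
  if (length(raw) != n || length(high_quality) != n || length(chimeras) != n)
    stop("samples, raw, high_quality, chimeras must have equal length")
  bad <- chimeras < 0 | high_quality < chimeras | raw < high_quality
  if (any(bad))
    stop("count ordering violated (need 0 <= chimeras <= high_quality ",
         "<= raw) for sample(s): ", paste(samples[bad], collapse = ", "))
  df <- data.frame(sample = c(samples, "Total"),
                   raw = c(raw, sum(raw)),
                   high_quality = c(high_quality, sum(high_quality)),
                   chimeras = c(chimeras, sum(chimeras)))
  df$hqnc <- df$high_quality - df$chimeras
  df$hq_pct <- 100 * df$high_quality / df$raw
  df$chimera_pct <- 100 * df$chimeras / df$high_quality
  df$hqnc_pct <- 100 * df$hqnc / df$raw
  df <- df[c("sample", "raw", "high_quality", "hq_pct", "chimeras",
             "chimera_pct", "hqnc", "hqnc_pct")]
  structure(df, class = c("read_accounting", "data.frame"))
}

#' @export
print.read_accounting <- function(x, ...) {
  df <- as.data.frame(x)
  for (p in c("hq_pct", "chimera_pct", "hqnc_pct"))
    df[[p]] <- sprintf("%.1f", df[[p]])
  print(df, row.names = FALSE)
  invisible(x)
}

# Stable hash of the effective configuration, stamped into every output so
# artifacts can be traced to the run that produced them.
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

.default_pipeline_config <- function() {
  list(shared = NULL, label = NULL, taxonomy = NULL, tree = NULL,
       env = NULL, accounting = NULL,
       depth = NULL, replicates = 5L, seed = 1L,
       use_averaged = FALSE,
       metrics = c("braycurtis", "morisitahorn"),
       min_count = 1,
       evenness_min = 0.9, min_reads_per_sample = 3,
       min_freq_per_sample = 0.001,
       out_dir = "microcore_out")
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end analysis from a single configuration:
#' read inputs, down-sample every sample to a common depth (the minimum
#' sample total unless `depth` is given), compute the alpha-diversity
#' summary over `replicates` down-samplings, pairwise dissimilarity matrices
#' for the requested metrics, the shared-OTU (Venn) accounting, the core
#' microbiome report, and — when an environment table is supplied — the
#' rank correlations of every diversity measure against every variable.
#' All outputs are written to `out_dir` as plain text, each stamped with the
#' MD5 hash of the effective configuration; re-running with an identical
#' configuration reproduces them bit for bit.
#'
#' Core delineation runs on the single down-sampled table by default; set
#' `use_averaged = TRUE` to run it (and the dissimilarities and Venn
#' accounting) on the replicate-averaged table instead.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognized fields: `shared` (path, required), `label`, `taxonomy`,
#'   `tree`, `env`, `accounting` (paths or `NULL`), `depth`, `replicates`,
#'   `seed`, `use_averaged`, `metrics`, `min_count`, `evenness_min`,
#'   `min_reads_per_sample`, `min_freq_per_sample`, `out_dir`. The
#'   `accounting` TSV needs columns `sample`, `raw`, `high_quality`,
#'   `chimeras`.
#' @return invisibly, a list with the in-memory results (`alpha`, `dists`,
#'   `venn`, `core`, `correlations`, `accounting`, `config_hash`,
#'   `out_dir`, `files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- utils::modifyList(.default_pipeline_config(), config)
  unknown <- setdiff(names(config), names(.default_pipeline_config()))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$shared)) stop("config must name a 'shared' input file")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  log_lines <- character()
  log_add <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  tab <- stage("read_shared", read_shared(cfg$shared, label = cfg$label))
  cfg$label <- otu_label(tab)
  taxonomy <- if (!is.null(cfg$taxonomy))
    stage("read_taxonomy", read_taxonomy(cfg$taxonomy)) else NULL
  tree <- if (!is.null(cfg$tree)) stage("read_tree", read_tree(cfg$tree))
          else NULL
  env <- if (!is.null(cfg$env)) stage("read_env", read_env(cfg$env))
         else NULL
  stage("check_links",
        check_links(tab, env = env, taxonomy = taxonomy, tree = tree))
  if (is.null(cfg$depth)) cfg$depth <- min(rowSums(tab))
  # the hash identifies the analysis, not where its outputs land
  hash <- .config_hash(cfg[setdiff(names(cfg), "out_dir")])

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_add("run config hash: ", hash)
  log_add("package version: ",
          as.character(utils::packageVersion("microcore")))
  log_add("seed: ", cfg$seed, "; depth: ", cfg$depth,
          "; replicates: ", cfg$replicates, "; label: ", cfg$label)
  if (is.null(tree))
    log_add("no tree supplied: phylogenetic diversity column omitted")

  alpha <- stage("alpha_summary",
                 alpha_summary(tab, depth = cfg$depth,
                               replicates = cfg$replicates,
                               seed = cfg$seed, tree = tree))
  seeds <- derive_seeds(cfg$seed + 1L, 1L)
  work <- if (isTRUE(cfg$use_averaged)) {
    log_add("community comparisons on the replicate-averaged table")
    stage("averaged_shared",
          averaged_shared(tab, depth = cfg$depth,
                          replicates = cfg$replicates, seed = cfg$seed))
  } else {
    log_add("community comparisons on a single down-sampled table")
    stage("downsample", downsample(tab, depth = cfg$depth, seed = seeds[1L]))
  }

  dists <- lapply(cfg$metrics, function(mt)
    stage(paste0("dist_", mt), dist_matrix(work, metric = mt)))
  names(dists) <- cfg$metrics
  venn <- stage("overlap_report",
                overlap_report(work, min_count = cfg$min_count))
  core <- stage("delineate_core",
                delineate_core(work,
                               core_criteria(cfg$evenness_min,
                                             cfg$min_reads_per_sample,
                                             cfg$min_freq_per_sample),
                               taxonomy = taxonomy))
  log_add("core OTUs: ", sum(core$core), " of ", nrow(core))

  correlations <- NULL
  if (!is.null(env)) {
    correlations <- stage("correlate_all", correlate_all(alpha, env))
    log_add("correlations: ", attr(correlations, "n_tests"),
            " tests, no multiplicity correction")
  }
  accounting <- NULL
  if (!is.null(cfg$accounting)) {
    acc_in <- stage("read_accounting_input",
                    utils::read.delim(cfg$accounting, sep = "\t"))
    accounting <- stage("read_accounting",
                        read_accounting(acc_in$sample, acc_in$raw,
                                        acc_in$high_quality,
                                        acc_in$chimeras))
  }

  files <- c(alpha = file.path(cfg$out_dir, "alpha.tsv"),
             venn = file.path(cfg$out_dir, "venn.json"),
             core = file.path(cfg$out_dir, "core_report.tsv"),
             log = file.path(cfg$out_dir, "run_log.txt"))
  hdr <- paste0("# config_hash: ", hash)
  .write_tsv_commented(as.data.frame(alpha), files["alpha"], hdr)
  for (mt in cfg$metrics) {
    f <- file.path(cfg$out_dir, paste0("dist_", mt, ".tsv"))
    write_dist(dists[[mt]], f, comment = sub("^# ", "", hdr))
    files[paste0("dist_", mt)] <- f
  }
  jsonlite::write_json(
    list(config_hash = hash, min_count = cfg$min_count,
         total_otus = venn$total_otus,
         shared_all_otus = venn$shared_all_otus,
         shared_all_read_fraction = venn$shared_all_read_fraction,
         cells = venn$cells),
    files["venn"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_core_report(core, files["core"],
                    comment = sub("^# ", "", hdr))
  if (!is.null(correlations)) {
    files["correlations"] <- file.path(cfg$out_dir, "correlations.tsv")
    .write_tsv_commented(correlations, files["correlations"], hdr)
  }
  if (!is.null(accounting)) {
    files["accounting"] <- file.path(cfg$out_dir, "accounting.tsv")
    .write_tsv_commented(as.data.frame(accounting), files["accounting"], hdr)
  }
  writeLines(c(hdr, log_lines), files["log"])

  invisible(list(alpha = alpha, dists = dists, venn = venn, core = core,
                 correlations = correlations, accounting = accounting,
                 config_hash = hash, out_dir = cfg$out_dir, files = files))
}

.write_tsv_commented <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
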