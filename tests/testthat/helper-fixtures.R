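# Shared test fixtures, all generated in code.

# Random integer OTU table with no all-zero columns.
rand_table <- function(n_samples = 4, n_otus = 12, max_count = 20,
                       label = "0.03") {
  m <- matrix(rpois(n_samples * n_otus, max_count / 3), n_samples, n_otus)
  empty <- colSums(m) == 0
  m[1, empty] <- 1L
  suppressMessages(otu_table(
    m, sample_ids = paste0("S", seq_len(n_samples)),
    otu_ids = sprintf("Otu%03d", seq_len(n_otus)), label = label))
}

# Write a two-label shared file and return its path.
write_two_label_shared <- function(path = tempfile(fileext = ".shared")) {
  lines <- c(
    "label\tGroup\tnumOtus\tOtu1\tOtu2\tOtu3",
    "0.03\tS1\t3\t1\t2\t0",
    "0.03\tS2\t3\t0\t1\t1",
    "0.10\tS1\t3\t3\t0\t0",
    "0.10\tS2\t3\t0\t1\t1")
  writeLines(lines, path)
  path
}

# The five-sample bioavailable-zinc gradient and tabulated diversity values
# used by the correlation tests (transcribed reference inputs shipped with
# the package).
extdata <- function(name) {
  system.file("extdata", name, package = "microcore", mustWork = TRUE)
}
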