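test_that("cross-sample evenness reproduces the tabulated core statistics", {
  core03 <- read.delim(extdata("core_counts_0.03.tsv"))
  core10 <- read.delim(extdata("core_counts_0.10.tsv"))
  for (tbl in list(core03, core10)) {
    counts <- as.matrix(tbl[, c("A1", "A2", "O1", "O2", "O3")])
    for (i in seq_len(nrow(tbl))) {
      expect_equal(round(otu_evenness(counts[i, ]), 3), tbl$evenness[i],
                   info = tbl$otu[i])
      expect_equal(sum(counts[i, ]), tbl$total[i], info = tbl$otu[i])
    }
  }
  expect_error(otu_evenness(c(0, 0, 0)), "zero total")
  expect_error(otu_evenness(5), "at least 2")
})

test_that("criteria constructor validates its ranges", {
  cr <- core_criteria()
  expect_equal(cr$evenness_min, 0.9)
  expect_equal(cr$min_reads_per_sample, 3)
  expect_equal(cr$min_freq_per_sample, 0.001)
  expect_error(core_criteria(evenness_min = 1.2), "evenness_min")
  expect_error(core_criteria(min_reads_per_sample = 0), "min_reads")
  expect_error(core_criteria(min_freq_per_sample = 1), "min_freq")
})

test_that("core verdicts apply all three filters conjunctively", {
  m <- cbind(even = c(4, 3, 4, 6, 6),        # passes everything
             low1 = c(2, 5, 5, 5, 5),        # fails min-reads in sample 1
             skew = c(100, 3, 3, 3, 3))      # fails evenness (~0.304)
  # sample totals well below 2632 so 3 reads always clears 0.1%
  tab <- otu_table(m, sample_ids = paste0("S", 1:5),
                   otu_ids = colnames(m), label = "0.03")
  rep <- delineate_core(tab)
  expect_equal(core_otus(rep), "even")
  row <- function(o) rep[rep$otu == o, ]
  expect_false(row("low1")$pass_reads)
  expect_true(row("low1")$pass_evenness)
  expect_true(row("low1")$near_miss)
  expect_false(row("skew")$pass_evenness)
  expect_equal(round(row("skew")$evenness, 3),
               round(-sum((m[, 3] / 112) * log(m[, 3] / 112)) / log(5), 3))
  expect_true(all(rep$core == (rep$pass_reads & rep$pass_freq &
                               rep$pass_evenness)))
  # sorted by total descending
  expect_equal(rep$otu[1], "skew")
})

test_that("frequency filter bites independently of the read-count filter", {
  # 3 reads in a deep sample is > 2 reads but below 0.1%
  m <- cbind(target = c(3, 40, 40, 40, 40),
             filler = c(3997, 60, 60, 60, 60))
  tab <- otu_table(m, sample_ids = paste0("S", 1:5),
                   otu_ids = colnames(m), label = "l")
  rep <- delineate_core(tab)
  r <- rep[rep$otu == "target", ]
  expect_true(r$pass_reads)          # 3 >= 3 everywhere
  expect_false(r$pass_freq)          # 3/4000 = 0.075% <= 0.1%
  expect_false(r$core)
})

test_that("core set is invariant to row and column order", {
  set.seed(41)
  tab <- rand_table(5, 40, max_count = 12)
  rep1 <- suppressWarnings(delineate_core(tab))
  ps <- sample(nrow(tab)); po <- sample(ncol(tab))
  tab2 <- otu_table(unclass(tab)[ps, po], sample_ids = sample_ids(tab)[ps],
                    otu_ids = otu_ids(tab)[po], label = otu_label(tab))
  rep2 <- suppressWarnings(delineate_core(tab2))
  expect_setequal(core_otus(rep1), core_otus(rep2))
})

test_that("raising thresholds never adds a core OTU (monotonicity)", {
  set.seed(43)
  for (i in 1:5) {
    tab <- rand_table(5, 30, max_count = 10)
    prev <- NULL
    for (emin in c(0.5, 0.7, 0.9, 0.95)) {
      cur <- core_otus(suppressWarnings(
        delineate_core(tab, core_criteria(evenness_min = emin))))
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
    prev <- NULL
    for (mr in c(1, 2, 4, 8)) {
      cur <- core_otus(suppressWarnings(
        delineate_core(tab, core_criteria(min_reads_per_sample = mr))))
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("identical samples make every abundant OTU core with E = 1", {
  row <- c(10, 4, 3, 9, 1)
  tab <- otu_table(rbind(row, row, row),
                   sample_ids = c("a", "b", "c"),
                   otu_ids = paste0("o", 1:5), label = "l")
  rep <- delineate_core(tab)
  abundant <- paste0("o", which(row >= 3))
  expect_setequal(core_otus(rep), abundant)
  expect_true(all(abs(rep$evenness - 1) < 1e-12))
})

test_that("averaged tables are accepted and flagged", {
  set.seed(47)
  tab <- rand_table(4, 15, max_count = 25)
  avg <- suppressMessages(averaged_shared(tab, min(rowSums(tab)), 3,
                                          seed = 2))
  rep <- suppressWarnings(delineate_core(avg))
  expect_true(attr(rep, "averaged"))
})

test_that("consensus taxonomy follows majority rule with sentinels", {
  lin <- c("Bacteria", "Proteobacteria", "Rhodospirillales")
  expect_equal(consensus_taxonomy(lin),
               "Bacteria;Proteobacteria;Rhodospirillales;")
  expect_equal(consensus_taxonomy(list(lin)), paste0(paste(lin, collapse = ";"), ";"))

  # 2 vs 1 split at genus, same family: family consensus + unclassified genus
  members <- list(c("Bacteria", "Proteobacteria", "Sphingomonadaceae", "Sphingomonas"),
                  c("Bacteria", "Proteobacteria", "Sphingomonadaceae", "Sphingomonas"),
                  c("Bacteria", "Proteobacteria", "Sphingomonadaceae", "Novosphingobium"))
  expect_equal(consensus_taxonomy(members),
               "Bacteria;Proteobacteria;Sphingomonadaceae;Sphingomonas;")
  members3 <- list(c("Bacteria", "Proteobacteria", "Sphingomonadaceae", "Sphingomonas"),
                   c("Bacteria", "Proteobacteria", "Sphingomonadaceae", "Novosphingobium"))
  expect_equal(consensus_taxonomy(members3),
               "Bacteria;Proteobacteria;Sphingomonadaceae;unclassified;")
  # no majority at the first divergent rank stops the consensus there
  split <- list(c("Bacteria", "Proteobacteria"),
                c("Bacteria", "Acidobacteria"),
                c("Bacteria", "Chloroflexi"))
  expect_equal(consensus_taxonomy(split), "Bacteria;unclassified;")
  expect_error(consensus_taxonomy(list()), "no lineages")
})

test_that("taxonomy strings are joined into the report", {
  m <- cbind(a = c(5, 5, 5), b = c(9, 1, 40))
  tab <- otu_table(m, sample_ids = c("x", "y", "z"), otu_ids = c("a", "b"),
                   label = "l")
  tax <- structure(list(
    otu_ids = c("a", "b"),
    lineages = list(a = c("Bacteria", "Chloroflexi", "KD4-96"),
                    b = c("Bacteria", "Acidobacteria")),
    confidences = list(a = rep(100, 3), b = rep(100, 2))),
    class = "taxonomy_table")
  rep <- delineate_core(tab, taxonomy = tax)
  expect_equal(rep$taxonomy[rep$otu == "a"], "Bacteria;Chloroflexi;KD4-96;")
})

test_that("a planted core is recovered from synthetic data", {
  ds <- simulate_communities(sim_config(seed = 101))
  work <- suppressMessages(
    downsample(ds$table, min(rowSums(ds$table)), seed = 102))
  rep <- suppressWarnings(delineate_core(work))
  found <- core_otus(rep)
  truth <- ds$truth$core_otus
  tp <- length(intersect(found, truth))
  expect_gte(tp / length(found), 0.9)
  expect_gte(tp / length(truth), 0.9)
})
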