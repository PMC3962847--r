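test_that("Shannon index and evenness reproduce hand-computed values", {
  expect_equal(shannon(c(10, 10, 10, 10, 10)), log(5))
  expect_equal(shannon(c(23, 0, 0, 0, 0)), 0)
  # hand evaluation of -sum(p log p) for (13,26,24,36,41)
  p <- c(13, 26, 24, 36, 41) / 140
  expect_equal(shannon(c(13, 26, 24, 36, 41)), -sum(p * log(p)))
  expect_equal(shannon(c(13, 26, 24, 36, 41)), 1.5447, tolerance = 1e-3)
  expect_error(shannon(c(0, 0)), "all-zero")

  expect_equal(shannon_evenness(c(7, 7, 7), 3), 1)
  expect_equal(round(shannon_evenness(c(4, 3, 4, 6, 6), 5), 3), 0.979)
  expect_equal(round(shannon_evenness(c(11, 3, 12, 4, 9), 5), 3), 0.925)
  expect_error(shannon_evenness(c(1, 2), 1), "n_categories")
  expect_error(shannon_evenness(c(1, 2, 3), 2), "occupied")
})

test_that("evenness is permutation- and scale-invariant (property)", {
  set.seed(21)
  for (i in 1:20) {
    x <- rpois(5, 20) + 1
    expect_equal(shannon_evenness(sample(x), 5), shannon_evenness(x, 5))
    expect_equal(shannon_evenness(10 * x, 5), shannon_evenness(x, 5))
    e <- shannon_evenness(x, 5)
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("Chao1 closed forms and interval behaviour", {
  # five singletons, no doubletons: 5 + 5*4/2 = 15
  expect_equal(chao1(rep(1, 5))$estimate, 15)
  # no singletons: estimate collapses to S_obs
  expect_equal(chao1(c(3, 4, 5))$estimate, 3)
  expect_equal(chao1(c(3, 4, 5))$ci, c(3, 3))
  # direct formula: S=5, F1=2, F2=2 -> 5 + 2*1/6
  ch <- chao1(c(1, 1, 2, 2, 3))
  expect_equal(ch$estimate, 5 + 2 * 1 / 6)
  expect_gte(ch$estimate, ch$S_obs)
  expect_lte(ch$ci[1], ch$estimate)
  expect_gte(ch$ci[2], ch$estimate)
})

test_that("Chao1 point estimate and se agree with vegan's (cross-check)", {
  set.seed(31)
  for (i in 1:10) {
    x <- rpois(40, 2); x <- x[x > 0]
    if (length(x) < 3) next
    ours <- chao1(x)
    ref <- vegan::estimateR(x)
    expect_equal(ours$estimate, unname(ref["S.chao1"]), tolerance = 1e-10)
    # variance-formula variants differ slightly between implementations
    expect_equal(ours$se, unname(ref["se.chao1"]), tolerance = 0.01)
  }
})

test_that("ACE matches a spreadsheet-style formula evaluation", {
  # counts {1,1,2,3,12}: rare = {1,1,2,3}, abundant = {12}
  # S_abund=1, S_rare=4, N_rare=7, F1=2, C = 1 - 2/7 = 5/7
  # sum k(k-1)F_k = 2*1*1 + 3*2*1 = 8
  # gamma^2 = max(4/C * 8/(7*6) - 1, 0) = 0.0666...
  # ACE = 1 + 4/C + (2/C)*gamma^2
  C <- 5 / 7
  g2 <- max(4 / C * 8 / 42 - 1, 0)
  expected <- 1 + 4 / C + 2 / C * g2
  a <- ace(c(1, 1, 2, 3, 12))
  expect_equal(a$estimate, expected)
  expect_false(a$fallback)
  expect_equal(a$estimate, unname(vegan::estimateR(c(1, 1, 2, 3, 12))["S.ACE"]),
               tolerance = 1e-10)
})

test_that("ACE edge branches: empty rare class and zero coverage", {
  a <- ace(c(20, 30, 40))
  expect_equal(a$estimate, 3)           # all abundant: nothing to extrapolate
  f <- ace(c(1, 1, 1))                  # all rare reads are singletons
  expect_true(f$fallback)
  expect_equal(f$estimate, chao1(c(1, 1, 1))$estimate)
})

test_that("Chao1 and ACE never fall below observed richness (property)", {
  set.seed(7)
  for (i in 1:25) {
    x <- rpois(sample(5:60, 1), sample(1:4, 1))
    x <- x[x > 0]
    if (length(x) == 0) next
    s <- length(x)
    expect_gte(chao1(x)$estimate, s)
    expect_gte(ace(x)$estimate, s)
  }
})

test_that("rooted PD sums the spanning subtree including stem edges", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(faith_pd(tr, c("A", "B", "C")), 5)   # whole tree
  expect_equal(faith_pd(tr, "A"), 2)                # tip edge + stem to root
  expect_equal(faith_pd(tr, c("A", "B")), 3)
  expect_error(faith_pd(tr, c("A", "Z")), "Z")

  # star tree with unit branches: PD of k tips is k
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  for (k in 1:4)
    expect_equal(faith_pd(star, LETTERS[1:k]), k)
})

test_that("rooted PD agrees with picante on random coalescent trees", {
  skip_if_not_installed("picante")
  set.seed(13)
  for (i in 1:5) {
    tr <- ape::rcoal(12)
    pres <- sample(tr$tip.label, sample(2:10, 1))
    m <- matrix(as.integer(tr$tip.label %in% pres), 1,
                dimnames = list("s", tr$tip.label))
    ref <- picante::pd(m, tr, include.root = TRUE)$PD
    expect_equal(faith_pd(tr, pres), ref, tolerance = 1e-10)
  }
})

test_that("rarefaction expectation matches enumeration and Monte Carlo", {
  # exhaustive: draws of 2 from (2,2): E[S] = 2 - 2*C(2,2)/C(4,2) = 5/3
  expect_equal(unname(suppressWarnings(rarefaction_curve(c(2, 2), 2))), 5 / 3)
  # boundary conventions
  expect_equal(unname(rarefaction_curve(c(3, 1), c(0, 1, 4))), c(0, 1, 2))

  # Monte-Carlo oracle on a random small sample
  set.seed(17)
  x <- c(4, 3, 2, 1, 1)
  tab <- otu_table(matrix(x, 1), sample_ids = "s",
                   otu_ids = paste0("o", 1:5), label = "l")
  n_draw <- 10000
  sims <- replicate(n_draw,
    sum(unclass(suppressMessages(downsample(tab, 5))) > 0))
  analytic <- unname(rarefaction_curve(x, 5))
  expect_lt(abs(mean(sims) - analytic), 3 * sd(sims) / sqrt(n_draw))

  # nondecreasing in depth, bounded by S_obs
  curve <- rarefaction_curve(x, 1:11)
  expect_true(all(diff(curve) >= -1e-12))
  expect_lte(max(curve), 5)
  expect_equal(unname(curve[11]), 5)  # full depth recovers S_obs
})

test_that("alpha summary at full depth equals single-table estimators", {
  set.seed(9)
  tab <- rand_table(3, 25, max_count = 15)
  depth <- min(rowSums(tab))
  full <- otu_table(unclass(tab)[, colSums(unclass(tab)) > 0, drop = FALSE],
                    label = otu_label(tab))
  a <- suppressMessages(
    alpha_summary(tab, depth = depth, replicates = 1, seed = 1))
  d <- suppressMessages(downsample(tab, depth, seed = 1))
  i <- 1
  v <- unclass(d)[i, ]
  expect_equal(a$sobs[i], sum(v > 0))
  expect_equal(a$chao1[i], chao1(v)$estimate)
  expect_equal(a$ace[i], ace(v)$estimate)
  expect_equal(a$shannon[i], shannon(v))
  # intervals contain the point estimates
  expect_true(all(a$chao1_lci <= a$chao1 & a$chao1 <= a$chao1_uci))
  expect_true(all(a$shannon_lci <= a$shannon & a$shannon <= a$shannon_uci))
})

test_that("one-OTU samples give degenerate summaries", {
  m <- matrix(c(40, 30), 2, 1)
  tab <- otu_table(m, sample_ids = c("x", "y"), otu_ids = "only",
                   label = "l")
  a <- alpha_summary(tab, depth = 30, replicates = 3, seed = 5)
  expect_equal(a$sobs, c(1, 1))
  expect_equal(a$shannon, c(0, 0))
  expect_equal(a$chao1, c(1, 1))
  expect_equal(a$evenness, c(0, 0))
})

test_that("estimators underestimate a rich community but beat S_obs", {
  ds <- simulate_communities(sim_config(n_otus = 400, core_size = 10,
                                        contamination = rep(0, 5),
                                        depths = 1500, seed = 77))
  a <- suppressMessages(
    alpha_summary(ds$table, depth = 1500, replicates = 3, seed = 78))
  expect_true(all(a$chao1 > a$sobs))
  expect_true(all(a$chao1 < 400 * 1.5))   # sane scale
})
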