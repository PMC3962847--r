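# Per-sample richness and diversity estimators. Shannon quantities use the
# natural logarithm throughout (evenness is log-base invariant, but H'
# magnitudes are reported in nats).

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` in nats over the non-zero proportions of a
#' count vector. Zero for a single category; errors on an all-zero vector.
#'
#' @param counts non-negative numeric vector with at least one positive entry.
#' @return Shannon index in nats.
#' @examples
#' shannon(c(10, 10, 10, 10, 10))  # log(5)
#' @export
shannon <- function(counts) {
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of missing values")
  total <- sum(counts)
  if (total <= 0) stop("all-zero count vector: Shannon index undefined")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Shannon evenness
#'
#' `E = H / log(k)` where `k = n_categories`, the number of categories the
#' counts could have been spread over. With `k` at least the number of
#' occupied categories, arithmetic alone keeps `E` in `[0, 1]`; no truncation
#' is applied.
#'
#' @param counts non-negative numeric vector.
#' @param n_categories number of categories (`>= 2`, and at least the number
#'   of occupied categories). Defaults to `length(counts)`.
#' @return evenness in `[0, 1]`.
#' @examples
#' shannon_evenness(c(4, 3, 4, 6, 6), 5)  # 0.979
#' @export
shannon_evenness <- function(counts, n_categories = length(counts)) {
  n_categories <- as.integer(n_categories)
  if (length(n_categories) != 1L || is.na(n_categories) || n_categories < 2L)
    stop("n_categories must be a single integer >= 2")
  occupied <- sum(counts > 0)
  if (n_categories < occupied)
    stop("n_categories (", n_categories, ") smaller than number of occupied ",
         "categories (", occupied, ")")
  shannon(counts) / log(n_categories)
}

#' Frequency-count decomposition of a sample
#'
#' Abundance frequency counts feeding the nonparametric richness estimators:
#' `F[k]` is the number of OTUs seen exactly `k` times, `S_obs` the observed
#' richness and `N` the read total. The ACE quantities (rare/abundant split
#' at `rare_cutoff`, sample coverage `C_ace`, squared coefficient of
#' variation `gamma_sq`) are derived on demand by [ace()].
#'
#' @param counts non-negative integer vector (one sample).
#' @return list with `F` (named integer vector over observed k), `S_obs`, `N`.
#' @export
frequency_counts <- function(counts) {
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of missing values")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("frequency counts require integer abundances")
  counts <- as.integer(round(counts[counts > 0]))
  tab <- table(counts)
  list(F = stats::setNames(as.integer(tab), names(tab)),
       S_obs = length(counts), N = sum(counts))
}

.fk <- function(fc, k) {
  v <- fc$F[as.character(k)]
  if (is.na(v)) 0L else as.integer(v)
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, the bias-corrected form
#' that stays defined when no doubletons are observed. The 95% confidence
#' interval is the standard log-normal interval on `S_chao1 - S_obs` using
#' the bias-corrected variance.
#'
#' @param counts non-negative integer vector (one sample).
#' @param conf confidence level for the interval.
#' @return list with `estimate`, `se`, `ci` (length-2), `S_obs`.
#' @examples
#' chao1(c(1, 1, 2, 2, 3))$estimate  # 5.3333
#' @export
chao1 <- function(counts, conf = 0.95) {
  fc <- frequency_counts(counts)
  f1 <- .fk(fc, 1); f2 <- .fk(fc, 2)
  s <- fc$S_obs
  est <- s + f1 * (f1 - 1) / (2 * (f2 + 1))
  v <- f1 * (f1 - 1) / (2 * (f2 + 1)) +
    f1 * (2 * f1 - 1)^2 / (4 * (f2 + 1)^2) +
    f1^2 * f2 * (f1 - 1)^2 / (4 * (f2 + 1)^4)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  d <- est - s
  ci <- if (d > 0 && v > 0) {
    k <- exp(z * sqrt(log(1 + v / d^2)))
    c(s + d / k, s + d * k)
  } else c(s, s)
  list(estimate = est, se = sqrt(v), ci = ci, S_obs = s)
}

#' ACE (abundance-based coverage) richness estimate
#'
#' Splits OTUs into rare (`count <= rare_cutoff`) and abundant classes and
#' estimates `S_ACE = S_abund + S_rare / C_ace + (F1 / C_ace) * gamma_sq`,
#' with `C_ace = 1 - F1 / N_rare` the rare-class sample coverage and
#' `gamma_sq` the (non-negative) squared coefficient of variation of the
#' rare-class abundances. When every rare read is a singleton the coverage is
#' zero and ACE is undefined; the estimate then falls back to [chao1()] and
#' the fallback is flagged.
#'
#' The 95% interval is a normal-approximation interval using the ACE standard
#' error of `vegan::estimateR()` (available at the conventional cutoff of
#' 10); for other cutoffs no closed-form standard error is provided and the
#' interval is `NA` with a note.
#'
#' @param counts non-negative integer vector (one sample).
#' @param rare_cutoff rare-class abundance threshold (convention: 10).
#' @param conf confidence level.
#' @return list with `estimate`, `ci`, `S_obs`, `fallback` (logical), `note`.
#' @export
ace <- function(counts, rare_cutoff = 10, conf = 0.95) {
  fc <- frequency_counts(counts)
  s <- fc$S_obs
  x <- counts[counts > 0]
  rare <- x[x <= rare_cutoff]
  s_rare <- length(rare); s_abund <- s - s_rare
  if (s_rare == 0L)   # empty rare class: nothing to extrapolate from
    return(list(estimate = s, ci = c(s, s), S_obs = s,
                fallback = FALSE, note = "no rare class"))
  n_rare <- sum(rare)
  f1 <- .fk(fc, 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    ch <- chao1(counts, conf)
    return(list(estimate = ch$estimate, ci = ch$ci, S_obs = s,
                fallback = TRUE,
                note = "zero rare-class coverage; Chao1 fallback"))
  }
  ks <- seq_len(rare_cutoff)
  fk <- vapply(ks, function(k) .fk(fc, k), 0L)
  gamma_sq <- max(s_rare / c_ace * sum(ks * (ks - 1) * fk) /
                    (n_rare * (n_rare - 1)) - 1, 0)
  est <- s_abund + s_rare / c_ace + f1 / c_ace * gamma_sq
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (rare_cutoff == 10) {
    er <- vegan::estimateR(as.integer(round(counts)))
    se <- unname(er["se.ACE"])
    ci <- c(est - z * se, est + z * se)
    note <- ""
  } else {
    ci <- c(NA_real_, NA_real_)
    note <- "no closed-form se at non-default rare cutoff"
  }
  list(estimate = est, ci = ci, S_obs = s, fallback = FALSE, note = note)
}

#' Faith's phylogenetic diversity (rooted)
#'
#' Sum of the branch lengths of the minimal subtree connecting the present
#' leaves to the root. The stem edges up to the root are included (rooted
#' PD), so a single present leaf contributes its full root-to-tip path.
#'
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param present_leaves character vector of leaf names present in the
#'   sample; must be a non-empty subset of `tree$tip.label`.
#' @return PD in branch-length units.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' faith_pd(tr, "A")  # 2: A's edge plus its stem to the root
#' @export
faith_pd <- function(tree, present_leaves) {
  stopifnot(inherits(tree, "phylo"))
  present_leaves <- unique(as.character(present_leaves))
  if (length(present_leaves) == 0L) stop("present_leaves must be non-empty")
  miss <- setdiff(present_leaves, tree$tip.label)
  if (length(miss))
    stop("leaf name(s) not in tree: ", paste(miss, collapse = ", "))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  subtends <- logical(ntip + tr$Nnode)
  subtends[match(present_leaves, tr$tip.label)] <- TRUE
  parent <- tr$edge[, 1L]; child <- tr$edge[, 2L]
  for (e in seq_along(parent))   # postorder: children before parents
    if (subtends[child[e]]) subtends[parent[e]] <- TRUE
  sum(tr$edge.length[subtends[child]])
}

#' Analytic rarefaction curve
#'
#' Expected number of OTUs observed in a without-replacement draw of `n`
#' reads from a sample:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`,
#' evaluated through `vegan::rarefy()`'s numerically stable implementation.
#' Depth 0 yields 0 by convention.
#'
#' @param counts non-negative integer vector (one sample).
#' @param depths non-negative integer depths, each `<= sum(counts)`.
#' @return numeric vector of expected richness, named by depth.
#' @export
rarefaction_curve <- function(counts, depths) {
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("rarefaction requires integer counts")
  counts <- as.integer(round(counts))
  n_total <- sum(counts)
  depths <- as.integer(depths)
  if (any(depths < 0) || any(depths > n_total))
    stop("depths must lie in [0, ", n_total, "]")
  out <- numeric(length(depths))
  pos <- depths > 0L
  if (any(pos))
    out[pos] <- as.numeric(vegan::rarefy(counts, sample = depths[pos]))
  stats::setNames(out, depths)
}

# Analytic variance of the Shannon estimator (first-order):
# var(H) ~ (sum p log(p)^2 - H^2) / N
.shannon_ci <- function(counts, conf = 0.95) {
  total <- sum(counts)
  p <- counts[counts > 0] / total
  h <- -sum(p * log(p))
  v <- max((sum(p * log(p)^2) - h^2) / total, 0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(h - z * sqrt(v), h + z * sqrt(v))
}

#' Per-sample alpha-diversity summary over down-sampling replicates
#'
#' Computes, for each sample, observed richness, bias-corrected Chao1 and ACE
#' (with 95% intervals), Shannon diversity and evenness, and (when a tree is
#' supplied) Faith's rooted PD — each on `replicates` independent even-depth
#' down-samplings at `depth`, reported as the mean across replicates.
#' Interval bounds are, by default, the means of the per-replicate analytic
#' bounds (the presentation used when tabulating subsample means); an
#' empirical alternative (normal interval on the replicate means) is
#' available.
#'
#' @param x an integer [otu_table()].
#' @param depth reads per sample per replicate.
#' @param replicates number of down-sampling replicates (study convention 5).
#' @param seed master seed (see [averaged_shared()] for the derivation rule).
#' @param tree optional rooted [ape::phylo] whose leaves cover the table's
#'   OTU ids; enables the `pd` column.
#' @param rare_cutoff ACE rare-class cutoff.
#' @param ci_method `"analytic"` (mean of per-replicate analytic intervals)
#'   or `"empirical"` (interval of the replicate means).
#' @return an `alpha_summary`: data frame with one row per sample and
#'   attributes `depth`, `replicates`, `label`, `ci_method`.
#' @export
alpha_summary <- function(x, depth, replicates = 5L, seed = NULL, tree = NULL,
                          rare_cutoff = 10,
                          ci_method = c("analytic", "empirical")) {
  stopifnot(inherits(x, "otu_table"))
  .assert_integer_table(x, "alpha_summary()")
  ci_method <- match.arg(ci_method)
  if (!is.null(tree)) check_links(x, tree = tree)
  replicates <- as.integer(replicates)
  seeds <- if (is.null(seed)) rep(list(NULL), replicates)
           else if (replicates == 1L) list(seed)
           else as.list(derive_seeds(seed, replicates))
  ns <- nrow(x)
  cols <- c("sobs", "chao1", "chao1_lci", "chao1_uci", "ace", "ace_lci",
            "ace_uci", "shannon", "shannon_lci", "shannon_uci", "evenness",
            "pd")
  acc <- array(NA_real_, dim = c(replicates, ns, length(cols)),
               dimnames = list(NULL, sample_ids(x), cols))
  fallback <- matrix(FALSE, replicates, ns)
  for (r in seq_len(replicates)) {
    d <- downsample(x, depth, seed = seeds[[r]])
    m <- unclass(d)
    for (i in seq_len(ns)) {
      v <- m[i, ]
      ch <- chao1(v)
      ac <- ace(v, rare_cutoff = rare_cutoff)
      h <- shannon(v)
      hci <- .shannon_ci(v)
      sobs <- sum(v > 0)
      pd <- if (!is.null(tree))
        faith_pd(tree, otu_ids(d)[v > 0]) else NA_real_
      acc[r, i, ] <- c(sobs, ch$estimate, ch$ci, ac$estimate, ac$ci,
                       h, hci,
                       if (sobs > 1) h / log(sobs) else 0,
                       pd)
      fallback[r, i] <- ac$fallback
    }
  }
  agg <- apply(acc, c(2, 3), mean)
  if (ci_method == "empirical" && replicates > 1L) {
    z <- stats::qnorm(0.975)
    for (est in c("chao1", "ace", "shannon")) {
      mm <- agg[, est]
      sdm <- apply(acc[, , est, drop = FALSE], 2, stats::sd)
      agg[, paste0(est, "_lci")] <- mm - z * sdm / sqrt(replicates)
      agg[, paste0(est, "_uci")] <- mm + z * sdm / sqrt(replicates)
    }
  }
  out <- data.frame(sample = sample_ids(x), agg, row.names = NULL,
                    check.names = FALSE)
  out$ace_fallback <- colSums(fallback) > 0
  if (is.null(tree)) out$pd <- NULL
  structure(out, depth = depth, replicates = replicates,
            label = otu_label(x), ci_method = ci_method,
            class = c("alpha_summary", "data.frame"))
}

#' @export
print.alpha_summary <- function(x, digits = 3, ...) {
  cat("Alpha diversity (label ", attr(x, "label"), "): mean of ",
      attr(x, "replicates"), " down-sampling replicate(s) at depth ",
      attr(x, "depth"), "\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
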