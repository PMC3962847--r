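# Even-depth normalization: without-replacement down-sampling of integer
# count tables and replicate-averaged tables. Down-sampling reads is sampling
# without replacement from the physical pool of sequenced reads, so each
# sample's draw is multivariate hypergeometric (rarefaction semantics), not
# multinomial.

# Run code with a temporarily seeded RNG, restoring (or clearing) the
# caller's RNG state afterwards. seed = NULL leaves the global stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Independent sub-seeds derived from one master seed, so a replicate set is
# reproducible as a whole. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# One sample's without-replacement draw: multivariate hypergeometric via a
# uniform draw of `depth` reads from the pool of N labelled reads.
.hyper_draw <- function(counts, depth) {
  n <- sum(counts)
  if (depth == n) return(counts)
  pool <- rep.int(seq_along(counts), counts)
  picked <- sample(pool, depth, replace = FALSE)
  tabulate(picked, nbins = length(counts))
}

#' Down-sample every sample to a common read depth
#'
#' Draws exactly `depth` reads per sample without replacement (multivariate
#' hypergeometric), emulating rarefaction of the sequencing effort to the
#' smallest sample. A sample whose total already equals `depth` is returned
#' unchanged.
#'
#' @param x an integer [otu_table()].
#' @param depth target reads per sample; must not exceed any sample total.
#' @param seed integer seed for reproducibility; `NULL` uses the current RNG
#'   stream.
#' @return an integer `otu_table` whose sample totals all equal `depth`.
#'   OTU columns left with zero total are dropped (with a message), as for
#'   any table construction.
#' @examples
#' tab <- otu_table(matrix(c(10, 5, 5, 0), 1), sample_ids = "S1", label = "0.03")
#' rowSums(downsample(tab, depth = 8, seed = 1))
#' @export
downsample <- function(x, depth, seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  .assert_integer_table(x, "downsample()")
  depth <- as.integer(depth)
  if (length(depth) != 1L || is.na(depth) || depth < 1L)
    stop("depth must be a single positive integer")
  totals <- rowSums(x)
  short <- totals < depth
  if (any(short))
    stop("depth ", depth, " exceeds total reads of sample(s): ",
         paste(sprintf("%s (%d)", sample_ids(x)[short], totals[short]),
               collapse = ", "))
  m <- unclass(x)
  out <- matrix(0L, nrow(m), ncol(m))
  with_seed(seed, {
    for (i in seq_len(nrow(m)))
      out[i, ] <- .hyper_draw(as.integer(round(m[i, ])), depth)
  })
  otu_table(out, sample_ids = sample_ids(x), otu_ids = otu_ids(x),
            label = otu_label(x))
}

#' Replicate-averaged even-depth table
#'
#' Draws `replicates` independent down-samplings at `depth` and returns their
#' entry-wise arithmetic mean: the "averaged shared table" used to normalize
#' unequal sequencing effort before community comparison. Means of
#' constant-sum draws keep the conservation property: every output sample
#' still sums to `depth` exactly. Fractional means are kept as is; consumers
#' that need whole reads must state their own rounding policy.
#'
#' @param x an integer [otu_table()].
#' @param depth reads per sample for each replicate draw.
#' @param replicates number of independent draws to average (study convention
#'   is 5).
#' @param seed master seed; each replicate uses a deterministically derived
#'   sub-seed, so the replicate set is reproducible as a whole.
#' @return a real-valued `otu_table`.
#' @export
averaged_shared <- function(x, depth, replicates = 5L, seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  replicates <- as.integer(replicates)
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1L)
    stop("replicates must be a single positive integer")
  seeds <- if (is.null(seed)) rep(list(NULL), replicates)
           else if (replicates == 1L) list(seed)  # degenerate mean == one draw
           else as.list(derive_seeds(seed, replicates))
  acc <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  for (r in seq_len(replicates)) {
    d <- downsample(x, depth, seed = seeds[[r]])
    # replicate draws can drop different zero columns; realign on input ids
    acc[, otu_ids(d)] <- acc[, otu_ids(d)] + unclass(d)
  }
  otu_table(acc / replicates, sample_ids = sample_ids(x),
            otu_ids = otu_ids(x), label = otu_label(x))
}
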