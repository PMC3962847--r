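# Rank correlation of diversity measures against environmental gradients.
# At the tiny sample sizes typical of soil surveys (n = 5 here) the
# large-sample p-value approximations are unreliable, so the two-sided
# p-value is computed by full enumeration of rank permutations for n <= 8.

# All permutations of 1..n as an n! x n matrix (n <= 8 => at most 40,320
# rows; fine to enumerate).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' `rho` is the Pearson correlation of the mid-rank-transformed vectors
#' (ties receive average ranks). The two-sided p-value is exact — computed
#' by full enumeration of all `n!` permutations of one rank vector — when
#' `n <= 8`, and otherwise uses the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, no missing values,
#'   neither constant.
#' @param x_name,y_name names recorded in the result.
#' @return a `spearman_cor` list: `x_name`, `y_name`, `rho`, `p_value`, `n`,
#'   `method` (`"exact-permutation"` or `"t-approximation"`).
#' @examples
#' spearman_cor(c(521, 538, 863, 692, 1478),
#'              c(6.367, 6.309, 5.978, 6.196, 5.321))  # rho = -1
#' @export
spearman_cor <- function(x, y, x_name = deparse(substitute(x)),
                         y_name = deparse(substitute(y))) {
  if (length(x) != length(y))
    stop("vectors differ in length (", length(x), " vs ", length(y), ")")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- .permutations(n)
    rho_perm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p_value <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  structure(list(x_name = x_name, y_name = y_name, rho = rho,
                 p_value = min(p_value, 1), n = n, method = method),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: %s vs %s\n", x$x_name, x$y_name))
  cat(sprintf("rho = %.4f, p = %.4g (%s, n = %d)\n",
              x$rho, x$p_value, x$method, x$n))
  invisible(x)
}

#' Correlate every diversity measure against every environment variable
#'
#' Tests each (measure, variable) pair by [spearman_cor()]. Samples are
#' aligned by identifier; a mismatch in the sample sets is an error (listing
#' the differences), never a silent drop. No multiplicity correction is
#' applied by default — the number of tests performed is recorded so readers
#' can judge — with Holm adjustment available.
#'
#' @param alpha an [alpha_summary()] (or any data frame with a `sample`
#'   column and numeric measure columns).
#' @param env environment data frame, row names = sample ids, numeric
#'   columns.
#' @param measures measure columns to use; default: all numeric columns of
#'   `alpha` except interval bounds.
#' @param variables environment columns to use; default: all.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return data frame with `measure`, `variable`, `rho`, `p_value`, `n`,
#'   `method` (plus `p_adjusted` when requested); attribute `n_tests`.
#' @export
correlate_all <- function(alpha, env, measures = NULL, variables = NULL,
                          p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  df <- as.data.frame(alpha)
  if (!"sample" %in% names(df)) stop("alpha table lacks a 'sample' column")
  miss <- setdiff(df$sample, rownames(env))
  extra <- setdiff(rownames(env), df$sample)
  if (length(miss) || length(extra))
    stop("sample-set mismatch; in alpha but not env: {",
         paste(miss, collapse = ", "), "}; in env but not alpha: {",
         paste(extra, collapse = ", "), "}")
  env <- env[df$sample, , drop = FALSE]
  if (is.null(measures)) {
    num <- names(df)[vapply(df, is.numeric, TRUE)]
    measures <- setdiff(num, grep("_lci$|_uci$", num, value = TRUE))
  }
  if (is.null(variables)) variables <- names(env)
  grid <- expand.grid(measure = measures, variable = variables,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- spearman_cor(env[[grid$variable[i]]], df[[grid$measure[i]]],
                      x_name = grid$variable[i], y_name = grid$measure[i])
    data.frame(measure = grid$measure[i], variable = grid$variable[i],
               rho = r$rho, p_value = r$p_value, n = r$n, method = r$method)
  })
  out <- do.call(rbind, res)
  if (p_adjust == "holm")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  structure(out, n_tests = nrow(out), p_adjust = p_adjust)
}
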