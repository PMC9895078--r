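# Internal helpers shared across modules.

# log2(TPM/10 + 1) transform used for clustering and differential expression.
log_tpm <- function(x) log2(x / 10 + 1)

# Symmetric/general Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))  # degenerate tiny-alpha guard
  g / sum(g)
}

# Allocate `total` integer units to components proportional to `weights`
# (largest-remainder rounding; ties broken by component index).
largest_remainder <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Pearson correlation of each column of `mat` with vector `y`, plus two-sided
# test p values from the t distribution. Zero-variance columns (or a
# zero-variance y) yield r = 0, p = 1, flagged.
cor_with_vector <- function(mat, y) {
  n <- length(y)
  sdy <- stats::sd(y)
  sdx <- apply(mat, 2, stats::sd)
  degenerate <- !is.finite(sdx) | sdx == 0 | !is.finite(sdy) | sdy == 0
  r <- rep(0, ncol(mat))
  if (!all(degenerate)) {
    r[!degenerate] <- as.vector(stats::cor(mat[, !degenerate, drop = FALSE], y))
  }
  r[!is.finite(r)] <- 0
  p <- rep(1, ncol(mat))
  ok <- !degenerate & abs(r) < 1 & n > 2
  tt <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!degenerate & abs(r) >= 1 & n > 2] <- 0
  names(r) <- names(p) <- colnames(mat)
  list(r = r, p = p, degenerate = degenerate)
}

# Scale every column of a non-negative matrix to sum `scale` (TPM = 1e6).
# All-zero columns are left untouched.
scale_columns <- function(x, scale = 1e6) {
  cs <- colSums(x)
  nz <- cs > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, cs[nz] / scale, "/")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
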