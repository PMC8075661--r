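#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree dist hclust pt rnorm runif sd setNames var
#' @importFrom utils read.table write.table
NULL

# Deterministic per-unit seed stream: mixes a master seed with an index using
# 32-bit-safe modular arithmetic (Lehmer-style multipliers, modulus 2^31 - 1).
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 %% m
  s <- (s + as.numeric(index) * 1299721) %% m
  as.integer(s %% 2147483562 + 1)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Trapezoidal integral of y over grid x (strictly increasing).
trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2, all(diff(x) > 0))
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

upper_tri_index <- function(n) which(upper.tri(matrix(0, n, n)))

# Vectorized two-sample Student (equal-variance) t-test across columns.
# x: n1 x p, y: n2 x p. Zero pooled variance: p = 1 when means agree
# (no evidence), p = 0 when they differ (infinitely strong evidence).
col_t_test <- function(x, y) {
  n1 <- nrow(x); n2 <- nrow(y)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- apply(x, 2, var); v2 <- apply(y, 2, var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  p <- 2 * pt(-abs(tt), df)
  zero <- se == 0
  if (any(zero)) {
    same <- zero & (m1 == m2)
    tt[same] <- 0; p[same] <- 1
    diffp <- zero & (m1 != m2)
    tt[diffp] <- sign(m1[diffp] - m2[diffp]) * Inf; p[diffp] <- 0
  }
  list(t = tt, p = p, df = df)
}
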