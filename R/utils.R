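# Internal helpers shared across modules.

# Run `expr` under a reproducible RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. A NULL seed means "use the session stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

clamp01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Rolling mean / SD over a centered window of `w` samples, ignoring NAs and
# shrinking at the edges. Returns a list(mean, sd, n).
roll_stats <- function(x, w) {
  stopifnot(w >= 1)
  n <- length(x)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  k <- rep(1, min(w, n))
  cnt <- as.numeric(stats::filter(as.numeric(ok), k, sides = 2))
  s1 <- as.numeric(stats::filter(x0, k, sides = 2))
  s2 <- as.numeric(stats::filter(x0^2, k, sides = 2))
  # stats::filter leaves NAs at the edges; recompute those with shrunk windows
  half <- (length(k) - 1) %/% 2
  for (i in which(is.na(cnt))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    seg <- x[lo:hi]
    cnt[i] <- sum(!is.na(seg))
    s1[i] <- sum(seg, na.rm = TRUE)
    s2[i] <- sum(seg^2, na.rm = TRUE)
  }
  m <- ifelse(cnt > 0, s1 / cnt, NA_real_)
  v <- ifelse(cnt > 1, pmax(0, (s2 - cnt * m^2) / (cnt - 1)), NA_real_)
  list(mean = m, sd = sqrt(v), n = cnt)
}
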