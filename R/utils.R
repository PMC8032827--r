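# Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` with the RNG temporarily seeded at `seed`, restoring the
# caller's stream afterwards. seed = NULL uses (and advances) the current
# stream, which is what the Monte-Carlo inner loop relies on.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    .stopf("seed must be a single finite number (got %s)", deparse(seed))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# ---- interval primitives (0-based half-open, single chromosome) ----------
# All coordinates are doubles holding integral values; chromosome lengths
# stay far below 2^53 so exact integer arithmetic is guaranteed.

# Merge possibly overlapping intervals; book-ended runs collapse too.
# Returns a 2-column matrix (start, end) sorted by start.
.iv_merge1 <- function(start, end) {
  n <- length(start)
  if (n == 0L) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  if (n == 1L) return(cbind(start = start, end = end))
  cm <- cummax(end)
  new_run <- c(TRUE, start[-1L] > cm[-n])
  last <- c(which(new_run)[-1L] - 1L, n)
  cbind(start = start[new_run], end = cm[last])
}

# Total bases in the union of two already-merged interval lists.
.iv_union_bp2 <- function(s1, e1, s2, e2) {
  s <- c(s1, s2)
  if (!length(s)) return(0)
  e <- c(e1, e2)
  o <- order(s)
  s <- s[o]
  cm <- cummax(e[o])
  n <- length(s)
  if (n == 1L) return(cm - s)
  gaps <- pmax(0, s[-1L] - cm[-n])
  (cm[n] - s[1L]) - sum(gaps)
}

# Covered bases in [0, x) for each x, given merged intervals (s, e).
.iv_cov_upto <- function(x, s, e) {
  res <- numeric(length(x))
  if (!length(s)) return(res)
  cum <- c(0, cumsum(e - s))
  i <- findInterval(x, s)
  pos <- i > 0L
  ii <- i[pos]
  res[pos] <- cum[ii] + pmax(0, pmin(x[pos], e[ii]) - s[ii])
  res
}
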