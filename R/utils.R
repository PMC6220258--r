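# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All user-facing randomness in the package funnels through this helper so
# identical seeds give bit-identical output without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("`seed` must be a single integer", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a reproducible sub-seed for a named stage from a master seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

# Point-in-intervals test: intervals are 0-based half-open [start, end).
# `pos0` are 0-based positions; `ivl` a data.frame with columns start, end.
in_intervals <- function(pos0, ivl) {
  if (is.null(ivl) || nrow(ivl) == 0L) return(rep(FALSE, length(pos0)))
  hit <- rep(FALSE, length(pos0))
  for (k in seq_len(nrow(ivl))) {
    hit <- hit | (pos0 >= ivl$start[k] & pos0 < ivl$end[k])
  }
  hit
}

# Merge/normalise an interval set (0-based half-open) into disjoint sorted rows.
merge_intervals <- function(ivl) {
  if (is.null(ivl) || nrow(ivl) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  ivl <- ivl[order(ivl$start, ivl$end), , drop = FALSE]
  out_s <- ivl$start[1]; out_e <- ivl$end[1]
  ss <- c(); ee <- c()
  if (nrow(ivl) > 1L) {
    for (k in 2:nrow(ivl)) {
      if (ivl$start[k] <= out_e) {
        out_e <- max(out_e, ivl$end[k])
      } else {
        ss <- c(ss, out_s); ee <- c(ee, out_e)
        out_s <- ivl$start[k]; out_e <- ivl$end[k]
      }
    }
  }
  data.frame(start = c(ss, out_s), end = c(ee, out_e))
}

# Convex hull of an interval set.
hull_interval <- function(ivl) {
  if (is.null(ivl) || nrow(ivl) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = min(ivl$start), end = max(ivl$end))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
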