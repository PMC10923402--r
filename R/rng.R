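# Deterministic seed substreams and vectorized categorical draws.
#
# All randomness in the package flows from a single master seed. Each
# operation/zone pair derives its own substream seed by hashing the master
# seed together with string tags, so zones are order-independent and adding
# an operation does not perturb the draws of the others.

# Polynomial string hash modulo the Mersenne prime 2^31 - 1, mapped into
# [1, 2^31 - 2] so it is always a valid set.seed() argument.
hash_seed <- function(master_seed, ...) {
  tag <- paste(c(as.character(master_seed), vapply(list(...), as.character,
                                                  character(1))),
               collapse = "\x1f")
  h <- 0
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Run `expr` under a substream derived from (master_seed, tags...), restoring
# the caller's RNG state afterwards.
with_substream <- function(master_seed, ..., expr) {
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
  set.seed(hash_seed(master_seed, ...))
  expr
}

# One draw per row from a row-stochastic matrix of category probabilities.
# Returns 1-based column indices. Rows that sum to zero raise an error
# (callers mask infeasible categories before renormalizing).
rcat_rows <- function(prob) {
  n <- nrow(prob)
  if (n == 0L) return(integer(0))
  tot <- rowSums(prob)
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    stop("sampling error: a conditional row has no admissible category",
         call. = FALSE)
  }
  prob <- prob / tot
  k <- ncol(prob)
  cum <- prob
  if (k > 1L) for (j in 2:k) cum[, j] <- cum[, j - 1L] + prob[, j]
  u <- stats::runif(n)
  idx <- rowSums(cum < u) + 1L
  pmin(idx, k)
}

# One Dirichlet(alpha) draw.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha   # numerically degenerate shapes
  g / sum(g)
}

# Uniform integer draws on [lo, hi] elementwise (vectors recycled).
runif_int <- function(n, lo, hi) {
  if (any(lo > hi)) {
    stop("constraint error: empty feasible age interval", call. = FALSE)
  }
  lo + floor(stats::runif(n) * (hi - lo + 1))
}
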