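# Internal helpers shared across modules.

# Risk classes in label order 0, 1, 2.
risk_levels <- function() c("low", "medium", "high")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library calls never perturb user RNG streams.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

# Largest-remainder apportionment of `total` integer units over fractional
# quotas. Ties in remainders are broken by lower index (deterministic).
largest_remainder <- function(quotas, total) {
  stopifnot(all(quotas >= 0), total >= 0)
  base <- floor(quotas)
  left <- total - sum(base)
  if (left < 0) stop("quotas exceed total; cannot apportion")
  if (left > 0) {
    rem <- quotas - base
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Row-validated probability matrix helper: rescale rows to sum exactly 1 and
# guard against negative round-off.
normalize_prob_rows <- function(P) {
  P[P < 0] <- 0
  s <- rowSums(P)
  if (any(s <= 0)) stop("probability rows must have positive mass")
  P / s
}

check_labels <- function(y, arg = "y") {
  if (length(y) == 0) stop(sprintf("'%s' is empty", arg))
  if (anyNA(y) || !all(y %in% 0:2))
    stop(sprintf("'%s' must contain only labels 0, 1, 2", arg))
  as.integer(y)
}
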