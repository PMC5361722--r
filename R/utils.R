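# Run code under a temporary RNG state. seed = NULL leaves the current
# stream untouched so callers can manage randomness themselves.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-signature seed so batch results do not depend on the
# order signatures are processed in. Kept below 2^31 - 1.
sig_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

activation_levels <- function() c("low", "independent", "high")

as_activation_factor <- function(x) {
  factor(as.character(x), levels = activation_levels())
}
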