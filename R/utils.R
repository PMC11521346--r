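# internal helpers shared across modules

DAYS_PER_YEAR <- 365.25

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# deterministic child seed; kept well below 2^31
child_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  s <- 0
  for (p in parts) s <- (s * 31 + as.numeric(p)) %% 2147483629
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sc_warn <- function(...) warning(sprintf(...), call. = FALSE)
sc_stop <- function(...) stop(sprintf(...), call. = FALSE)
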