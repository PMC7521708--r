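# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible sub-seed from a master seed and a stream offset, so
# that e.g. regenerating the network does not perturb the sequence stream.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) %% 1000003) + 1
  as.integer((s * 48271 + as.numeric(offset) * 7919) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed_ <- function(seed, code) {
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

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

canonical_labels <- function(labels) {
  # Accepts factor/character/0-1 coding; returns character vector in
  # {"essential", "nonessential"} keeping names.
  nm <- names(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels) || is.logical(labels)) {
    labels <- ifelse(as.numeric(labels) > 0, "essential", "nonessential")
  }
  bad <- setdiff(unique(labels), c("essential", "nonessential"))
  if (length(bad)) stopf("unknown labels: %s", paste(bad, collapse = ", "))
  names(labels) <- nm
  labels
}
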