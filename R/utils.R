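# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the session stream.
with_seed <- function(seed, expr) {
  force(seed)  # before the state snapshot: a lazily passed seed expression may
               # itself draw from the RNG, and that draw must not be rolled back
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# round() in R rounds half to even; percentages here round half away from zero.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

BASES <- c("A", "C", "G", "T")

# Split a sequence string into a 1..4 base code vector; N (or anything
# non-ACGT after normalization) becomes NA.
seq_to_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
}

codes_to_seq <- function(codes) {
  out <- BASES[codes]
  out[is.na(codes)] <- "N"
  paste(out, collapse = "")
}
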