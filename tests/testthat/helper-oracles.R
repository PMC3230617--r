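# Independent oracles used across the suite. These are deliberately naive
# re-derivations (window-by-window enumeration, explicit hypergeometric sums)
# so they never share code with the implementation they check.

# Window-by-window dinucleotide enumeration.
naive_dinuc_counts <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  mono <- setNames(integer(4), bases)
  for (ch in chars) if (ch %in% bases) mono[ch] <- mono[ch] + 1L
  di <- setNames(integer(16), as.vector(outer(bases, bases, function(a, b) paste0(a, b))))
  W <- 0L
  if (length(chars) >= 2L) {
    for (i in seq_len(length(chars) - 1L)) {
      a <- chars[i]; b <- chars[i + 1L]
      if (a %in% bases && b %in% bases) {
        di[paste0(a, b)] <- di[paste0(a, b)] + 1L
        W <- W + 1L
      }
    }
  }
  list(mono = mono, L_eff = sum(mono), di = di, W = W)
}

naive_oe <- function(seq, xy) {
  nc <- naive_dinuc_counts(seq)
  x <- substr(xy, 1, 1); y <- substr(xy, 2, 2)
  if (nc$W == 0 || nc$mono[x] == 0 || nc$mono[y] == 0) return(NA_real_)
  (nc$di[xy] / nc$W) / ((nc$mono[x] / nc$L_eff) * (nc$mono[y] / nc$L_eff))
}

# Explicit hypergeometric upper tail by summation of choose() terms.
brute_hyper_ge <- function(list_hits, list_size, pop_hits, pop_size) {
  jmax <- min(list_size, pop_hits)
  if (list_hits > jmax) return(0)
  j <- max(list_hits, 0):jmax
  sum(choose(pop_hits, j) * choose(pop_size - pop_hits, list_size - j)) /
    choose(pop_size, list_size)
}

# sample() treats a length-1 numeric vector as 1:n; this always picks one
# element of v
sample_one <- function(v) v[sample.int(length(v), 1L)]

# A random consistent 2x2 over-representation table.
random_table <- function(max_pop = 30) {
  pop_size <- sample_one(5:max_pop)
  pop_hits <- sample_one(0:pop_size)
  list_size <- sample_one(1:pop_size)
  lo <- max(0, list_size - (pop_size - pop_hits))
  hi <- min(list_size, pop_hits)
  list(list_hits = sample_one(lo:hi), list_size = list_size,
       pop_hits = pop_hits, pop_size = pop_size)
}

random_seq <- function(n, p_n = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alphabet <- c("A", "C", "G", "T", "N")
  p <- c(rep((1 - p_n) / 4, 4), p_n)
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# A hand-buildable k=2 fit for boundary/classification tests.
make_fit <- function(weights, means, sds, converged = TRUE) {
  structure(list(k = 2L, weights = weights, means = means, sds = sds,
                 loglik = 0, n_iter = 1L, converged = converged, seed = 1L,
                 n = 100L, loglik_trace = 0),
            class = "mixture_fit")
}
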