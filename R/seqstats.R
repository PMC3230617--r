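DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          paste0))  # AA, CA, GA, TA, AC, ... (column-major)

#' Count mono- and dinucleotides with N-aware windows
#'
#' Counts the four mononucleotides over the non-N positions of a sequence and
#' the sixteen ACGT dinucleotides over the N-free adjacent windows. A window
#' contributes only when both of its bases are in `{A, C, G, T}`, so runs of N
#' (and the two windows flanking each run) are excluded rather than being
#' miscounted. This is the counting layer behind the N-corrected
#' observed/expected ratios.
#'
#' @param seq A residue string over `{A, C, G, T, N}` (lowercase accepted), or
#'   a length-1 named character vector.
#' @param id Gene identifier; defaults to `names(seq)` when present.
#' @return An object of class `dinuc_counts`: a list with `gene_id`, `mono`
#'   (named length-4 count vector), `L_eff` (number of non-N bases), `di`
#'   (named length-16 count vector) and `W` (number of N-free windows).
#' @examples
#' count_dinucleotides("CGCGCGCG")
#' @export
count_dinucleotides <- function(seq, id = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq) else NA_character_
  codes <- seq_to_codes(seq)
  mono <- tabulate(codes, nbins = 4L)
  names(mono) <- BASES
  n <- length(codes)
  if (n >= 2L) {
    a <- codes[-n]
    b <- codes[-1L]
    pair <- (b - 1L) * 4L + a  # column-major over (first, second)
    di <- tabulate(pair[!is.na(pair)], nbins = 16L)
  } else {
    di <- integer(16L)
  }
  names(di) <- DINUCS
  structure(
    list(gene_id = unname(id), mono = mono, L_eff = sum(mono),
         di = di, W = sum(di), length = n),
    class = "dinuc_counts"
  )
}

#' Dinucleotide observed/expected ratio with N correction
#'
#' The observed frequency of dinucleotide `xy` is its count divided by the
#' number of N-free windows `W`; the expected frequency is the product of the
#' mononucleotide frequencies of `x` and `y` taken over the `L_eff` non-N
#' bases:
#' \deqn{O/E = \frac{d_{xy} / W}{(m_x / L_{eff}) (m_y / L_{eff})}}
#' With no Ns present this reduces to the textbook estimator. The ratio is
#' undefined (returned as `NA` with a reason code) when a denominator term is
#' zero or the sequence has fewer than `min_length` non-N bases; a zero
#' numerator with valid denominators yields 0, not `NA`.
#'
#' @param counts A `dinuc_counts` object from [count_dinucleotides()].
#' @param xy Two-letter dinucleotide, e.g. `"CG"`.
#' @param min_length Minimum `L_eff` for the ratio to be defined (default 0
#'   here; [oe_profile()] applies its own dataset-level default).
#' @return List with `oe` (non-negative numeric, or `NA`) and `reason`
#'   (`NA_character_` when defined; otherwise one of `"short"`,
#'   `"zero_mono_x"`, `"zero_mono_y"`, `"no_windows"`).
#' @examples
#' dinucleotide_oe(count_dinucleotides("CGCGCGCG"), "CG")
#' @export
dinucleotide_oe <- function(counts, xy, min_length = 0L) {
  stopifnot(inherits(counts, "dinuc_counts"))
  xy <- toupper(xy)
  if (!xy %in% DINUCS) stop("not an ACGT dinucleotide: ", xy)
  x <- substr(xy, 1L, 1L)
  y <- substr(xy, 2L, 2L)
  if (counts$L_eff < min_length) {
    return(list(oe = NA_real_, reason = "short"))
  }
  if (counts$W == 0L) {
    return(list(oe = NA_real_, reason = "no_windows"))
  }
  if (counts$mono[[x]] == 0L) {
    return(list(oe = NA_real_, reason = "zero_mono_x"))
  }
  if (counts$mono[[y]] == 0L) {
    return(list(oe = NA_real_, reason = "zero_mono_y"))
  }
  obs <- counts$di[[xy]] / counts$W
  exp <- (counts$mono[[x]] / counts$L_eff) * (counts$mono[[y]] / counts$L_eff)
  list(oe = obs / exp, reason = NA_character_)
}

#' Per-gene observed/expected profile for one dinucleotide
#'
#' Computes the O/E ratio of `xy` for every gene (or for a subset of gene
#' ids), preserving input order. Genes whose ratio is undefined are kept in
#' the table with `oe = NA` and a reason code, so exclusions are auditable.
#'
#' @param seqs Named character vector of sequences (as from [read_fasta()]).
#' @param xy Dinucleotide (default `"CG"`).
#' @param min_length Minimum number of non-N bases for a defined ratio
#'   (default 100, matching EST-scale unigene data whose shortest members are
#'   around 100 bp).
#' @param subset Optional character vector of gene ids to restrict to; must
#'   all be present in `seqs`.
#' @return Data frame with columns `gene_id`, `dinucleotide`, `oe`, `reason`,
#'   `L_eff`, `W`, `mono_A`, `mono_C`, `mono_G`, `mono_T`, `di_count`.
#' @export
oe_profile <- function(seqs, xy = "CG", min_length = 100L, subset = NULL) {
  stopifnot(is.character(seqs))
  if (length(seqs) == 0L) stop("empty sequence set")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by gene id")
  }
  if (!is.null(subset)) {
    missing <- setdiff(subset, names(seqs))
    if (length(missing)) {
      stop("subset ids absent from sequence set: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    seqs <- seqs[subset]
  }
  counts <- lapply(names(seqs), function(id) count_dinucleotides(seqs[[id]], id = id))
  oe_profile_from_counts(counts, xy = xy, min_length = min_length)
}

# Shared assembly used by oe_profile() and all_dinucleotide_profiles() so the
# counting pass over the sequences happens once.
oe_profile_from_counts <- function(counts, xy, min_length) {
  xy <- toupper(xy)
  x <- substr(xy, 1L, 1L)
  y <- substr(xy, 2L, 2L)
  res <- lapply(counts, dinucleotide_oe, xy = xy, min_length = min_length)
  data.frame(
    gene_id = vapply(counts, `[[`, character(1), "gene_id"),
    dinucleotide = xy,
    oe = vapply(res, `[[`, numeric(1), "oe"),
    reason = vapply(res, `[[`, character(1), "reason"),
    L_eff = vapply(counts, `[[`, numeric(1), "L_eff"),
    W = vapply(counts, `[[`, numeric(1), "W"),
    mono_A = vapply(counts, function(cc) cc$mono[["A"]], numeric(1)),
    mono_C = vapply(counts, function(cc) cc$mono[["C"]], numeric(1)),
    mono_G = vapply(counts, function(cc) cc$mono[["G"]], numeric(1)),
    mono_T = vapply(counts, function(cc) cc$mono[["T"]], numeric(1)),
    di_count = vapply(counts, function(cc) cc$di[[xy]], numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' O/E profiles for all sixteen dinucleotides
#'
#' Runs [oe_profile()] for every ACGT dinucleotide over a single shared
#' counting pass. Used as the specificity control: under CpG-specific
#' deamination only the CG distribution shifts low while the other fifteen
#' stay unimodal.
#'
#' @inheritParams oe_profile
#' @return Named list of sixteen data frames, one per dinucleotide, each as
#'   returned by [oe_profile()].
#' @export
all_dinucleotide_profiles <- function(seqs, min_length = 100L) {
  stopifnot(is.character(seqs))
  if (length(seqs) == 0L) stop("empty sequence set")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by gene id")
  }
  counts <- lapply(names(seqs), function(id) count_dinucleotides(seqs[[id]], id = id))
  out <- lapply(DINUCS, function(xy)
    oe_profile_from_counts(counts, xy = xy, min_length = min_length))
  names(out) <- DINUCS
  out[order(names(out))]
}

#' Percent identity of two pre-aligned sequences
#'
#' Columns gapped in both sequences are dropped; the remaining columns are the
#' compared sites. A column counts as identical only when both residues are
#' present and equal, so a gap against a residue is compared but never
#' identical. The percentage is reported to one decimal place.
#'
#' @param aligned_a,aligned_b Aligned residue strings of equal length; `-`
#'   (or `.`) marks a gap. Alignment construction is out of scope here; the
#'   strings are consumed as given.
#' @return List with `identical_sites`, `compared_sites` and `percent`.
#' @examples
#' pairwise_identity("AC-G", "ACTG")  # 3/4 = 75.0
#' @export
pairwise_identity <- function(aligned_a, aligned_b) {
  stopifnot(is.character(aligned_a), is.character(aligned_b),
            length(aligned_a) == 1L, length(aligned_b) == 1L)
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences differ in length (",
         nchar(aligned_a), " vs ", nchar(aligned_b), ")")
  }
  a <- strsplit(toupper(aligned_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aligned_b), "", fixed = TRUE)[[1]]
  gap_a <- a %in% c("-", ".")
  gap_b <- b %in% c("-", ".")
  keep <- !(gap_a & gap_b)
  compared <- sum(keep)
  if (compared == 0L) stop("no compared columns (all doubly gapped)")
  identical_sites <- sum(keep & !gap_a & !gap_b & a == b)
  list(identical_sites = identical_sites,
       compared_sites = compared,
       percent = round(100 * identical_sites / compared, 1L))
}

#' Clone-census percentages
#'
#' Converts per-category clone counts into integer percentages of the total,
#' rounding halves away from zero (so 15/49 prints as 31, not 30).
#'
#' @param counts Named numeric vector of non-negative category counts with at
#'   least one clone in total.
#' @return Named integer vector of percentages in the input category order.
#' @examples
#' clone_census_percentages(c(repetitive = 15, est = 9, unknown = 25))
#' @export
clone_census_percentages <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) >= 1L, !is.null(names(counts)))
  if (any(counts < 0) || any(counts != as.integer(counts))) {
    stop("counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total < 1) stop("census total must be at least 1")
  out <- as.integer(round_half_away(100 * counts / total))
  names(out) <- names(counts)
  out
}
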