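# In-silico methylation-sensitive restriction digestion.
#
# Coordinate convention (documented here once, used throughout the module):
# base positions are 0-based; a cut position is an inter-base offset, i.e. the
# number of bases to its left. HpaII and MspI both recognize CCGG and cut
# C^CGG, one base into the site. HpaII is blocked when the internal cytosine
# of the site is 5-methylated on either strand; MspI cuts regardless of
# internal-C methylation. Molecules are linear.

#' Find occurrences of a restriction motif
#'
#' Exact forward-strand matches of `motif`, scanning every offset (CCGG is its
#' own reverse complement, so one strand suffices for HpaII/MspI). Any N in a
#' window prevents a match.
#'
#' @param seq Residue string (lowercase accepted).
#' @param motif Recognition sequence (default `"CCGG"`).
#' @return Integer vector of 0-based start positions (possibly empty).
#' @examples
#' find_sites("AACCGGTT")  # 2
#' @export
find_sites <- function(seq, motif = "CCGG") {
  stopifnot(is.character(seq), length(seq) == 1L)
  m <- gregexpr(paste0("(?=", toupper(motif), ")"), toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Construct a methylation mask
#'
#' A mask is the set of 0-based positions carrying 5-methylcytosine, kept
#' separately per strand: `forward` positions must be C on the forward
#' strand; `reverse` positions are given in forward-strand coordinates and
#' must be G there (i.e. C on the reverse strand). Validation against the
#' sequence happens in [digest()].
#'
#' @param forward,reverse Integer vectors of 0-based positions (default
#'   empty).
#' @return Object of class `methylation_mask`.
#' @export
methylation_mask <- function(forward = integer(0), reverse = integer(0)) {
  stopifnot(is.numeric(forward), is.numeric(reverse))
  if (length(forward) && any(forward < 0)) stop("negative forward position")
  if (length(reverse) && any(reverse < 0)) stop("negative reverse position")
  structure(list(forward = sort(unique(as.integer(forward))),
                 reverse = sort(unique(as.integer(reverse)))),
            class = "methylation_mask")
}

#' Symmetric CpG methylation mask
#'
#' Convenience constructor for the usual symmetric case: methylation of the C
#' of a CpG on both strands. For each 0-based position `p` with `C` at `p`
#' and `G` at `p + 1`, the forward strand is masked at `p` and the reverse
#' strand at `p + 1` (the G pairs with the reverse-strand C).
#'
#' @param seq Residue string.
#' @param cpg_positions 0-based positions of the C of each CpG to methylate.
#' @return A `methylation_mask`.
#' @export
symmetric_cpg_mask <- function(seq, cpg_positions) {
  stopifnot(is.character(seq), length(seq) == 1L, is.numeric(cpg_positions))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  p <- as.integer(cpg_positions)
  bad <- p < 0 | p + 2L > length(chars) | chars[p + 1L] != "C" | chars[p + 2L] != "G"
  if (any(bad)) {
    stop("position(s) not at a CpG: ", paste(p[bad], collapse = ", "))
  }
  methylation_mask(forward = p, reverse = p + 1L)
}

#' Digest a sequence with HpaII or MspI under a methylation mask
#'
#' Every CCGG site is cut at `start + 1` (C^CGG) unless blocked. HpaII is
#' blocked when the internal C is methylated on either strand: forward
#' position `start + 1`, or reverse-strand position `start + 2` (the G
#' pairing with the reverse-strand internal C). MspI ignores internal-C
#' methylation entirely (its outer-C sensitivities are not modeled).
#'
#' @param seq Residue string (linear molecule).
#' @param enzyme `"HpaII"` or `"MspI"`.
#' @param mask A [methylation_mask()]; every forward position must index a C
#'   and every reverse position a G in `seq`.
#' @return Object of class `digest_result`: `enzyme`, `cut_positions`
#'   (ascending 0-based inter-base offsets), `fragment_lengths` (summing to
#'   the sequence length) and `molecule_length`.
#' @examples
#' digest("AACCGGTTCCGGAA", "HpaII", methylation_mask())
#' @export
digest <- function(seq, enzyme = c("HpaII", "MspI"), mask = methylation_mask()) {
  stopifnot(is.character(seq), length(seq) == 1L,
            inherits(mask, "methylation_mask"))
  enzyme <- match.arg(enzyme)
  s <- toupper(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (length(mask$forward)) {
    if (any(mask$forward + 1L > L) || any(chars[mask$forward + 1L] != "C")) {
      stop("forward mask position does not index a C")
    }
  }
  if (length(mask$reverse)) {
    if (any(mask$reverse + 1L > L) || any(chars[mask$reverse + 1L] != "G")) {
      stop("reverse mask position does not index a G on the forward strand")
    }
  }
  sites <- find_sites(s, "CCGG")
  if (enzyme == "HpaII" && length(sites)) {
    blocked <- (sites + 1L) %in% mask$forward | (sites + 2L) %in% mask$reverse
    sites <- sites[!blocked]
  }
  cuts <- sites + 1L
  fragments <- diff(c(0L, cuts, L))
  structure(list(enzyme = enzyme, cut_positions = cuts,
                 fragment_lengths = fragments, molecule_length = L),
            class = "digest_result")
}

#' Summarize a digest's fragment-length distribution
#'
#' The high-molecular-weight (HMW) mass fraction is the proportion of total
#' sequence mass carried by fragments of at least `hmw_threshold` bases — the
#' in-silico counterpart of the prominent slow-migrating band a
#' methylation-blocked digest leaves on a gel.
#'
#' @param result A `digest_result`.
#' @param hmw_threshold Fragment length (bases) from which a fragment counts
#'   as high molecular weight.
#' @return List: `n_fragments`, `mean_length`, `median_length`, `max_length`,
#'   `hmw_fraction`.
#' @export
fragment_summary <- function(result, hmw_threshold) {
  stopifnot(inherits(result, "digest_result"), is_count(hmw_threshold, min = 1L))
  f <- result$fragment_lengths
  if (!length(f)) stop("empty digest result")
  list(n_fragments = length(f),
       mean_length = mean(f),
       median_length = median(f),
       max_length = max(f),
       hmw_fraction = sum(f[f >= hmw_threshold]) / sum(f))
}

#' Methylation signal from paired HpaII/MspI digests
#'
#' The assay readout as a number: the high-molecular-weight mass fraction of
#' the methylation-sensitive HpaII digest minus that of the insensitive MspI
#' digest of the same molecule. Zero for an unmethylated molecule (identical
#' digests); positive, and increasing with the number of methylation-blocked
#' sites, otherwise.
#'
#' @param hpaII,mspI `digest_result`s of the same molecule with the
#'   respective enzymes.
#' @param hmw_threshold Passed to [fragment_summary()].
#' @return Numeric signal in `[-1, 1]` (non-negative under this blocking
#'   model).
#' @export
compare_digests <- function(hpaII, mspI, hmw_threshold) {
  stopifnot(inherits(hpaII, "digest_result"), inherits(mspI, "digest_result"))
  if (hpaII$molecule_length != mspI$molecule_length) {
    stop("digests are not of the same molecule (lengths differ)")
  }
  fragment_summary(hpaII, hmw_threshold)$hmw_fraction -
    fragment_summary(mspI, hmw_threshold)$hmw_fraction
}
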