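# Ground-truth generators: ancestral sequences, CpG-deamination evolution,
# two-population unigene sets, planted-enrichment annotations, and
# repeat-bearing genomes with methylation masks. Every generator is a pure
# function of its parameters and seed.

#' Generate an ancestral i.i.d. sequence
#'
#' Bases are drawn independently with `P(C) = P(G) = gc_content / 2` and
#' `P(A) = P(T) = (1 - gc_content) / 2`. The expected CpG O/E of such a
#' sequence is 1: observed and expected dinucleotide frequencies coincide for
#' i.i.d. letters, which makes these sequences the calibration baseline for
#' the O/E estimator.
#'
#' @param length Sequence length (>= 1).
#' @param gc_content G+C proportion in (0, 1); default 0.42, a typical insect
#'   transcriptome composition.
#' @param seed Integer seed.
#' @return A residue string.
#' @export
generate_ancestral_sequence <- function(length, gc_content = 0.42, seed = 1L) {
  if (!is_count(length, min = 1L)) stop("length must be a positive integer")
  if (!is.numeric(gc_content) || gc_content <= 0 || gc_content >= 1) {
    stop("gc_content must lie strictly between 0 and 1")
  }
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  with_seed(seed, paste(sample(BASES, length, replace = TRUE, prob = p),
                        collapse = ""))
}

#' Evolve a sequence under CpG-deamination hypermutability
#'
#' Discrete-round mutation model of the process that depletes CpG in
#' germline-methylated DNA: 5-methylcytosine deaminates to thymine, so
#' methylated CpG sites lose their C (and, via the reverse strand, their G)
#' faster than background. Per round the CpG context is re-evaluated, then
#' each CpG-context C deaminates to T — and each CpG-context G, as the
#' reverse-strand partner C, to A — with probability
#' `min(1, base_rate * cpg_multiplier)`, while every other site mutates to a
#' uniformly chosen different base with probability `base_rate`. At
#' `cpg_multiplier = 1` every site therefore carries the same total mutation
#' probability and CpG is not preferentially depleted; multipliers above 1
#' emulate increasing germline methylation. Newly created CpGs become
#' hypermutable in later rounds. N positions are never mutated. No indels.
#'
#' @param seq Residue string over `{A, C, G, T, N}`.
#' @param base_rate Per-site, per-round substitution probability in
#'   `[0, 0.5]`.
#' @param cpg_multiplier Deamination rate multiplier at CpG sites (>= 1).
#' @param rounds Number of mutation rounds (>= 0).
#' @param seed Integer seed.
#' @return The evolved residue string (same length).
#' @export
evolve_sequence <- function(seq, base_rate = 0.01, cpg_multiplier = 1,
                            rounds = 1L, seed = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!is.numeric(base_rate) || base_rate < 0 || base_rate > 0.5) {
    stop("base_rate must lie in [0, 0.5]")
  }
  if (!is.numeric(cpg_multiplier) || cpg_multiplier < 1) {
    stop("cpg_multiplier must be >= 1")
  }
  if (!is_count(rounds)) stop("rounds must be a non-negative integer")
  codes <- seq_to_codes(seq)
  codes[is.na(codes)] <- 0L
  p_deam <- min(1, base_rate * cpg_multiplier)
  out <- with_seed(seed,
                   evolve_codes(codes, base_rate, p_deam, as.integer(rounds)))
  out[out == 0L] <- NA_integer_
  codes_to_seq(out)
}

#' Generate a two-population unigene set with known methylation truth
#'
#' Emulates an EST-derived unigene collection containing two populations of
#' genes: a historically germline-methylated fraction whose CpG content has
#' been eroded by deamination, and an unmethylated fraction near the
#' compositional expectation. Lengths are drawn from a log-normal law
#' (median ~450 bp, mean ~600 bp) clipped to `length_range`, matching
#' EST-scale unigene data. Each gene is an ancestral i.i.d. sequence evolved
#' under its class's CpG multiplier. The default multipliers (4 for
#' methylated, 1.3 for unmethylated, 40 rounds at base rate 0.01) were
#' calibrated once so the two CpG O/E modes land near 0.4 and 0.9; they are
#' simulation dials, not biological rate estimates.
#'
#' @param n_genes Number of genes (>= 1).
#' @param prop_methylated Proportion of genes in the methylated class, in
#'   `[0, 1]`.
#' @param length_meanlog,length_sdlog Log-normal length parameters.
#' @param length_range Two-element inclusive clip range for lengths.
#' @param gc_content Ancestral G+C proportion.
#' @param base_rate Per-site, per-round substitution probability.
#' @param rounds Mutation rounds applied to every gene.
#' @param cpg_multiplier_methylated,cpg_multiplier_unmethylated Deamination
#'   multipliers for the two classes (both >= 1).
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector, ids `gene0001`,
#'   ...) and `truth` (data frame `gene_id`, `class` in
#'   `{"methylated", "unmethylated"}`, `length`).
#' @export
generate_unigene_set <- function(n_genes = 2000L, prop_methylated = 0.5,
                                 length_meanlog = log(450), length_sdlog = 0.75,
                                 length_range = c(101L, 4278L),
                                 gc_content = 0.42, base_rate = 0.01,
                                 rounds = 40L,
                                 cpg_multiplier_methylated = 4,
                                 cpg_multiplier_unmethylated = 1.3,
                                 seed = 1L) {
  if (!is_count(n_genes, min = 1L)) stop("n_genes must be a positive integer")
  if (!is.numeric(prop_methylated) || prop_methylated < 0 || prop_methylated > 1) {
    stop("prop_methylated must lie in [0, 1]")
  }
  stopifnot(length(length_range) == 2L, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  plan <- with_seed(seed, {
    lengths <- pmin(pmax(round(rlnorm(n_genes, length_meanlog, length_sdlog)),
                         length_range[1]), length_range[2])
    methylated <- runif(n_genes) < prop_methylated
    seeds <- matrix(sample.int(.Machine$integer.max, 2L * n_genes), ncol = 2L)
    list(lengths = as.integer(lengths), methylated = methylated, seeds = seeds)
  })
  ids <- sprintf("gene%04d", seq_len(n_genes))
  seqs <- character(n_genes)
  for (i in seq_len(n_genes)) {
    anc <- generate_ancestral_sequence(plan$lengths[i], gc_content,
                                       seed = plan$seeds[i, 1L])
    mult <- if (plan$methylated[i]) cpg_multiplier_methylated
            else cpg_multiplier_unmethylated
    seqs[i] <- evolve_sequence(anc, base_rate = base_rate,
                               cpg_multiplier = mult, rounds = rounds,
                               seed = plan$seeds[i, 2L])
  }
  names(seqs) <- ids
  list(
    sequences = seqs,
    truth = data.frame(
      gene_id = ids,
      class = ifelse(plan$methylated, "methylated", "unmethylated"),
      length = plan$lengths,
      stringsAsFactors = FALSE
    )
  )
}

#' Plant a known enrichment signal in an annotation table
#'
#' Assigns each background term to each gene independently with probability
#' `baseline`; the `enriched_term` is instead assigned to methylated-class
#' genes with probability `min(1, enrichment_factor * baseline)` (and
#' `baseline` to unmethylated genes), planting a ground-truth
#' over-representation in the methylated class. Genes that end up with no
#' terms are absent from the table, as in real annotation data.
#'
#' @param truth Truth data frame from [generate_unigene_set()].
#' @param terms Character vector of term identifiers (background terms).
#' @param enriched_term The term to enrich; added to `terms` if absent.
#' @param enrichment_factor Multiplier >= 1 on the baseline probability.
#' @param baseline Per-gene, per-term annotation probability (default 0.05).
#' @param seed Integer seed.
#' @return Named list of per-gene term sets (the annotation-table format).
#' @export
plant_annotations <- function(truth, terms, enriched_term,
                              enrichment_factor = 1, baseline = 0.05,
                              seed = 1L) {
  stopifnot(is.data.frame(truth), all(c("gene_id", "class") %in% names(truth)),
            is.character(terms), length(terms) >= 1L)
  if (!is.numeric(enrichment_factor) || enrichment_factor < 1) {
    stop("enrichment_factor must be >= 1")
  }
  if (!is.numeric(baseline) || baseline <= 0 || baseline > 1) {
    stop("baseline must lie in (0, 1]")
  }
  terms <- union(terms, enriched_term)
  p_enriched <- min(1, enrichment_factor * baseline)
  with_seed(seed, {
    ann <- lapply(seq_len(nrow(truth)), function(i) {
      p <- ifelse(terms == enriched_term & truth$class[i] == "methylated",
                  p_enriched, baseline)
      sort(terms[runif(length(terms)) < p])
    })
    names(ann) <- truth$gene_id
    ann[lengths(ann) > 0L]
  })
}

#' Generate a genome of methylation-masked repeats and random spacers
#'
#' Builds a linear genome alternating random spacer segments with exact
#' copies of one randomly generated repeat unit carrying a CCGG site at its
#' center. When `methylate_repeats` is `TRUE`, the internal C of every CCGG
#' site falling inside a repeat copy is masked on both strands — emulating a
#' genome whose repetitive fraction is methylated — so an HpaII digest leaves
#' repeat-spanning high-molecular-weight fragments that the MspI digest cuts.
#'
#' @param n_repeats Number of repeat copies (>= 1).
#' @param repeat_length Length of the repeat unit (>= 8).
#' @param spacer_length Length of each spacer segment (>= 0); there are
#'   `n_repeats + 1` spacers.
#' @param methylate_repeats Mask CCGG sites inside repeats?
#' @param gc_content Base composition of spacers and repeat unit.
#' @param seed Integer seed.
#' @return List with `sequence` (residue string), `mask`
#'   (a [methylation_mask()]), and `repeat_intervals` (data frame of 0-based
#'   half-open `start`, `end` coordinates of the repeat copies).
#' @export
generate_genome_with_repeats <- function(n_repeats = 20L, repeat_length = 60L,
                                         spacer_length = 300L,
                                         methylate_repeats = TRUE,
                                         gc_content = 0.42, seed = 1L) {
  if (!is_count(n_repeats, min = 1L)) stop("n_repeats must be >= 1")
  if (!is_count(repeat_length, min = 8L)) stop("repeat_length must be >= 8")
  if (!is_count(spacer_length)) stop("spacer_length must be >= 0")
  parts <- with_seed(seed, {
    unit <- strsplit(generate_ancestral_sequence(
      repeat_length, gc_content, seed = sample.int(.Machine$integer.max, 1L)
    ), "", fixed = TRUE)[[1]]
    at <- floor(repeat_length / 2L) - 1L  # center the CCGG (0-based start)
    unit[(at + 1L):(at + 4L)] <- c("C", "C", "G", "G")
    unit <- paste(unit, collapse = "")
    spacers <- vapply(seq_len(n_repeats + 1L), function(i) {
      if (spacer_length == 0L) "" else generate_ancestral_sequence(
        spacer_length, gc_content, seed = sample.int(.Machine$integer.max, 1L))
    }, character(1))
    list(unit = unit, spacers = spacers)
  })
  pieces <- character(2L * n_repeats + 1L)
  pieces[seq(1L, length(pieces), by = 2L)] <- parts$spacers
  pieces[seq(2L, length(pieces), by = 2L)] <- parts$unit
  genome <- paste(pieces, collapse = "")
  starts <- spacer_length + (seq_len(n_repeats) - 1L) * (spacer_length + repeat_length)
  intervals <- data.frame(start = starts, end = starts + repeat_length)

  mask <- methylation_mask()
  if (methylate_repeats) {
    sites <- find_sites(genome, "CCGG")
    in_repeat <- vapply(sites, function(s)
      any(s >= intervals$start & s + 4L <= intervals$end), logical(1))
    masked <- sites[in_repeat]
    mask <- methylation_mask(forward = masked + 1L, reverse = masked + 2L)
  }
  list(sequence = genome, mask = mask, repeat_intervals = intervals)
}
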