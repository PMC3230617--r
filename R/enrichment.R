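check_margins <- function(list_hits, list_size, pop_hits, pop_size) {
  for (v in list(list_hits, list_size, pop_hits, pop_size)) {
    if (!is_count(v)) stop("2x2 margins must be non-negative integers")
  }
  if (list_size > pop_size) stop("list_size exceeds pop_size")
  if (pop_hits > pop_size) stop("pop_hits exceeds pop_size")
  if (list_hits > min(list_size, pop_hits)) {
    stop("list_hits exceeds min(list_size, pop_hits)")
  }
  if (list_hits < max(0, list_size - (pop_size - pop_hits))) {
    stop("list_hits below the minimum feasible overlap for these margins")
  }
  invisible(TRUE)
}

#' One-sided Fisher (hypergeometric upper tail) over-representation p-value
#'
#' Probability of drawing at least `list_hits` annotated genes when
#' `list_size` genes are sampled without replacement from a background of
#' `pop_size` genes of which `pop_hits` carry the term:
#' `P(X >= list_hits)` for `X ~ Hypergeometric(pop_size, pop_hits,
#' list_size)`.
#'
#' @param list_hits Genes in the class annotated with the term.
#' @param list_size Genes in the class.
#' @param pop_hits Background genes annotated with the term.
#' @param pop_size Background genes.
#' @return p-value in (0, 1].
#' @export
fisher_exact_ge <- function(list_hits, list_size, pop_hits, pop_size) {
  check_margins(list_hits, list_size, pop_hits, pop_size)
  phyper(list_hits - 1, pop_hits, pop_size - pop_hits, list_size,
         lower.tail = FALSE)
}

#' EASE score (jackknifed one-sided Fisher p-value)
#'
#' The EASE score removes one gene from the overlap cell before computing the
#' hypergeometric upper tail: `fisher_exact_ge(max(list_hits - 1, 0), ...)`
#' with the other margins unchanged. The jackknife penalizes categories
#' supported by very few genes — a single-gene category can never score below
#' 1 — making the score deliberately conservative relative to the plain
#' Fisher tail.
#'
#' @inheritParams fisher_exact_ge
#' @return p-value in (0, 1]; always `>=` the corresponding
#'   [fisher_exact_ge()] value.
#' @export
ease_score <- function(list_hits, list_size, pop_hits, pop_size) {
  check_margins(list_hits, list_size, pop_hits, pop_size)
  phyper(max(list_hits - 1, 0) - 1, pop_hits, pop_size - pop_hits, list_size,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: with p-values sorted ascending,
#' `q_(i) = min_{j >= i}(p_(j) * m / j)` capped at 1, returned in the input
#' order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues), length(pvalues) >= 1L)
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' GO term over-representation of a gene class (EASE style)
#'
#' Tests every GO term annotated to at least `min_term_size` background genes
#' for over-representation in `class_genes` relative to the background of all
#' annotated genes. Each gene counts once per term regardless of annotation
#' multiplicity; genes without annotations never enter any margin. The EASE
#' score is the primary statistic; the unmodified Fisher tail is reported
#' alongside, and Benjamini-Hochberg adjustment is applied to the EASE scores
#' across all tested terms. No GO-hierarchy propagation is performed — terms
#' are tested exactly as annotated.
#'
#' @param class_genes Character vector of gene ids in the class (e.g. the
#'   low-CpG-O/E population).
#' @param background_genes Character vector of candidate background gene ids;
#'   genes without annotations are dropped, and `class_genes` must be a
#'   subset of the annotated background.
#' @param annotations Named list of per-gene term sets, as from
#'   [read_annotations()].
#' @param min_term_size Minimum background count for a term to be tested
#'   (default 2: the jackknife makes singleton terms uninformative).
#' @param top_n Optional presentation trim: keep only the `top_n` smallest
#'   EASE scores after adjustment (adjustment always uses all tested terms).
#' @return Data frame sorted by ascending `ease_p` (ties broken by term
#'   string): columns `term`, `list_hits`, `list_size`, `pop_hits`,
#'   `pop_size`, `ease_p`, `fisher_p`, `bh_q`.
#' @export
enrich <- function(class_genes, background_genes, annotations,
                   min_term_size = 2L, top_n = NULL) {
  stopifnot(is.character(class_genes), is.character(background_genes),
            is.list(annotations), !is.null(names(annotations)))
  background <- intersect(unique(background_genes), names(annotations))
  if (!length(background)) stop("no annotated genes in the background")
  class <- unique(class_genes)
  if (!all(class %in% background_genes)) {
    stop("class_genes must be a subset of background_genes")
  }
  class <- intersect(class, background)
  if (!length(class)) stop("no annotated genes in the class")

  term_genes <- split(
    rep(background, lengths(annotations[background])),
    unlist(annotations[background], use.names = FALSE)
  )
  pop_hits <- lengths(term_genes)
  keep <- pop_hits >= min_term_size
  if (!any(keep)) stop("no terms meet min_term_size = ", min_term_size)
  term_genes <- term_genes[keep]

  pop_size <- length(background)
  list_size <- length(class)
  list_hits <- vapply(term_genes, function(g) length(intersect(g, class)),
                      integer(1))
  pop_hits <- lengths(term_genes)

  ease <- mapply(ease_score, list_hits, MoreArgs = list(
    list_size = list_size, pop_size = pop_size), pop_hits = pop_hits)
  fisher <- mapply(fisher_exact_ge, list_hits, MoreArgs = list(
    list_size = list_size, pop_size = pop_size), pop_hits = pop_hits)
  q <- bh_adjust(ease)

  out <- data.frame(
    term = names(term_genes),
    list_hits = unname(list_hits),
    list_size = list_size,
    pop_hits = unname(pop_hits),
    pop_size = pop_size,
    ease_p = unname(ease),
    fisher_p = unname(fisher),
    bh_q = unname(q),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$ease_p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}
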