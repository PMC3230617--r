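#' Read a FASTA file of nucleotide sequences
#'
#' Reads a (possibly line-wrapped) FASTA file and returns a named character
#' vector of uppercase residues over the alphabet `{A, C, G, T, N}`. IUPAC
#' ambiguity codes other than N (R, Y, S, W, K, M, B, D, H, V) and gap
#' characters are converted to `N`; one warning reports how many residues were
#' converted. Sequence identifiers are the first whitespace-delimited token of
#' each header line and must be unique.
#'
#' @param path Path to an existing FASTA file.
#' @return Named character vector: names are sequence ids, values are residue
#'   strings over `{A, C, G, T, N}`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA record with empty identifier in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- toupper(as.character(set))
  if (any(nchar(res) == 0L)) {
    stop("zero-length sequence for id(s): ",
         paste(ids[nchar(res) == 0L], collapse = ", "))
  }
  n_before <- sum(nchar(res))
  n_acgtn <- sum(nchar(gsub("[^ACGTN]", "", res)))
  if (n_acgtn < n_before) {
    res <- gsub("[^ACGTN]", "N", res)
    warning(sprintf("%d ambiguous residue(s) converted to N", n_before - n_acgtn))
  }
  names(res) <- ids
  res
}

#' Write sequences to a FASTA file
#'
#' Companion writer to [read_fasta()]; `read_fasta(write_fasta(x, f))` is the
#' identity on ids and residues.
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a gene-to-GO annotation table
#'
#' Parses a two-column TSV (`gene_id<TAB>go_term`, one pair per line, no
#' header) into a named list mapping each gene id to its set of unique term
#' identifiers. Repeated pairs are de-duplicated; malformed lines (fewer than
#' two non-empty fields) are skipped with a warning giving their count. Terms
#' are opaque strings; no ontology parsing is performed.
#'
#' @param path Path to the TSV file.
#' @return Named list of character vectors (gene id -> unique GO terms).
#' @export
read_annotations <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("annotation file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) >= 2L && nzchar(p[1]) && nzchar(p[2]),
               logical(1))
  if (!any(ok)) {
    stop("no valid gene_id<TAB>go_term lines in ", path)
  }
  if (any(!ok)) {
    warning(sprintf("%d malformed annotation line(s) skipped", sum(!ok)))
  }
  gene <- vapply(parts[ok], `[`, character(1), 1L)
  term <- vapply(parts[ok], `[`, character(1), 2L)
  ann <- lapply(split(term, gene), function(x) sort(unique(x)))
  ann[order(names(ann))]
}

#' Write an annotation table
#'
#' Inverse of [read_annotations()]: writes one `gene_id<TAB>go_term` line per
#' pair.
#'
#' @param annotations Named list of character vectors as returned by
#'   [read_annotations()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  gene <- rep(names(annotations), lengths(annotations))
  term <- unlist(annotations, use.names = FALSE)
  writeLines(paste(gene, term, sep = "\t"), path)
  invisible(path)
}

#' Write a result table as headered TSV
#'
#' All result tables in this package are tab-separated UTF-8 text with a
#' header row and Unix newlines. Floating-point columns are serialized with
#' `%.17g` so that [read_table()] round-trips them losslessly.
#'
#' @param rows A data frame (possibly zero-row).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a headered TSV result table
#'
#' @param path Path to a file written by [write_table()].
#' @return A data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a gene-id subset list
#'
#' One gene id per line; blank lines ignored; order preserved; duplicates
#' removed keeping first occurrence. Used to restrict an O/E profile to, e.g.,
#' a differentially-expressed gene list.
#'
#' @param path Path to the list file.
#' @return Character vector of gene ids.
#' @export
read_gene_subset <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  unique(ids)
}
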