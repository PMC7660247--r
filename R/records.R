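#' @keywords internal
"_PACKAGE"

# Allowed residue alphabets. Nucleotide: IUPAC codes (incl. U and ambiguity
# codes); protein: IUPAC amino acids plus B/J/Z/U/O ambiguity/rare codes,
# X and the stop symbol '*'.
.NUC_RE <- "^[ACGTURYSWKMBDHVN]+$"
.PROT_RE <- "^[ACDEFGHIKLMNPQRSTVWYBJZUOX*]+$"

#' Create a sequence record
#'
#' The shared in-memory unit of the package: an identifier (first
#' whitespace-delimited token of a FASTA header), an optional free-text
#' description, an uppercase residue string and its alphabet.
#'
#' @param id Character scalar, non-empty, no whitespace.
#' @param seq Character scalar of residues; uppercased on construction.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param desc Free-text description (remainder of the header), may be `""`.
#' @return An object of class `seq_record` (a named list).
#' @export
seq_record <- function(id, seq, alphabet = c("nucleotide", "protein"),
                       desc = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    stop("record id must be a non-empty token without whitespace")
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("record '", id, "': residues must be a non-empty string")
  seq <- toupper(seq)
  re <- if (alphabet == "nucleotide") .NUC_RE else .PROT_RE
  if (!grepl(re, seq))
    stop("record '", id, "': residues outside the ", alphabet, " alphabet")
  structure(list(id = id, desc = desc, seq = seq, alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s [%s, %d residues]>\n", x$id, x$alphabet,
              nchar(x$seq)))
  invisible(x)
}

#' Create a genome
#'
#' A genome is a strain identifier plus an ordered set of nucleotide contigs.
#'
#' @param strain_id Strain token.
#' @param contigs List of nucleotide `seq_record`s (or a named character
#'   vector, converted on the fly).
#' @return An object of class `genome`.
#' @export
genome <- function(strain_id, contigs) {
  if (is.character(contigs)) {
    ids <- names(contigs)
    if (is.null(ids)) ids <- paste0("contig", seq_along(contigs))
    contigs <- Map(function(i, s) seq_record(i, s, "nucleotide"), ids, contigs)
    names(contigs) <- NULL
  }
  if (length(contigs) < 1L) stop("genome '", strain_id, "' has no contigs")
  ok <- vapply(contigs, function(r) inherits(r, "seq_record") &&
                 r$alphabet == "nucleotide", logical(1))
  if (!all(ok)) stop("genome contigs must be nucleotide seq_records")
  ids <- vapply(contigs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate contig id: ",
                               ids[duplicated(ids)][1])
  structure(list(strain_id = strain_id, contigs = contigs), class = "genome")
}

#' Total genome length (bp)
#' @param g A `genome`.
#' @return Integer total contig length.
#' @export
genome_length <- function(g) {
  sum(vapply(g$contigs, function(r) nchar(r$seq), numeric(1)))
}

#' Create a proteome
#'
#' A strain's protein complement, optionally with the matching CDS
#' nucleotide sequences keyed by protein id. When CDS are present each CDS
#' must be 3L or 3L+3 nucleotides long for a protein of length L (the +3
#' accommodating a terminal stop codon).
#'
#' @param strain_id Strain token.
#' @param proteins List of protein `seq_record`s (or a named character
#'   vector).
#' @param cds Optional named list/character vector of CDS nucleotide
#'   sequences, names matching protein ids.
#' @return An object of class `proteome`.
#' @export
proteome <- function(strain_id, proteins, cds = NULL) {
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) stop("protein character vector must be named")
    proteins <- Map(function(i, s) seq_record(i, s, "protein"), ids, proteins)
    names(proteins) <- NULL
  }
  if (length(proteins) < 1L) stop("proteome '", strain_id, "' is empty")
  ids <- vapply(proteins, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate protein id: ",
                               ids[duplicated(ids)][1])
  names(proteins) <- ids
  if (!is.null(cds)) {
    if (is.character(cds)) {
      cn <- names(cds)
      cds <- Map(function(i, s) seq_record(i, s, "nucleotide"), cn, cds)
      names(cds) <- cn
    }
    bad <- setdiff(names(cds), ids)
    if (length(bad)) stop("cds key without matching protein: ", bad[1])
    for (pid in names(cds)) {
      lp <- nchar(proteins[[pid]]$seq)
      lc <- nchar(cds[[pid]]$seq)
      if (!(lc == 3L * lp || lc == 3L * lp + 3L))
        stop("cds '", pid, "' length ", lc,
             " inconsistent with protein length ", lp)
    }
  }
  structure(list(strain_id = strain_id, proteins = proteins, cds = cds),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome %s: %d proteins%s>\n", x$strain_id,
              length(x$proteins),
              if (is.null(x$cds)) "" else sprintf(", %d cds", length(x$cds))))
  invisible(x)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome %s: %d contigs, %d bp>\n", x$strain_id,
              length(x$contigs), genome_length(x)))
  invisible(x)
}

# Internal: records -> Biostrings set
.as_xstringset <- function(records, alphabet) {
  seqs <- vapply(records, `[[`, character(1), "seq")
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  if (alphabet == "protein") Biostrings::AAStringSet(seqs)
  else Biostrings::DNAStringSet(seqs)
}
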