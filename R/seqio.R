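#' Read a FASTA file
#'
#' Parses a FASTA file into a list of [seq_record()]s. The record id is the
#' first whitespace-delimited token of the header; the remainder becomes the
#' description. Residues are uppercased; input order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return List of `seq_record`s (empty list for an empty file).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(list())
  first <- nonblank[1]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA: sequence before first header at line ", first,
         " of ", path)
  set <- if (alphabet == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("empty header in ", path)
  if (anyDuplicated(ids))
    stop("duplicate record id '", ids[duplicated(ids)][1], "' in ", path)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(toupper(as.character(set)))
  out <- vector("list", length(ids))
  for (i in seq_along(ids))
    out[[i]] <- seq_record(ids[i], seqs[i], alphabet, descs[i])
  out
}

#' Write records to FASTA
#'
#' @param records Non-empty list of `seq_record`s.
#' @param path Output path.
#' @param wrap Line width for sequence lines; `0` writes each sequence on a
#'   single line. Default 60.
#' @return `path`, invisibly. Round-trips with [read_fasta()].
#' @export
write_fasta <- function(records, path, wrap = 60) {
  if (!length(records)) stop("refusing to write an empty FASTA file")
  ids <- vapply(records, `[[`, character(1), "id")
  descs <- vapply(records, `[[`, character(1), "desc")
  seqs <- vapply(records, `[[`, character(1), "seq")
  headers <- ifelse(nzchar(descs), paste(ids, descs), ids)
  width <- if (wrap <= 0) max(nchar(seqs)) else as.integer(wrap)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Genomic G+C content (mol%)
#'
#' Percentage of G+C among the unambiguous bases (A, C, G, T) of all
#' contigs. Ambiguity codes (including N runs from assembly gaps) are
#' excluded from both numerator and denominator by default, which makes the
#' statistic insensitive to scaffolding gaps; set
#' `denominator = "all"` to divide by the full sequence length instead.
#'
#' @param g A [genome()] (or a single nucleotide `seq_record`).
#' @param denominator `"unambiguous"` (default) or `"all"`.
#' @return G+C mol percentage (full precision; round at report time).
#' @export
gc_content <- function(g, denominator = c("unambiguous", "all")) {
  denominator <- match.arg(denominator)
  if (inherits(g, "seq_record")) g <- genome("g", list(g))
  set <- .as_xstringset(g$contigs, "nucleotide")
  freq <- colSums(Biostrings::alphabetFrequency(set))
  gc <- freq[["G"]] + freq[["C"]]
  denom <- if (denominator == "unambiguous")
    freq[["A"]] + freq[["C"]] + freq[["G"]] + freq[["T"]]
  else sum(freq)
  if (denom == 0) stop("genome '", g$strain_id, "' has no unambiguous bases")
  100 * gc / denom
}

#' Read a 12-column blast-like tabular hit file
#'
#' Columns: query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, query start, query end, subject start, subject
#' end, e-value, bit/raw score. Coordinates are kept 1-based inclusive as
#' in the file.
#'
#' @param path Path to a tab-separated file.
#' @return `data.frame` with one row per hit (zero rows for an empty file),
#'   columns `query_id, subject_id, pct_identity, aln_length, mismatches,
#'   gap_opens, q_start, q_end, s_start, s_end, evalue, score`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "score")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols))
    df[3:12] <- lapply(df[3:12], as.numeric)
    return(df)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("hit table row ", which(nf != 12L)[1], " has ", nf[nf != 12L][1],
         " columns, expected 12")
  m <- do.call(rbind, parts)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   stringsAsFactors = FALSE)
  num <- apply(m[, 3:12, drop = FALSE], 2, as.numeric)
  if (length(lines) == 1L) num <- matrix(num, nrow = 1)
  colnames(num) <- cols[3:12]
  df <- cbind(df, as.data.frame(num))
  if (any(is.na(df$pct_identity)) ||
      any(df$pct_identity < 0 | df$pct_identity > 100))
    stop("pct_identity outside [0,100] in ", path)
  if (any(df$q_start > df$q_end))
    stop("q_start > q_end in ", path, " (row ",
         which(df$q_start > df$q_end)[1], ")")
  df
}

#' Read a genome FASTA as a `genome`
#' @param path Nucleotide FASTA path.
#' @param strain_id Strain token; defaults to the file base name.
#' @return A [genome()].
#' @export
read_genome <- function(path, strain_id = NULL) {
  if (is.null(strain_id))
    strain_id <- sub("\\.[^.]*$", "", basename(path))
  genome(strain_id, read_fasta(path, "nucleotide"))
}

#' Read a proteome FASTA (optionally with CDS FASTA) as a `proteome`
#' @param path Protein FASTA path.
#' @param cds_path Optional CDS nucleotide FASTA path with matching ids.
#' @param strain_id Strain token; defaults to the file base name.
#' @return A [proteome()].
#' @export
read_proteome <- function(path, cds_path = NULL, strain_id = NULL) {
  if (is.null(strain_id))
    strain_id <- sub("\\.[^.]*$", "", basename(path))
  prots <- read_fasta(path, "protein")
  cds <- NULL
  if (!is.null(cds_path)) {
    recs <- read_fasta(cds_path, "nucleotide")
    cds <- stats::setNames(recs, vapply(recs, `[[`, character(1), "id"))
  }
  proteome(strain_id, prots, cds)
}
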