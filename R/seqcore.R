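#' @importFrom stats median p.adjust phyper runif as.dist setNames
#' @importFrom utils write.table read.table combn
NULL

# Standard genetic code, keyed by codon (DNA alphabet). All taxa in this
# package are mammals, so no alternative codes are offered.
GENETIC_CODE_STD <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

SENSE_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
STOP_CODONS  <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]
NUC <- c("A", "C", "G", "T")

#' Split a coding sequence into codons
#'
#' @param seq A single DNA string whose length is a multiple of 3.
#' @return Character vector of codons.
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("frame error: sequence length ", n, " is not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a codon vector or CDS string
#'
#' Codons containing the ambiguity code N (or any non-ACGT letter)
#' translate to `X`; stop codons render as `*`.
#'
#' @param cds A DNA string with length a multiple of 3, or a character
#'   vector of codons.
#' @return Single-letter amino-acid string.
#' @examples
#' translate_cds("ATGAAG")  # "MK"
#' translate_cds("TGG")     # "W"
#' @export
translate_cds <- function(cds) {
  codons <- if (length(cds) == 1L && nchar(cds[1L]) != 3L)
    split_codons(cds) else as.character(cds)
  if (length(codons) == 0L) return("")
  aa <- GENETIC_CODE_STD[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Nucleotide span of a codon
#'
#' Maps a 1-based codon index to its 1-based inclusive nucleotide
#' positions within the CDS, the coordinate bridge used by the
#' mutation-screen site reports.
#'
#' @param codon_index 1-based codon index (vectorised).
#' @return A two-column matrix with columns `start` and `end`.
#' @examples
#' codon_to_nt_span(79)  # 235 237
#' @export
codon_to_nt_span <- function(codon_index) {
  if (any(codon_index < 1L))
    stop("codon_index must be >= 1")
  cbind(start = 3L * codon_index - 2L, end = 3L * codon_index)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read. Wrapped and unwrapped dialects are
#' both accepted. Duplicate record ids are an error.
#'
#' @param path Path to a FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  set <- if (type == "DNA") Biostrings::readBStringSet(path)
         else Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Enumerate ATG-initiated ORFs in one reading frame of one strand.
# An ORF runs from ATG to the codon before the next stop; if no stop
# occurs before the sequence end it may end at the last full codon
# (transcriptome fragments), with has_stop = FALSE.
orfs_in_frame <- function(seq, frame, strand, allow_no_atg = FALSE) {
  n <- nchar(seq)
  usable <- n - frame + 1L
  n_codons <- usable %/% 3L
  if (n_codons < 1L) return(NULL)
  starts <- frame + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  is_stop <- codons %in% STOP_CODONS
  is_atg <- codons == "ATG"
  # segment boundaries between stops
  seg_id <- cumsum(c(TRUE, is_stop[-n_codons]))
  out <- list()
  for (s in split(seq_len(n_codons), seg_id)) {
    s <- s[!is_stop[s]]
    if (!length(s)) next
    first <- if (allow_no_atg) s[1L] else {
      atg <- s[is_atg[s]]
      if (!length(atg)) next
      atg[1L]
    }
    last <- s[length(s)]
    has_stop <- (last < n_codons) && is_stop[last + 1L]
    out[[length(out) + 1L]] <- list(
      seq = paste0(codons[first:last], collapse = ""),
      start = starts[first], end = starts[last] + 2L,
      strand = strand, has_stop = has_stop)
  }
  out
}

#' Find the longest open reading frame
#'
#' Six-frame search for the longest ATG-initiated ORF, the stand-in
#' this pipeline uses for CDS recovery from assembled unigenes. The
#' reported CDS excludes the terminal stop codon; ORFs may end at the
#' sequence end without a stop (`has_stop = FALSE`). Coordinates are
#' 1-based inclusive on the input sequence; minus-strand ORFs report
#' coordinates on the input (plus) strand.
#'
#' @param seq A DNA string (may contain N).
#' @param min_len_nt Minimum CDS length in nucleotides; ORFs shorter
#'   than this return `NULL`. The retention rule is `>= min_len_nt`.
#' @param allow_no_atg If `TRUE`, stop-to-stop ORFs without an ATG
#'   start are also considered (default off).
#' @return A list with `seq`, `start`, `end`, `strand`, `has_stop`,
#'   and `length_nt`, or `NULL` if no ORF reaches `min_len_nt`.
#' @export
find_longest_orf <- function(seq, min_len_nt = 300L, allow_no_atg = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("input error: seq must be a single non-empty DNA string")
  if (min_len_nt < 3L) stop("min_len_nt must be >= 3")
  seq <- toupper(seq)
  cands <- list()
  for (frame in 1:3)
    cands <- c(cands, orfs_in_frame(seq, frame, "+", allow_no_atg))
  rc <- reverse_complement(seq)
  n <- nchar(seq)
  for (frame in 1:3) {
    for (o in orfs_in_frame(rc, frame, "-", allow_no_atg)) {
      # map back to plus-strand coordinates
      o2 <- o
      o2$start <- n - o$end + 1L
      o2$end <- n - o$start + 1L
      cands <- c(cands, list(o2))
    }
  }
  if (!length(cands)) return(NULL)
  lens <- vapply(cands, function(o) nchar(o$seq), integer(1))
  # deterministic tie-break: longest, then + strand, then leftmost
  strd <- vapply(cands, function(o) o$strand, character(1))
  st <- vapply(cands, function(o) o$start, numeric(1))
  ord <- order(-lens, strd != "+", st)
  best <- cands[[ord[1L]]]
  if (nchar(best$seq) < min_len_nt) return(NULL)
  best$length_nt <- nchar(best$seq)
  best
}

#' Extract filtered CDSs from a unigene set
#'
#' Applies [find_longest_orf()] to every unigene and keeps CDSs of at
#' least `min_len_nt` nucleotides, the length filter used before all
#' downstream ortholog and selection analyses.
#'
#' @param unigenes Named character vector of DNA sequences.
#' @param min_len_nt Minimum CDS length (default 300 nt).
#' @return List with `cds` (named character vector) and `stats`
#'   (data.frame: id, unigene_len, cds_len, strand, kept).
#' @export
extract_cds_set <- function(unigenes, min_len_nt = 300L) {
  ids <- names(unigenes)
  cds <- character(0)
  stats <- data.frame(id = ids, unigene_len = nchar(unigenes),
                      cds_len = NA_integer_, strand = NA_character_,
                      kept = FALSE, row.names = NULL,
                      stringsAsFactors = FALSE)
  for (i in seq_along(unigenes)) {
    orf <- find_longest_orf(unigenes[[i]], min_len_nt = 3L)
    if (is.null(orf)) next
    stats$cds_len[i] <- orf$length_nt
    stats$strand[i] <- orf$strand
    if (orf$length_nt >= min_len_nt) {
      stats$kept[i] <- TRUE
      cds[[ids[i]]] <- orf$seq
    }
  }
  list(cds = cds, stats = stats)
}
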