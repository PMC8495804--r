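# Single-copy ortholog pairing by reciprocal best hit over global
# protein alignment scores. Single-copy orthologs are exactly the pairs
# RBH recovers, which is all the downstream analyses use.

#' Score a protein pair by global alignment
#'
#' Needleman-Wunsch with BLOSUM62 and affine gaps (open 10, extend
#' 0.5). Coverage of each member is the fraction of its residues
#' aligned opposite a residue (not a gap) of the other.
#'
#' @param a,b Protein strings (letters of the 20 amino acids plus X).
#' @return List with `score`, `cov_a`, `cov_b`.
#' @export
score_protein_pair <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  ok <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"
  if (!grepl(ok, a) || !grepl(ok, b))
    stop("invalid amino-acid letters in input")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- sum(pat != "-" & sub != "-")
  list(score = Biostrings::score(aln),
       cov_a = both / nchar(a), cov_b = both / nchar(b))
}

# all-vs-all score/coverage matrices between two protein sets
score_matrix <- function(setA, setB) {
  nA <- length(setA); nB <- length(setB)
  sc <- matrix(NA_real_, nA, nB, dimnames = list(names(setA), names(setB)))
  ca <- sc; cb <- sc
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    r <- score_protein_pair(setA[[i]], setB[[j]])
    sc[i, j] <- r$score; ca[i, j] <- r$cov_a; cb[i, j] <- r$cov_b
  }
  list(score = sc, cov_a = ca, cov_b = cb)
}

# row indices of the unique maximum per row; NA where the top score is
# tied (conservative single-copy rule: ties drop the gene)
unique_best <- function(m) {
  apply(m, 1L, function(row) {
    top <- max(row)
    hits <- which(row == top)
    if (length(hits) == 1L) hits else NA_integer_
  })
}

#' Reciprocal-best-hit ortholog pairs
#'
#' Pairs are kept only when each member is the unique top-scoring hit
#' of the other and both coverages reach `min_coverage`. Equal-top-score
#' ties exclude the gene rather than being broken arbitrarily, which
#' preserves the single-copy guarantee. Output is sorted by `gene_a`,
#' so it is invariant to input record order.
#'
#' @param setA,setB Named character vectors of protein sequences.
#' @param min_coverage Minimum alignment coverage on both members.
#' @return Data frame: `gene_a`, `gene_b`, `score`, `cov_a`, `cov_b`.
#' @export
reciprocal_best_hits <- function(setA, setB, min_coverage = 0.5) {
  if (!length(setA) || !length(setB))
    stop("both sequence sets must be non-empty")
  m <- score_matrix(setA, setB)
  bestA <- unique_best(m$score)        # per gene in A
  bestB <- unique_best(t(m$score))     # per gene in B
  rows <- list()
  for (i in seq_along(setA)) {
    j <- bestA[i]
    if (is.na(j)) next
    if (is.na(bestB[j]) || bestB[j] != i) next
    if (m$cov_a[i, j] < min_coverage || m$cov_b[i, j] < min_coverage) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = names(setA)[i], gene_b = names(setB)[j],
      score = m$score[i, j], cov_a = m$cov_a[i, j],
      cov_b = m$cov_b[i, j], stringsAsFactors = FALSE)
  }
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(gene_a = character(0), gene_b = character(0),
                  score = numeric(0), cov_a = numeric(0),
                  cov_b = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join wild/farmed ortholog pairs into four-taxon quartets
#'
#' A quartet links an AF-BF pair with an RF-SF pair through a
#' reciprocal-best hit between the AF and RF members, giving the set of
#' orthologous genes shared by the two comparison groups.
#'
#' @param pairs_AFBF,pairs_RFSF Pair tables from
#'   [reciprocal_best_hits()] (AF vs BF, RF vs SF).
#' @param prot_AF,prot_RF The protein sets used to cross-link groups.
#' @param min_coverage Coverage threshold for the cross-comparison.
#' @return Data frame: `gene`, `AF`, `BF`, `RF`, `SF` (member ids; the
#'   quartet label is the AF member id).
#' @export
join_quartets <- function(pairs_AFBF, pairs_RFSF, prot_AF, prot_RF,
                          min_coverage = 0.5) {
  if (!nrow(pairs_AFBF) || !nrow(pairs_RFSF))
    return(data.frame(gene = character(0), AF = character(0),
                      BF = character(0), RF = character(0),
                      SF = character(0), stringsAsFactors = FALSE))
  cross <- reciprocal_best_hits(
    prot_AF[pairs_AFBF$gene_a], prot_RF[pairs_RFSF$gene_a],
    min_coverage = min_coverage)
  rows <- list()
  for (k in seq_len(nrow(cross))) {
    af <- cross$gene_a[k]; rf <- cross$gene_b[k]
    bf <- pairs_AFBF$gene_b[match(af, pairs_AFBF$gene_a)]
    sf <- pairs_RFSF$gene_b[match(rf, pairs_RFSF$gene_a)]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = af, AF = af, BF = bf, RF = rf, SF = sf,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
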