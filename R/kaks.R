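# Nei-Gojobori (1986) counting estimation of Ka/Ks. Site fractions are
# renormalized over non-stop single-nucleotide neighbours; multi-step
# codon differences are averaged over all substitution pathways that do
# not pass through a stop codon; proportions are Jukes-Cantor corrected.

.ng_cache <- new.env(parent = emptyenv())

codon_neighbors <- function(codon, pos) {
  base <- substr(codon, pos, pos)
  alts <- NUC[NUC != base]
  vapply(alts, function(a) {
    x <- codon
    substr(x, pos, pos) <- a
    x
  }, character(1), USE.NAMES = FALSE)
}

#' Nonsynonymous/synonymous site fractions of a codon
#'
#' For each codon position the synonymous fraction is the number of
#' synonymous single-nucleotide neighbours divided by the number of
#' non-stop neighbours; the three per-position fractions each sum to 1,
#' so `n + s == 3` for every sense codon.
#'
#' @param codon A sense codon.
#' @return Named numeric vector `c(n = ..., s = ...)`.
#' @export
count_sites <- function(codon) {
  if (!codon %in% SENSE_CODONS)
    stop("stop or invalid codon: ", codon)
  key <- paste0("S:", codon)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  aa <- GENETIC_CODE_STD[[codon]]
  s <- 0
  for (pos in 1:3) {
    nb <- codon_neighbors(codon, pos)
    nb <- nb[!nb %in% STOP_CODONS]
    if (!length(nb)) next
    s <- s + sum(GENETIC_CODE_STD[nb] == aa) / length(nb)
  }
  res <- c(n = 3 - s, s = s)
  .ng_cache[[key]] <- res
  res
}

#' Pathway-averaged substitution counts between two codons
#'
#' Averages synonymous and nonsynonymous step counts over all orderings
#' of the differing positions, excluding pathways through stop codons.
#' `nd + sd` equals the number of differing nucleotide positions.
#'
#' @param codonA,codonB Sense codons.
#' @return Named numeric vector `c(nd = ..., sd = ...)`.
#' @export
count_differences <- function(codonA, codonB) {
  if (!codonA %in% SENSE_CODONS) stop("stop or invalid codon: ", codonA)
  if (!codonB %in% SENSE_CODONS) stop("stop or invalid codon: ", codonB)
  key <- paste0("D:", codonA, codonB)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  a <- strsplit(codonA, "")[[1]]
  b <- strsplit(codonB, "")[[1]]
  diffpos <- which(a != b)
  d <- length(diffpos)
  if (d == 0L) {
    res <- c(nd = 0, sd = 0)
  } else {
    perms <- if (d == 1L) list(diffpos)
      else if (d == 2L) list(diffpos, rev(diffpos))
      else {
        p <- list()
        for (i in 1:3) for (j in setdiff(1:3, i))
          p[[length(p) + 1L]] <- diffpos[c(i, j, setdiff(1:3, c(i, j)))]
        p
      }
    path_counts <- lapply(perms, function(ord) {
      cur <- a
      nd <- 0; sd <- 0
      for (pos in ord) {
        nxt <- cur
        nxt[pos] <- b[pos]
        cfrom <- paste0(cur, collapse = "")
        cto <- paste0(nxt, collapse = "")
        if (cto %in% STOP_CODONS && cto != codonB) return(NULL)
        if (GENETIC_CODE_STD[[cfrom]] == GENETIC_CODE_STD[[cto]])
          sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(nd, sd)
    })
    path_counts <- Filter(Negate(is.null), path_counts)
    if (!length(path_counts)) {
      # all orderings blocked by stops (cannot happen for sense
      # endpoints under the standard code, kept for safety): count
      # every step as nonsynonymous
      res <- c(nd = d, sd = 0)
    } else {
      m <- Reduce(`+`, path_counts) / length(path_counts)
      res <- c(nd = m[1], sd = m[2])
    }
  }
  .ng_cache[[key]] <- res
  res
}

#' Jukes-Cantor correction of a difference proportion
#'
#' @param p Proportion of differing sites, `0 <= p`.
#' @return Corrected distance; `NA` when `p >= 0.75` (saturated).
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Codon-aware pairwise alignment of two CDSs
#'
#' Aligns the translated proteins globally (BLOSUM62, affine gaps) and
#' back-translates the gap pattern onto the nucleotide sequences, so
#' gaps always come in whole-codon units. Columns containing a gap, an
#' N-containing codon, or a stop in either row are flagged uncountable
#' and excluded from Ka/Ks counting.
#'
#' @param cdsA,cdsB Frame-validated CDS strings (length multiple of 3,
#'   no internal stop).
#' @param gene_id Optional label carried into downstream reports.
#' @return Object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (aligned codon vectors, `---` for gaps), `countable`
#'   (logical per column) and `gene_id`.
#' @export
codon_aware_align <- function(cdsA, cdsB, gene_id = NA_character_) {
  ca <- split_codons(cdsA)
  cb <- split_codons(cdsB)
  for (nm in c("A", "B")) {
    cc <- if (nm == "A") ca else cb
    stops <- which(cc %in% STOP_CODONS)
    if (length(stops))
      stop("internal stop codon in sequence ", nm,
           " at codon ", stops[1L])
  }
  pa <- translate_cds(ca)
  pb <- translate_cds(cb)
  aln <- Biostrings::pairwiseAlignment(
    pa, pb, type = "global",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  n <- length(pat)
  codons_a <- character(n); codons_b <- character(n)
  for (k in seq_len(n)) {
    if (pat[k] == "-") codons_a[k] <- "---"
    else { ia <- ia + 1L; codons_a[k] <- ca[ia] }
    if (sub[k] == "-") codons_b[k] <- "---"
    else { ib <- ib + 1L; codons_b[k] <- cb[ib] }
  }
  countable <- codons_a %in% SENSE_CODONS & codons_b %in% SENSE_CODONS
  structure(list(codons_a = codons_a, codons_b = codons_b,
                 countable = countable, gene_id = gene_id),
            class = "codon_alignment")
}

blosum62_matrix <- function() {
  if (is.null(.ng_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ng_cache$blosum62 <- e$BLOSUM62
  }
  .ng_cache$blosum62
}

#' Pairwise Ka/Ks by the Nei-Gojobori counting method
#'
#' Sites are averaged over the two sequences; differences are summed
#' over countable columns and Jukes-Cantor corrected. Omega is Ka/Ks
#' when `Ks > 0`; an identical pair, a saturated proportion, or
#' `Ks == 0` all yield an undefined omega (flag `undefined`).
#'
#' @param alignment A `codon_alignment`, or a CDS string (with `cdsB`)
#'   which is aligned first.
#' @param cdsB Optional second CDS when `alignment` is a string.
#' @return Object of class `kaks_result`: list with `N`, `S`, `Nd`,
#'   `Sd`, `pN`, `pS`, `ka`, `ks`, `omega`, `flag`, `n_codons`,
#'   `gene_id`. Flags: `positive` (omega > 1), `purifying` (< 1),
#'   `neutral` (== 1), `undefined`.
#' @export
kaks <- function(alignment, cdsB = NULL) {
  if (is.character(alignment))
    alignment <- codon_aware_align(alignment, cdsB)
  stopifnot(inherits(alignment, "codon_alignment"))
  keep <- alignment$countable
  if (!any(keep)) stop("zero countable codon columns")
  ca <- alignment$codons_a[keep]
  cb <- alignment$codons_b[keep]
  sites_a <- vapply(ca, count_sites, numeric(2))
  sites_b <- vapply(cb, count_sites, numeric(2))
  N <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2
  S <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  diffs <- mapply(function(x, y) count_differences(x, y), ca, cb)
  Nd <- sum(diffs["nd", ]); Sd <- sum(diffs["sd", ])
  pN <- Nd / N; pS <- Sd / S
  ka <- jukes_cantor(pN); ks <- jukes_cantor(pS)
  omega <- NA_real_
  flag <- "undefined"
  note <- ""
  if (!is.na(ka) && !is.na(ks) && ks > 0) {
    omega <- ka / ks
    flag <- if (omega > 1) "positive" else if (omega < 1) "purifying"
            else "neutral"
  } else if (!is.na(ka) && ka > 0 && !is.na(ks) && ks == 0) {
    note <- "undefined (Ka>0, Ks=0)"
  }
  structure(list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 ka = ka, ks = ks, omega = omega, flag = flag,
                 note = note, n_codons = sum(keep),
                 gene_id = alignment$gene_id),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "Ka/Ks (NG86)%s: Ka=%.5f Ks=%.5f omega=%s [%s]  (N=%.1f S=%.1f Nd=%.2f Sd=%.2f, %d codons)\n",
    if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
    x$ka, x$ks,
    if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega),
    x$flag, x$N, x$S, x$Nd, x$Sd, x$n_codons))
  invisible(x)
}

#' Ka/Ks table for a set of ortholog pairs
#'
#' @param cds_a,cds_b Named character vectors of CDSs; names are
#'   matched by `pairs`.
#' @param pairs Data frame with columns `gene_a`, `gene_b` (e.g. from
#'   [reciprocal_best_hits()]).
#' @param group Label for the comparison (e.g. `"AF versus BF"`).
#' @return Data frame with gene ids, Ka, Ks, omega, flag and group.
#' @export
kaks_table <- function(cds_a, cds_b, pairs, group = NA_character_) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    r <- kaks(codon_aware_align(cds_a[[ga]], cds_b[[gb]], gene_id = ga))
    data.frame(gene_a = ga, gene_b = gb, ka = r$ka, ks = r$ks,
               omega = r$omega, flag = r$flag, note = r$note,
               n_codons = r$n_codons, group = group,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
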