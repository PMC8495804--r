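# Screen for lineage-exclusive amino-acid substitutions: alignment
# columns where a focal group (both farmed foxes, one farmed fox, or
# the wild pair) carries a residue found in no other taxon, at
# positions otherwise invariant across a mammalian conservation panel.

SCREEN_CATEGORIES <- c("shared_farmed", "farmed_species_specific",
                       "wild_specific")

#' Build a conservation-panel alignment object
#'
#' @param gene_id Gene label.
#' @param seqs Named character vector of aligned sequences over the
#'   taxa (equal lengths; codon data when `is_codon = TRUE`).
#' @param groups Named character vector mapping each taxon to one of
#'   `wild_fox`, `farmed_fox`, `panel`.
#' @param is_codon `TRUE` when `seqs` are nucleotide CDSs (enables
#'   nucleotide-level site reporting); `FALSE` for amino acids.
#' @return Object of class `panel_alignment`.
#' @export
panel_alignment <- function(gene_id, seqs, groups, is_codon = TRUE) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("panel rows must have equal length")
  if (!all(names(seqs) %in% names(groups)))
    stop("group map must cover all taxa")
  groups <- groups[names(seqs)]
  if (sum(groups == "panel") < 2L)
    stop("panel must contain at least two background taxa")
  structure(list(gene_id = gene_id, seqs = seqs, groups = groups,
                 is_codon = is_codon), class = "panel_alignment")
}

#' Classify one amino-acid column for lineage-exclusive substitution
#'
#' Categories: `shared_farmed` when exactly the two farmed taxa share a
#' residue absent from all other taxa (which are themselves invariant);
#' `farmed_species_specific` when exactly one farmed taxon differs from
#' a residue shared by every other taxon; `wild_specific` symmetrically
#' for the wild pair. Any polymorphism among the remaining taxa (the
#' conservation requirement) yields `NA`, as do columns containing
#' gaps or `X`. `max_mismatch` panel taxa may deviate from the
#' background residue before a column is discarded (default 0: strict
#' invariance).
#'
#' @param column Named character vector, taxon -> residue.
#' @param groups Named character vector, taxon -> group.
#' @param max_mismatch Tolerated non-focal panel deviations.
#' @return List with `category` and `focal` taxa, or `NULL`.
#' @export
classify_column <- function(column, groups, max_mismatch = 0L) {
  if (any(column %in% c("X", "-", "*"))) return(NULL)
  groups <- groups[names(column)]
  farmed <- names(column)[groups == "farmed_fox"]
  wild <- names(column)[groups == "wild_fox"]

  check <- function(focal) {
    fr <- unique(column[focal])
    if (length(fr) != 1L) return(NULL)
    rest <- column[setdiff(names(column), focal)]
    bg <- names(which.max(table(rest)))
    mism <- names(rest)[rest != bg]
    # only non-focal *panel* taxa may use the tolerance; any fox taxon
    # outside the focal set must match the background exactly
    if (any(groups[mism] != "panel")) return(NULL)
    if (length(mism) > max_mismatch) return(NULL)
    if (fr == bg) return(NULL)
    list(background = bg, derived = unname(fr))
  }

  r <- check(farmed)
  if (!is.null(r))
    return(c(list(category = "shared_farmed", focal = farmed), r))
  r <- check(wild)
  if (!is.null(r))
    return(c(list(category = "wild_specific", focal = wild), r))
  for (t in farmed) {
    r <- check(t)
    if (!is.null(r))
      return(c(list(category = "farmed_species_specific", focal = t), r))
  }
  NULL
}

#' Screen one gene panel for lineage-exclusive substitutions
#'
#' Walks every codon (or amino-acid) column, classifies it with
#' [classify_column()], and reports flagged sites with 1-based CDS
#' nucleotide positions. For codon data the reported `nt_site` is the
#' single differing nucleotide within the codon; codons differing at
#' more than one nucleotide report the first differing position with
#' `multi_nt = TRUE`.
#'
#' @param panel A [panel_alignment()].
#' @param max_mismatch Passed to [classify_column()].
#' @return Data frame of flagged sites: `gene`, `codon_index`,
#'   `nt_site`, `category`, `focal_taxa`, `background_aa`,
#'   `derived_aa`, `multi_nt`.
#' @export
screen_gene <- function(panel, max_mismatch = 0L) {
  stopifnot(inherits(panel, "panel_alignment"))
  empty <- data.frame(gene = character(0), codon_index = integer(0),
                      nt_site = integer(0), category = character(0),
                      focal_taxa = character(0),
                      background_aa = character(0),
                      derived_aa = character(0), multi_nt = logical(0),
                      stringsAsFactors = FALSE)
  taxa <- names(panel$seqs)
  if (panel$is_codon) {
    codons <- lapply(panel$seqs, split_codons)
    n_col <- length(codons[[1]])
  } else {
    chars <- lapply(panel$seqs, function(s) strsplit(s, "")[[1]])
    n_col <- length(chars[[1]])
  }
  rows <- list()
  for (ci in seq_len(n_col)) {
    if (panel$is_codon) {
      col_codons <- vapply(codons, `[[`, character(1), ci)
      if (any(col_codons == "---") || any(grepl("[^ACGT]", col_codons)))
        next
      col <- setNames(GENETIC_CODE_STD[col_codons], taxa)
      col[is.na(col)] <- "X"
    } else {
      col <- setNames(vapply(chars, `[[`, character(1), ci), taxa)
    }
    hit <- classify_column(col, panel$groups, max_mismatch)
    if (is.null(hit)) next
    if (panel$is_codon) {
      bg_codon <- col_codons[setdiff(taxa, hit$focal)][1]
      de_codon <- col_codons[hit$focal][1]
      diffp <- which(strsplit(bg_codon, "")[[1]] !=
                     strsplit(de_codon, "")[[1]])
      nt_site <- 3L * (ci - 1L) + diffp[1L]
      multi <- length(diffp) > 1L
    } else {
      nt_site <- NA_integer_
      multi <- FALSE
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = panel$gene_id, codon_index = ci, nt_site = nt_site,
      category = hit$category,
      focal_taxa = paste(sort(hit$focal), collapse = ","),
      background_aa = hit$background, derived_aa = hit$derived,
      multi_nt = multi, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Screen all shared ortholog quartets against their panels
#'
#' @param quartets Quartet table from [join_quartets()].
#' @param panels Named list of [panel_alignment()] objects keyed by
#'   quartet gene label; genes without a panel are skipped with a
#'   warning.
#' @param max_mismatch Passed to [screen_gene()].
#' @return Aggregated data frame, genes with flagged sites first,
#'   sorted by category then gene id.
#' @export
screen_quartets <- function(quartets, panels, max_mismatch = 0L) {
  rows <- list()
  for (g in quartets$gene) {
    if (is.null(panels[[g]])) {
      warning("no conservation panel for gene ", g, "; skipped")
      next
    }
    rows[[g]] <- screen_gene(panels[[g]], max_mismatch)
  }
  # deterministic single report per gene even if a panel is duplicated
  out <- if (length(rows))
    do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
  else NULL
  if (is.null(out) || !nrow(out)) {
    return(data.frame(gene = character(0), codon_index = integer(0),
                      nt_site = integer(0), category = character(0),
                      focal_taxa = character(0),
                      background_aa = character(0),
                      derived_aa = character(0), multi_nt = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$category, out$gene, out$codon_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
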