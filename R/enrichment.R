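# Over-representation testing of a study gene set against a background
# annotation, the single statistic to which GO/KEGG enrichment tools
# reduce for this purpose: the hypergeometric upper tail.

#' Build a term map from a gene-term table
#'
#' @param gene_term Data frame with columns `gene`, `term`.
#' @param descriptions Optional data frame with columns `term`,
#'   `description`.
#' @param population Background gene set; defaults to all genes in the
#'   annotation.
#' @return List of class `term_map`: `terms` (term -> gene vector),
#'   `descriptions`, `population`.
#' @export
term_map <- function(gene_term, descriptions = NULL, population = NULL) {
  stopifnot(all(c("gene", "term") %in% names(gene_term)))
  if (is.null(population)) population <- unique(gene_term$gene)
  terms <- split(gene_term$gene, gene_term$term)
  terms <- lapply(terms, unique)
  bad <- unlist(terms)[!unlist(terms) %in% population]
  if (length(bad))
    stop("term genes missing from population: ",
         paste(unique(bad), collapse = ", "))
  desc <- setNames(rep(NA_character_, length(terms)), names(terms))
  if (!is.null(descriptions))
    desc[descriptions$term] <- descriptions$description
  structure(list(terms = terms, descriptions = desc,
                 population = unique(population)), class = "term_map")
}

#' Hypergeometric term enrichment
#'
#' For each term, the p-value is the upper-tail hypergeometric
#' probability of drawing at least `k` term genes when `n` study genes
#' are sampled without replacement from a population of `N` genes of
#' which `K` carry the term.
#'
#' @param study Character vector of study gene ids (must be a subset
#'   of the population).
#' @param map A [term_map()].
#' @return Data frame sorted by p: `term`, `description`, `k`, `K`,
#'   `n`, `N`, `p_value`, `genes` (study genes in the term).
#' @export
hypergeom_enrich <- function(study, map) {
  stopifnot(inherits(map, "term_map"))
  study <- unique(study)
  missing <- study[!study %in% map$population]
  if (length(missing))
    stop("study gene(s) absent from population: ",
         paste(missing, collapse = ", "))
  N <- length(map$population)
  n <- length(study)
  rows <- lapply(names(map$terms), function(t) {
    genes <- map$terms[[t]]
    K <- length(genes)
    hits <- intersect(study, genes)
    k <- length(hits)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, description = map$descriptions[[t]],
               k = k, K = K, n = n, N = N, p_value = p,
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; offered as an option since
#' raw over-representation p-values are what comparable studies
#' report.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order as input).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
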