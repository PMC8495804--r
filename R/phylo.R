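# Four-taxon (plus outgroup) phylogeny from concatenated ortholog
# alignments: p-distances with pairwise deletion, neighbor-joining,
# and nonparametric bootstrap over alignment columns.

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param alignments List of named character vectors (aligned amino
#'   acid strings over an identical taxon set).
#' @return Named character vector (the supermatrix) with a
#'   `partitions` attribute (data frame: gene, start, end).
#' @export
concat_alignment <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  taxa <- sort(names(alignments[[1]]))
  parts <- list(); pos <- 0L
  out <- setNames(rep("", length(taxa)), taxa)
  for (g in seq_along(alignments)) {
    aln <- alignments[[g]]
    if (!setequal(names(aln), taxa))
      stop("taxon missing from gene ",
           if (!is.null(names(alignments)[g])) names(alignments)[g] else g)
    w <- unique(nchar(aln))
    if (length(w) != 1L) stop("unequal row lengths in gene ", g)
    out <- paste0(out, aln[taxa])
    parts[[g]] <- data.frame(
      gene = if (!is.null(names(alignments))) names(alignments)[g]
             else as.character(g),
      start = pos + 1L, end = pos + w)
    pos <- pos + w
  }
  out <- setNames(out, taxa)
  attr(out, "partitions") <-
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' Each entry is the proportion of differing columns among columns
#' where neither member has a gap (`-`) or `X`.
#'
#' @param supermatrix Named character vector of equal-length aligned
#'   sequences.
#' @return Symmetric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(supermatrix) {
  taxa <- names(supermatrix)
  stopifnot(length(taxa) >= 2L)
  chars <- lapply(supermatrix, function(s) strsplit(s, "")[[1]])
  usable <- lapply(chars, function(x) !(x %in% c("-", "X", "?")))
  d <- matrix(0, length(taxa), length(taxa),
              dimnames = list(taxa, taxa))
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (j <= i) next
    ok <- usable[[i]] & usable[[j]]
    if (!any(ok))
      stop("zero comparable columns between ", taxa[i], " and ", taxa[j])
    pd <- mean(chars[[i]][ok] != chars[[j]][ok])
    d[i, j] <- pd; d[j, i] <- pd
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration; on additive matrices it recovers the
#' generating topology exactly. Optionally rooted on an outgroup leaf.
#'
#' @param d Symmetric distance matrix with taxon dimnames.
#' @param outgroup Optional leaf label to root on.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  if (!is.null(outgroup))
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  tr
}

#' Bootstrap support for the NJ tree of a supermatrix
#'
#' Columns are resampled with replacement `n_reps` times, a tree is
#' rebuilt from each resampled matrix, and bipartition frequencies are
#' mapped as percentages onto the full-data tree's internal nodes.
#'
#' @param supermatrix Named character vector (aligned rows).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param outgroup Optional outgroup for rooting the reported tree.
#' @return The full-data [ape::phylo] tree with `node.label` holding
#'   integer bootstrap percentages.
#' @export
bootstrap_support <- function(supermatrix, n_reps = 100L, seed = 1L,
                              outgroup = NULL) {
  stopifnot(n_reps >= 1L)
  set.seed(seed)
  chars <- do.call(rbind, lapply(supermatrix, function(s)
    strsplit(s, "")[[1]]))
  rownames(chars) <- names(supermatrix)
  mat_of <- function(m) {
    sm <- setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
    p_distance_matrix(sm)
  }
  full <- nj_tree(mat_of(chars))
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
    reps[[b]] <- nj_tree(mat_of(chars[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- as.character(round(100 * counts / n_reps))
  if (!is.null(outgroup))
    full <- ape::root(full, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  full
}

#' Write a tree to Newick
#'
#' @param tree An [ape::phylo].
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
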