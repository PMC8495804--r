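# Synthetic study generator: ortholog quartets evolved under controlled
# omega, conservation panels with planted group-exclusive codons, and
# unigenes with planted SSR motifs. Everything is deterministic under a
# fixed seed, so fixtures never need to be stored on disk.

FOX_TAXA <- c("AF", "BF", "RF", "SF")
PANEL_MAMMALS <- c("dog", "wolf", "cat", "panda", "ferret", "cow",
                   "pig", "horse", "dolphin")

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic study. Defaults emulate the
#' study design: four fox taxa (wild arctic/red fox, farmed blue/silver
#' fox), a mammalian conservation panel, genes of a few hundred codons,
#' mostly purifying selection with a small positively selected subset.
#'
#' @param n_genes Number of ortholog quartets.
#' @param n_codons Codons per gene.
#' @param omega_target Default omega for genes not in the positive set.
#' @param n_positive Number of genes evolved under `omega_positive`.
#' @param omega_positive Omega for the positively selected subset.
#' @param n_events Substitution proposal events per lineage.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param taxa Taxon labels (first four: AF, BF, RF, SF).
#' @param n_ssr_seqs Number of SSR fixture sequences.
#' @param ssr_seq_len Length of each SSR fixture sequence.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 30L, n_codons = 300L,
                       omega_target = 0.2, n_positive = 3L,
                       omega_positive = 3, n_events = 120L,
                       seed = 1L,
                       taxa = c(FOX_TAXA, PANEL_MAMMALS),
                       n_ssr_seqs = 20L, ssr_seq_len = 500L) {
  stopifnot(n_codons >= 1L, omega_target > 0, omega_positive > 0,
            n_positive <= n_genes, length(taxa) >= 4L)
  structure(list(n_genes = as.integer(n_genes),
                 n_codons = as.integer(n_codons),
                 omega_target = omega_target,
                 n_positive = as.integer(n_positive),
                 omega_positive = omega_positive,
                 n_events = as.integer(n_events),
                 seed = as.integer(seed), taxa = taxa,
                 n_ssr_seqs = as.integer(n_ssr_seqs),
                 ssr_seq_len = as.integer(ssr_seq_len)),
            class = "sim_config")
}

#' Generate a random ancestral CDS
#'
#' Starts with ATG, then draws codons uniformly from the 61 sense
#' codons; never contains an internal stop.
#'
#' @param n_codons Number of codons (>= 1).
#' @param seed Integer seed.
#' @return A CDS string of length `3 * n_codons`.
#' @export
generate_ancestral_cds <- function(n_codons, seed = NULL) {
  stopifnot(n_codons >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (n_codons == 1L) return("ATG")
  paste0(c("ATG", sample(SENSE_CODONS, n_codons - 1L, replace = TRUE)),
         collapse = "")
}

# One lineage of acceptance-ratio codon evolution. Each event proposes
# a uniform single-nucleotide change at a uniform site; proposals that
# create a stop codon are rejected; synonymous proposals are accepted
# with probability min(1, 1/omega) and nonsynonymous with min(1, omega).
evolve_lineage <- function(codons, omega, n_events) {
  p_syn <- min(1, 1 / omega)
  p_non <- min(1, omega)
  L <- length(codons) * 3L
  # the start codon is conserved (sites 1-3 never mutate) so every
  # descendant remains a valid ATG-initiated CDS
  for (ev in seq_len(n_events)) {
    site <- if (L > 3L) sample.int(L - 3L, 1L) + 3L else sample.int(L, 1L)
    ci <- (site - 1L) %/% 3L + 1L
    pos <- (site - 1L) %% 3L + 1L
    codon <- codons[ci]
    cur <- substr(codon, pos, pos)
    alt <- sample(NUC[NUC != cur], 1L)
    newc <- codon
    substr(newc, pos, pos) <- alt
    if (newc %in% STOP_CODONS) next
    syn <- GENETIC_CODE_STD[[newc]] == GENETIC_CODE_STD[[codon]]
    p <- if (syn) p_syn else p_non
    if (runif(1) <= p) codons[ci] <- newc
  }
  codons
}

#' Evolve an ortholog pair from a common ancestor
#'
#' Two descendants evolve on independent lineages (star topology, no
#' shared branch) under the acceptance-ratio scheme, so the realised
#' nonsynonymous:synonymous substitution ratio scales with `omega`
#' relative to the neutral site ratio and the pairwise divergence is
#' the sum of the two lineages. The ATG start codon is conserved.
#'
#' @param ancestor CDS string without internal stops.
#' @param omega Target Ka/Ks (> 0).
#' @param n_events Proposal events per lineage (>= 0).
#' @param seed Optional integer seed.
#' @return List of two CDS strings (`a`, `b`).
#' @export
evolve_pair <- function(ancestor, omega, n_events, seed = NULL) {
  stopifnot(omega > 0, n_events >= 0)
  codons <- split_codons(ancestor)
  if (any(codons %in% STOP_CODONS))
    stop("input error: ancestor contains an internal stop codon")
  if (!is.null(seed)) set.seed(seed)
  list(a = paste0(evolve_lineage(codons, omega, n_events), collapse = ""),
       b = paste0(evolve_lineage(codons, omega, n_events), collapse = ""))
}

#' Plant specification for a conservation panel
#'
#' @param codon_index 1-based codon index.
#' @param focal_taxa Character vector of taxa carrying the derived codon.
#' @param background_codon,derived_codon Sense codons differing at
#'   exactly one nucleotide position.
#' @return A one-row data frame.
#' @export
plant_spec <- function(codon_index, focal_taxa, background_codon,
                       derived_codon) {
  if (!background_codon %in% SENSE_CODONS ||
      !derived_codon %in% SENSE_CODONS)
    stop("plant codons must be sense codons")
  nd <- sum(strsplit(background_codon, "")[[1]] !=
            strsplit(derived_codon, "")[[1]])
  if (nd != 1L)
    stop("background and derived codon must differ at exactly one ",
         "nucleotide (got ", nd, ")")
  data.frame(codon_index = as.integer(codon_index),
             focal_taxa = paste(focal_taxa, collapse = ","),
             background_codon = background_codon,
             derived_codon = derived_codon, stringsAsFactors = FALSE)
}

#' Build a multi-taxon codon panel with planted substitutions
#'
#' All taxa carry the base sequence except at planted codons, where the
#' background codon is installed in every taxon and exactly the focal
#' taxa carry the derived codon. The result is gap-free.
#'
#' @param base Base CDS string.
#' @param plants Data frame of [plant_spec()] rows (may be empty).
#' @param taxa Taxon labels.
#' @return Named character vector of CDS strings, one per taxon.
#' @export
generate_panel <- function(base, plants, taxa) {
  n_codons <- nchar(base) %/% 3L
  if (nrow(plants) > 0) {
    if (anyDuplicated(plants$codon_index))
      stop("overlapping plants at one codon")
    if (any(plants$codon_index > n_codons))
      stop("plant codon index beyond base length")
    focal_all <- unlist(strsplit(plants$focal_taxa, ","))
    if (!all(focal_all %in% taxa))
      stop("focal taxa not a subset of panel taxa")
  }
  rows <- setNames(rep(base, length(taxa)), taxa)
  for (i in seq_len(nrow(plants))) {
    span <- codon_to_nt_span(plants$codon_index[i])
    focal <- strsplit(plants$focal_taxa[i], ",")[[1]]
    for (t in taxa) {
      codon <- if (t %in% focal) plants$derived_codon[i]
               else plants$background_codon[i]
      substr(rows[[t]], span[1, "start"], span[1, "end"]) <- codon
    }
  }
  rows
}

#' Insert a perfect tandem repeat into a sequence
#'
#' Overwrites `repeats` copies of `motif` starting at `position`,
#' leaving all flanking sequence unchanged.
#'
#' @param seq DNA string.
#' @param motif Repeat unit, 1-6 nt.
#' @param repeats Copy number (>= 1).
#' @param position 1-based start of the first copy.
#' @return Modified sequence string.
#' @export
plant_ssr <- function(seq, motif, repeats, position) {
  u <- nchar(motif)
  stopifnot(u >= 1L, u <= 6L, repeats >= 1L)
  tract <- strrep(motif, repeats)
  end <- position + nchar(tract) - 1L
  if (position < 1L || end > nchar(seq))
    stop("planted SSR does not fit at position ", position)
  substr(seq, position, end) <- tract
  seq
}

# regex scan for any perfect SSR at-or-above MISA-style thresholds;
# used to reject random backgrounds that contain natural repeats.
has_natural_ssr <- function(seq, thresholds = misa_thresholds()) {
  for (u in as.integer(names(thresholds))) {
    k <- thresholds[[as.character(u)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, k - 1L)
    if (grepl(pat, seq, perl = TRUE)) return(TRUE)
  }
  FALSE
}

random_dna <- function(len) paste0(sample(NUC, len, TRUE), collapse = "")

# repeat-free random background (rejection sampling via the regex scan)
repeat_free_dna <- function(len, thresholds = misa_thresholds(),
                            max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(len)
    if (!has_natural_ssr(s, thresholds)) return(s)
  }
  stop("could not generate a repeat-free background of length ", len)
}

# plant an SSR and break one nucleotide on each side so the planted
# locus is maximal and exactly recoverable
plant_ssr_bounded <- function(seq, motif, repeats, position) {
  u <- nchar(motif)
  seq <- plant_ssr(seq, motif, repeats, position)
  end <- position + u * repeats - 1L
  last <- substr(motif, u, u)
  first <- substr(motif, 1L, 1L)
  if (position > 1L && substr(seq, position - 1L, position - 1L) == last)
    substr(seq, position - 1L, position - 1L) <-
      sample(NUC[NUC != last], 1L)
  if (end < nchar(seq) && substr(seq, end + 1L, end + 1L) == first)
    substr(seq, end + 1L, end + 1L) <- sample(NUC[NUC != first], 1L)
  seq
}

#' Figure-style panel plants for the three reported fox genes
#'
#' The three worked substitutions of the study: a wild-fox-exclusive
#' TGG->AGG (W->R) at codon 79 (CDS site 235), a silver-fox-exclusive
#' CTA->CAA (L->Q) at codon 176 (site 527), and a silver-fox-exclusive
#' AAG->AAC (K->N) at codon 51 (site 153).
#'
#' @return Named list of one-row plant data frames, keyed by gene-like
#'   labels (`LEMD2`, `RRBP1`, `IGBP1`).
#' @export
reference_plants <- function() {
  list(
    LEMD2 = plant_spec(79L, c("AF", "RF"), "TGG", "AGG"),
    RRBP1 = plant_spec(176L, "SF", "CTA", "CAA"),
    IGBP1 = plant_spec(51L, "SF", "AAG", "AAC"))
}

#' Generate the full synthetic study fixture tree
#'
#' Writes every input the pipeline needs under `out_dir`: per-taxon CDS
#' FASTAs for the AF/BF and RF/SF ortholog quartets (all four members
#' of each gene descend from one ancestor), conservation-panel FASTAs
#' with planted group-exclusive codons, a unigene FASTA with planted
#' SSRs, a synthetic gene-to-term annotation map, and TSV truth tables
#' (per-gene true omega, planted panel sites, planted SSR loci)
#' sufficient for automated scoring. Identical seeds give byte-identical
#' trees.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the truth tables and file paths.
#' @export
generate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  ng <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(ng))
  omegas <- rep(config$omega_target, ng)
  if (config$n_positive > 0)
    omegas[seq_len(config$n_positive)] <- config$omega_positive

  seqs <- list(AF = character(0), BF = character(0),
               RF = character(0), SF = character(0))
  for (i in seq_len(ng)) {
    anc <- paste0(c("ATG",
      sample(SENSE_CODONS, config$n_codons - 1L, TRUE)), collapse = "")
    ab <- evolve_pair(anc, omegas[i], config$n_events)
    rs <- evolve_pair(anc, omegas[i], config$n_events)
    seqs$AF[[gene_ids[i]]] <- ab$a
    seqs$BF[[gene_ids[i]]] <- ab$b
    seqs$RF[[gene_ids[i]]] <- rs$a
    seqs$SF[[gene_ids[i]]] <- rs$b
  }
  for (t in FOX_TAXA)
    write_fasta(seqs[[t]], file.path(out_dir, paste0("cds_", t, ".fasta")))
  omega_truth <- data.frame(gene = gene_ids, true_omega = omegas,
                            stringsAsFactors = FALSE)
  write_tsv(omega_truth, file.path(out_dir, "truth_omega.tsv"))

  # conservation panels with the three reference plants in the first
  # three genes; panel rows are gap-free and identical to AF except at
  # planted codons
  plants <- reference_plants()
  panel_dir <- file.path(out_dir, "panels")
  dir.create(panel_dir, showWarnings = FALSE)
  plant_rows <- list()
  panel_genes <- gene_ids[seq_len(min(ng, length(plants) + 2L))]
  for (j in seq_along(panel_genes)) {
    g <- panel_genes[j]
    base <- seqs$AF[[g]]
    pl <- if (j <= length(plants)) plants[[j]] else
      plants[[1]][0, ]  # no plants: conserved control panel
    pl <- pl[pl$codon_index <= config$n_codons, , drop = FALSE]
    panel <- generate_panel(base, pl, config$taxa)
    write_fasta(panel, file.path(panel_dir, paste0(g, ".fasta")))
    if (nrow(pl)) {
      span <- codon_to_nt_span(pl$codon_index)
      diffp <- which(strsplit(pl$background_codon, "")[[1]] !=
                     strsplit(pl$derived_codon, "")[[1]])
      plant_rows[[g]] <- data.frame(
        gene = g, codon_index = pl$codon_index,
        nt_site = span[1, "start"] + diffp - 1L,
        focal_taxa = pl$focal_taxa,
        background_aa = GENETIC_CODE_STD[[pl$background_codon]],
        derived_aa = GENETIC_CODE_STD[[pl$derived_codon]],
        stringsAsFactors = FALSE)
    }
  }
  panel_truth <- do.call(rbind, c(plant_rows, list(make.row.names = FALSE)))
  write_tsv(panel_truth, file.path(out_dir, "truth_panel.tsv"))
  groups <- data.frame(
    taxon = config$taxa,
    group = ifelse(config$taxa %in% c("AF", "RF"), "wild_fox",
            ifelse(config$taxa %in% c("BF", "SF"), "farmed_fox",
                   "panel")), stringsAsFactors = FALSE)
  write_tsv(groups, file.path(out_dir, "taxon_groups.tsv"))

  # unigene fixture with planted SSRs (repeat-free backgrounds)
  motifs <- c("A", "AC", "ATG", "AATC", "AATCG", "AATCGG")
  thr <- misa_thresholds()
  uni <- character(0)
  ssr_rows <- list()
  for (i in seq_len(config$n_ssr_seqs)) {
    id <- sprintf("uni%04d", i)
    s <- repeat_free_dna(config$ssr_seq_len)
    motif <- motifs[(i - 1L) %% length(motifs) + 1L]
    u <- nchar(motif)
    reps <- thr[[as.character(u)]] + (i %% 3L)
    pos <- 101L
    s <- plant_ssr_bounded(s, motif, reps, pos)
    uni[[id]] <- s
    ssr_rows[[i]] <- data.frame(
      seq_id = id, motif = motif, unit_size = u, repeats = reps,
      start = pos, end = pos + u * reps - 1L, stringsAsFactors = FALSE)
  }
  write_fasta(uni, file.path(out_dir, "unigenes_ssr.fasta"))
  ssr_truth <- do.call(rbind, c(ssr_rows, list(make.row.names = FALSE)))
  write_tsv(ssr_truth, file.path(out_dir, "truth_ssr.tsv"))

  # synthetic gene-to-term annotation for enrichment; the first term
  # collects the positively selected genes
  terms <- c("T:0001", "T:0002", "T:0003", "T:0004")
  ann <- data.frame(
    gene = rep(gene_ids, 2),
    term = c(ifelse(seq_len(ng) <= config$n_positive, terms[1],
                    terms[2L + (seq_len(ng) %% 3L)]),
             terms[2L + ((seq_len(ng) + 1L) %% 3L)]),
    stringsAsFactors = FALSE)
  write_tsv(ann, file.path(out_dir, "annotation.tsv"))

  meta <- c(paste0("seed\t", config$seed),
            paste0("n_genes\t", config$n_genes),
            paste0("n_codons\t", config$n_codons),
            paste0("omega_target\t", config$omega_target),
            paste0("omega_positive\t", config$omega_positive),
            paste0("n_positive\t", config$n_positive),
            paste0("n_events\t", config$n_events))
  writeLines(meta, file.path(out_dir, "config.tsv"))
  invisible(list(omega_truth = omega_truth, panel_truth = panel_truth,
                 ssr_truth = ssr_truth, groups = groups,
                 annotation = ann, dir = out_dir))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
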