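# End-to-end pipeline over a synthetic (or user-supplied) study: CDS
# extraction -> ortholog pairing -> Ka/Ks -> positive-selection calls
# -> mutation screen; SSR detection and enrichment as side branches;
# concatenated NJ tree at the end. All intermediates are plain TSV and
# every run is deterministic under its seed (no wall-clock anywhere in
# the outputs).

#' Run the full comparative pipeline on a study directory
#'
#' Expects the layout written by [generate_study()]: per-taxon CDS
#' FASTAs, per-gene conservation panels, a taxon-group map, an SSR
#' unigene FASTA and a gene-term annotation. Writes a deterministic
#' report bundle under `out_dir`.
#'
#' @param study_dir Directory holding the inputs.
#' @param out_dir Output directory for the report bundle.
#' @param min_cds_len Minimum CDS length in nt (the `>= 300` filter
#'   convention; CDSs from [generate_study()] are already coding, the
#'   filter applies to user unigene input).
#' @param min_coverage RBH coverage threshold.
#' @param max_mismatch Conservation-screen tolerance (panel taxa).
#' @param thresholds SSR thresholds from [misa_thresholds()].
#' @param bootstrap_reps Bootstrap replicates for the tree.
#' @param seed Integer seed recorded in the run log and used for the
#'   bootstrap.
#' @return Invisibly, a list of the in-memory tables and the bundle
#'   paths.
#' @export
run_all <- function(study_dir, out_dir, min_cds_len = 300L,
                    min_coverage = 0.5, max_mismatch = 0L,
                    thresholds = misa_thresholds(),
                    bootstrap_reps = 100L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  cds <- lapply(setNames(FOX_TAXA, FOX_TAXA), function(t)
    read_fasta(file.path(study_dir, paste0("cds_", t, ".fasta"))))
  for (t in FOX_TAXA)
    if (!length(cds[[t]]))
      stop("stage cds: no sequences for taxon ", t)

  # CDS stats (the length filter applied to the supplied CDS sets)
  cds_stats <- do.call(rbind, lapply(FOX_TAXA, function(t)
    data.frame(taxon = t, id = names(cds[[t]]),
               cds_len = nchar(cds[[t]]),
               kept = nchar(cds[[t]]) >= min_cds_len,
               stringsAsFactors = FALSE)))
  cds <- lapply(cds, function(s) s[nchar(s) >= min_cds_len])
  paths$cds_stats <- file.path(out_dir, "cds_stats.tsv")
  write_tsv(cds_stats, paths$cds_stats)

  prot <- lapply(cds, function(s)
    vapply(s, translate_cds, character(1)))

  pairs_afbf <- reciprocal_best_hits(prot$AF, prot$BF, min_coverage)
  pairs_rfsf <- reciprocal_best_hits(prot$RF, prot$SF, min_coverage)
  quartets <- join_quartets(pairs_afbf, pairs_rfsf, prot$AF, prot$RF,
                            min_coverage)
  orth <- rbind(cbind(pairs_afbf, group = "AF versus BF"),
                cbind(pairs_rfsf, group = "RF versus SF"))
  paths$orthologs <- file.path(out_dir, "orthologs.tsv")
  write_tsv(orth, paths$orthologs)
  paths$quartets <- file.path(out_dir, "quartets.tsv")
  write_tsv(quartets, paths$quartets)

  kk <- rbind(kaks_table(cds$AF, cds$BF, pairs_afbf, "AF versus BF"),
              kaks_table(cds$RF, cds$SF, pairs_rfsf, "RF versus SF"))
  paths$kaks <- file.path(out_dir, "kaks.tsv")
  write_tsv(kk, paths$kaks)
  pos <- kk[!is.na(kk$omega) & kk$omega > 1, , drop = FALSE]
  paths$positive_selection <- file.path(out_dir, "positive_selection.tsv")
  write_tsv(pos, paths$positive_selection)

  # mutation screen over the shared quartets
  groups_df <- read_tsv(file.path(study_dir, "taxon_groups.tsv"))
  groups <- setNames(groups_df$group, groups_df$taxon)
  panel_dir <- file.path(study_dir, "panels")
  panels <- list()
  for (g in quartets$gene) {
    f <- file.path(panel_dir, paste0(g, ".fasta"))
    if (file.exists(f))
      panels[[g]] <- panel_alignment(g, read_fasta(f), groups)
  }
  screen <- screen_quartets(quartets, panels, max_mismatch)
  paths$screen <- file.path(out_dir, "screen.tsv")
  write_tsv(screen, paths$screen)

  # SSR branch
  uni <- read_fasta(file.path(study_dir, "unigenes_ssr.fasta"))
  loci <- merge_compound(detect_ssrs_set(uni, thresholds))
  paths$ssr <- file.path(out_dir, "ssr.misa.tsv")
  write_misa(loci, paths$ssr)
  paths$ssr_summary <- file.path(out_dir, "ssr_summary.tsv")
  write_tsv(ssr_summary(loci), paths$ssr_summary)

  # enrichment of positively selected genes against the annotation
  ann <- read_tsv(file.path(study_dir, "annotation.tsv"))
  map <- term_map(ann)
  study_genes <- intersect(unique(pos$gene_a), map$population)
  enr <- if (length(study_genes)) hypergeom_enrich(study_genes, map)
         else hypergeom_enrich(character(0), map)
  paths$enrichment <- file.path(out_dir, "enrichment.tsv")
  write_tsv(enr, paths$enrichment)

  # concatenated tree over the quartet proteins, outgroup = first
  # panel taxon when panels provide one
  alns <- lapply(seq_len(nrow(quartets)), function(i) {
    q <- quartets[i, ]
    seqs <- c(AF = prot$AF[[q$AF]], BF = prot$BF[[q$BF]],
              RF = prot$RF[[q$RF]], SF = prot$SF[[q$SF]])
    # star-evolved quartets are indel-free; truncate defensively to a
    # common length so concatenation never fails on user input
    w <- min(nchar(seqs))
    setNames(substr(seqs, 1L, w), names(seqs))
  })
  names(alns) <- quartets$gene
  tree <- NULL
  if (nrow(quartets) >= 1L) {
    sm <- concat_alignment(alns)
    tree <- bootstrap_support(sm, n_reps = bootstrap_reps, seed = seed)
    paths$tree <- file.path(out_dir, "tree.nwk")
    write_newick(tree, paths$tree)
  }

  log_lines <- c(
    paste0("package_version\t", as.character(utils::packageVersion("farmfox"))),
    paste0("seed\t", seed),
    paste0("min_cds_len\t", min_cds_len),
    paste0("min_coverage\t", min_coverage),
    paste0("max_mismatch\t", max_mismatch),
    paste0("bootstrap_reps\t", bootstrap_reps),
    paste0("n_orthologs_AFBF\t", nrow(pairs_afbf)),
    paste0("n_orthologs_RFSF\t", nrow(pairs_rfsf)),
    paste0("n_quartets\t", nrow(quartets)),
    paste0("n_positive\t", nrow(pos)),
    paste0("n_flagged_sites\t", nrow(screen)),
    paste0("n_ssr_loci\t", nrow(loci)))
  paths$run_log <- file.path(out_dir, "run_log.tsv")
  writeLines(log_lines, paths$run_log)

  invisible(list(cds_stats = cds_stats, orthologs = orth,
                 quartets = quartets, kaks = kk, positive = pos,
                 screen = screen, ssr = loci, enrichment = enr,
                 tree = tree, paths = paths))
}
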