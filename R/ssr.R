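# MISA-style microsatellite detection: maximal perfect tandem repeats
# of 1-6 nt units, compound merging by interruption distance, and a
# primer-placement feasibility check with GC-proximity ranking.

#' Default SSR detection thresholds
#'
#' MISA's defaults: minimum repeat counts of 10 (mono), 6 (di) and 5
#' (tri/tetra/penta/hexa); compound SSRs merge loci separated by at
#' most 100 nt.
#'
#' @param mono,di,tri,tetra,penta,hexa Minimum repeat counts.
#' @return Named list keyed by unit size `"1"`..`"6"`.
#' @export
misa_thresholds <- function(mono = 10L, di = 6L, tri = 5L, tetra = 5L,
                            penta = 5L, hexa = 5L) {
  thr <- list(mono, di, tri, tetra, penta, hexa)
  names(thr) <- as.character(1:6)
  if (any(unlist(thr) < 2L)) stop("all repeat minima must be >= 2")
  thr
}

# smallest period of a motif string; a motif is primitive iff its
# smallest period equals its length
smallest_period <- function(motif) {
  u <- nchar(motif)
  for (p in seq_len(u - 1L)) {
    if (u %% p != 0L) next
    if (strrep(substr(motif, 1L, p), u %/% p) == motif) return(p)
  }
  u
}

#' Canonical motif (lexicographic minimum over rotations)
#'
#' @param motif Repeat unit.
#' @param both_strands Also minimise over rotations of the reverse
#'   complement (strand-joint canonicalisation, default off).
#' @return Canonical motif string.
#' @export
canonical_motif <- function(motif, both_strands = FALSE) {
  u <- nchar(motif)
  rots <- vapply(seq_len(u) - 1L, function(k)
    paste0(substr(motif, k + 1L, u), substr(motif, 1L, k)), character(1))
  if (both_strands) {
    rc <- reverse_complement(motif)
    rots <- c(rots, vapply(seq_len(u) - 1L, function(k)
      paste0(substr(rc, k + 1L, u), substr(rc, 1L, k)), character(1)))
  }
  min(rots)
}

#' Detect perfect microsatellites in a sequence
#'
#' Reports every maximal perfect tandem repeat whose unit size is 1-6
#' and whose complete-unit copy number reaches the threshold for that
#' unit size. A repeat whose unit is itself periodic (e.g. ACAC) is
#' reported at its smallest period only. Runs containing non-ACGT
#' letters are not reported. Coordinates are 1-based inclusive and
#' cover complete units only.
#'
#' @param seq DNA string.
#' @param thresholds From [misa_thresholds()].
#' @param seq_id Sequence id carried into the report.
#' @param both_strands Strand-joint motif canonicalisation flag.
#' @return Data frame of loci: `seq_id`, `motif` (as found),
#'   `motif_canonical`, `unit_size`, `repeats`, `start`, `end`,
#'   `compound_id` (NA until [merge_compound()]).
#' @export
detect_ssrs <- function(seq, thresholds = misa_thresholds(),
                        seq_id = NA_character_, both_strands = FALSE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  valid <- chars %in% NUC
  rows <- list()
  for (u in 1:6) {
    k_min <- thresholds[[as.character(u)]]
    if (n < u * k_min) next
    same <- chars[seq_len(n - u)] == chars[(u + 1L):n] &
            valid[seq_len(n - u)] & valid[(u + 1L):n]
    r <- rle(same)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values)) {
      m <- r$lengths[ri]               # matched comparisons
      region_len <- m + u              # perfect tract length (may be partial)
      reps <- region_len %/% u
      if (reps < k_min) next
      start <- starts[ri]
      motif <- substr(seq, start, start + u - 1L)
      if (smallest_period(motif) < u) next  # report at smallest period only
      end <- start + u * reps - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, motif = motif,
        motif_canonical = canonical_motif(motif, both_strands),
        unit_size = u, repeats = reps, start = start, end = end,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(seq_id = character(0), motif = character(0),
                  motif_canonical = character(0), unit_size = integer(0),
                  repeats = integer(0), start = integer(0),
                  end = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$unit_size), , drop = FALSE]
  out$compound_id <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  out
}

#' Detect SSRs across a sequence set
#'
#' @param seqs Named character vector of DNA sequences.
#' @inheritParams detect_ssrs
#' @return Combined locus table in input order.
#' @export
detect_ssrs_set <- function(seqs, thresholds = misa_thresholds(),
                            both_strands = FALSE) {
  tabs <- lapply(names(seqs), function(id)
    detect_ssrs(seqs[[id]], thresholds, seq_id = id,
                both_strands = both_strands))
  do.call(rbind, c(tabs, list(make.row.names = FALSE)))
}

#' Assign compound ids to nearby SSR loci
#'
#' Consecutive loci on the same sequence separated by at most
#' `max_interruption` nucleotides share a compound id; isolated loci
#' keep `NA`.
#'
#' @param loci Locus table sorted by `seq_id` then `start`.
#' @param max_interruption Maximum interruption in nt (default 100).
#' @return The locus table with `compound_id` filled in.
#' @export
merge_compound <- function(loci, max_interruption = 100L) {
  if (!nrow(loci)) return(loci)
  for (id in unique(loci$seq_id)) {
    idx <- which(loci$seq_id == id)
    if (is.unsorted(loci$start[idx]))
      stop("loci must be sorted by start within each sequence")
  }
  comp <- 0L
  loci$compound_id <- NA_character_
  for (id in unique(loci$seq_id)) {
    idx <- which(loci$seq_id == id)
    if (length(idx) < 2L) next
    open <- FALSE
    for (k in seq_len(length(idx) - 1L)) {
      gap <- loci$start[idx[k + 1L]] - loci$end[idx[k]] - 1L
      if (gap <= max_interruption) {
        if (!open) { comp <- comp + 1L; open <- TRUE }
        cid <- sprintf("c%03d", comp)
        loci$compound_id[idx[k]] <- cid
        loci$compound_id[idx[k + 1L]] <- cid
      } else open <- FALSE
    }
  }
  loci
}

gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  mean(chars %in% c("G", "C"))
}

#' Primer placement feasibility around an SSR locus
#'
#' Checks whether the flanks of a locus admit forward/reverse primer
#' windows of the allowed lengths whose amplified product (inclusive of
#' both primers) falls in `product_range`. Candidate window pairs are
#' ranked by the summed closeness of their GC content to 50% (a
#' screening stand-in for thermodynamic primer design) and up to three
#' are returned.
#'
#' @param seq DNA string containing the locus.
#' @param locus One row of a [detect_ssrs()] table (needs `start`,
#'   `end`).
#' @param primer_len_range Allowed primer lengths (default 18-22).
#' @param product_range Allowed product lengths (default 100-400).
#' @param flank_min Minimum gap between a primer and the locus.
#' @param max_candidates Number of ranked window pairs to return.
#' @return List with `feasible` (logical) and `windows` (data frame:
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end`, `product_len`,
#'   `gc_penalty`).
#' @export
primer_feasible <- function(seq, locus, primer_len_range = c(18L, 22L),
                            product_range = c(100L, 400L),
                            flank_min = 0L, max_candidates = 3L) {
  n <- nchar(seq)
  ls <- locus$start; le <- locus$end
  stopifnot(ls >= 1L, le <= n)
  fwd_max_end <- ls - 1L - flank_min
  rev_min_start <- le + 1L + flank_min
  lens <- primer_len_range[1]:primer_len_range[2]
  enum_windows <- function(lo, hi) {
    out <- list()
    for (wlen in lens) {
      if (hi - lo + 1L < wlen) next
      st <- lo:(hi - wlen + 1L)
      out[[length(out) + 1L]] <- data.frame(start = st,
                                            end = st + wlen - 1L)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  fwd <- if (fwd_max_end >= 1L) enum_windows(1L, fwd_max_end) else NULL
  rev <- if (rev_min_start <= n) enum_windows(rev_min_start, n) else NULL
  if (is.null(fwd) || is.null(rev))
    return(list(feasible = FALSE, windows = data.frame()))
  is_gc <- strsplit(toupper(seq), "")[[1]] %in% c("G", "C")
  cgc <- c(0, cumsum(is_gc))
  win_gc <- function(w)
    (cgc[w$end + 1L] - cgc[w$start]) / (w$end - w$start + 1L)
  fwd$gc <- win_gc(fwd); rev$gc <- win_gc(rev)
  # all fwd x rev combinations whose product length is in range
  prod_len <- outer(rev$end, fwd$start, function(re, fs) re - fs + 1L)
  ok <- prod_len >= product_range[1] & prod_len <= product_range[2]
  if (!any(ok)) return(list(feasible = FALSE, windows = data.frame()))
  idx <- which(ok, arr.ind = TRUE)
  w <- data.frame(
    fwd_start = fwd$start[idx[, 2]], fwd_end = fwd$end[idx[, 2]],
    rev_start = rev$start[idx[, 1]], rev_end = rev$end[idx[, 1]],
    product_len = prod_len[idx],
    gc_penalty = abs(fwd$gc[idx[, 2]] - 0.5) +
                 abs(rev$gc[idx[, 1]] - 0.5))
  w <- w[order(w$gc_penalty, w$fwd_start, w$product_len), , drop = FALSE]
  rownames(w) <- NULL
  list(feasible = TRUE, windows = utils::head(w, max_candidates))
}

#' Write an SSR table in MISA-compatible layout
#'
#' Columns: ID, SSR nr., SSR type (p1-p6 or c for compound members),
#' SSR (motif and copy number), size, start, end.
#'
#' @param loci Locus table (after [merge_compound()]).
#' @param path Output TSV path.
#' @export
write_misa <- function(loci, path) {
  type <- ifelse(!is.na(loci$compound_id), "c",
                 paste0("p", loci$unit_size))
  misa <- data.frame(
    ID = loci$seq_id,
    `SSR nr.` = stats::ave(seq_len(nrow(loci)), loci$seq_id,
                           FUN = seq_along),
    `SSR type` = type,
    SSR = sprintf("(%s)%d", loci$motif, loci$repeats),
    size = loci$end - loci$start + 1L,
    start = loci$start, end = loci$end,
    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(misa, path)
}

#' Summarise SSR counts by unit size
#'
#' @param loci Locus table.
#' @param include_mono Include mononucleotide loci (both modes are
#'   supported since repeat-class conventions vary between studies).
#' @return Data frame: `unit_size`, `n_loci`, `n_compound_members`.
#' @export
ssr_summary <- function(loci, include_mono = TRUE) {
  if (!include_mono) loci <- loci[loci$unit_size > 1L, , drop = FALSE]
  us <- sort(unique(loci$unit_size))
  data.frame(unit_size = us,
             n_loci = vapply(us, function(u)
               sum(loci$unit_size == u), integer(1)),
             n_compound_members = vapply(us, function(u)
               sum(loci$unit_size == u & !is.na(loci$compound_id)),
               integer(1)))
}
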