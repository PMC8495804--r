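# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

GC_TAB <- Biostrings::GENETIC_CODE
SENSE <- names(GC_TAB)[GC_TAB != "*"]
STOPS <- names(GC_TAB)[GC_TAB == "*"]
BASES <- c("A", "C", "G", "T")

# translation via seqinr (independent code path from the package table);
# memoised into a lookup so the exhaustive codon sweeps stay fast
ORACLE_AA <- local({
  all64 <- apply(expand.grid(BASES, BASES, BASES), 1, paste0,
                 collapse = "")
  setNames(vapply(all64, function(cd)
    seqinr::translate(strsplit(tolower(cd), "")[[1]]), character(1)),
    all64)
})
oracle_translate_codon <- function(codon) ORACLE_AA[[codon]]

# NG86 site fractions by direct enumeration of the 9 single-nt
# neighbours against the seqinr-translated code
oracle_sites <- function(codon) {
  aa <- oracle_translate_codon(codon)
  s_total <- 0
  for (pos in 1:3) {
    nbs <- character(0)
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      x <- codon; substr(x, pos, pos) <- b
      nbs <- c(nbs, x)
    }
    nbs <- nbs[!nbs %in% STOPS]
    if (!length(nbs)) next
    syn <- sum(vapply(nbs, oracle_translate_codon, character(1)) == aa)
    s_total <- s_total + syn / length(nbs)
  }
  c(n = 3 - s_total, s = s_total)
}

# pathway-averaged difference counts by explicit permutation listing
oracle_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  dp <- which(a != b)
  if (!length(dp)) return(c(nd = 0, sd = 0))
  perms <- if (length(dp) == 1) matrix(dp, 1) else {
    pm <- do.call(rbind, lapply(
      combinat_perms(length(dp)), function(ix) dp[ix]))
    pm
  }
  acc <- list()
  for (r in seq_len(nrow(perms))) {
    cur <- a; nd <- 0; sd <- 0; okpath <- TRUE
    for (pos in perms[r, ]) {
      nxt <- cur; nxt[pos] <- b[pos]
      cto <- paste0(nxt, collapse = "")
      if (cto %in% STOPS) { okpath <- FALSE; break }
      if (oracle_translate_codon(paste0(cur, collapse = "")) ==
          oracle_translate_codon(cto)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (okpath) acc[[length(acc) + 1]] <- c(nd, sd)
  }
  if (!length(acc)) return(c(nd = length(dp), sd = 0))
  m <- Reduce(`+`, acc) / length(acc)
  c(nd = m[1], sd = m[2])
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1))
  out <- list()
  for (i in seq_len(n)) {
    for (p in combinat_perms(n - 1))
      out[[length(out) + 1]] <- c(i, ifelse(p >= i, p + 1, p))
  }
  out
}

# naive quadratic six-frame longest-ORF oracle
oracle_longest_orf_len <- function(seq) {
  best <- 0L
  scan <- function(s) {
    n <- nchar(s)
    for (st in seq_len(max(0L, n - 2L))) {
      if (substr(s, st, st + 2L) != "ATG") next
      len <- 0L
      i <- st
      while (i + 2L <= n) {
        codon <- substr(s, i, i + 2L)
        if (codon %in% STOPS) break
        len <- len + 3L
        i <- i + 3L
      }
      best <<- max(best, len)
    }
  }
  scan(seq)
  scan(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq))))
  best
}

# regex SSR oracle (PCRE backreferences), reporting complete-unit spans
oracle_ssr_scan <- function(seq, thresholds) {
  rows <- list()
  for (u in 1:6) {
    k <- thresholds[[as.character(u)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, k - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (i in seq_along(m)) {
      st <- m[i]
      len <- attr(m, "match.length")[i]
      motif <- substr(seq, st, st + u - 1L)
      # only keep primitive motifs; complete units only
      is_prim <- !any(vapply(seq_len(u - 1L), function(p)
        u %% p == 0 && strrep(substr(motif, 1, p), u / p) == motif,
        logical(1)))
      if (u > 1 && !is_prim) next
      reps <- len %/% u
      rows[[length(rows) + 1]] <- data.frame(
        motif = motif, unit_size = u, repeats = reps,
        start = st, end = st + u * reps - 1L)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# brute-force affine-gap global alignment score by enumerating all
# alignments (tiny inputs only); gap of length L costs open + ext*L
oracle_align_score <- function(a, b, open = 10, ext = 0.5) {
  mat <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                envir = e); e$BLOSUM62
  })
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, sc, prev) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, sc); return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1, j + 1, sc + mat[A[i], B[j]], "M")
    if (i <= length(A))
      rec(i + 1, j, sc - (if (prev == "D") ext else open + ext), "D")
    if (j <= length(B))
      rec(i, j + 1, sc - (if (prev == "I") ext else open + ext), "I")
  }
  rec(1, 1, 0, "start")
  best
}

# exact hypergeometric upper tail by explicit combinatorial sums
oracle_hyper_upper <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# random additive distance matrix from a random topology with known
# generating tree
oracle_additive_matrix <- function(taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(length(taxa), tip.label = taxa)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  list(tree = tr, d = cophenetic(tr)[taxa, taxa])
}

# shared fixture taxa
PANEL13 <- c("AF", "BF", "RF", "SF", "dog", "wolf", "cat", "panda",
             "ferret", "cow", "pig", "horse", "dolphin")
PANEL13_GROUPS <- setNames(
  c("wild_fox", "farmed_fox", "wild_fox", "farmed_fox", rep("panel", 9)),
  PANEL13)
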