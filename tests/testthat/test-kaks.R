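test_that("site counting matches hand-derived codon cases", {
  # TTT: only the third-position change to TTC is synonymous
  expect_equal(count_sites("TTT"), c(n = 8 / 3, s = 1 / 3))
  # TGG (Trp) has no synonymous neighbour; its two stop neighbours are
  # excluded from the denominator
  expect_equal(count_sites("TGG"), c(n = 3, s = 0))
  expect_error(count_sites("TAA"), "stop")
  # every sense codon contributes exactly 3 sites in total
  tot <- sum(vapply(SENSE, function(cd) sum(count_sites(cd)), numeric(1)))
  expect_equal(tot, 183)
})

test_that("difference counting averages over stop-free pathways", {
  expect_equal(count_differences("TTT", "TTC"), c(nd = 0, sd = 1))
  # TTT vs GTA: via GTT one nonsyn + one syn; via TTA two nonsyn
  expect_equal(count_differences("TTT", "GTA"), c(nd = 1.5, sd = 0.5))
  expect_equal(count_differences("AAA", "AAA"), c(nd = 0, sd = 0))
  expect_error(count_differences("TGA", "TGG"), "stop")
  # nd + sd always equals the number of differing positions
  set.seed(4)
  for (i in 1:40) {
    pair <- sample(SENSE, 2)
    d <- sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]])
    expect_equal(sum(count_differences(pair[1], pair[2])), d,
                 info = paste(pair, collapse = "/"))
  }
})

test_that("site and difference counts equal brute-force enumeration (spot panel)", {
  # the exhaustive 61 + 61x61 sweep runs in the acceptance suite; here
  # a randomized spot panel guards the day-to-day path
  set.seed(9)
  for (cd in sample(SENSE, 12))
    expect_equal(count_sites(cd), oracle_sites(cd), tolerance = 1e-12,
                 info = cd)
  for (i in 1:25) {
    pr <- sample(SENSE, 2, replace = TRUE)
    expect_equal(count_differences(pr[1], pr[2]),
                 oracle_diffs(pr[1], pr[2]), tolerance = 1e-12,
                 info = paste(pr, collapse = "/"))
  }
})

test_that("Jukes-Cantor correction matches the closed form and saturates", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.10), 0.1073256, tolerance = 1e-6)
  expect_true(jukes_cantor(0.5) > 0.5)  # d >= p
  expect_true(is.na(jukes_cantor(0.75)))
  expect_true(is.na(jukes_cantor(0.8)))
})

test_that("codon-aware alignment back-translates protein gaps in whole codons", {
  a <- generate_ancestral_cds(60, seed = 31)
  aln <- codon_aware_align(a, a)
  expect_true(all(aln$countable))
  expect_equal(aln$codons_a, aln$codons_b)

  # deleting one codon yields exactly one 3-nt gap unit
  codons <- farmfox:::split_codons(a)
  b <- paste0(codons[-30], collapse = "")
  aln2 <- codon_aware_align(a, b)
  expect_equal(sum(aln2$codons_b == "---"), 1)
  expect_equal(length(aln2$codons_a), 60)

  expect_error(codon_aware_align(paste0("ATG", "TAA", "AAA"), a),
               "stop.*codon 2")

  # random indel fixtures keep codon structure: alignment length is a
  # whole number of codons and gaps never split a codon
  set.seed(5)
  for (i in 1:20) {
    x <- generate_ancestral_cds(50, seed = 100 + i)
    xc <- farmfox:::split_codons(x)
    drop <- sample(2:50, sample(1:4, 1))
    y <- paste0(xc[-drop], collapse = "")
    al <- codon_aware_align(x, y)
    expect_true(all(nchar(c(al$codons_a, al$codons_b)) == 3))
    expect_equal(length(al$codons_a), length(al$codons_b))
  }
})

test_that("kaks on an identical pair is zero and undefined", {
  a <- generate_ancestral_cds(100, seed = 41)
  r <- kaks(a, a)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(is.na(r$omega))
  expect_equal(r$flag, "undefined")
  expect_equal(r$N + r$S, 3 * 100)
})

test_that("kaks is symmetric and conserves pathway-weighted differences", {
  p <- evolve_pair(generate_ancestral_cds(200, seed = 51), 1, 80,
                   seed = 52)
  r1 <- kaks(p$a, p$b)
  r2 <- kaks(p$b, p$a)
  for (f in c("N", "S", "Nd", "Sd", "ka", "ks", "omega"))
    expect_equal(r1[[f]], r2[[f]], info = f)
  # Nd + Sd equals the total differing-position count over codons
  ca <- farmfox:::split_codons(p$a)
  cb <- farmfox:::split_codons(p$b)
  ndiff <- sum(mapply(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), ca, cb))
  expect_equal(r1$Nd + r1$Sd, ndiff)
})

test_that("omega estimation recovers simulated selection regimes (small panel)", {
  # a reduced-replicate recovery check; the full 50-replicate sweep
  # with the published band runs in the acceptance suite
  est <- function(om, n = 8) {
    vapply(seq_len(n), function(i) {
      p <- evolve_pair(generate_ancestral_cds(400, seed = 700 + i),
                       om, 150, seed = 800 + i)
      kaks(p$a, p$b)$omega
    }, numeric(1))
  }
  lo <- est(0.2); hi <- est(3)
  expect_true(mean(lo) < 0.5)
  expect_true(all(hi > 1))
})

test_that("kaks_table mirrors the per-gene report layout", {
  a <- c(g1 = generate_ancestral_cds(80, seed = 61))
  p <- evolve_pair(a[[1]], 0.5, 30, seed = 62)
  tab <- kaks_table(c(g1 = p$a), c(g1 = p$b),
                    data.frame(gene_a = "g1", gene_b = "g1"),
                    group = "AF versus BF")
  expect_equal(names(tab), c("gene_a", "gene_b", "ka", "ks", "omega",
                             "flag", "note", "n_codons", "group"))
  expect_equal(tab$group, "AF versus BF")
})
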