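test_that("planted repeats are detected with exact coordinates", {
  set.seed(201)
  bg <- farmfox:::repeat_free_dna(400)
  s <- farmfox:::plant_ssr_bounded(bg, "AC", 7, 101)
  loci <- detect_ssrs(s, seq_id = "u1")
  expect_equal(nrow(loci), 1)
  expect_equal(loci$motif, "AC")
  expect_equal(loci$repeats, 7)
  expect_equal(loci$start, 101)
  expect_equal(loci$end, 114)

  # mononucleotide run of 12 against threshold 10
  s2 <- farmfox:::plant_ssr_bounded(bg, "A", 12, 50)
  l2 <- detect_ssrs(s2)
  expect_equal(l2$repeats, 12)
  expect_equal(l2$unit_size, 1)

  # below-threshold repeats are not reported
  s3 <- farmfox:::plant_ssr_bounded(bg, "AC", 5, 101)
  expect_equal(nrow(detect_ssrs(s3)), 0)
  # repeat-free background reports nothing at all
  expect_equal(nrow(detect_ssrs(bg)), 0)
})

test_that("periodic units are reported at their smallest period only", {
  set.seed(211)
  bg <- farmfox:::repeat_free_dna(300)
  s <- farmfox:::plant_ssr_bounded(bg, "AC", 8, 100)
  loci <- detect_ssrs(s)
  expect_equal(loci$unit_size, 2)  # never reported as ACAC x 4
  hom <- farmfox:::plant_ssr_bounded(bg, "T", 14, 150)
  l2 <- detect_ssrs(hom)
  expect_equal(l2$unit_size, 1)
})

test_that("detection matches the regex oracle over random planted fixtures", {
  thr <- misa_thresholds()
  motifs <- c("G", "AG", "CTG", "AGAT", "AACGT", "ACGCTA")
  set.seed(221)
  for (i in 1:30) {
    m <- motifs[(i - 1) %% 6 + 1]
    reps <- thr[[as.character(nchar(m))]] + sample(0:4, 1)
    s <- farmfox:::plant_ssr_bounded(farmfox:::repeat_free_dna(350),
                                     m, reps, sample(60:120, 1))
    got <- detect_ssrs(s)
    want <- oracle_ssr_scan(s, thr)
    expect_equal(nrow(got), nrow(want), info = paste("rep", i))
    expect_equal(got$start, want$start, info = paste("rep", i))
    expect_equal(got$end, want$end, info = paste("rep", i))
    expect_equal(got$repeats, want$repeats, info = paste("rep", i))
  }
})

test_that("reported loci are maximal and detection is strand-involutive", {
  set.seed(231)
  s <- farmfox:::plant_ssr_bounded(farmfox:::repeat_free_dna(400),
                                   "AGC", 7, 120)
  loci <- detect_ssrs(s)
  expect_equal(nrow(loci), 1)
  # extending by one unit either way breaks perfection
  u <- loci$unit_size
  left <- substr(s, loci$start - u, loci$start - 1)
  right <- substr(s, loci$end + 1, loci$end + u)
  motif_left <- substr(s, loci$start, loci$start + u - 1)
  expect_false(left == motif_left)
  expect_false(right == motif_left)

  rc <- farmfox:::reverse_complement(s)
  loci_rc <- detect_ssrs(rc)
  n <- nchar(s)
  expect_equal(nrow(loci_rc), nrow(loci))
  expect_equal(sort(n - loci$end + 1), sort(loci_rc$start))
  expect_equal(sort(n - loci$start + 1), sort(loci_rc$end))
})

test_that("motif canonicalisation minimises over rotations (and strands on request)", {
  expect_equal(canonical_motif("GA"), "AG")
  expect_equal(canonical_motif("TGA"), "ATG")
  expect_equal(canonical_motif("GT", both_strands = TRUE), "AC")
  expect_equal(canonical_motif("A"), "A")
})

test_that("compound merging groups loci by interruption distance", {
  set.seed(241)
  bg <- farmfox:::repeat_free_dna(600)
  s <- farmfox:::plant_ssr_bounded(bg, "AC", 7, 101)     # ends 114
  s <- farmfox:::plant_ssr_bounded(s, "AG", 6, 125)      # 10 nt spacer
  s <- farmfox:::plant_ssr_bounded(s, "CTG", 6, 400)     # far away
  loci <- detect_ssrs(s, seq_id = "u")
  expect_equal(nrow(loci), 3)
  merged <- merge_compound(loci, max_interruption = 100)
  expect_equal(sum(!is.na(merged$compound_id)), 2)
  expect_length(unique(na.omit(merged$compound_id)), 1)

  # spacer beyond the limit: no compound
  far <- merge_compound(loci, max_interruption = 5)
  expect_true(all(is.na(far$compound_id)))
  # single locus: no compound id
  one <- merge_compound(detect_ssrs(
    farmfox:::plant_ssr_bounded(bg, "AT", 8, 50), seq_id = "u"), 100)
  expect_true(all(is.na(one$compound_id)))
  # unsorted input is rejected
  expect_error(merge_compound(loci[c(2, 1, 3), ], 100), "sorted")
})

test_that("primer feasibility honors flank and product constraints", {
  set.seed(251)
  s <- farmfox:::plant_ssr_bounded(farmfox:::repeat_free_dna(500),
                                   "AC", 7, 240)
  locus <- detect_ssrs(s)[1, ]
  res <- primer_feasible(s, locus)
  expect_true(res$feasible)
  expect_true(nrow(res$windows) >= 1 && nrow(res$windows) <= 3)
  w <- res$windows
  expect_true(all(w$fwd_end < locus$start))
  expect_true(all(w$rev_start > locus$end))
  expect_true(all(w$product_len >= 100 & w$product_len <= 400))
  expect_true(all(w$product_len == w$rev_end - w$fwd_start + 1))
  lens <- c(w$fwd_end - w$fwd_start + 1, w$rev_end - w$rev_start + 1)
  expect_true(all(lens >= 18 & lens <= 22))

  # locus too close to the sequence end: no downstream flank
  s2 <- farmfox:::plant_ssr_bounded(farmfox:::repeat_free_dna(300),
                                    "AC", 7, 283)
  expect_false(primer_feasible(s2, detect_ssrs(s2)[1, ])$feasible)
  # sequence shorter than the minimum product
  s3 <- farmfox:::plant_ssr_bounded(farmfox:::repeat_free_dna(80),
                                    "AC", 6, 30)
  l3 <- detect_ssrs(s3)[1, ]
  expect_false(primer_feasible(s3, l3)$feasible)
})

test_that("misa-layout writer and summary table are consistent", {
  set.seed(261)
  seqs <- c(u1 = farmfox:::plant_ssr_bounded(
              farmfox:::repeat_free_dna(300), "AC", 7, 100),
            u2 = farmfox:::plant_ssr_bounded(
              farmfox:::repeat_free_dna(300), "TTG", 6, 80))
  loci <- merge_compound(detect_ssrs_set(seqs))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_misa(loci, tmp)
  tab <- read.table(tmp, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(nrow(tab), nrow(loci))
  expect_equal(tab$ID, loci$seq_id)
  expect_equal(tab$size, loci$end - loci$start + 1)
  smry <- ssr_summary(loci)
  expect_equal(sum(smry$n_loci), nrow(loci))
  expect_equal(ssr_summary(loci, include_mono = FALSE)$unit_size,
               smry$unit_size[smry$unit_size > 1])
})
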