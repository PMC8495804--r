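make_column <- function(default, ...) {
  col <- setNames(rep(default, length(PANEL13)), PANEL13)
  over <- list(...)
  col[names(over)] <- unlist(over)
  col
}

test_that("column classification covers the three lineage categories", {
  # wild pair carries R where every other taxon is W
  hit <- classify_column(make_column("W", AF = "R", RF = "R"),
                         PANEL13_GROUPS)
  expect_equal(hit$category, "wild_specific")
  expect_setequal(hit$focal, c("AF", "RF"))
  expect_equal(hit$background, "W")
  expect_equal(hit$derived, "R")

  # silver fox alone carries N against an invariant K
  hit2 <- classify_column(make_column("K", SF = "N"), PANEL13_GROUPS)
  expect_equal(hit2$category, "farmed_species_specific")
  expect_equal(hit2$focal, "SF")

  # both farmed foxes share a residue absent elsewhere
  hit3 <- classify_column(make_column("L", BF = "Q", SF = "Q"),
                          PANEL13_GROUPS)
  expect_equal(hit3$category, "shared_farmed")

  # panel polymorphism breaks the conservation requirement
  expect_null(classify_column(
    make_column("W", AF = "R", RF = "R", cow = "Y"), PANEL13_GROUPS))
  # invariant column, or focal residue equal to background: nothing
  expect_null(classify_column(make_column("K"), PANEL13_GROUPS))
  # ambiguous residues skip the column
  expect_null(classify_column(make_column("K", SF = "N", dog = "X"),
                              PANEL13_GROUPS))
})

test_that("a fox taxon outside the focal set must match the background exactly", {
  # even with a relaxed panel tolerance, a farmed fox deviating from
  # the background blocks a wild_specific call
  col <- make_column("W", AF = "R", RF = "R", BF = "S")
  expect_null(classify_column(col, PANEL13_GROUPS, max_mismatch = 2))
  # panel tolerance does admit panel deviations when requested
  col2 <- make_column("W", AF = "R", RF = "R", cow = "Y")
  expect_null(classify_column(col2, PANEL13_GROUPS, max_mismatch = 0))
  hit <- classify_column(col2, PANEL13_GROUPS, max_mismatch = 1)
  expect_equal(hit$category, "wild_specific")
})

test_that("screen_gene reproduces the three reported fox substitutions", {
  base <- generate_ancestral_cds(200, seed = 101)
  plants <- do.call(rbind, reference_plants())
  panel <- generate_panel(base, plants, PANEL13)
  hits <- screen_gene(panel_alignment("fox3", panel, PANEL13_GROUPS))
  expect_equal(nrow(hits), 3)
  expect_setequal(hits$nt_site, c(235, 527, 153))
  expect_equal(sort(hits$category),
               c("farmed_species_specific", "farmed_species_specific",
                 "wild_specific"))
  w <- hits[hits$nt_site == 235, ]
  expect_equal(w$background_aa, "W"); expect_equal(w$derived_aa, "R")
  expect_equal(w$focal_taxa, "AF,RF")
  q <- hits[hits$nt_site == 527, ]
  expect_equal(q$background_aa, "L"); expect_equal(q$derived_aa, "Q")
  n <- hits[hits$nt_site == 153, ]
  expect_equal(n$background_aa, "K"); expect_equal(n$derived_aa, "N")
  # every flagged site translates consistently
  expect_false(any(hits$background_aa == hits$derived_aa))
  expect_true(all(hits$nt_site >= 3 * (hits$codon_index - 1) + 1 &
                    hits$nt_site <= 3 * hits$codon_index))
})

test_that("identical panels yield no hits; planted truth is recovered exactly", {
  base <- generate_ancestral_cds(150, seed = 111)
  empty <- screen_gene(panel_alignment(
    "flat", generate_panel(base, reference_plants()[[1]][0, ], PANEL13),
    PANEL13_GROUPS))
  expect_equal(nrow(empty), 0)

  # ten random plants, truth-table recovery
  set.seed(121)
  idx <- sort(sample(2:150, 10))
  plants <- list(); truth_sites <- integer(0)
  for (ci in idx) {
    focal <- sample(list("SF", "BF", c("AF", "RF"), c("BF", "SF")), 1)[[1]]
    repeat {
      bg <- sample(SENSE, 1)
      pos <- sample(1:3, 1)
      alts <- setdiff(BASES, substr(bg, pos, pos))
      de <- bg; substr(de, pos, pos) <- sample(alts, 1)
      if (!de %in% STOPS &&
          GC_TAB[[de]] != GC_TAB[[bg]]) break
    }
    plants[[length(plants) + 1]] <- plant_spec(ci, focal, bg, de)
    truth_sites <- c(truth_sites, 3 * (ci - 1) + pos)
  }
  panel <- generate_panel(base, do.call(rbind, plants), PANEL13)
  hits <- screen_gene(panel_alignment("rnd", panel, PANEL13_GROUPS))
  expect_equal(sort(hits$nt_site), sort(truth_sites))
})

test_that("screening is invariant to taxon order and monotone under panel growth", {
  base <- generate_ancestral_cds(120, seed = 131)
  plants <- rbind(plant_spec(20, "SF", "AAG", "AAC"),
                  plant_spec(60, c("AF", "RF"), "TGG", "AGG"))
  panel <- generate_panel(base, plants, PANEL13)
  pa <- panel_alignment("g", panel, PANEL13_GROUPS)
  hits <- screen_gene(pa)

  perm <- sample(PANEL13)
  pa2 <- panel_alignment("g", panel[perm], PANEL13_GROUPS)
  hits2 <- screen_gene(pa2)
  expect_equal(hits, hits2)

  # adding a panel taxon can only remove sites, never add new ones
  bigger <- c(panel, camel = unname(panel[["cow"]]))
  groups2 <- c(PANEL13_GROUPS, camel = "panel")
  hits3 <- screen_gene(panel_alignment("g", bigger, groups2))
  expect_true(all(hits3$nt_site %in% hits$nt_site))
})

test_that("multi-nucleotide codon differences are flagged with the first site", {
  base <- generate_ancestral_cds(50, seed = 141)
  # install AAA background and CCA in SF by direct surgery (two
  # differing positions within codon 10)
  taxa_seqs <- generate_panel(base, reference_plants()[[1]][0, ], PANEL13)
  for (t in PANEL13) substr(taxa_seqs[[t]], 28, 30) <- "AAA"
  substr(taxa_seqs[["SF"]], 28, 30) <- "CCA"
  hits <- screen_gene(panel_alignment("g", taxa_seqs, PANEL13_GROUPS))
  expect_equal(nrow(hits), 1)
  expect_true(hits$multi_nt)
  expect_equal(hits$nt_site, 28)  # first differing position of codon 10
})

test_that("quartet-level screening aggregates and warns on missing panels", {
  base <- generate_ancestral_cds(100, seed = 151)
  plants <- reference_plants()$IGBP1
  panel <- generate_panel(base, plants, PANEL13)
  quartets <- data.frame(gene = c("gA", "gB"), AF = c("gA", "gB"),
                         BF = c("gA", "gB"), RF = c("gA", "gB"),
                         SF = c("gA", "gB"), stringsAsFactors = FALSE)
  panels <- list(gA = panel_alignment("gA", panel, PANEL13_GROUPS))
  expect_warning(rep <- screen_quartets(quartets, panels), "gB")
  expect_equal(rep$gene, "gA")
  expect_equal(rep$nt_site, 153)
  # no panels at all: as many warnings as genes, empty report
  w <- testthat::capture_warnings(
    rep0 <- screen_quartets(quartets, list()))
  expect_length(w, 2)
  expect_equal(nrow(rep0), 0)
})
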