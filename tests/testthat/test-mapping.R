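test_that("an exact substring maps uniquely with zero mismatches", {
  g <- plastome(random_seq(600, seed = 61), circular = FALSE)
  rd <- tibble::tibble(id = "r1", seq = substr(g$seq, 101, 125))
  al <- map_reads(rd, g)
  expect_equal(nrow(al), 1)
  expect_equal(al$start, 101)
  expect_equal(al$strand, "+")
  expect_equal(al$mismatches, 0)
  expect_equal(al$multi_hits, 1)
})

test_that("reads beyond the mismatch budget are reported unmapped", {
  g <- plastome(random_seq(600, seed = 62), circular = FALSE)
  r <- substr(g$seq, 201, 230)
  for (i in c(3, 12, 25)) substr(r, i, i) <- comp_char(substr(r, i, i))
  al <- map_reads(tibble::tibble(id = "mut3", seq = r), g, max_mismatch = 2)
  expect_equal(nrow(al), 0)
  expect_equal(unmapped_reads(al), "mut3")
  # the same read passes with a looser budget
  al2 <- map_reads(tibble::tibble(id = "mut3", seq = r), g, max_mismatch = 3)
  expect_equal(al2$start, 201)
  expect_equal(al2$mismatches, 3)
})

test_that("reads from an inverted repeat hit both copies", {
  sim <- make_plastome(2000, 400, 600, seed = 63)
  irb <- sim$partition$regions
  s <- irb$start[irb$region == "IRb"] + 100
  rd <- tibble::tibble(id = "ir_read", seq = substr(sim$genome$seq, s, s + 29))
  al <- map_reads(rd, sim$genome, max_mismatch = 0)
  expect_equal(nrow(al), 2)
  expect_equal(unique(al$multi_hits), 2)
  expect_setequal(al$strand, c("+", "-"))
  al1 <- map_reads(rd, sim$genome, max_mismatch = 0, report_multi = FALSE)
  expect_equal(nrow(al1), 1)
  expect_equal(al1$start, min(al$start))
  expect_equal(al1$multi_hits, 2)
})

test_that("mapping agrees with the naive all-positions Hamming scan", {
  g <- plastome(random_seq(400, seed = 64))
  withr::with_seed(65, {
    reads <- purrr::map_dfr(1:12, function(i) {
      s <- sample(380, 1)
      r <- plastex:::circ_substr(g$seq, s, 22)
      if (i %% 2 == 0) r <- revcomp(r)
      nmut <- sample(0:3, 1)
      for (p in sample(22, nmut)) substr(r, p, p) <- comp_char(substr(r, p, p))
      tibble::tibble(id = sprintf("r%02d", i), seq = r)
    })
  })
  al <- map_reads(reads, g, max_mismatch = 2)
  for (id in reads$id) {
    want <- oracle_map_read(reads$seq[reads$id == id], g$seq, 2)
    got <- al[al$read_id == id, c("start", "strand", "mismatches")]
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE, info = id)
  }
})

test_that("mapping is symmetric under reverse-complementing read and genome", {
  g <- plastome(random_seq(300, seed = 66), circular = FALSE)
  g_rc <- plastome(revcomp(g$seq), circular = FALSE)
  rd <- substr(g$seq, 41, 70)
  al_fwd <- map_reads(tibble::tibble(id = "r", seq = rd), g, max_mismatch = 1)
  al_rc <- map_reads(tibble::tibble(id = "r", seq = revcomp(rd)), g_rc, max_mismatch = 1)
  # same placement, mirrored coordinates and strand
  expect_equal(al_rc$start, 300 - (al_fwd$start + 30 - 1) + 1)
  expect_equal(al_fwd$mismatches, al_rc$mismatches)
})

test_that("circular genomes allow origin-spanning placements", {
  g <- plastome(random_seq(500, seed = 67), circular = TRUE)
  rd <- paste0(substr(g$seq, 491, 500), substr(g$seq, 1, 10))
  al <- map_reads(tibble::tibble(id = "wrap", seq = rd), g, max_mismatch = 0)
  expect_true(491 %in% al$start)
  lin <- plastome(g$seq, circular = FALSE)
  expect_equal(nrow(map_reads(tibble::tibble(id = "wrap", seq = rd), lin,
                              max_mismatch = 0)), 0)
})

test_that("pileup columns tally per-strand bases in genome space", {
  g <- plastome(random_seq(200, seed = 68), circular = FALSE)
  rd <- tibble::tibble(id = "r", seq = substr(g$seq, 50, 74))
  al <- map_reads(rd, g)
  pile <- build_pileup(al, rd, g)
  expect_equal(sort(unique(pile$position)), 50:74)
  expect_true(all(pile$count == 1))
  totals <- pileup_totals(pile)
  expect_equal(totals$coverage, rep(1, 25))
  # a minus-strand read contributes complemented bases at the same positions
  rd2 <- tibble::tibble(id = "m", seq = revcomp(substr(g$seq, 50, 74)))
  al2 <- map_reads(rd2, g)
  expect_equal(al2$strand, "-")
  pile2 <- build_pileup(al2, rd2, g)
  expect_equal(dplyr::select(pile2, -"strand"), dplyr::select(pile, -"strand"))
})

test_that("a mixed column reproduces published-style base counts", {
  g <- plastome(random_seq(300, seed = 69), circular = FALSE)
  site <- 150L
  stopifnot(substr(g$seq, site, site) != "C")
  base_read <- substr(g$seq, 131, 160)
  ref_read <- base_read
  substr(ref_read, 20, 20) <- "C"   # 27 reads agree with C
  alt_read <- base_read
  substr(alt_read, 20, 20) <- "T"   # 11 reads carry T
  gmod <- plastome(paste0(substr(g$seq, 1, 149), "C", substr(g$seq, 151, 300)),
                   circular = FALSE)
  reads <- tibble::tibble(
    id = sprintf("r%02d", 1:38),
    seq = c(rep(ref_read, 27), rep(alt_read, 11))
  )
  al <- map_reads(reads, gmod, max_mismatch = 2)
  pile <- build_pileup(al, reads, gmod)
  tot <- pileup_totals(pile)
  row <- tot[tot$position == site, ]
  expect_equal(row$C, 27)
  expect_equal(row$T, 11)
  expect_equal(row$coverage, 38)
})

test_that("pileup totals equal independent overlap counting", {
  sim <- make_plastome(1500, 300, 300, seed = 70)
  g <- plant_genes(sim$genome, sim$partition, n_genes = 3, n_intron_genes = 0,
                   n_ir_duplicates = 0, exon_len = 180, seed = 71)
  rs <- simulate_rnaseq(sim$genome, g, n_fragments = 120, read_len = 50,
                        fragment_len = 120, error_rate = 0, seed = 72)
  al <- map_reads(rs$reads, sim$genome, max_mismatch = 0)
  pile <- build_pileup(al, rs$reads, sim$genome)
  expect_equal(sum(pile$count), sum(al$read_length))
  cov <- oracle_coverage(al, plastome_length(sim$genome))
  tot <- pileup_totals(pile)
  expect_equal(tot$coverage, cov[tot$position])
  expect_true(all(cov[-tot$position] == 0))
})

test_that("length filtering keeps the requested range and its complement", {
  reads <- tibble::tibble(id = paste0("r", 1:4),
                          seq = strrep("A", c(18, 20, 24, 31)))
  kept <- filter_reads_by_length(reads, 20, 24)
  expect_equal(kept$id, c("r2", "r3"))
  expect_equal(attr(kept, "rejected")$id, c("r1", "r4"))
  expect_equal(nrow(filter_reads_by_length(reads[0, ], 20, 24)), 0)
})
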