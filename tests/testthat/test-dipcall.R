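test_that("coverage counts primary records per position", {
  aln <- make_aln("T1", 10, 20, c(T1 = 30L))
  prof <- transcript_coverage(aln, "T1")
  expect_equal(prof$depth, c(rep(0L, 10), rep(1L, 10), rep(0L, 10)))

  aln2 <- make_aln("T1", c(0, 10), c(30, 20), c(T1 = 30L))
  prof2 <- transcript_coverage(aln2, "T1")
  expect_equal(prof2$depth, c(rep(1L, 10), rep(2L, 10), rep(1L, 10)))

  # uniform full-length reads: relative depth 1 everywhere
  aln3 <- make_aln("T1", rep(0, 25), rep(30, 25), c(T1 = 30L))
  expect_equal(transcript_coverage(aln3, "T1")$relative, rep(1, 30))
  expect_error(transcript_coverage(aln3, "NOPE"), "unknown transcript")
})

test_that("coverage conserves the total aligned bases", {
  set.seed(21)
  s <- sample(0:400, 300, replace = TRUE)
  e <- pmin(s + sample(30:200, 300, replace = TRUE), 500L)
  aln <- make_aln("T1", s, e, c(T1 = 500L))
  prof <- transcript_coverage(aln, "T1")
  expect_equal(sum(prof$depth), sum(e - s))
  expect_equal(mean(prof$relative), 1, tolerance = 1e-12)
})

test_that("a constructed dip is called at its exact interval", {
  # depth 100 everywhere except 40 on [200, 215) of a 600 nt transcript
  aln <- make_aln("T1",
                  c(rep(0, 40), rep(0, 60), rep(215, 60)),
                  c(rep(600, 40), rep(200, 60), rep(600, 60)),
                  c(T1 = 600L))
  prof <- transcript_coverage(aln, "T1")
  expect_equal(unique(prof$depth[201:215]), 40L)
  dips <- detect_dips(prof)
  expect_equal(nrow(dips), 1L)
  expect_equal(dips$start, 200L)
  expect_equal(dips$end, 215L)
  expect_equal(dips$depth_ratio, 0.4, tolerance = 1e-9)

  # flat profile: nothing
  flat <- make_aln("T1", rep(0, 100), rep(600, 100), c(T1 = 600L))
  expect_equal(nrow(detect_dips(transcript_coverage(flat, "T1"))), 0L)
})

test_that("width, edge and depth rules filter candidate dips", {
  mk_dip <- function(at, width, L = 600L, deep = 40, base = 100) {
    make_aln("T1",
             c(rep(0, deep), rep(0, base - deep), rep(at + width, base - deep)),
             c(rep(L, deep), rep(at, base - deep), rep(L, base - deep)),
             c(T1 = L))
  }
  # width 5 < width_range[1]: rejected
  expect_equal(nrow(detect_dips(transcript_coverage(mk_dip(200, 5), "T1"))), 0L)
  # width 40 > width_range[2]: rejected
  expect_equal(nrow(detect_dips(transcript_coverage(mk_dip(200, 40), "T1"))), 0L)
  # dip at 10 nt from the start: inside edge_exclusion
  expect_equal(nrow(detect_dips(transcript_coverage(mk_dip(10, 15), "T1"))), 0L)
  # shallow dip (ratio 0.8): not below threshold
  aln <- make_aln("T1", c(rep(0, 80), rep(0, 20), rep(215, 20)),
                  c(rep(600, 80), rep(200, 20), rep(600, 20)), c(T1 = 600L))
  expect_equal(nrow(detect_dips(transcript_coverage(aln, "T1"))), 0L)
  # low coverage: skipped with a message
  lowc <- make_aln("T1", rep(0, 5), rep(600, 5), c(T1 = 600L))
  expect_message(out <- detect_dips(transcript_coverage(lowc, "T1")), "mean depth")
  expect_equal(nrow(out), 0L)
})

test_that("close dips merge and distinct dips stay separate", {
  # two deficits separated by 2 positions merge into one run
  base <- make_aln("T1", rep(0, 100), rep(600, 100), c(T1 = 600L))
  prof <- transcript_coverage(base, "T1")
  d <- prof$depth
  d[201:208] <- 30L; d[211:218] <- 30L     # gap of 2 at 209:210
  prof$depth <- d
  dips <- detect_dips(prof)
  expect_equal(nrow(dips), 1L)
  # gap of 2 sits above threshold so refinement keeps the wider candidate run
  expect_lte(dips$start, 202L)
  expect_gte(dips$end, 216L)

  d2 <- prof$depth
  d2[201:218] <- 100L
  d2[101:112] <- 30L; d2[301:312] <- 30L   # far apart: two dips
  prof$depth <- d2
  expect_equal(nrow(detect_dips(prof)), 2L)
})

test_that("cleavage positions go to the uracil nearest the dip 5' boundary", {
  # "AAUGCCGG" with dip [3, 6): U at index 2, context UG
  dips <- data.frame(transcript_id = "S1", start = 3L, end = 6L,
                     depth_ratio = 0.3, baseline = 100)
  out <- assign_cleavage_sites(dips, c(S1 = "AAUGCCGG"))
  expect_equal(out$position, 2L)
  expect_equal(out$dinucleotide, "UG")

  # no U in the window: position absent, dip retained
  out2 <- assign_cleavage_sites(data.frame(transcript_id = "S2", start = 10L,
                                           end = 20L, depth_ratio = 0.3,
                                           baseline = 1),
                                c(S2 = paste(rep("GCA", 12), collapse = "")))
  expect_true(is.na(out2$position))
  expect_equal(nrow(out2), 1L)

  # U at the dip start (distance 0) beats a U two positions upstream
  s3 <- paste0(strrep("G", 8), "U", "G", "U", strrep("GC", 10))  # U at 8 and 10
  out3 <- assign_cleavage_sites(data.frame(transcript_id = "S3", start = 10L,
                                           end = 22L, depth_ratio = 0.3,
                                           baseline = 1), c(S3 = s3))
  expect_equal(out3$position, 10L)

  # equidistant interior/upstream candidates resolve upstream
  s4 <- paste0(strrep("G", 9), "U", "G", "U", strrep("GC", 10))  # U at 9 and 11
  out4 <- assign_cleavage_sites(data.frame(transcript_id = "S4", start = 10L,
                                           end = 22L, depth_ratio = 0.3,
                                           baseline = 1), c(S4 = s4))
  expect_equal(out4$position, 9L)
})

test_that("the context PFM, information content and dinucleotide table agree", {
  # all sites UG in identical 13-mers
  seqs <- c(A1 = "GGGGGUGGGGGG", A2 = "CCCCCUGCCCCC")
  calls <- data.frame(transcript_id = c("A1", "A2"), start = 6L, end = 10L,
                      position = 5L)
  cs <- cleavage_context_pfm(calls, seqs, flank = 3)
  expect_equal(unname(cs$pfm["U", "0"]), 1)
  expect_equal(unname(cs$pfm["G", "1"]), 1)
  expect_equal(unname(cs$information[["0"]]), 2)
  expect_equal(unname(cs$information[["1"]]), 2)
  expect_equal(colSums(cs$pfm), rep(1, 7), ignore_attr = TRUE)
  expect_equal(unname(cs$dinucleotides["UG"]), 2L)

  # uniform composition at +1: IC 0 there
  seqs2 <- setNames(paste0("GGGGGU", c("A", "C", "G", "U"), "GGGGG"),
                    paste0("B", 1:4))
  calls2 <- data.frame(transcript_id = names(seqs2), start = 6L, end = 10L,
                       position = 5L)
  cs2 <- cleavage_context_pfm(calls2, seqs2, flank = 3)
  expect_equal(unname(cs2$information[["1"]]), 0, tolerance = 1e-12)
  expect_equal(unname(cs2$information[["0"]]), 2)

  # windows beyond transcript ends are excluded; none left -> error
  calls3 <- data.frame(transcript_id = "A1", start = 1L, end = 4L, position = 0L)
  expect_error(cleavage_context_pfm(calls3, seqs, flank = 3), "full context")
  expect_error(cleavage_context_pfm(
    data.frame(transcript_id = "A1", start = 1L, end = 4L,
               position = NA_integer_), seqs), "no assigned")
})

test_that("mapped-length statistics summarize and honor exclusions", {
  aln <- make_aln(c("T1", "T1", "H2"), c(0, 0, 0), c(1000, 500, 900),
                  c(T1 = 1000L, H2 = 900L))
  aln$transcript_id <- c("T1", "T1", "H2")
  st <- mapped_length_stats(aln)
  expect_equal(sort(st$per_read$ratio), c(0.5, 1.0, 1.0))
  expect_equal(st$summary$full_length_fraction, 2 / 3)

  st2 <- mapped_length_stats(aln, exclusions = "H2")
  expect_equal(st2$summary$median_ratio, 0.75)      # ratios {1.0, 0.5}
  expect_equal(st2$summary$n_reads, 2L)
  # all full length
  aln3 <- make_aln("T1", rep(0, 4), rep(1000, 4), c(T1 = 1000L))
  expect_equal(mapped_length_stats(aln3)$summary$full_length_fraction, 1.0)
})

test_that("dips replicate across independent simulations of one ground truth", {
  tx <- make_flat_tx(30, len = c(1200, 1200), abundance = 400, seed = 51)
  seqs <- setNames(tx$transcripts$sequence, tx$transcripts$id)
  truth <- plant_spaced_positions(seqs, seed = 52)
  sites <- manual_sites(tx, truth, weight = 10)
  m <- cleavage_model()
  calls <- lapply(c(101, 202), function(s) {
    pool <- simulate_fragment_pool(tx, sites, m, 200, seed = s)
    aln <- simulate_read_alignments(pool, depth = 1, seed = s + 1)
    call_cleavage_dips(aln, sequences = seqs)
  })
  expect_gte(dip_jaccard(calls[[1]], calls[[2]]), 0.7)
})
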