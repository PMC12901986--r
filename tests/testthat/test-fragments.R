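flat_curve <- function(level, times = c(0, 100)) {
  data.frame(time = times, level = rep(level, length(times)))
}

test_that("no activation and no target hazard leaves every molecule intact", {
  tx <- make_flat_tx(5, len = c(500, 800), abundance = 50, seed = 2)
  m <- cleavage_model(activation_curve = flat_curve(0))
  sites <- plant_cleavage_sites(tx, m, density = 5, seed = 2)
  pool <- simulate_fragment_pool(tx, sites, m, timepoint = 100, seed = 3)
  lens <- attr(pool, "transcript_lengths")
  expect_true(all(pool$start == 0L))
  expect_equal(pool$end, unname(lens[pool$transcript_id]))
  expect_true(all(pool$has_native_polyA))
  expect_equal(cut_fraction(pool), 0)
})

test_that("a certain cut yields exactly two fragments split at the site", {
  tx <- make_tx(c(ONE = random_rna_seq(400, seed = 5)), abundance = 200)
  seqc <- strsplit(tx$transcripts$sequence, "")[[1]]
  p <- which(seqc == "U")[10] - 1L
  sites <- manual_sites(tx, list(ONE = p), weight = 1e9)   # p(cut) = 1
  m <- cleavage_model(activation_curve = flat_curve(1),
                      class_multipliers = c(protein_coding = 1, mito_mRNA = 0,
                                            nuclear_ncRNA = 0, spike_in = 0))
  pool <- simulate_fragment_pool(tx, sites, m, 100, seed = 7)
  per <- data.table::as.data.table(pool)[, .N, by = molecule]
  expect_true(all(per$N == 2L))
  expect_setequal(unique(pool$start), c(0L, p + 1L))
  expect_setequal(unique(pool$end), c(p + 1L, 400L))
})

test_that("realized cut fraction matches the binomial oracle at p = 0.5", {
  # hazard chosen so 1 - exp(-A w m a) = 0.5 exactly; 10^4 molecules
  tx <- make_tx(c(B = random_rna_seq(600, seed = 6)), abundance = 10000)
  p <- which(strsplit(tx$transcripts$sequence, "")[[1]] == "U")[20] - 1L
  sites <- manual_sites(tx, list(B = p), weight = log(2))
  m <- cleavage_model(activation_curve = flat_curve(1), abundance_slope = 0,
                      class_multipliers = c(protein_coding = 1, mito_mRNA = 0,
                                            nuclear_ncRNA = 0, spike_in = 0))
  pool <- simulate_fragment_pool(tx, sites, m, 100, seed = 9)
  # 99% binomial band for n = 10^4 (n is Poisson(10^4); band is conservative
  # for the observed count within 2%)
  f <- cut_fraction(pool)
  expect_gt(f, 0.485)
  expect_lt(f, 0.515)
})

test_that("fragments of each molecule tile it without overlap", {
  tx <- build_transcriptome(n_transcripts = 40, seed = 4)
  m <- cleavage_model()
  sites <- plant_cleavage_sites(tx, m, seed = 4)
  pool <- simulate_fragment_pool(tx, sites, m, 200, n_molecules_scale = 0.5, seed = 5)
  lens <- attr(pool, "transcript_lengths")
  dt <- data.table::as.data.table(pool)
  per <- dt[, .(tot = sum(end - start), n = .N,
                ok = all(start[order(start)][-1] == end[order(end)][-.N]) || .N == 1),
            by = .(transcript_id, molecule)]
  expect_equal(per$tot, unname(lens[per$transcript_id]))
  expect_true(all(per$ok))
  # exactly one poly(A) fragment per molecule
  pa <- dt[, sum(has_native_polyA), by = .(transcript_id, molecule)]
  expect_true(all(pa$V1 == 1L))
})

test_that("spike-ins are never cut, under any parameterization", {
  tx <- build_transcriptome(n_transcripts = 40, seed = 8)
  m <- cleavage_model(site_weights = c(UA = 100, UC = 100, UG = 100, UU = 100),
                      loop_mask_fraction = 1,
                      activation_curve = flat_curve(1, c(0, 200)))
  sites <- plant_cleavage_sites(tx, m, density = 20, seed = 8)
  pool <- simulate_fragment_pool(tx, sites, m, 200, n_molecules_scale = 2, seed = 9)
  spikes <- tx$transcripts$id[tx$transcripts$biotype == "spike_in"]
  sp <- data.table::as.data.table(pool)[transcript_id %in% spikes]
  expect_gt(nrow(sp), 0)
  expect_true(all(sp$start == 0L))
  expect_equal(cut_fraction(pool, tx, "spike_in"), 0)
  # mito and nuclear ncRNA classes are likewise immune under defaults
  expect_equal(cut_fraction(simulate_fragment_pool(
    tx, plant_cleavage_sites(tx, cleavage_model(), seed = 8),
    cleavage_model(), 200, n_molecules_scale = 2, seed = 9), tx, "mito_mRNA"), 0)
})

test_that("cleavage peaks at 100-200 min and relaxes by 24 h", {
  tx <- build_transcriptome(n_transcripts = 80, seed = 10)
  m <- cleavage_model()
  sites <- plant_cleavage_sites(tx, m, seed = 10)
  cf <- vapply(c(0, 100, 200, 1440), function(tp)
    cut_fraction(simulate_fragment_pool(tx, sites, m, tp,
                                        n_molecules_scale = 2, seed = 11)),
    numeric(1))
  expect_gt(cf[2], cf[1])   # 100 min > 0 min
  expect_gt(cf[3], cf[1])   # 200 min > 0 min
  expect_gt(cf[2], cf[4])   # 100 min > 1440 min
  expect_gt(cf[3], cf[4])
})

test_that("US-weighted cutting exceeds the equal-weight multinomial share", {
  # 2 US + 2 UW sites with weights 10 vs 1: expected US share of realized
  # cuts is 2p10/(2p10 + 2p1) with p_w = 1 - exp(-w m); equal weights give 1/2
  tx <- make_tx(c(CTX = random_rna_seq(3000, seed = 12)), abundance = 2000)
  seqc <- strsplit(tx$transcripts$sequence, "")[[1]]
  us_pos <- which(seqc == "U" & c(seqc[-1], "") %in% c("G", "C")) - 1L
  uw_pos <- which(seqc == "U" & c(seqc[-1], "") %in% c("A", "U")) - 1L
  pos <- sort(c(us_pos[c(10, 20)], uw_pos[c(10, 20)]))
  mlt <- 0.1
  m <- cleavage_model(activation_curve = flat_curve(1), abundance_slope = 0,
                      class_multipliers = c(protein_coding = mlt, mito_mRNA = 0,
                                            nuclear_ncRNA = 0, spike_in = 0))
  sites <- manual_sites(tx, list(CTX = pos), weight = 1)
  sites$CTX$weight <- unname(m$site_weights[sites$CTX$dinucleotide])
  pool <- simulate_fragment_pool(tx, sites, m, 100, seed = 13)
  cuts <- data.table::as.data.table(pool)[start > 0, .N, by = start]
  cut_pos <- cuts$start - 1L
  n_us <- sum(cuts$N[cut_pos %in% us_pos])
  n_uw <- sum(cuts$N[cut_pos %in% uw_pos])
  p10 <- 1 - exp(-10 * mlt); p1 <- 1 - exp(-1 * mlt)
  expected_share <- p10 / (p10 + p1)
  share <- n_us / (n_us + n_uw)
  expect_gt(share, 0.5)                         # beats equal-weight multinomial
  expect_equal(share, expected_share, tolerance = 0.05)  # matches the oracle
})

test_that("unknown timepoints are rejected with the available list", {
  tx <- make_flat_tx(2, seed = 1)
  m <- cleavage_model()
  sites <- plant_cleavage_sites(tx, m, seed = 1)
  expect_error(simulate_fragment_pool(tx, sites, m, 123, seed = 1),
               "available: 0, 50, 100, 200, 500, 1440")
})

test_that("fragment pools are bit-reproducible under a fixed seed", {
  tx <- build_transcriptome(n_transcripts = 20, seed = 3)
  m <- cleavage_model()
  sites <- plant_cleavage_sites(tx, m, seed = 3)
  a <- simulate_fragment_pool(tx, sites, m, 200, seed = 21)
  b <- simulate_fragment_pool(tx, sites, m, 200, seed = 21)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- simulate_fragment_pool(tx, sites, m, 200, seed = 22)
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
})

test_that("guide-directed target cleavage cuts at the protospacer from t = 0", {
  tx <- make_tx(c(TGT = random_rna_seq(500, seed = 14)), abundance = 300)
  ps <- c(100L, 128L)
  m <- cleavage_model(activation_curve = flat_curve(0, c(0, 100)),
                      target_id = "TGT", target_hazard = 1, protospacer = ps)
  sites <- manual_sites(tx, list(TGT = integer(0)))
  pool <- simulate_fragment_pool(tx, sites, m, 0, seed = 15)
  mid <- floor((ps[1] + ps[2]) / 2)
  expect_setequal(unique(pool$start), c(0L, mid + 1L))

  m2 <- cleavage_model(activation_curve = flat_curve(0, c(0, 100)),
                       target_id = "TGT", target_hazard = 1, protospacer = ps,
                       target_cut_mode = "nearest_u")
  pool2 <- simulate_fragment_pool(tx, sites, m2, 0, seed = 15)
  seqc <- strsplit(tx$transcripts$sequence, "")[[1]]
  last_u <- max(which(seqc[seq_len(mid + 1)] == "U")) - 1L
  expect_setequal(unique(pool2$start), c(0L, last_u + 1L))
})
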