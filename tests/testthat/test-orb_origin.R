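# The ten co-aligned 22-base ORB motifs reported for the three genomes
# (used for the consensus check); col 16 is a 5:5 A/G tie.
orb_motif_set <- c(
  "GTTCCAGTGGAAATGGTGGGGT", "GTTCCACTGGAAACAGAGGGGT",
  "TTTCCACTGGAAACAGAGGGGT", "GTTCCACTGGAAATGGTGGGGT",
  "ATTACAGTGGAAATGAAGGGGT", "TTTGCAGTGGAAATGAAGGGGT",
  "GTTCCAGTGGAAATGAAGGGGT", "TCTGCACTGGAAATGAAGGGGT",
  "GTTCCATTGGAAATCGGCAGGA", "GTTCCAGTGGAAATAAAGGGGT")

test_that("exact cores are found on the forward and reverse strand", {
  core <- orb_core_default()
  g <- genome_record("g", core, "linear")
  h <- scan_motif(g, orb_motif(core, 0))
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, 1L)
  expect_identical(h$end, 22L)
  expect_identical(h$strand, "+")
  expect_identical(h$mismatches, 0L)
  g2 <- genome_record("g", revcomp(core), "linear")
  h2 <- scan_motif(g2, orb_motif(core, 0))
  expect_identical(h2$strand, "-")
  expect_identical(h2$matched_sequence, core)
})

test_that("scanning matches the brute-force Hamming oracle", {
  core <- orb_core_default()
  for (seed in 1:5) {
    g <- random_genome(20000, seed = 400 + seed)
    for (mm in c(2L, 4L)) {
      got <- scan_motif(g, orb_motif(core, mm))
      want <- oracle_hamming_scan(g$sequence, core, mm)
      expect_identical(got$start, want$start)
      expect_identical(got$strand, want$strand)
      expect_identical(got$mismatches, want$mismatches)
    }
  }
})

test_that("hit sets are monotone in the mismatch allowance", {
  g <- random_genome(30000, seed = 88)
  h3 <- scan_motif(g, orb_motif(max_mismatch = 3))
  h4 <- scan_motif(g, orb_motif(max_mismatch = 4))
  key <- function(h) paste(h$start, h$strand)
  expect_true(all(key(h3) %in% key(h4)))
})

test_that("reverse-complement scanning mirrors the hit set", {
  g0 <- random_genome(25000, seed = 17)
  set.seed(18)
  s <- g0$sequence
  core <- orb_core_default()
  for (at in c(2000L, 9000L, 16000L)) {
    v <- strsplit(core, "")[[1]]
    for (j in sample(22, 3)) v[j] <- sample(setdiff(c("A","C","G","T"), v[j]), 1)
    variant <- paste(v, collapse = "")
    if (at == 9000L) variant <- revcomp(variant)
    substr(s, at, at + 21L) <- variant
  }
  g <- genome_record(g0$id, s, "linear")
  m <- orb_motif(max_mismatch = 4)
  h <- scan_motif(g, m)
  expect_gte(nrow(h), 3L)
  rc <- revcomp_annotated(g)
  h2 <- scan_motif(rc$genome, m)
  L <- g$length
  remap <- data.frame(start = L - h$end + 1L, end = L - h$start + 1L,
                      strand = ifelse(h$strand == "+", "-", "+"),
                      mismatches = h$mismatches)
  remap <- remap[order(remap$start, remap$strand), ]
  expect_identical(h2$start, remap$start)
  expect_identical(h2$strand, remap$strand)
  expect_identical(h2$mismatches, remap$mismatches)
})

test_that("circular genomes yield origin-spanning hits", {
  core <- orb_core_default()
  pre <- paste(rep("A", 40), collapse = "")
  # place the core across the origin: last 10 bases | first 12 bases
  s <- paste0(substr(core, 11, 22), pre, substr(core, 1, 10))
  g <- genome_record("g", s, "circular")
  h <- scan_motif(g, orb_motif(core, 0))
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, nchar(s) - 10L + 1L)
  expect_identical(h$end - h$start + 1L, 22L)
  # the same sequence treated as linear has no hit
  gl <- genome_record("g", s, "linear")
  expect_identical(nrow(scan_motif(gl, orb_motif(core, 0))), 0L)
})

test_that("pairing reproduces the published spacing arithmetic", {
  hits <- data.frame(start = c(78L, 138L), end = c(99L, 159L),
                     strand = c("+", "-"), mismatches = 0L,
                     matched_sequence = "")
  p <- pair_hits(hits)
  expect_identical(nrow(p), 1L)
  expect_identical(p$spacing, 39L)
  expect_identical(p$orientation, "inverted")
  expect_identical(nrow(pair_hits(hits[1, , drop = FALSE])), 0L)
})

test_that("clustered hits pair exhaustively", {
  hits <- data.frame(start = c(100L, 160L, 230L), end = c(121L, 181L, 251L),
                     strand = "+", mismatches = 0L, matched_sequence = "")
  p <- pair_hits(hits, max_pair_spacing = 300)
  expect_identical(nrow(p), 3L)  # all C(3,2) ordered pairs within range
  # enumeration oracle
  cnt <- 0L
  for (i in 1:2) for (j in (i + 1):3) {
    sp <- hits$start[j] - hits$end[i]
    if (sp >= 0 && sp <= 300) cnt <- cnt + 1L
  }
  expect_identical(nrow(p), cnt)
  expect_identical(nrow(pair_hits(hits, max_pair_spacing = 30)), 0L)
})

test_that("consensus derivation is column majority with IUPAC ties", {
  expect_identical(derive_consensus(c("ACGT", "ACGA", "ACGT")), "ACGT")
  expect_identical(derive_consensus(c("A", "C")), "M")
  expect_identical(derive_consensus(c("AT", "GT")), "RT")
  expect_identical(derive_consensus(c("AG", "GA", "CT")), "VD")
  expect_error(derive_consensus(c("AC", "ACG")), "equal length")
  expect_error(derive_consensus("AC"), ">= 2")
})

test_that("consensus over the published motif set equals the hand-tallied majority", {
  # independently tallied per-column majority (col 16 ties A/G -> R)
  expect_identical(derive_consensus(orb_motif_set), "GTTCCAGTGGAAATGRAGGGGT")
})

test_that("origin calls name the orc1/cdc6 gene nearest a motif pair", {
  gen <- generate_genome(small_config(123, length = 5e4,
                                      planted = list(plant_spec("orb_pair"))))
  tr <- gen$truth$planted[[1]]
  h <- scan_motif(gen$genome, orb_motif(tr$core, 0))
  expect_identical(nrow(h), 2L)
  expect_identical(h$start, c(tr$hit1$start, tr$hit2$start))
  p <- pair_hits(h)
  expect_identical(p$spacing, tr$spacing)
  oc <- call_origin(p, gen$features, origin_window = 10000)
  expect_identical(nrow(oc), 1L)
  expect_identical(oc$gene_id, tr$cdc6_id)
  expect_lt(abs(oc$distance - tr$distance), nchar(tr$core) + tr$spacing)
  # a faraway pair is not called
  far <- p; far$midpoint <- far$midpoint + 40000
  expect_identical(nrow(call_origin(far, gen$features, origin_window = 10000)), 0L)
})

test_that("with two orc1/cdc6 genes the candidate names the near one", {
  fs <- feature_set("g", data.frame(
    id = c("cdc6_a", "cdc6_b"), kind = "CDS",
    start = c(5000, 60000), end = c(6200, 61200), strand = c("+", "-"),
    product = "replication initiator Orc1/Cdc6"), 1e5)
  pairs <- data.frame(start1 = 3000L, end1 = 3021L, strand1 = "+",
                      start2 = 3060L, end2 = 3081L, strand2 = "-",
                      spacing = 39L, orientation = "inverted",
                      midpoint = 3040.5)
  oc <- call_origin(pairs, fs, origin_window = 10000)
  expect_identical(oc$gene_id, "cdc6_a")
  expect_identical(oc$side, "upstream")
  # no annotated initiator -> warning and empty result
  fs0 <- feature_set("g", data.frame(id = "x", kind = "CDS", start = 1,
                                     end = 300, strand = "+",
                                     product = "hypothetical"), 1e5)
  expect_warning(oc0 <- call_origin(pairs, fs0), "no orc1/cdc6")
  expect_identical(nrow(oc0), 0L)
})
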