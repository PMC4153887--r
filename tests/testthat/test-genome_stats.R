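mkfeat <- function(gid, starts, ends, strands = "+", kinds = "CDS", L = NULL) {
  n <- length(starts)
  feature_set(gid, data.frame(
    id = sprintf("f%02d", seq_len(n)), kind = rep(kinds, length.out = n),
    start = starts, end = ends, strand = rep(strands, length.out = n),
    product = "", stringsAsFactors = FALSE), L)
}

test_that("coding density counts covered positions once", {
  g <- random_genome(1000, seed = 1)
  expect_identical(coding_density(g, mkfeat("rand_1", 1, 1000)), 1)
  expect_identical(coding_density(g, mkfeat("rand_1", c(1, 51), c(100, 150))), 0.150)
  expect_error(coding_density(NULL, mkfeat("x", 1, 10)), "empty genome")
})

test_that("intergenic gaps match the spec examples", {
  g <- random_genome(300, seed = 2)
  ig <- intergenic_stats(g, mkfeat(g$id, c(1, 201), c(100, 300)))
  expect_identical(ig$mean, 100)
  expect_identical(ig$sd, 0)
  ig2 <- intergenic_stats(g, mkfeat(g$id, c(1, 101), c(100, 300)))
  expect_identical(ig2$mean, 0)
  expect_error(intergenic_stats(g, mkfeat(g$id, 1, 100)), "at least two")
})

test_that("intergenic gaps equal brute-force enumeration on 50 random fixtures", {
  set.seed(13)
  for (i in 1:50) {
    L <- sample(2000:5000, 1)
    circular <- i %% 2 == 0
    g <- genome_record("t", strrep("A", L),
                       if (circular) "circular" else "linear")
    n <- sample(3:12, 1)
    starts <- sort(sample(seq_len(L - 150), n))
    ends <- pmin(starts + sample(30:140, n, TRUE), L)
    fs <- mkfeat("t", starts, ends, L = L)
    got <- sort(intergenic_stats(g, fs)$gaps)
    want <- sort(as.integer(oracle_intergenic_gaps(L, starts, ends, circular)))
    expect_identical(got, want)
  }
})

test_that("coding density and intergenic gaps satisfy the conservation identity", {
  for (seed in c(3, 4, 5)) {
    gen <- generate_genome(small_config(seed, length = 3e4))
    ig <- intergenic_stats(gen$genome, gen$features)
    expect_equal(coding_density(gen$genome, gen$features),
                 1 - sum(ig$gaps) / gen$genome$length, tolerance = 1e-12)
  }
})

rbind2_fs <- function(a, b, gid) {
  df <- rbind(as.data.frame(a), as.data.frame(b))
  df$id <- sprintf("f%02d", seq_len(nrow(df)))
  feature_set(gid, df)
}

test_that("stop codon usage classifies terminal codons and sums to one", {
  # 10 CDS: 9 end TAA, 1 ends TAG
  nts <- c(rep("ATGAAATAA", 9), "ATGAAATAG")
  s <- paste(nts, collapse = "")
  g <- genome_record("g", s, "linear")
  fs <- mkfeat("g", seq(1, by = 9, length.out = 10), seq(9, by = 9, length.out = 10))
  su <- stop_codon_usage(g, fs)
  expect_equal(su$fraction_TAG, 0.10)
  expect_equal(su$fraction_TAA + su$fraction_TAG + su$fraction_TGA, 1)
  expect_identical(su$n_cds, 10L)
  # stop codon excluded from the annotation: recovered from downstream
  fs2 <- mkfeat("g", 1, 6)
  fs2b <- mkfeat("g", 10, 15)
  su2 <- stop_codon_usage(g, rbind2_fs(fs2, fs2b, "g"))
  expect_identical(su2$n_cds, 2L)
  expect_equal(su2$fraction_TAA, 1)
})

cds_seqs_for_test <- function(genome, features) {
  df <- as.data.frame(features)
  df <- df[df$kind == "CDS", ]
  vapply(unique(df$id), function(i) {
    extract_feature_sequence(genome, df[df$id == i, ])
  }, character(1))
}

test_that("codon usage tables conserve totals and tally starts", {
  g <- genome_record("g", "ATGAAATAA", "linear")
  cu <- codon_usage(g, mkfeat("g", 1, 9))
  expect_identical(unname(cu$counts["ATG"]), 1L)
  expect_identical(unname(cu$counts["AAA"]), 1L)
  expect_identical(unname(cu$stop_counts["TAA"]), 1L)
  expect_identical(unname(cu$start_counts["ATG"]), 1L)
  # conservation on a synthetic genome
  gen <- generate_genome(small_config(17, length = 3e4))
  cu2 <- codon_usage(gen$genome, gen$features)
  cds_len <- sum(nchar(cds_seqs_for_test(gen$genome, gen$features)))
  expect_identical(sum(cu2$counts), as.integer(cds_len / 3))
  expect_identical(sum(cu2$start_counts), cu2$n_cds)
})

test_that("GC-rich genomes show higher GC3 than AT-rich ones", {
  gc3 <- function(cu) {
    third <- substr(names(cu$counts), 3, 3)
    sum(cu$counts[third %in% c("G", "C")]) / sum(cu$counts)
  }
  hi <- generate_genome(synth_config(seed = 71, genome_length = 3e4,
                                     gc_fraction = 0.61,
                                     target_coding_density = 0.85))
  lo <- generate_genome(synth_config(seed = 71, genome_length = 3e4,
                                     gc_fraction = 0.41,
                                     target_coding_density = 0.85))
  expect_gt(gc3(codon_usage(hi$genome, hi$features)),
            gc3(codon_usage(lo$genome, lo$features)))
})

test_that("rRNA organization distinguishes operonic from scattered layouts", {
  op <- feature_set("g", data.frame(
    id = c("r16", "r23"), kind = c("rRNA-16S", "rRNA-23S"),
    start = c(1000, 2600), end = c(2500, 5500), strand = "+",
    product = ""), 6000)
  expect_identical(rrna_organization(op)$classification, "operonic")
  sc <- feature_set("g", data.frame(
    id = c("r16", "r23"), kind = c("rRNA-16S", "rRNA-23S"),
    start = c(1000, 401000), end = c(2500, 403900), strand = "+",
    product = ""), 5e5)
  expect_identical(rrna_organization(sc)$classification, "scattered")
  # opposite strands never form an operon even when adjacent
  opp <- feature_set("g", data.frame(
    id = c("r16", "r23"), kind = c("rRNA-16S", "rRNA-23S"),
    start = c(1000, 2600), end = c(2500, 5500), strand = c("+", "-"),
    product = ""), 6000)
  expect_identical(rrna_organization(opp)$classification, "scattered")
  expect_warning(rrna_organization(op[op$kind == "rRNA-16S", , drop = FALSE]),
                 "missing")
})

test_that("planted rRNA arrangements are classified correctly across seeds", {
  for (seed in 1:10) {
    arrangement <- if (seed %% 2 == 0) "operonic" else "scattered"
    gen <- generate_genome(small_config(300 + seed, length = 4e4,
      planted = list(plant_spec("rrna_set", arrangement = arrangement))))
    expect_identical(rrna_organization(gen$features)$classification, arrangement,
                     info = sprintf("seed %d (%s)", seed, arrangement))
  }
})

test_that("summary statistics are invariant under reverse complement", {
  gen <- generate_genome(small_config(91, length = 3e4))
  rc <- revcomp_annotated(gen$genome, gen$features)
  a <- genome_summary(gen$genome, gen$features)
  b <- genome_summary(rc$genome, rc$features)
  expect_equal(a$gc_fraction, b$gc_fraction)
  expect_equal(a$coding_fraction, b$coding_fraction)
  expect_equal(a$intergenic_mean, b$intergenic_mean)
  expect_equal(a$cds_mean_length, b$cds_mean_length)
  expect_identical(as.vector(a$gene_count), as.vector(b$gene_count))
  sa <- stop_codon_usage(gen$genome, gen$features)
  sb <- stop_codon_usage(rc$genome, rc$features)
  expect_identical(sa$counts, sb$counts)
})
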