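test_that("FASTA round trip preserves sequences and id order", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  set.seed(11)
  s1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 45, TRUE), collapse = "")
  write_genome_fasta(list(genome_record("chrA", s1), genome_record("chrB", s2)), tmp)
  recs <- read_genome(tmp, "fasta")
  expect_length(recs, 2L)
  expect_identical(names(recs), c("chrA", "chrB"))
  expect_identical(recs$chrA$length, 60L)
  expect_identical(recs$chrA$sequence, s1)
  expect_identical(recs$chrB$sequence, s2)
})

test_that("GenBank parsing yields record plus features, including join/complement", {
  tmp <- withr::local_tempfile(fileext = ".gbk")
  # 210 bp circular record: CDS on +, CDS on -, wrap-around CDS via join
  set.seed(3)
  bg <- paste(sample(c("A", "C", "G", "T"), 210, TRUE), collapse = "")
  s <- bg
  substr(s, 10, 21) <- "ATGAAATTTTAA"              # cds1 +
  substr(s, 40, 51) <- revcomp("ATGCCCGGGTAA")     # cds2 -
  # wrap CDS: last 6 bases + first 6 bases code ATGGTT|GCGTAA
  substr(s, 205, 210) <- "ATGGTT"
  substr(s, 1, 6) <- "GCGTAA"
  lines <- c(
    "LOCUS       testrec              210 bp    DNA     circular CON 01-JAN-2024",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..210",
    "     CDS             10..21",
    '                     /locus_tag="cds1"',
    '                     /product="protein one"',
    "     CDS             complement(40..51)",
    '                     /locus_tag="cds2"',
    '                     /product="protein two"',
    "     CDS             join(205..210,1..6)",
    '                     /locus_tag="cds3"',
    '                     /product="wraparound protein"',
    "ORIGIN",
    paste0("        1 ", tolower(substr(s, 1, 60))),
    paste0("       61 ", tolower(substr(s, 61, 120))),
    paste0("      121 ", tolower(substr(s, 121, 180))),
    paste0("      181 ", tolower(substr(s, 181, 210))),
    "//"
  )
  writeLines(lines, tmp)
  recs <- read_genome(tmp, "genbank")
  expect_length(recs, 1L)
  rec <- recs[[1]]
  expect_identical(rec$id, "testrec")
  expect_identical(rec$topology, "circular")
  expect_identical(rec$length, 210L)
  fs <- attr(recs, "features")[["testrec"]]
  expect_s3_class(fs, "feature_set")
  expect_setequal(unique(fs$id), c("cds1", "cds2", "cds3"))
  expect_true(all(fs$kind == "CDS"))
  expect_identical(extract_feature_sequence(rec, fs[fs$id == "cds1", ]),
                   "ATGAAATTTTAA")
  expect_identical(extract_feature_sequence(rec, fs[fs$id == "cds2", ]),
                   "ATGCCCGGGTAA")
  expect_identical(extract_feature_sequence(rec, fs[fs$id == "cds3", ]),
                   "ATGGTTGCGTAA")
  expect_identical(translate_cds("ATGGTTGCGTAA"), "MVA")
})

test_that("feature extraction is strand-aware and bounds-checked", {
  g <- genome_record("g1", "ATGAAATAG", "linear")
  plus <- data.frame(id = "f", kind = "CDS", start = 1, end = 9,
                     strand = "+", product = "")
  minus <- plus; minus$strand <- "-"
  expect_identical(extract_feature_sequence(g, plus), "ATGAAATAG")
  expect_identical(extract_feature_sequence(g, minus), "CTATTTCAT")
  oob <- plus; oob$end <- 12
  expect_error(extract_feature_sequence(g, oob), "outside")
})

test_that("extract -> revcomp remap -> extract is an involution", {
  set.seed(42)
  for (i in 1:10) {
    L <- 300L
    g <- random_genome(L, seed = 100 + i, topology = "linear")
    st <- sample(1:(L - 60), 1); en <- st + 3 * sample(5:15, 1) - 1
    f <- feature_set(g$id, data.frame(
      id = "x", kind = "CDS", start = st, end = en,
      strand = sample(c("+", "-"), 1), product = ""), L)
    rc <- revcomp_annotated(g, f)
    expect_identical(extract_feature_sequence(rc$genome, rc$features),
                     extract_feature_sequence(g, f))
    back <- revcomp_annotated(rc$genome, rc$features)
    expect_identical(back$genome$sequence, g$sequence)
    expect_identical(as.data.frame(back$features), as.data.frame(f))
  }
})

test_that("translation handles amber readthrough, stops, N and length errors", {
  expect_identical(translate_cds("ATGAAATAA"), "MK")
  expect_identical(translate_cds("ATGTAGTAA", readthrough_amber = TRUE), "MO")
  expect_identical(translate_cds("ATGTAGTAA"), "M")
  expect_identical(translate_cds("ATGANATAA"), "MX")
  expect_identical(translate_cds("ATGTGATAG", readthrough_amber = TRUE), "M")
  expect_error(translate_cds("ATGAA"), "multiple of 3")
})

test_that("plain translation is the pre-amber prefix of readthrough translation", {
  set.seed(7)
  cods <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TGA"))
  for (i in 1:25) {
    nt <- paste(c(sample(cods, 30, TRUE), "TAA"), collapse = "")
    rt <- translate_cds(nt, readthrough_amber = TRUE)
    plain <- translate_cds(nt)
    first_o <- regexpr("O", rt, fixed = TRUE)
    if (first_o > 0) {
      expect_identical(plain, substr(rt, 1, first_o - 1))
    } else {
      expect_identical(plain, rt)
    }
  }
})

test_that("feature_set -> GFF3 -> feature_set round trip preserves everything", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  g <- random_genome(5000, seed = 5, id = "chr", topology = "circular")
  df <- data.frame(
    id = c("c1", "t1", "r16", "r23", "r5", "n1"),
    kind = c("CDS", "tRNA", "rRNA-16S", "rRNA-23S", "rRNA-5S", "ncRNA"),
    start = c(10, 500, 700, 2300, 4500, 4800),
    end = c(309, 572, 2199, 4199, 4619, 4890),
    strand = c("+", "-", "+", "+", "-", "+"),
    product = c("hypothetical protein", "tRNA-Pyl (anticodon CTA)",
                "", "", "", "small RNA"),
    stringsAsFactors = FALSE)
  fs <- feature_set("chr", df, 5000)
  write_gff3(fs, tmp, genome = g)
  fs2 <- read_gff3(tmp, genome_id = "chr", genome_length = 5000)
  expect_identical(fs2$id, fs$id)
  expect_identical(fs2$kind, fs$kind)
  expect_identical(fs2$start, fs$start)
  expect_identical(fs2$end, fs$end)
  expect_identical(fs2$strand, fs$strand)
  expect_identical(attr(fs2, "genome_id"), "chr")
})

test_that("readers reject malformed and empty input", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_genome(empty, "fasta"))
  expect_error(read_genome("no/such/file.fasta", "fasta"), "no such file")
  bad <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       broken 100 bp", "no origin here"), bad)
  expect_error(read_genome(bad, "genbank"), "ORIGIN")
  expect_error(genome_record("x", "ACGU"), "outside")
  expect_error(genome_record("x", ""), "empty")
})
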