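make_proteome <- function(id, n, len = 120, seed) {
  set.seed(seed)
  prots <- vapply(seq_len(n), function(i) random_aa(len), "")
  names(prots) <- sprintf("%s_p%02d", id, seq_len(n))
  proteome(id, prots)
}

test_that("identical proteomes give reciprocal 100/100 best hits and an all-core Venn", {
  a <- make_proteome("A", 8, seed = 1)
  b <- proteome("B", stats::setNames(a$proteins, sub("^A", "B", names(a$proteins))))
  bh <- best_hits(a, b)
  expect_identical(nrow(bh), 8L)
  expect_identical(bh$subject, sub("^A", "B", bh$query))
  expect_true(all(bh$identity == 100))
  expect_true(all(bh$coverage == 100))
  c3 <- proteome("C", stats::setNames(a$proteins, sub("^A", "C", names(a$proteins))))
  vp <- venn_partition(a, b, c3)
  expect_identical(unname(vp$counts[, "core"]), c(8L, 8L, 8L))
  expect_identical(sum(vp$counts[1, ]), 8L)
  expect_identical(unname(vp$core_size), 8L)
})

test_that("queries without a qualifying subject have no hit", {
  a <- make_proteome("A", 5, seed = 2)
  b <- make_proteome("B", 5, seed = 3)   # unrelated random proteins
  bh <- best_hits(a, b)
  expect_identical(nrow(bh), 0L)
  vp <- venn_partition(a, b, make_proteome("C", 5, seed = 4))
  expect_identical(unname(vp$counts[, "core"]), c(0L, 0L, 0L))
  expect_identical(unname(vp$counts[1, "A_only"]), 5L)
})

test_that("best hits equal the exhaustive all-pairs oracle on 3x20-protein fixtures", {
  set.seed(50)
  # three related proteomes: 12 shared families (mutated copies) + 8 unique
  base <- lapply(1:12, function(i) random_aa(100))
  mk <- function(id) {
    shared <- vapply(base, function(s) mutate_aa(s, sample(5:25, 1)), "")
    uniq <- vapply(1:8, function(i) random_aa(100), "")
    prots <- c(shared, uniq)
    names(prots) <- sprintf("%s_%02d", id, seq_along(prots))
    proteome(id, prots)
  }
  ps <- list(mk("A"), mk("B"), mk("C"))
  for (qi in 1:3) for (si in setdiff(1:3, qi)) {
    got <- best_hits(ps[[qi]], ps[[si]])
    want <- oracle_best_hits(ps[[qi]]$proteins, ps[[si]]$proteins, 30, 80)
    expect_identical(got$query, want$query,
                     info = sprintf("queries %d vs %d", qi, si))
    expect_identical(got$subject, want$subject,
                     info = sprintf("subjects %d vs %d", qi, si))
  }
})

test_that("the Venn partition reproduces a designed family structure exactly", {
  set.seed(60)
  cells <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  fam <- lapply(cells, function(cl) list(members = strsplit(cl, "")[[1]],
                                         seq = random_aa(110)))
  build <- function(tax) {
    prots <- character(0)
    for (i in seq_along(fam)) {
      if (tax %in% fam[[i]]$members) {
        prots[sprintf("%s_f%d", tax, i)] <- mutate_aa(fam[[i]]$seq, 6)
      }
    }
    proteome(tax, prots)
  }
  vp <- venn_partition(build("A"), build("B"), build("C"))
  expect_identical(unname(vp$counts["A", "A_only"]), 1L)
  expect_identical(unname(vp$counts["A", "A&B"]), 1L)
  expect_identical(unname(vp$counts["A", "A&C"]), 1L)
  expect_identical(unname(vp$counts["A", "core"]), 1L)
  expect_identical(unname(vp$counts["A", "B&C"]), 0L)
  expect_identical(unname(vp$counts["B", "B_only"]), 1L)
  expect_identical(unname(vp$counts["C", "core"]), 1L)
  # per-proteome conservation: cells sum to proteome size (4 each)
  expect_identical(as.integer(rowSums(vp$counts)), c(4L, 4L, 4L))
})

test_that("the partition is invariant under permutation of protein order", {
  set.seed(70)
  base <- lapply(1:6, function(i) random_aa(90))
  ids <- c("A", "B", "C")
  protsets <- lapply(ids, function(id) {
    prots <- vapply(base, function(s) mutate_aa(s, 4), "")
    names(prots) <- sprintf("%s_%d", id, 1:6)
    prots
  })
  mk <- function(i, perm) proteome(ids[i], protsets[[i]][perm])
  v1 <- venn_partition(mk(1, 1:6), mk(2, 1:6), mk(3, 1:6))
  v2 <- venn_partition(mk(1, sample(6)), mk(2, sample(6)), mk(3, sample(6)))
  expect_identical(v1$counts, v2$counts)
  expect_identical(v1$assignments$A[sort(names(v1$assignments$A))],
                   v2$assignments$A[sort(names(v2$assignments$A))])
})

test_that("outgroup screening counts targets absent from all references", {
  set.seed(80)
  refA <- make_proteome("refA", 6, seed = 81)
  refB <- make_proteome("refB", 6, seed = 82)
  # 12 targets: 7 derived from reference proteins, 5 novel
  derived <- vapply(refA$proteins[1:4], function(s) mutate_aa(s, 8), "")
  derived2 <- vapply(refB$proteins[1:3], function(s) mutate_aa(s, 8), "")
  novel <- vapply(1:5, function(i) random_aa(120), "")
  targets <- c(derived, derived2, novel)
  names(targets) <- sprintf("t%02d", seq_along(targets))
  sr <- screen_against(targets, list(refA, refB))
  expect_identical(sr$absent_from_all, 5L)
  expect_identical(sr$absent_ids, sprintf("t%02d", 8:12))
  expect_true(all(sr$presence[1:4, "refA"]))
  expect_true(all(sr$presence[5:7, "refB"]))
  # identical target is always present
  sr2 <- screen_against(c(x = refA$proteins[[1]]), list(refA))
  expect_true(sr2$presence[1, 1])
  # random targets are absent from all (negative control)
  set.seed(83)
  rnd <- stats::setNames(vapply(1:20, function(i) random_aa(100), ""),
                         sprintf("r%02d", 1:20))
  sr3 <- screen_against(rnd, list(refA, refB))
  expect_identical(sr3$absent_from_all, 20L)
})
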