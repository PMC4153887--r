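# Independent oracles and small fixture builders. These deliberately use
# different code paths from the package implementation.

# Brute-force Hamming scan: position-by-position mismatch count on both
# strands, character-vector arithmetic (no Biostrings).
oracle_hamming_scan <- function(seq, core, max_mismatch) {
  n <- nchar(seq); w <- nchar(core)
  sb <- strsplit(seq, "")[[1]]
  one <- function(corestr, strand) {
    cb <- strsplit(corestr, "")[[1]]
    npos <- n - w + 1L
    if (npos < 1L) return(NULL)
    mm <- integer(npos)
    for (j in seq_len(w)) {
      mm <- mm + (sb[j:(j + npos - 1L)] != cb[j])
    }
    hit <- which(mm <= max_mismatch)
    if (!length(hit)) return(NULL)
    data.frame(start = hit, end = hit + w - 1L, strand = strand,
               mismatches = mm[hit], stringsAsFactors = FALSE)
  }
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(core, "")[[1]])), collapse = "")
  res <- rbind(one(core, "+"), one(rc, "-"))
  if (is.null(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  res[order(res$start, res$strand), , drop = FALSE]
}

# Brute-force gap enumeration by an explicit sweep over sorted intervals
# (overlapping intervals merged; abutting ones kept distinct, their gap is 0).
oracle_intergenic_gaps <- function(L, starts, ends, circular) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- integer(0); me <- integer(0)
  cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce) {
      ce <- max(ce, ends[i])
    } else {
      ms <- c(ms, cs); me <- c(me, ce)
      cs <- starts[i]; ce <- ends[i]
    }
  }
  ms <- c(ms, cs); me <- c(me, ce)
  gaps <- if (length(ms) > 1L) ms[-1L] - me[-length(me)] - 1L else integer(0)
  if (circular) gaps <- c(gaps, (L - me[length(me)]) + (ms[1L] - 1L))
  gaps
}

# Straight-line predicate oracle for the six marker categories, written as
# integer counting rather than fraction comparison.
oracle_marker_category <- function(present, focal_idx, other_idx, out_idx) {
  nf <- length(focal_idx); no <- length(other_idx); nx <- length(out_idx)
  kf <- sum(present[focal_idx]); ko <- sum(present[other_idx])
  kx <- sum(present[out_idx])
  all_meth <- (kf == nf) && (ko == no)
  if (all_meth && kx == 0) return(1L)
  if (all_meth && nx > 0 && 20L * kx < nx) return(2L)
  if (all_meth && nx == 0) return(2L)  # <5% of zero outgroup taxa: vacuous
  meth_frac_ok <- 10L * (kf + ko) > 9L * (nf + no)
  out_lt5 <- if (nx == 0) TRUE else 20L * kx < nx
  if (kf == nf && meth_frac_ok && out_lt5) return(3L)
  if (kf == 0 && ko == no && kx == 0) return(4L)
  other_gt90 <- 10L * ko > 9L * no
  if (kf == 0 && other_gt90 && kx == 0) return(5L)
  if (kf == 0 && other_gt90 && out_lt5) return(6L)
  NA_integer_
}

# random ACGT genome record (uniform base composition)
random_genome <- function(n, seed, id = sprintf("rand_%d", seed),
                          topology = "linear") {
  set.seed(seed)
  genome_record(id, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
                topology)
}

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, n, TRUE), collapse = "")
}

# point-mutate a protein at a given number of positions
mutate_aa <- function(s, n_mut) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  b <- strsplit(s, "")[[1]]
  idx <- sample(length(b), n_mut)
  for (i in idx) b[i] <- sample(setdiff(aa, b[i]), 1)
  paste(b, collapse = "")
}

# Independent best-hit oracle: per-pair Smith-Waterman via Biostrings
# directly (single alignments, explicit identity/coverage arithmetic),
# exhaustive over subjects.
oracle_best_hits <- function(query_prots, subject_prots, min_id, min_cov) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  rows <- list()
  for (q in names(query_prots)) {
    best <- NULL
    for (s in sort(names(subject_prots))) {   # lexicographic tie-break
      a <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(subject_prots[[s]]),
        Biostrings::AAString(query_prots[[q]]),
        type = "local", substitutionMatrix = BLOSUM62,
        gapOpening = 11, gapExtension = 1)
      pm <- as.character(Biostrings::alignedPattern(a))
      sm <- as.character(Biostrings::alignedSubject(a))
      cols <- nchar(pm)
      mtch <- sum(strsplit(pm, "")[[1]] == strsplit(sm, "")[[1]])
      idy <- if (cols > 0) 100 * mtch / cols else 0
      cov <- 100 * nchar(gsub("-", "", sm)) / nchar(query_prots[[q]])
      sc <- BiocGenerics::score(a)
      if (idy >= min_id && cov >= min_cov &&
          (is.null(best) || sc > best$score)) {
        best <- list(subject = s, score = sc)
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(query = q, subject = best$subject,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(query = character(0), subject = character(0)))
  do.call(rbind, rows)
}

# small synthetic config shorthand used across tests (scaled-down genome,
# defaults otherwise the stated envelope)
small_config <- function(seed, length = 5e4, planted = list(), ...) {
  synth_config(seed = seed, genome_length = length,
               target_coding_density = 0.85, planted = planted, ...)
}
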