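# Genome summary statistics: coding density, intergenic gap sizes, codon /
# stop-codon / start-codon usage and rRNA gene organization.

merged_gene_ranges <- function(features) {
  df <- as.data.frame(features)
  ir <- IRanges::IRanges(df$start, df$end)
  # min.gapwidth = 0 keeps abutting genes separate, so their 0-length gap
  # is still counted by intergenic_stats
  IRanges::reduce(ir, min.gapwidth = 0L)
}

#' Coding density
#'
#' Fraction of genome positions covered by at least one gene feature of any
#' kind (CDS and RNA genes alike), overlaps counted once.
#'
#' @param genome A \code{genome_record}.
#' @param features A \code{feature_set}.
#' @return Fraction in [0, 1].
#' @export
coding_density <- function(genome, features) {
  if (is.null(genome) || genome$length == 0L) stop("coding_density: empty genome")
  if (!nrow(features)) return(0)
  if (max(features$end) > genome$length) {
    stop("coding_density: features beyond genome bounds")
  }
  sum(IRanges::width(merged_gene_ranges(features))) / genome$length
}

#' Intergenic gap statistics
#'
#' Gap sizes between consecutive merged gene intervals (strand-ignored).
#' For circular genomes the wrap gap between the last and first interval is
#' included; for linear genomes the two flanks are not gaps. Abutting or
#' overlapping genes contribute a gap of 0 (after merging, abutting merged
#' intervals remain distinct).
#'
#' @inheritParams coding_density
#' @return List: \code{mean}, \code{sd} (population SD), \code{gaps}
#'   (integer vector).
#' @export
intergenic_stats <- function(genome, features) {
  if (length(unique(features$id)) < 2L) {
    stop("intergenic_stats: need at least two features")
  }
  m <- merged_gene_ranges(features)
  s <- IRanges::start(m); e <- IRanges::end(m)
  gaps <- if (length(s) > 1L) s[-1L] - e[-length(e)] - 1L else integer(0)
  if (genome$topology == "circular") {
    gaps <- c(gaps, (genome$length - e[length(e)]) + (s[1L] - 1L))
  }
  if (!length(gaps)) {
    return(list(mean = NaN, sd = NaN, gaps = integer(0)))
  }
  m0 <- mean(gaps)
  list(mean = m0, sd = sqrt(mean((gaps - m0)^2)), gaps = as.integer(gaps))
}

# coding-strand sequence of every CDS, one element per feature id
cds_sequences <- function(genome, features) {
  df <- as.data.frame(features)
  df <- df[df$kind == "CDS", , drop = FALSE]
  if (!nrow(df)) return(character(0))
  ids <- unique(df$id)
  out <- vapply(ids, function(i) {
    extract_feature_sequence(genome, df[df$id == i, , drop = FALSE])
  }, character(1))
  names(out) <- ids
  out
}

#' Stop-codon usage over the CDS complement
#'
#' Classifies each CDS by its terminal codon on the coding strand. A CDS
#' whose final codon is not a canonical stop is checked for an in-frame stop
#' immediately downstream (annotations that exclude the stop); failing both,
#' it is excluded and counted in \code{n_without_stop}.
#'
#' @inheritParams coding_density
#' @return List of class \code{stop_usage}: \code{fraction_TAA},
#'   \code{fraction_TAG}, \code{fraction_TGA}, \code{n_cds},
#'   \code{n_without_stop}, \code{counts}.
#' @export
stop_codon_usage <- function(genome, features) {
  seqs <- cds_sequences(genome, features)
  if (!length(seqs)) stop("stop_codon_usage: no CDS features")
  stops <- c("TAA", "TAG", "TGA")
  df <- as.data.frame(features)
  terminal <- vapply(names(seqs), function(i) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n >= 3L && n %% 3L == 0L) {
      last <- substr(s, n - 2L, n)
      if (last %in% stops) return(last)
    }
    # stop possibly excluded from the deposit: look one codon downstream
    nxt <- downstream_codon(genome, df[df$id == i, , drop = FALSE])
    if (!is.na(nxt) && nxt %in% stops) return(nxt)
    NA_character_
  }, character(1))
  counts <- table(factor(terminal, levels = stops))
  n_ok <- sum(counts)
  if (n_ok == 0L) stop("stop_codon_usage: no CDS with a recognized stop codon")
  structure(list(
    fraction_TAA = unname(counts["TAA"] / n_ok),
    fraction_TAG = unname(counts["TAG"] / n_ok),
    fraction_TGA = unname(counts["TGA"] / n_ok),
    n_cds = as.integer(n_ok),
    n_without_stop = as.integer(sum(is.na(terminal))),
    counts = counts
  ), class = "stop_usage")
}

# the codon immediately 3' of a feature on its coding strand (NA at a
# linear contig end); used when deposits exclude the stop codon
downstream_codon <- function(genome, feature) {
  last <- feature[nrow(feature), ]
  L <- genome$length
  if (last$strand == "+") {
    from <- last$end + 1L
    idx <- from:(from + 2L)
  } else {
    from <- last$start - 1L
    idx <- from:(from - 2L)
  }
  if (genome$topology == "circular") {
    idx <- ((idx - 1L) %% L) + 1L
  } else if (any(idx < 1L | idx > L)) {
    return(NA_character_)
  }
  b <- vapply(idx, function(i) substr(genome$sequence, i, i), character(1))
  cod <- paste(b, collapse = "")
  if (last$strand == "-") cod <- chartr("ACGT", "TGCA", cod)
  cod
}

#' Codon usage table
#'
#' Counts over all complete codons of all CDS; stop codons are tabulated
#' separately from sense codons; the start codon is tallied from codon 1.
#' CDS whose length is not a multiple of 3 are skipped with a warning.
#'
#' @inheritParams coding_density
#' @return List of class \code{codon_usage}: \code{counts} (named 64-vector),
#'   \code{relative} (per-amino-acid relative synonymous frequencies),
#'   \code{start_counts} (ATG/GTG/TTG), \code{stop_counts},
#'   \code{n_cds}, \code{skipped} (ids).
#' @export
codon_usage <- function(genome, features) {
  seqs <- cds_sequences(genome, features)
  if (!length(seqs)) stop("codon_usage: no CDS features")
  ok <- nchar(seqs) %% 3L == 0L & nchar(seqs) >= 6L
  if (any(!ok)) {
    warning("codon_usage: skipping ", sum(!ok), " CDS with length not a multiple of 3")
  }
  seqs <- seqs[ok]
  tab <- codon_table()
  all_codons <- names(tab)
  counts <- stats::setNames(integer(64L), all_codons)
  starts <- stats::setNames(integer(3L), c("ATG", "GTG", "TTG"))
  for (s in seqs) {
    n <- nchar(s)
    cods <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    first <- cods[1L]
    if (first %in% names(starts)) starts[first] <- starts[first] + 1L
    t0 <- table(cods)
    known <- intersect(names(t0), all_codons)
    counts[known] <- counts[known] + as.integer(t0[known])
  }
  is_stop <- tab[all_codons] == "*"
  sense <- counts[!is_stop]
  aa <- tab[names(sense)]
  rel <- as.numeric(sense)
  names(rel) <- names(sense)
  for (a in unique(aa)) {
    idx <- aa == a
    tot <- sum(sense[idx])
    if (tot > 0) rel[idx] <- sense[idx] / tot
  }
  structure(list(
    counts = counts,
    relative = rel,
    start_counts = starts,
    stop_counts = counts[is_stop],
    n_cds = length(seqs),
    skipped = names(ok)[!ok]
  ), class = "codon_usage")
}

#' rRNA gene organization
#'
#' Classifies the ribosomal gene layout as \code{operonic} (some 16S/23S
#' pair on the same strand within \code{max_operon_gap}) or \code{scattered},
#' and reports the positional gene-order string.
#'
#' @param features A \code{feature_set}.
#' @param max_operon_gap Maximum 16S-23S inter-feature gap (bp) for an
#'   operon call; default 500, a typical internal transcribed spacer bound.
#' @return List: \code{classification}, \code{order} (e.g.
#'   \code{"16S...23S...5S,5S"}), \code{genes} (data.frame), \code{pairs}.
#' @export
rrna_organization <- function(features, max_operon_gap = 500L) {
  df <- as.data.frame(features)
  df <- df[grepl("^rRNA-", df$kind), , drop = FALSE]
  has16 <- any(df$kind == "rRNA-16S"); has23 <- any(df$kind == "rRNA-23S")
  if (!has16 || !has23) {
    warning("rrna_organization: missing ",
            paste(c("16S", "23S")[!c(has16, has23)], collapse = " and "),
            " rRNA gene(s); partial report")
  }
  df <- df[order(df$start), , drop = FALSE]
  pairs <- NULL
  s16 <- df[df$kind == "rRNA-16S", , drop = FALSE]
  s23 <- df[df$kind == "rRNA-23S", , drop = FALSE]
  if (nrow(s16) && nrow(s23)) {
    for (i in seq_len(nrow(s16))) for (j in seq_len(nrow(s23))) {
      a <- s16[i, ]; b <- s23[j, ]
      gap <- max(a$start, b$start) - min(a$end, b$end) - 1L
      if (gap < 0L) gap <- 0L
      if (a$strand == b$strand) {
        pairs <- rbind(pairs, data.frame(
          id_16S = a$id, id_23S = b$id, gap = gap,
          operonic = gap <= max_operon_gap, stringsAsFactors = FALSE))
      }
    }
  }
  classification <- if (!is.null(pairs) && any(pairs$operonic)) "operonic" else "scattered"
  short <- sub("^rRNA-", "", df$kind)
  sep <- if (nrow(df) > 1L) {
    gaps <- df$start[-1L] - df$end[-nrow(df)] - 1L
    ifelse(gaps <= max_operon_gap, ",", "...")
  } else character(0)
  ord <- if (nrow(df)) paste0(short, c(sep, ""), collapse = "") else ""
  list(classification = classification, order = ord, genes = df, pairs = pairs)
}

#' Genome summary (size, GC, density, gene counts, CDS sizes)
#'
#' @inheritParams coding_density
#' @return List of class \code{genome_summary}.
#' @export
genome_summary <- function(genome, features) {
  df <- as.data.frame(features)
  gc <- function(s) {
    f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("G", "C"))
    sum(f) / nchar(s)
  }
  cds <- cds_sequences(genome, features)
  cds_len <- nchar(cds)
  ig <- if (length(unique(df$id)) >= 2L) intergenic_stats(genome, features)
        else list(mean = NA_real_, sd = NA_real_)
  gene_gc <- if (length(cds)) mean(vapply(cds, gc, numeric(1))) else NA_real_
  structure(list(
    genome_size = genome$length,
    gc_fraction = gc(genome$sequence),
    coding_fraction = coding_density(genome, features),
    intergenic_mean = ig$mean,
    intergenic_sd = ig$sd,
    gene_count = table(factor(df$kind[!duplicated(df$id)],
                              levels = c("CDS", "tRNA", "rRNA-5S", "rRNA-16S",
                                         "rRNA-23S", "ncRNA"))),
    cds_mean_length = if (length(cds_len)) mean(cds_len) else NA_real_,
    cds_median_length = if (length(cds_len)) stats::median(cds_len) else NA_real_,
    cds_sd_length = if (length(cds_len)) stats::sd(cds_len) else NA_real_,
    gene_gc_mean = gene_gc
  ), class = "genome_summary")
}
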