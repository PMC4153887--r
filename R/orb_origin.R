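# Replication-origin mapping by ORB (Origin Recognition Box) motif scanning.
#
# Archaeal replication origins carry pairs of degenerate ORB motifs bound by
# the Orc1/Cdc6 initiator; the origin is called where a motif pair lies near
# an annotated orc1/cdc6 gene.

#' Default ORB scan core (22-mer)
#'
#' The Methanomassiliicoccales consensus without the unsupported trailing
#' base: \code{GTTCCAGTGGAAATGG} + \code{AGGGGT}. Any IUPAC string may be
#' used instead.
#' @return Character scalar.
#' @export
orb_core_default <- function() "GTTCCAGTGGAAATGGAGGGGT"

#' ORB motif definition
#'
#' @param core DNA string (IUPAC codes allowed).
#' @param max_mismatch Maximum Hamming distance (IUPAC-aware); default 4,
#'   matching the divergence of the published motif set from its consensus.
#' @return List of class \code{orb_motif}.
#' @export
orb_motif <- function(core = orb_core_default(), max_mismatch = 4L) {
  core <- toupper(core)
  if (grepl("[^ACGTRYSWKMBDHVN]", core)) stop("orb_motif: invalid IUPAC core")
  max_mismatch <- as.integer(max_mismatch)
  if (max_mismatch >= nchar(core)) stop("orb_motif: max_mismatch must be < core length")
  structure(list(core = core, max_mismatch = max_mismatch), class = "orb_motif")
}

#' Scan a genome for ORB motif hits
#'
#' Finds every position on both strands within \code{max_mismatch}
#' (IUPAC-aware Hamming distance, no indels) of the core. On circular
#' genomes hits spanning the origin are found; their \code{end} stays
#' unwrapped (\code{end > length}) so \code{end - start + 1} equals the core
#' length.
#'
#' @param genome A \code{genome_record}.
#' @param motif An \code{\link{orb_motif}}.
#' @return data.frame of class \code{orb_hits}, sorted by start:
#'   \code{start}, \code{end}, \code{strand}, \code{mismatches},
#'   \code{matched_sequence} (in motif orientation).
#' @export
scan_motif <- function(genome, motif = orb_motif()) {
  w <- nchar(motif$core)
  if (genome$length < w) stop("scan_motif: genome shorter than the core")
  s <- genome$sequence
  if (genome$topology == "circular" && genome$length > w) {
    s <- paste0(s, substr(genome$sequence, 1L, w - 1L))
  }
  subj <- Biostrings::DNAString(s)
  one_strand <- function(pat, strand) {
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = motif$max_mismatch,
                                  with.indels = FALSE, fixed = FALSE)
    if (!length(m)) return(NULL)
    st <- Biostrings::start(m)
    keep <- st <= genome$length        # avoid double-reporting wrapped hits
    if (!any(keep)) return(NULL)
    st <- st[keep]
    frag <- as.character(m)[keep]
    mm <- vapply(frag, iupac_mismatches, integer(1), core = pat)
    data.frame(start = st, end = st + w - 1L, strand = strand,
               mismatches = mm,
               matched_sequence = if (strand == "+") frag
                                  else vapply(frag, revcomp, ""),
               stringsAsFactors = FALSE)
  }
  res <- rbind(one_strand(motif$core, "+"),
               one_strand(revcomp_iupac(motif$core), "-"))
  if (is.null(res)) {
    res <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      matched_sequence = character(0), stringsAsFactors = FALSE)
  }
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("orb_hits", "data.frame")
  res
}

iupac_sets <- function() {
  strsplit(Biostrings::IUPAC_CODE_MAP, "")
}

# IUPAC-aware mismatch count of a concrete fragment against a degenerate core
iupac_mismatches <- function(frag, core) {
  fb <- strsplit(frag, "")[[1]]
  cb <- strsplit(core, "")[[1]]
  sets <- iupac_sets()
  sum(vapply(seq_along(cb), function(i) !(fb[i] %in% sets[[cb[i]]]), logical(1)))
}

revcomp_iupac <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

#' Pair ORB hits by spacing
#'
#' All ordered pairs of distinct hits with
#' \code{0 <= start(hit2) - end(hit1) <= max_pair_spacing}. The spacing
#' definition \code{start2 - end1} reproduces the published values (e.g.
#' hits at 78-99 and 138-159 give spacing 39). Orientation is
#' \code{inverted} iff the strands differ.
#'
#' @param hits An \code{orb_hits} data.frame.
#' @param max_pair_spacing Maximum spacing in bp (default 300; published
#'   spacings are 39-256 bp).
#' @return data.frame of class \code{orb_pairs}: coordinates of both hits,
#'   \code{spacing}, \code{orientation}, \code{midpoint}.
#' @export
pair_hits <- function(hits, max_pair_spacing = 300L) {
  empty <- data.frame(start1 = integer(0), end1 = integer(0), strand1 = character(0),
                      start2 = integer(0), end2 = integer(0), strand2 = character(0),
                      spacing = integer(0), orientation = character(0),
                      midpoint = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("orb_pairs", "data.frame")
  if (nrow(hits) < 2L) return(empty)
  hits <- hits[order(hits$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hits) - 1L)) for (j in (i + 1L):nrow(hits)) {
    spacing <- hits$start[j] - hits$end[i]
    if (spacing < 0L) next
    if (spacing > max_pair_spacing) break
    out[[length(out) + 1L]] <- data.frame(
      start1 = hits$start[i], end1 = hits$end[i], strand1 = hits$strand[i],
      start2 = hits$start[j], end2 = hits$end[j], strand2 = hits$strand[j],
      spacing = spacing,
      orientation = if (hits$strand[i] == hits$strand[j]) "direct" else "inverted",
      midpoint = (hits$start[i] + hits$end[j]) / 2,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  class(res) <- c("orb_pairs", "data.frame")
  res
}

#' Column-majority consensus of co-aligned motifs
#'
#' Per-column strict majority base; ties emit the minimal IUPAC code
#' covering the tied bases.
#'
#' @param sequences Character vector (>= 2) of equal-length DNA strings.
#' @return Consensus string.
#' @export
derive_consensus <- function(sequences) {
  if (length(sequences) < 2L) stop("derive_consensus: need >= 2 sequences")
  sequences <- toupper(sequences)
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("derive_consensus: sequences must have equal length")
  mat <- do.call(rbind, strsplit(sequences, ""))
  code_for <- local({
    map <- Biostrings::IUPAC_CODE_MAP
    keys <- vapply(strsplit(map, ""), function(b) paste(sort(b), collapse = ""), "")
    stats::setNames(names(map), keys)
  })
  cons <- vapply(seq_len(w), function(j) {
    tb <- table(mat[, j])
    mx <- max(tb)
    top <- sort(names(tb)[tb == mx])
    if (length(top) == 1L) top else unname(code_for[paste(top, collapse = "")])
  }, character(1))
  paste(cons, collapse = "")
}

#' Call origin-of-replication candidates near orc1/cdc6 genes
#'
#' A candidate is an ORB pair whose midpoint lies within
#' \code{origin_window} of a boundary of an annotated orc1/cdc6 CDS
#' (identified by product or id matching \code{orc1|cdc6}).
#'
#' @param pairs An \code{orb_pairs} data.frame.
#' @param features A \code{feature_set}.
#' @param origin_window Maximum distance in bp (default 10 kb).
#' @return data.frame of class \code{origin_candidates}: pair coordinates,
#'   \code{gene_id}, \code{distance}, \code{side} (upstream/downstream/within
#'   relative to gene orientation). Empty (with a warning) when no orc1/cdc6
#'   gene is annotated.
#' @export
call_origin <- function(pairs, features, origin_window = 10000L) {
  df <- as.data.frame(features)
  genes <- df[df$kind == "CDS" &
                (grepl("orc1|cdc6", df$product, ignore.case = TRUE) |
                   grepl("orc1|cdc6", df$id, ignore.case = TRUE)), , drop = FALSE]
  empty <- data.frame(start1 = integer(0), end2 = integer(0),
                      midpoint = numeric(0), gene_id = character(0),
                      distance = numeric(0), side = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("origin_candidates", "data.frame")
  if (!nrow(genes)) {
    warning("call_origin: no orc1/cdc6 gene annotated; no origin called")
    return(empty)
  }
  if (!nrow(pairs)) return(empty)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    mid <- pairs$midpoint[i]
    d <- pmax(genes$start - mid, mid - genes$end, 0)
    k <- which.min(d)
    if (d[k] > origin_window) next
    g <- genes[k, ]
    side <- if (mid >= g$start && mid <= g$end) "within"
      else if (mid < g$start) { if (g$strand == "+") "upstream" else "downstream" }
      else { if (g$strand == "+") "downstream" else "upstream" }
    out[[length(out) + 1L]] <- data.frame(
      start1 = pairs$start1[i], end2 = pairs$end2[i], midpoint = mid,
      gene_id = g$id, distance = d[k], side = side, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  class(res) <- c("origin_candidates", "data.frame")
  res
}
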