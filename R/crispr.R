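# De novo CRISPR direct-repeat/spacer array detection.
#
# Seeds are exact k-mers recurring with a period inside the admissible
# repeat+spacer window; seed runs are chained into candidate arrays, the
# repeat is extended to the maximal unanimously agreeing length across
# instances, a column-majority consensus is built, units failing the
# mismatch bound are trimmed, and arrays with >= min_units repeats are
# reported non-overlapping in positional order.

#' CRISPR detection parameters
#'
#' The defaults admit the published Methanomassiliicoccales arrays
#' (direct repeats of 31-36 bp, spacers of 25-40 bp).
#'
#' @param dr_len_min,dr_len_max Direct-repeat length bounds (bp).
#' @param spacer_len_min,spacer_len_max Spacer length bounds (bp).
#' @param min_units Minimum number of repeat units per reported array.
#' @param max_dr_mismatch_fraction Maximum per-repeat mismatch fraction
#'   against the consensus.
#' @param seed_k Seed k-mer length.
#' @return List of class \code{crispr_params}.
#' @export
crispr_params <- function(dr_len_min = 23L, dr_len_max = 47L,
                          spacer_len_min = 20L, spacer_len_max = 60L,
                          min_units = 3L, max_dr_mismatch_fraction = 0.2,
                          seed_k = 16L) {
  stopifnot(dr_len_min <= dr_len_max, spacer_len_min <= spacer_len_max,
            min_units >= 2L, seed_k <= dr_len_min)
  structure(list(dr_len_min = as.integer(dr_len_min),
                 dr_len_max = as.integer(dr_len_max),
                 spacer_len_min = as.integer(spacer_len_min),
                 spacer_len_max = as.integer(spacer_len_max),
                 min_units = as.integer(min_units),
                 max_dr_mismatch_fraction = max_dr_mismatch_fraction,
                 seed_k = as.integer(seed_k)),
            class = "crispr_params")
}

#' Detect CRISPR arrays
#'
#' @param genome A \code{genome_record}.
#' @param params A \code{\link{crispr_params}}.
#' @return List of class \code{crispr_arrays}; each element is a
#'   \code{crispr_array}: \code{dr_consensus}, \code{repeats} (data.frame of
#'   1-based intervals), \code{spacers} (ordered character vector),
#'   \code{start}, \code{end}. Sorted by position, non-overlapping.
#' @export
find_arrays <- function(genome, params = crispr_params()) {
  s <- genome$sequence
  n <- nchar(s)
  k <- params$seed_k
  per_min <- params$dr_len_min + params$spacer_len_min
  per_max <- params$dr_len_max + params$spacer_len_max
  out <- list()
  if (n < 2L * params$dr_len_min + params$spacer_len_min) {
    return(structure(out, class = "crispr_arrays"))
  }
  pos <- seq_len(n - k + 1L)
  kmers <- substring(s, pos, pos + k - 1L)
  dup <- unique(kmers[duplicated(kmers)])
  if (!length(dup)) return(structure(out, class = "crispr_arrays"))
  keep <- kmers %in% dup
  groups <- split(pos[keep], kmers[keep])

  candidates <- list()
  for (g in groups) {
    if (length(g) < params$min_units) next
    g <- sort(g)
    d <- diff(g)
    ok <- d >= per_min & d <= per_max
    # maximal runs of admissible periods
    r <- rle(ok)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (m in which(r$values)) {
      anchors <- g[idx_start[m]:(idx_end[m] + 1L)]
      if (length(anchors) >= params$min_units) {
        candidates[[length(candidates) + 1L]] <- anchors
      }
    }
  }
  if (!length(candidates)) return(structure(out, class = "crispr_arrays"))

  # prefer candidates with more units, then longer span; accept greedily,
  # skipping any candidate overlapping an accepted array
  ord <- order(-vapply(candidates, length, 1L),
               vapply(candidates, min, 1L))
  accepted_spans <- NULL
  for (ci in ord) {
    anchors <- candidates[[ci]]
    arr <- build_array(s, anchors, k, params)
    if (is.null(arr)) next
    span <- c(arr$start, arr$end)
    if (!is.null(accepted_spans) &&
        any(span[1] <= accepted_spans[, 2] & span[2] >= accepted_spans[, 1])) next
    accepted_spans <- rbind(accepted_spans, span)
    out[[length(out) + 1L]] <- arr
  }
  if (length(out) > 1L) out <- out[order(vapply(out, `[[`, 1L, "start"))]
  structure(out, class = "crispr_arrays")
}

# extend seed anchors to the maximal unanimously agreeing repeat, build the
# consensus, trim failing units, split at invalid spacers
build_array <- function(s, anchors, k, params) {
  m <- length(anchors)
  gaps <- diff(anchors)
  # extension caps: stay inside the sequence, inside dr_len_max, and do not
  # let adjacent repeats touch
  max_left <- min(anchors[1L] - 1L, min(gaps) - k,
                  params$dr_len_max - k)
  max_right <- min(nchar(s) - (anchors[m] + k - 1L), min(gaps) - k,
                   params$dr_len_max - k)
  ext_l <- 0L
  while (ext_l < max_left) {
    b <- substring(s, anchors - ext_l - 1L, anchors - ext_l - 1L)
    if (length(unique(b)) != 1L) break
    ext_l <- ext_l + 1L
    if (k + ext_l >= params$dr_len_max) break
  }
  ext_r <- 0L
  while (ext_r < max_right && k + ext_l + ext_r < params$dr_len_max) {
    b <- substring(s, anchors + k + ext_r, anchors + k + ext_r)
    if (length(unique(b)) != 1L) break
    ext_r <- ext_r + 1L
  }
  rs <- anchors - ext_l
  re <- anchors + k - 1L + ext_r
  w <- k + ext_l + ext_r
  if (w < params$dr_len_min || w > params$dr_len_max) return(NULL)
  units <- substring(s, rs, re)
  cons <- derive_consensus_strict(units)
  mism <- vapply(units, function(u) {
    sum(strsplit(u, "")[[1]] != strsplit(cons, "")[[1]])
  }, integer(1))
  ok_unit <- mism / w <= params$max_dr_mismatch_fraction
  # trim failing units from the ends
  while (length(ok_unit) && !ok_unit[1L]) {
    rs <- rs[-1L]; re <- re[-1L]; ok_unit <- ok_unit[-1L]
  }
  while (length(ok_unit) && !ok_unit[length(ok_unit)]) {
    nn <- length(ok_unit); rs <- rs[-nn]; re <- re[-nn]; ok_unit <- ok_unit[-nn]
  }
  if (length(rs) < params$min_units) return(NULL)
  # spacers must respect the length bounds; split at violations and keep the
  # longest compliant stretch
  sp_len <- rs[-1L] - re[-length(re)] - 1L
  bad <- which(sp_len < params$spacer_len_min | sp_len > params$spacer_len_max)
  if (length(bad)) {
    cut <- c(0L, bad, length(rs))
    best <- which.max(diff(cut))
    sel <- (cut[best] + 1L):cut[best + 1L]
    if (length(sel) < params$min_units) return(NULL)
    rs <- rs[sel]; re <- re[sel]
    sp_len <- rs[-1L] - re[-length(re)] - 1L
  }
  units <- substring(s, rs, re)
  cons <- derive_consensus_strict(units)
  spacers <- substring(s, re[-length(re)] + 1L, rs[-1L] - 1L)
  structure(list(
    dr_consensus = cons,
    repeats = data.frame(start = rs, end = re),
    spacers = spacers,
    start = rs[1L], end = re[length(re)]
  ), class = "crispr_array")
}

# plain column-majority (first alphabetically on ties); internal, ungapped
derive_consensus_strict <- function(units) {
  mat <- do.call(rbind, strsplit(units, ""))
  paste(apply(mat, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1L]
  }), collapse = "")
}

#' Summarize a CRISPR array
#'
#' @param array A \code{crispr_array}.
#' @return List: \code{dr_length}, \code{dr_consensus}, \code{n_repeats},
#'   \code{n_spacers}, \code{spacer_len_min}, \code{spacer_len_max},
#'   \code{start}, \code{end}.
#' @export
array_summary <- function(array) {
  stopifnot(inherits(array, "crispr_array"))
  sl <- nchar(array$spacers)
  list(dr_length = nchar(array$dr_consensus),
       dr_consensus = array$dr_consensus,
       n_repeats = nrow(array$repeats),
       n_spacers = length(array$spacers),
       spacer_len_min = if (length(sl)) min(sl) else NA_integer_,
       spacer_len_max = if (length(sl)) max(sl) else NA_integer_,
       start = array$start, end = array$end)
}

#' Match spacers against a nucleotide database
#'
#' Best local nucleotide alignment per spacer; identity is matches over
#' aligned columns, reported with the matches/length breakdown (so a 25/27
#' match reports 92.6 percent).
#'
#' @param spacers Character vector of spacer sequences.
#' @param query_db Named character vector of DNA sequences.
#' @param min_identity Minimum percent identity for a reported hit.
#' @param min_coverage Minimum percent of the spacer inside the alignment
#'   (guards against trivially short perfect local matches).
#' @return data.frame: \code{spacer_index}, \code{subject}, \code{matches},
#'   \code{aln_length}, \code{identity}, \code{coverage}, \code{score}.
#' @export
match_spacer <- function(spacers, query_db, min_identity = 85,
                         min_coverage = 80) {
  stopifnot(length(spacers) >= 1L, length(query_db) >= 1L)
  out <- list()
  for (i in seq_along(spacers)) {
    h <- align_query_nt(spacers[i], query_db)
    h <- h[order(-h$score, h$subject), , drop = FALSE]
    b <- h[1L, ]
    if (b$identity >= min_identity && b$coverage >= min_coverage) {
      out[[length(out) + 1L]] <- data.frame(
        spacer_index = i, subject = b$subject, matches = b$matches,
        aln_length = b$aln_length, identity = b$identity,
        coverage = b$coverage, score = b$score, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(spacer_index = integer(0), subject = character(0),
                      matches = integer(0), aln_length = integer(0),
                      identity = numeric(0), coverage = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
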