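# Pyrrolysine readthrough prediction.
#
# The procedure: for every TAG-terminated CDS, translate the in-frame 3'
# flanking region up to the next stop codon; if the upstream protein and the
# extension share the same best local-alignment hit in a reference protein
# database, fuse them in silico with an 'O' (pyrrolysine) at the amber and
# report the candidate. The pyl cassette (pylT suppressor tRNA + pylSBCD)
# is detected by homology plus the annotated tRNA anticodon.

#' Parameters for readthrough detection
#'
#' @param min_identity Percent identity both segments must reach against the
#'   shared reference (default 30).
#' @param min_coverage Percent of each query segment the alignment must
#'   cover (default 50; the extension is a protein fragment, so the 80
#'   percent whole-protein threshold is not appropriate).
#' @param min_extension Minimum extension length in amino acids (default 15).
#' @param max_ambers Maximum number of successive amber readthroughs fused
#'   per locus (default 2; known Pyl proteins have one).
#' @param mode \code{"best"}: both segments must have the same best hit;
#'   \code{"shared"}: any common qualifying hit suffices.
#' @return List of class \code{pyl_params}.
#' @export
pyl_params <- function(min_identity = 30, min_coverage = 50,
                       min_extension = 15, max_ambers = 2,
                       mode = c("best", "shared")) {
  mode <- match.arg(mode)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 min_extension = min_extension, max_ambers = max_ambers,
                 mode = mode), class = "pyl_params")
}

# genomic coordinates of the codon immediately 3' of position `after` in
# reading order; returns NA when a linear replicon ends
next_codon_at <- function(genome, pos, strand) {
  L <- genome$length
  idx <- if (strand == "+") pos:(pos + 2L) else pos:(pos - 2L)
  if (genome$topology == "circular") {
    idx <- ((idx - 1L) %% L) + 1L
  } else if (any(idx < 1L | idx > L)) {
    return(NULL)
  }
  b <- substring(genome$sequence, idx, idx)
  cod <- paste(b, collapse = "")
  if (strand == "-") cod <- chartr("ACGT", "TGCA", cod)
  list(codon = cod, idx = idx)
}

#' In-frame translation of the 3' flanking region of a TAG-terminated CDS
#'
#' Translates successive codons starting immediately after the amber stop,
#' on the same strand and frame, up to but excluding the next stop codon
#' (TAA, TAG or TGA). Running off the end of a linear replicon truncates the
#' extension and sets attribute \code{truncated}.
#'
#' @param genome A \code{genome_record}.
#' @param cds One CDS feature (rows of a \code{feature_set} sharing an id);
#'   must end with TAG on its coding strand.
#' @param max_aa Safety cap on extension length.
#' @return Amino-acid string (possibly empty), with attributes
#'   \code{truncated} (logical) and \code{next_stop} (the terminating codon
#'   or NA).
#' @export
extension_translation <- function(genome, cds, max_aa = 10000L) {
  cds <- as.data.frame(cds)
  s <- extract_feature_sequence(genome, cds)
  n <- nchar(s)
  if (n < 3L || substr(s, n - 2L, n) != "TAG") {
    stop("extension_translation: CDS '", cds$id[1], "' is not TAG-terminated")
  }
  last <- cds[nrow(cds), ]
  strand <- last$strand
  pos <- if (strand == "+") last$end + 1L else last$start - 1L
  step <- if (strand == "+") 3L else -3L
  tab <- codon_table()
  out <- character(0)
  truncated <- FALSE; next_stop <- NA_character_
  limit <- min(max_aa, floor(genome$length / 3L))
  for (k in seq_len(limit)) {
    nc <- next_codon_at(genome, pos, strand)
    if (is.null(nc)) { truncated <- TRUE; break }
    aa <- unname(tab[nc$codon])
    if (is.na(aa)) aa <- "X"
    if (aa == "*") { next_stop <- nc$codon; break }
    out <- c(out, aa)
    pos <- pos + step
  }
  structure(paste(out, collapse = ""), truncated = truncated,
            next_stop = next_stop)
}

# TAG-terminated CDS ids in a feature set
tag_terminated_cds <- function(genome, features) {
  seqs <- cds_sequences(genome, features)
  if (!length(seqs)) return(character(0))
  n <- nchar(seqs)
  names(seqs)[n >= 3L & substr(seqs, n - 2L, n) == "TAG"]
}

#' Detect amber-readthrough (putative Pyl-containing) candidates
#'
#' For each TAG-terminated CDS, computes the best qualifying hit of the
#' upstream protein and of the in-frame 3' extension against \code{refdb};
#' a candidate is emitted iff both hits exist, name the same reference, and
#' the extension is at least \code{min_extension} residues. The fused
#' protein carries one 'O' per fused amber.
#'
#' @param genome A \code{genome_record}.
#' @param features A \code{feature_set}.
#' @param refdb Named character vector of reference protein sequences.
#' @param params A \code{\link{pyl_params}}.
#' @return data.frame of class \code{readthrough_candidates}, one row per
#'   candidate: \code{cds_id}, \code{amber_genome_position} (first base of
#'   the amber codon, in reading order), \code{upstream_aa},
#'   \code{extension_aa}, \code{ref_id}, identities/coverages of both
#'   segments, \code{fused_protein}, \code{n_ambers}.
#' @export
detect_readthrough_candidates <- function(genome, features, refdb,
                                          params = pyl_params()) {
  stopifnot(length(refdb) >= 1L)
  hp <- homology_params(params$min_identity, params$min_coverage)
  df <- as.data.frame(features)
  out <- list()
  for (id in tag_terminated_cds(genome, features)) {
    cds <- df[df$id == id, , drop = FALSE]
    s <- extract_feature_sequence(genome, cds)
    up_aa <- translate_cds(substr(s, 1L, nchar(s) - 3L))
    last <- cds[nrow(cds), ]
    strand <- last$strand
    amber_pos <- if (strand == "+") last$end - 2L else last$start + 2L
    # fuse successive amber extensions (usually one)
    ext_parts <- character(0)
    work <- cds
    n_ambers <- 0L
    repeat {
      ext <- extension_translation(genome, work)
      ext_parts <- c(ext_parts, as.character(ext))
      n_ambers <- n_ambers + 1L
      if (identical(attr(ext, "next_stop"), "TAG") &&
          n_ambers < params$max_ambers && nchar(ext) > 0L) {
        # pretend the CDS now extends through this amber and continue
        step <- (nchar(ext) + 1L) * 3L
        work <- last
        if (strand == "+") {
          work$end <- last$end + step
        } else {
          work$start <- last$start - step
        }
        if (work$start < 1L || work$end > genome$length) break
        last <- work
      } else break
    }
    extension_aa <- paste(ext_parts, collapse = "O")
    if (nchar(gsub("O", "", extension_aa)) < params$min_extension) next
    hit_up <- best_hit(up_aa, refdb, hp)
    if (is.null(hit_up)) next
    hit_ext <- best_hit(gsub("O", "X", extension_aa), refdb, hp)
    if (is.null(hit_ext)) next
    same <- if (params$mode == "best") {
      identical(hit_up$subject, hit_ext$subject)
    } else {
      shared_qualifying_hit(up_aa, gsub("O", "X", extension_aa), refdb, hp,
                            hit_up, hit_ext)
    }
    if (!same) next
    out[[length(out) + 1L]] <- data.frame(
      cds_id = id,
      amber_genome_position = amber_pos,
      upstream_aa = up_aa,
      extension_aa = extension_aa,
      ref_id = hit_up$subject,
      upstream_identity = hit_up$identity,
      upstream_coverage = hit_up$coverage,
      extension_identity = hit_ext$identity,
      extension_coverage = hit_ext$coverage,
      fused_protein = paste0(up_aa, "O", extension_aa),
      n_ambers = n_ambers,
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    cds_id = character(0), amber_genome_position = integer(0),
    upstream_aa = character(0), extension_aa = character(0),
    ref_id = character(0), upstream_identity = numeric(0),
    upstream_coverage = numeric(0), extension_identity = numeric(0),
    extension_coverage = numeric(0), fused_protein = character(0),
    n_ambers = integer(0), stringsAsFactors = FALSE
  )
  class(res) <- c("readthrough_candidates", "data.frame")
  res
}

shared_qualifying_hit <- function(up, ext, refdb, hp, hit_up, hit_ext) {
  h1 <- align_query(up, refdb)
  h2 <- align_query(ext, refdb)
  q1 <- h1$subject[h1$identity >= hp$min_identity & h1$coverage >= hp$min_coverage]
  q2 <- h2$subject[h2$identity >= hp$min_identity & h2$coverage >= hp$min_coverage]
  length(intersect(q1, q2)) > 0L
}

#' Detect the pyrrolysine (pyl) cassette
#'
#' Homology calls for pylS/pylB/pylC/pylD (best CDS hit against the
#' correspondingly named reference entries at the thresholds) and a pylT
#' call: an annotated tRNA whose product declares the amber-suppressor CUA
#' anticodon (written CTA on the gene). Because these are whole-gene calls,
#' the alignment must cover the threshold fraction of the reference as well
#' as of the query, which keeps short spurious local matches out.
#'
#' @param genome A \code{genome_record}.
#' @param features A \code{feature_set}.
#' @param refdb Named character vector containing entries whose names match
#'   \code{pylS}, \code{pylB}, \code{pylC}, \code{pylD} (case-insensitive).
#' @param params A \code{\link{homology_params}} (defaults 30/50).
#' @return List of class \code{pyl_cassette}: per gene a list
#'   \code{present}/\code{feature_id}, plus \code{complete}.
#' @export
detect_pyl_cassette <- function(genome, features, refdb,
                                params = homology_params(30, 50)) {
  df <- as.data.frame(features)
  out <- list()
  # pylT: annotated tRNA with CUA (gene CTA) anticodon
  trna <- df[df$kind == "tRNA", , drop = FALSE]
  hit_t <- trna$id[grepl("anticodon[ :=]*CTA|tRNA-Pyl", trna$product,
                         ignore.case = TRUE)]
  out$pylT <- list(present = length(hit_t) > 0L,
                   feature_id = if (length(hit_t)) hit_t[1L] else NA_character_)
  cds <- cds_sequences(genome, features)
  prots <- if (length(cds)) vapply(cds, translate_cds, "") else character(0)
  for (g in c("pylS", "pylB", "pylC", "pylD")) {
    ref_idx <- grep(g, names(refdb), ignore.case = TRUE)
    if (!length(ref_idx) || !length(prots)) {
      out[[g]] <- list(present = FALSE, feature_id = NA_character_)
      next
    }
    found <- NA_character_
    best_score <- -Inf
    for (ref1 in refdb[ref_idx]) {
      # vectorized: all CDS proteins against this reference in one call
      pat <- Biostrings::AAStringSet(vapply(prots, clean_aa, ""))
      aln <- Biostrings::pairwiseAlignment(
        pattern = pat, subject = Biostrings::AAString(clean_aa(ref1)),
        type = "local", substitutionMatrix = blosum62(),
        gapOpening = 11, gapExtension = 1)
      nmat <- Biostrings::nmatch(aln)
      alen <- Biostrings::nchar(aln)
      qres <- nchar(gsub("-", "", as.character(Biostrings::alignedPattern(aln))))
      rres <- nchar(gsub("-", "", as.character(Biostrings::alignedSubject(aln))))
      idy <- ifelse(alen > 0, 100 * nmat / alen, 0)
      cov <- 100 * qres / nchar(prots)
      rcov <- 100 * rres / nchar(ref1)
      sc <- BiocGenerics::score(aln)
      qual <- idy >= params$min_identity & cov >= params$min_coverage &
        rcov >= params$min_coverage
      if (any(qual) && max(sc[qual]) > best_score) {
        best_score <- max(sc[qual])
        found <- names(prots)[qual][which.max(sc[qual])]
      }
    }
    out[[g]] <- list(present = !is.na(found), feature_id = found)
  }
  out$complete <- all(vapply(out[c("pylT", "pylS", "pylB", "pylC", "pylD")],
                             function(x) x$present, logical(1)))
  class(out) <- "pyl_cassette"
  out
}
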