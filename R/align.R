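# Local-alignment engine shared by the homology-based detectors.
#
# Smith-Waterman via Biostrings::pairwiseAlignment, BLOSUM62, affine gap
# penalties 11/1 (BLAST-like). Identity is matches / aligned columns
# (gapped columns included); coverage is aligned query residues / query
# length. These explicit definitions stand in for BLASTP statistics.

#' Local-alignment parameters for protein homology calls
#'
#' @param min_identity Minimum percent identity (matches over aligned
#'   columns) for a qualifying hit.
#' @param min_coverage Minimum percent of the query covered by the
#'   alignment.
#' @return A list of class \code{homology_params}.
#' @export
homology_params <- function(min_identity = 30, min_coverage = 80) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100)
  structure(list(min_identity = min_identity, min_coverage = min_coverage),
            class = "homology_params")
}

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

clean_aa <- function(x) gsub("[^ARNDCQEGHILKMFPSTWYVBZX]", "X", toupper(x))

#' Align one protein query against a database
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1) of a
#' single query against every database entry.
#'
#' @param query Amino-acid string.
#' @param db Named character vector of amino-acid sequences.
#' @return data.frame with one row per db entry: \code{subject},
#'   \code{score}, \code{identity} (percent), \code{coverage} (percent of
#'   query), \code{matches}, \code{aln_length}.
#' @export
align_query <- function(query, db) {
  stopifnot(length(db) >= 1L, !is.null(names(db)))
  q <- clean_aa(query)
  pat <- Biostrings::AAStringSet(vapply(db, clean_aa, ""))
  aln <- Biostrings::pairwiseAlignment(
    pattern = pat, subject = Biostrings::AAString(q),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  nmat <- Biostrings::nmatch(aln)
  alen <- Biostrings::nchar(aln)      # alignment length incl. gap columns
  # query residues inside the alignment: subject side, gaps removed
  subj_chr <- as.character(Biostrings::alignedSubject(aln))
  qres <- nchar(gsub("-", "", subj_chr))
  data.frame(
    subject = names(db),
    score = BiocGenerics::score(aln),
    identity = ifelse(alen > 0, 100 * nmat / alen, 0),
    coverage = 100 * qres / nchar(q),
    matches = nmat,
    aln_length = alen,
    stringsAsFactors = FALSE
  )
}

#' Best qualifying hit of a query in a database
#'
#' Ranks hits by score (ties broken by lexicographic subject id, which makes
#' the result independent of database order) and returns the best hit
#' passing the identity/coverage thresholds, or \code{NULL}.
#'
#' @inheritParams align_query
#' @param params A \code{homology_params}.
#' @return One-row data.frame as in \code{\link{align_query}}, or \code{NULL}.
#' @export
best_hit <- function(query, db, params = homology_params()) {
  hits <- align_query(query, db)
  hits <- hits[hits$identity >= params$min_identity &
                 hits$coverage >= params$min_coverage, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  hits <- hits[order(-hits$score, hits$subject), , drop = FALSE]
  hits[1L, , drop = FALSE]
}

#' Local nucleotide alignment of a query against a database
#'
#' Used for spacer-vs-database matching. Match +2 / mismatch -3, gap open 5 /
#' extend 2 (BLASTN-like). Identity is matches over aligned columns.
#'
#' @param query DNA string.
#' @param db Named character vector of DNA sequences.
#' @return data.frame as in \code{\link{align_query}}.
#' @export
align_query_nt <- function(query, db) {
  stopifnot(length(db) >= 1L, !is.null(names(db)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(toupper(db)),
    subject = Biostrings::DNAString(toupper(query)),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2
  )
  nmat <- Biostrings::nmatch(aln)
  alen <- Biostrings::nchar(aln)
  subj_chr <- as.character(Biostrings::alignedSubject(aln))
  qres <- nchar(gsub("-", "", subj_chr))
  data.frame(
    subject = names(db),
    score = BiocGenerics::score(aln),
    identity = ifelse(alen > 0, 100 * nmat / alen, 0),
    coverage = 100 * qres / nchar(query),
    matches = nmat,
    aln_length = alen,
    stringsAsFactors = FALSE
  )
}
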