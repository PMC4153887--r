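# Best-hit orthology among proteomes, three-way core-genome (Venn)
# partitioning, and screening of a protein set against outgroup proteomes.
# Thresholds follow the published criterion: identity >= 30% with a minimum
# query length coverage of 80%.

#' Construct a proteome
#'
#' @param id Proteome (taxon) identifier.
#' @param proteins Named character vector of amino-acid sequences.
#' @return List of class \code{proteome}.
#' @export
proteome <- function(id, proteins) {
  stopifnot(is.character(id), length(id) == 1L, length(proteins) >= 1L,
            !is.null(names(proteins)), !anyDuplicated(names(proteins)))
  if (any(!nzchar(proteins))) stop("proteome: empty protein sequence in '", id, "'")
  structure(list(id = id, proteins = proteins), class = "proteome")
}

#' Best hits of every query protein in a subject proteome
#'
#' Per query, the highest-scoring local alignment (BLOSUM62, affine 11/1)
#' against the subject proteome that passes the identity/coverage
#' thresholds; score ties are broken by lexicographic subject id, so the
#' result does not depend on input order. Queries with no qualifying
#' subject are absent from the result.
#'
#' @param query,subject \code{\link{proteome}} objects.
#' @param params A \code{\link{homology_params}} (default 30/80).
#' @return data.frame: \code{query}, \code{subject}, \code{identity},
#'   \code{coverage}, \code{score}.
#' @export
best_hits <- function(query, subject, params = homology_params()) {
  stopifnot(inherits(query, "proteome"), inherits(subject, "proteome"))
  rows <- list()
  for (q in names(query$proteins)) {
    h <- best_hit(query$proteins[[q]], subject$proteins, params)
    if (is.null(h)) next
    rows[[length(rows) + 1L]] <- data.frame(
      query = q, subject = h$subject, identity = h$identity,
      coverage = h$coverage, score = h$score, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(query = character(0), subject = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Three-way core-genome (Venn) partition
#'
#' A protein of proteome i is "shared with" proteome j iff it has a
#' qualifying best hit in j. The seven disjoint cells (three unique, three
#' pairwise, one core) are reported with per-proteome counts; per proteome
#' the cell counts sum to the proteome size.
#'
#' @param p1,p2,p3 \code{\link{proteome}} objects.
#' @param params A \code{\link{homology_params}}.
#' @return List of class \code{venn_partition}: \code{counts} (3 x 7 matrix,
#'   rows = proteomes, columns = cells), \code{assignments} (per proteome, a
#'   named cell label per protein), \code{core_size} (core count of the
#'   first proteome).
#' @export
venn_partition <- function(p1, p2, p3, params = homology_params()) {
  ps <- list(p1, p2, p3)
  ids <- vapply(ps, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("venn_partition: proteome ids must differ")
  cells <- c(paste0(ids, "_only"),
             paste(ids[1], ids[2], sep = "&"),
             paste(ids[1], ids[3], sep = "&"),
             paste(ids[2], ids[3], sep = "&"),
             "core")
  counts <- matrix(0L, 3L, 7L, dimnames = list(ids, cells))
  assignments <- vector("list", 3L); names(assignments) <- ids
  pair_cell <- function(i, j) {
    a <- sort(c(i, j))
    paste(ids[a[1]], ids[a[2]], sep = "&")
  }
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    shared <- lapply(others, function(j) {
      hits <- best_hits(ps[[i]], ps[[j]], params)
      names(ps[[i]]$proteins) %in% hits$query
    })
    lab <- character(length(ps[[i]]$proteins))
    both <- shared[[1]] & shared[[2]]
    none <- !shared[[1]] & !shared[[2]]
    lab[both] <- "core"
    lab[none] <- paste0(ids[i], "_only")
    lab[shared[[1]] & !shared[[2]]] <- pair_cell(i, others[1])
    lab[!shared[[1]] & shared[[2]]] <- pair_cell(i, others[2])
    names(lab) <- names(ps[[i]]$proteins)
    assignments[[i]] <- lab
    tb <- table(factor(lab, levels = cells))
    counts[i, ] <- as.integer(tb)
  }
  structure(list(counts = counts, assignments = assignments,
                 core_size = counts[1, "core"]),
            class = "venn_partition")
}

#' Screen proteins against reference proteomes
#'
#' Presence/absence of qualifying hits (identity >= 30%, coverage >= 80% by
#' default) of each target in each reference proteome, plus the count of
#' targets absent from all references.
#'
#' @param targets Named character vector of protein sequences.
#' @param refs List of \code{\link{proteome}} objects.
#' @param params A \code{\link{homology_params}}.
#' @return List of class \code{screen_result}: \code{presence} (logical
#'   matrix targets x refs), \code{absent_from_all} (count),
#'   \code{absent_ids}.
#' @export
screen_against <- function(targets, refs, params = homology_params()) {
  stopifnot(length(targets) >= 1L, !is.null(names(targets)), length(refs) >= 1L)
  ref_ids <- vapply(refs, `[[`, "", "id")
  pres <- matrix(FALSE, length(targets), length(refs),
                 dimnames = list(names(targets), ref_ids))
  for (j in seq_along(refs)) {
    for (i in seq_along(targets)) {
      h <- best_hit(targets[[i]], refs[[j]]$proteins, params)
      pres[i, j] <- !is.null(h)
    }
  }
  absent <- rownames(pres)[rowSums(pres) == 0L]
  structure(list(presence = pres, absent_from_all = length(absent),
                 absent_ids = absent),
            class = "screen_result")
}
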