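# Phyletic-pattern classification of methanogenesis marker families.
#
# Given a boolean family x taxon presence matrix and a three-way taxon
# grouping (focal clade = Methanomassiliicoccales; other methanogens;
# other archaea), each family is assigned to one of six marker categories
# or none:
#   1  present in and unique to all sequenced methanogens, absent elsewhere
#   2  present in all sequenced methanogens, < 5% of other archaea
#   3  present in > 90% of methanogens *including* the focal clade, < 5%
#   4  absent from the focal clade, present in and unique to all other
#      methanogens
#   5  absent from the focal clade, > 90% of other methanogens, absent
#      elsewhere
#   6  absent from the focal clade, > 90% of other methanogens, < 5%
# Categories are evaluated 1 -> 6 and the first satisfied is returned
# (category 1 implies 2's condition, so ordered matching yields the most
# specific label). ">90%"/"<5%" are strict by default; "all" means every
# taxon of the group; "not in other archaea" means an outgroup fraction of
# exactly 0. "Other methanogens" fractions (categories 4-6) exclude the
# focal clade from the denominator.

#' Define the three taxon groups
#'
#' @param focal Character vector: the focal methanogen clade.
#' @param other_ingroup Character vector: all other methanogens.
#' @param outgroup Character vector: non-methanogen archaea.
#' @return List of class \code{taxon_groups}.
#' @export
taxon_groups <- function(focal, other_ingroup, outgroup) {
  all3 <- c(focal, other_ingroup, outgroup)
  if (anyDuplicated(all3)) stop("taxon_groups: the three groups must be disjoint")
  if (!length(focal) || !length(other_ingroup)) {
    stop("taxon_groups: focal and other_ingroup must be non-empty")
  }
  structure(list(focal = focal, other_ingroup = other_ingroup,
                 outgroup = outgroup), class = "taxon_groups")
}

#' Classify one family's phyletic pattern
#'
#' @param row Named logical vector of presence over taxa (names must cover
#'   every grouped taxon).
#' @param groups A \code{\link{taxon_groups}}.
#' @param strict Use strict inequalities for the 90%/5% bounds (default
#'   TRUE, following the category definitions' wording); \code{FALSE} makes
#'   them inclusive.
#' @return Integer 1-6, or \code{NA_integer_} for "none".
#' @export
classify_family <- function(row, groups, strict = TRUE) {
  stopifnot(inherits(groups, "taxon_groups"), is.logical(row))
  need <- c(groups$focal, groups$other_ingroup, groups$outgroup)
  if (!all(need %in% names(row))) {
    stop("classify_family: row lacks taxa: ",
         paste(setdiff(need, names(row)), collapse = ", "))
  }
  f_focal <- mean(row[groups$focal])
  f_other <- mean(row[groups$other_ingroup])
  f_meth <- mean(row[c(groups$focal, groups$other_ingroup)])
  f_out <- if (length(groups$outgroup)) mean(row[groups$outgroup]) else 0
  gt90 <- function(x) if (strict) x > 0.9 else x >= 0.9
  lt5 <- function(x) if (strict) x < 0.05 else x <= 0.05
  if (f_meth == 1 && f_out == 0) return(1L)
  if (f_meth == 1 && lt5(f_out)) return(2L)
  if (f_focal == 1 && gt90(f_meth) && lt5(f_out)) return(3L)
  if (f_focal == 0 && f_other == 1 && f_out == 0) return(4L)
  if (f_focal == 0 && gt90(f_other) && f_out == 0) return(5L)
  if (f_focal == 0 && gt90(f_other) && lt5(f_out)) return(6L)
  NA_integer_
}

#' Classify every family of a presence/absence matrix
#'
#' @param matrix Logical matrix (or 0/1 data.frame), rows = families,
#'   columns = taxa.
#' @param groups A \code{\link{taxon_groups}}.
#' @param strict See \code{\link{classify_family}}.
#' @return List of class \code{marker_classification}: \code{category}
#'   (named integer vector, NA = none), \code{summary} (counts per category
#'   including "none").
#' @export
classify_matrix <- function(matrix, groups, strict = TRUE) {
  m <- as.matrix(matrix)
  if (is.numeric(m)) m <- m > 0
  stopifnot(is.logical(m), !is.null(colnames(m)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("family_%03d", seq_len(nrow(m)))
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("classify_matrix: duplicate family or taxon ids")
  }
  cat <- vapply(seq_len(nrow(m)), function(i) {
    classify_family(stats::setNames(m[i, ], colnames(m)), groups, strict)
  }, integer(1))
  names(cat) <- rownames(m)
  smry <- table(factor(ifelse(is.na(cat), "none", as.character(cat)),
                       levels = c(as.character(1:6), "none")))
  structure(list(category = cat, summary = smry),
            class = "marker_classification")
}

#' Read a presence/absence matrix from TSV
#'
#' Expects families in rows (first column = family id) and 0/1 presence per
#' taxon column.
#'
#' @param path TSV path.
#' @return Logical matrix.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m > 0
}

#' Read taxon group definitions from TSV
#'
#' Two columns: taxon, group (one of focal / other_ingroup / outgroup).
#'
#' @param path TSV path.
#' @return A \code{\link{taxon_groups}}.
#' @export
read_taxon_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("taxon", "group") %in% names(df)))
  taxon_groups(df$taxon[df$group == "focal"],
               df$taxon[df$group == "other_ingroup"],
               df$taxon[df$group == "outgroup"])
}
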