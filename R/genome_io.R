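#' Construct a genome record
#'
#' A genome record holds one replicon: an uppercase DNA sequence over
#' \code{A,C,G,T,N} plus its id and topology. Completed archaeal chromosomes
#' are circular; draft contigs are linear.
#'
#' @param id Character scalar, replicon identifier.
#' @param sequence DNA string (coerced to uppercase).
#' @param topology \code{"circular"} or \code{"linear"}.
#' @return An object of class \code{genome_record}: a list with elements
#'   \code{id}, \code{sequence}, \code{topology}, \code{length}.
#' @export
genome_record <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("genome_record: empty sequence for '", id, "'")
  if (grepl("[^ACGTN]", sequence)) {
    stop("genome_record: sequence of '", id, "' contains letters outside {A,C,G,T,N}")
  }
  structure(
    list(id = id, sequence = sequence, topology = topology,
         length = nchar(sequence)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s\n",
              x$id, format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' Construct a feature set
#'
#' Strand-aware, 1-based inclusive annotation intervals for one genome.
#' Multi-segment features (e.g. a CDS wrapping the origin of a circular
#' replicon) are represented as several rows sharing one \code{id}, stored in
#' translation order.
#'
#' @param genome_id Character scalar naming the genome the features annotate.
#' @param features \code{data.frame} with columns \code{id}, \code{kind}
#'   (one of CDS, tRNA, rRNA-5S, rRNA-16S, rRNA-23S, ncRNA), \code{start},
#'   \code{end}, \code{strand} (\code{"+"}/\code{"-"}), \code{product}.
#' @param genome_length Optional genome length used to bound-check
#'   coordinates.
#' @return A \code{feature_set}: the validated data.frame (sorted by start,
#'   segment order preserved within an id) with attribute \code{genome_id}.
#' @export
feature_set <- function(genome_id, features, genome_length = NULL) {
  kinds <- c("CDS", "tRNA", "rRNA-5S", "rRNA-16S", "rRNA-23S", "ncRNA")
  need <- c("id", "kind", "start", "end", "strand", "product")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature_set: missing columns: ", paste(miss, collapse = ", "))
  features <- as.data.frame(features)[, need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(!features$kind %in% kinds)) {
    stop("feature_set: unknown feature kind(s): ",
         paste(unique(setdiff(features$kind, kinds)), collapse = ", "))
  }
  if (any(!features$strand %in% c("+", "-"))) stop("feature_set: strand must be '+' or '-'")
  if (any(features$start < 1L) || any(features$end < features$start)) {
    stop("feature_set: need 1 <= start <= end for every segment")
  }
  if (!is.null(genome_length) && any(features$end > genome_length)) {
    stop("feature_set: feature end beyond genome length ", genome_length)
  }
  # sort by start of the feature's first segment; keep segment order within id
  first <- tapply(features$start, features$id, min)[features$id]
  features <- features[order(first, match(features$id, unique(features$id))), , drop = FALSE]
  rownames(features) <- NULL
  structure(features, genome_id = genome_id, class = c("feature_set", "data.frame"))
}

#' Read genome sequences (and, for GenBank, annotations)
#'
#' @param path Path to a FASTA or GenBank flat file.
#' @param format \code{"fasta"} or \code{"genbank"}.
#' @param topology Topology assigned to FASTA records (GenBank records carry
#'   their own LOCUS topology).
#' @return A named list of \code{genome_record}. For GenBank input with
#'   annotated features, the list carries an attribute \code{"features"}: a
#'   named list of \code{feature_set}, one per record that has features.
#' @export
read_genome <- function(path, format = c("fasta", "genbank"),
                        topology = c("linear", "circular")) {
  format <- match.arg(format)
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("read_genome: no such file: ", path)
  if (format == "fasta") {
    dna <- Biostrings::readDNAStringSet(path)
    if (length(dna) == 0L) stop("read_genome: no sequences in ", path)
    ids <- sub("\\s.*$", "", names(dna))
    recs <- lapply(seq_along(dna), function(i) {
      genome_record(ids[i], as.character(dna[[i]]), topology)
    })
    names(recs) <- ids
    recs
  } else {
    read_genbank(path)
  }
}

# Minimal GenBank flat-file reader (no package on the image reads the format).
# Parses LOCUS (name, length, topology), FEATURES (CDS/tRNA/rRNA/ncRNA with
# complement()/join() locations and /product, /locus_tag qualifiers) and
# ORIGIN. Other feature keys (gene, source, ...) are ignored.
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("read_genbank: empty file: ", path)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("read_genbank: no LOCUS line in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  recs <- list(); feats <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    parsed <- parse_genbank_record(block, path)
    recs[[parsed$record$id]] <- parsed$record
    if (!is.null(parsed$features)) feats[[parsed$record$id]] <- parsed$features
  }
  if (length(feats)) attr(recs, "features") <- feats
  recs
}

parse_genbank_record <- function(block, path) {
  locus <- strsplit(trimws(block[1]), "\\s+")[[1]]
  id <- locus[2]
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
  ori <- grep("^ORIGIN", block)
  if (!length(ori)) stop("read_genbank: record '", id, "' has no ORIGIN (", path, ")")
  seq_lines <- block[(ori[1] + 1L):length(block)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("read_genbank: record '", id, "' has an empty ORIGIN")
  rec <- genome_record(id, sequence, topology)

  fst <- grep("^FEATURES", block)
  features <- NULL
  if (length(fst)) {
    fend <- ori[1] - 1L
    flines <- block[(fst[1] + 1L):fend]
    features <- parse_genbank_features(flines, id, rec$length)
  }
  list(record = rec, features = features)
}

parse_genbank_features <- function(flines, genome_id, genome_length) {
  # a new feature starts at column 6 (5 spaces + key); qualifiers at column 22
  is_new <- grepl("^ {5}\\S", flines)
  if (!any(is_new)) return(NULL)
  idx <- which(is_new)
  keep_keys <- c("CDS", "tRNA", "rRNA", "ncRNA")
  rows <- list(); auto <- 0L
  for (i in seq_along(idx)) {
    from <- idx[i]
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(flines)
    key <- sub("^ {5}(\\S+).*$", "\\1", flines[from])
    if (!key %in% keep_keys) next
    body <- flines[from:to]
    loc <- sub("^ {5}\\S+\\s+", "", body[1])
    j <- 2L
    while (j <= length(body) && !grepl("^\\s+/", body[j])) {
      loc <- paste0(loc, trimws(body[j])); j <- j + 1L
    }
    quals <- paste(body[seq.int(j, length.out = max(0L, length(body) - j + 1L))],
                   collapse = " ")
    product <- qual_value(quals, "product")
    locus_tag <- qual_value(quals, "locus_tag")
    auto <- auto + 1L
    fid <- if (!is.na(locus_tag)) locus_tag else sprintf("%s_f%04d", key, auto)
    segs <- parse_genbank_location(loc, genome_id)
    kind <- key
    if (key == "rRNA") {
      kind <- if (grepl("16S", product %||% "")) "rRNA-16S"
      else if (grepl("23S", product %||% "")) "rRNA-23S"
      else if (grepl("5S", product %||% "")) "rRNA-5S"
      else "ncRNA"
    }
    segs$id <- fid; segs$kind <- kind
    segs$product <- if (is.na(product)) "" else product
    rows[[length(rows) + 1L]] <- segs
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  feature_set(genome_id, df, genome_length)
}

qual_value <- function(quals, name) {
  m <- regmatches(quals, regexec(sprintf('/%s="([^"]*)"', name), quals))[[1]]
  if (length(m) == 2L) m[2] else NA_character_
}

parse_genbank_location <- function(loc, where) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", parts))
  bad <- vapply(m, length, 1L) != 3L
  single <- grepl("^\\d+$", parts)
  if (any(bad & !single)) {
    stop("read_genbank: cannot parse location '", loc, "' in ", where)
  }
  starts <- integer(length(parts)); ends <- integer(length(parts))
  for (i in seq_along(parts)) {
    if (single[i]) {
      starts[i] <- ends[i] <- as.integer(parts[i])
    } else {
      starts[i] <- as.integer(m[[i]][2]); ends[i] <- as.integer(m[[i]][3])
    }
  }
  # segments in translation order: GenBank join() lists them 5'->3' already;
  # for complement() the listed order is genomic, translation reads them
  # highest-coordinate first
  df <- data.frame(start = starts, end = ends, strand = strand,
                   stringsAsFactors = FALSE)
  if (strand == "-" && nrow(df) > 1L) df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  df
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Reverse complement of a DNA string
#' @param x DNA string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract the coding-strand sequence of a feature
#'
#' Returns the 5'->3' sequence a ribosome would read: minus-strand segments
#' are reverse-complemented, multi-segment features concatenated in
#' translation order (their row order in the feature set).
#'
#' @param genome A \code{genome_record}.
#' @param feature One feature: a data.frame of one or more segment rows
#'   sharing an id (subset of a \code{feature_set}).
#' @return DNA string.
#' @export
extract_feature_sequence <- function(genome, feature) {
  feature <- as.data.frame(feature)
  if (!nrow(feature)) stop("extract_feature_sequence: empty feature")
  if (any(feature$start < 1L) || any(feature$end > genome$length)) {
    stop("extract_feature_sequence: coordinates outside genome '", genome$id, "'")
  }
  segs <- vapply(seq_len(nrow(feature)), function(i) {
    s <- substr(genome$sequence, feature$start[i], feature$end[i])
    if (feature$strand[i] == "-") revcomp(s) else s
  }, character(1))
  paste(segs, collapse = "")
}

# codon -> amino acid lookup, NCBI table 11 (identical codon assignments to
# the standard table; table 11 differs only in permitted starts)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa <- as.character(gc)
  names(aa) <- names(gc)
  aa
}

#' Translate a CDS
#'
#' Standard archaeal/bacterial translation (NCBI table 11) with optional
#' amber readthrough: with \code{readthrough_amber = TRUE} the amber stop TAG
#' is decoded as pyrrolysine ('O') and translation continues; TAA and TGA
#' always terminate. Translation stops at (and excludes) the first
#' terminating stop codon. Codons containing N translate to 'X'.
#'
#' @param nt DNA string whose length is a multiple of 3.
#' @param readthrough_amber Logical; decode TAG as 'O' instead of stopping.
#' @return Amino-acid string over the 20 standard residues plus 'O'/'X'.
#' @export
translate_cds <- function(nt, readthrough_amber = FALSE) {
  nt <- toupper(as.character(nt))
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("translate_cds: length ", n, " is not a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"          # codons containing N (or other ambiguity)
  stop_mask <- aa == "*"
  if (readthrough_amber) {
    aa[codons == "TAG"] <- "O"
    stop_mask <- aa == "*"      # only TAA/TGA remain stops
  }
  first_stop <- which(stop_mask)
  keep <- if (length(first_stop)) seq_len(first_stop[1] - 1L) else seq_along(aa)
  paste(aa[keep], collapse = "")
}

#' Write genome records to FASTA
#' @param records List of \code{genome_record} (or a single one).
#' @param path Output path.
#' @param width Line width.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_record")) records <- list(records)
  dna <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(dna) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(dna, filepath = path, width = width)
  invisible(path)
}

#' Write protein sequences to FASTA ('O' permitted)
#' @param proteins Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Read a protein FASTA into a named character vector
#' @param path Protein FASTA path.
#' @return Named character vector (ids are the first header word).
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

rrna_product <- c("rRNA-5S" = "5S ribosomal RNA",
                  "rRNA-16S" = "16S ribosomal RNA",
                  "rRNA-23S" = "23S ribosomal RNA")

#' Write a feature set to GFF3
#'
#' Native GFF3 convention: 1-based inclusive coordinates, so no shifting
#' occurs relative to the internal representation. rRNA kinds are written
#' with type \code{rRNA} and a product naming the subunit; the reader maps
#' them back.
#'
#' @param features A \code{feature_set}.
#' @param path Output path.
#' @param genome Optional \code{genome_record} for the \code{##sequence-region}
#'   pragma.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(features, path, genome = NULL) {
  gid <- attr(features, "genome_id")
  df <- as.data.frame(features)
  type <- ifelse(grepl("^rRNA-", df$kind), "rRNA", df$kind)
  product <- df$product
  blank <- grepl("^rRNA-", df$kind) & !nzchar(product)
  product[blank] <- rrna_product[df$kind[blank]]
  gr <- GenomicRanges::GRanges(
    seqnames = gid,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    type = type, ID = df$id, product = product,
    phase = ifelse(type == "CDS", 0L, NA_integer_)
  )
  if (!is.null(genome)) {
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(genome$length, gid)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into a feature set
#'
#' @param path GFF3 path.
#' @param genome_id Optional: restrict to one seqid (default: the single
#'   seqid present; error if several and none named).
#' @param genome_length Optional bound check.
#' @return A \code{feature_set}. Rows sharing an \code{ID} become segments of
#'   one feature.
#' @export
read_gff3 <- function(path, genome_id = NULL, genome_length = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(genome_id)) {
    sq <- as.character(unique(GenomicRanges::seqnames(gr)))
    if (length(sq) != 1L) {
      stop("read_gff3: several seqids in ", path, "; pass genome_id")
    }
    genome_id <- sq
  } else {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == genome_id]
  }
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  product <- if ("product" %in% names(md)) as.character(md$product) else rep("", length(gr))
  product[is.na(product)] <- ""
  kind <- type
  is_r <- type == "rRNA"
  kind[is_r & grepl("16S", product)] <- "rRNA-16S"
  kind[is_r & grepl("23S", product)] <- "rRNA-23S"
  kind[is_r & grepl("5S", product)] <- "rRNA-5S"
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  id[is.na(id)] <- sprintf("feat_%04d", which(is.na(id)))
  df <- data.frame(
    id = id, kind = kind,
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = product, stringsAsFactors = FALSE
  )
  keep <- df$kind %in% c("CDS", "tRNA", "rRNA-5S", "rRNA-16S", "rRNA-23S", "ncRNA")
  feature_set(genome_id, df[keep, , drop = FALSE], genome_length)
}

#' Remap an annotated genome to its reverse complement
#'
#' Utility for strand-symmetry checks: reverse-complements the sequence and
#' remaps every feature (\code{start' = L - end + 1}, strand flipped).
#'
#' @param genome A \code{genome_record}.
#' @param features A \code{feature_set} (optional).
#' @return List with elements \code{genome} and \code{features}.
#' @export
revcomp_annotated <- function(genome, features = NULL) {
  rc <- genome_record(genome$id, revcomp(genome$sequence), genome$topology)
  fs <- NULL
  if (!is.null(features)) {
    df <- as.data.frame(features)
    L <- genome$length
    new_start <- L - df$end + 1L
    new_end <- L - df$start + 1L
    df$start <- new_start; df$end <- new_end
    df$strand <- ifelse(df$strand == "+", "-", "+")
    fs <- feature_set(attr(features, "genome_id"), df, L)
  }
  list(genome = rc, features = fs)
}
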