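# Synthetic annotated archaeal-like genomes with planted, truth-recorded
# instances of every signal the detectors target: amber-readthrough (Pyl)
# loci, the pylTSBCD cassette, ORB motif pairs flanking an orc1/cdc6 gene,
# CRISPR direct-repeat/spacer arrays, and operonic or scattered rRNA genes.
#
# Background is order-0 (iid) sequence at the configured GC; genes are
# random sense-codon runs with GC-weighted codon sampling. Stop codons are
# allocated by largest-remainder quota, so the realized stop usage matches
# the configured fractions to < 1 stop codon, then shuffled.

#' The "Ca. M. alvus" CRISPR direct repeat (36 bp)
#' @export
DR_ALVUS <- "ATCTACACTAGTAGAAATTCTGAATGAGTTTTAGAC"

#' Synthetic genome configuration
#'
#' Defaults state the parameter envelope of the three sequenced
#' Methanomassiliicoccales genomes: ~2 Mbp, GC inside 41-61%, coding
#' density ~88-90%, mean CDS ~900 bp.
#'
#' @param seed Integer RNG seed; identical configs give byte-identical
#'   output.
#' @param genome_length Genome size in bp.
#' @param gc_fraction Target G+C fraction of the background and of codon
#'   sampling weights.
#' @param target_coding_density Fraction of positions covered by gene
#'   features.
#' @param mean_cds_length Mean CDS length in bp (stop included).
#' @param stop_usage Named probabilities for TAA/TAG/TGA, summing to 1.
#' @param topology Replicon topology.
#' @param genome_id Record id.
#' @param planted List of \code{\link{plant_spec}} elements.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(seed = 1L,
                         genome_length = 2e6,
                         gc_fraction = 0.55,
                         target_coding_density = 0.89,
                         mean_cds_length = 900,
                         stop_usage = c(TAA = 0.45, TAG = 0.10, TGA = 0.45),
                         topology = c("circular", "linear"),
                         genome_id = NULL,
                         planted = list()) {
  topology <- match.arg(topology)
  stopifnot(genome_length > 0, gc_fraction > 0, gc_fraction < 1,
            target_coding_density > 0, target_coding_density < 1,
            mean_cds_length >= 150)
  if (!setequal(names(stop_usage), c("TAA", "TAG", "TGA"))) {
    stop("synth_config: stop_usage must be named TAA/TAG/TGA")
  }
  stop_usage <- stop_usage[c("TAA", "TAG", "TGA")]
  if (abs(sum(stop_usage) - 1) > 1e-9) stop("synth_config: stop_usage must sum to 1")
  if (is.null(genome_id)) genome_id <- sprintf("synth_%d", as.integer(seed))
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         gc_fraction = gc_fraction,
         target_coding_density = target_coding_density,
         mean_cds_length = mean_cds_length, stop_usage = stop_usage,
         topology = topology, genome_id = genome_id, planted = planted),
    class = "synth_config"
  )
}

#' Specification of one planted element
#'
#' @param kind One of \code{pyl_locus}, \code{pyl_cassette}, \code{orb_pair},
#'   \code{crispr_array}, \code{rrna_set}.
#' @param ... Kind-specific parameters; missing ones take documented
#'   defaults at generation time. \code{pyl_locus}: \code{reference_protein},
#'   \code{split_position}, \code{ref_id}. \code{orb_pair}: \code{core},
#'   \code{spacing}, \code{orientation}, \code{distance}.
#'   \code{crispr_array}: \code{dr}, \code{n_spacers}, \code{spacer_len_min},
#'   \code{spacer_len_max}. \code{rrna_set}: \code{arrangement}
#'   (\code{"operonic"}/\code{"scattered"}).
#' @return A \code{plant_spec} list.
#' @export
plant_spec <- function(kind = c("pyl_locus", "pyl_cassette", "orb_pair",
                                "crispr_array", "rrna_set"), ...) {
  kind <- match.arg(kind)
  structure(c(list(kind = kind), list(...)), class = "plant_spec")
}

## ---- low-level sequence samplers ----------------------------------------

base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  p <- base_probs(gc)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rand_protein <- function(n, start_met = TRUE) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  s <- paste(sample(aa, n, replace = TRUE), collapse = "")
  if (start_met) s <- paste0("M", substr(s, 2, n))
  s
}

codon_gc_weight <- function(codons, gc) {
  p <- base_probs(gc)
  vapply(strsplit(codons, ""), function(b) prod(p[b]), numeric(1))
}

sense_codons <- function() {
  tab <- codon_table()
  names(tab)[tab != "*"]
}

# sample n sense codons with GC-dependent weights
rand_codons <- function(n, gc) {
  cods <- sense_codons()
  w <- codon_gc_weight(cods, gc)
  sample(cods, n, replace = TRUE, prob = w)
}

#' Back-translate a protein with GC-weighted codon sampling
#'
#' Synonymous codons are drawn with probability proportional to the
#' iid-base probability of the codon at the configured GC, so coding
#' sequence composition tracks the genomic GC target.
#'
#' @param protein Amino-acid string (20 standard residues).
#' @param gc_fraction Target GC.
#' @return DNA string of length \code{3 * nchar(protein)} (no stop).
#' @export
back_translate <- function(protein, gc_fraction = 0.5) {
  tab <- codon_table()
  by_aa <- split(names(tab), tab)
  res <- vapply(strsplit(toupper(protein), "")[[1]], function(a) {
    cods <- by_aa[[a]]
    if (is.null(cods)) stop("back_translate: no codon for residue '", a, "'")
    if (length(cods) == 1L) return(cods)
    sample(cods, 1L, prob = codon_gc_weight(cods, gc_fraction))
  }, character(1))
  paste(res, collapse = "")
}

## ---- planted blocks ------------------------------------------------------

#' Encode a pyrrolysine readthrough locus
#'
#' Builds the positive case the readthrough detector must find: a
#' TAG-terminated CDS encoding the first \code{split_position} residues of a
#' reference protein, followed immediately in frame by the remaining
#' residues and an ochre stop. Standard-code translation of the CDS stops at
#' the amber; readthrough translation of the fused gene equals the reference
#' with 'O' inserted after \code{split_position} (so the 'O' sits at
#' position \code{split_position + 1} of the fusion).
#'
#' @param reference_protein Amino-acid string.
#' @param split_position Integer, \code{1 < split_position < nchar(reference)}.
#' @param gc_fraction GC for back-translation.
#' @return List: \code{cds_nt} (ends in TAG), \code{tail_nt} (in-frame
#'   continuation ending in TAA), \code{unit_seq}, \code{upstream_aa},
#'   \code{extension_aa}, \code{expected_fusion}.
#' @export
plant_pyl_locus <- function(reference_protein, split_position, gc_fraction = 0.5) {
  n <- nchar(reference_protein)
  split_position <- as.integer(split_position)
  if (split_position <= 1L || split_position >= n) {
    stop("plant_pyl_locus: split_position must lie strictly inside the reference")
  }
  up_aa <- substr(reference_protein, 1L, split_position)
  ext_aa <- substr(reference_protein, split_position + 1L, n)
  cds_nt <- paste0(back_translate(up_aa, gc_fraction), "TAG")
  tail_nt <- paste0(back_translate(ext_aa, gc_fraction), "TAA")
  list(cds_nt = cds_nt, tail_nt = tail_nt,
       unit_seq = paste0(cds_nt, tail_nt),
       upstream_aa = up_aa, extension_aa = ext_aa,
       expected_fusion = paste0(up_aa, "O", ext_aa))
}

# Each realize_* returns a list of "units". A unit:
#   list(seq, feats = data.frame(id, kind, lstart, lend, strand, product)
#        with coords local to seq, feature = logical rows counted as genic,
#        truth = list(...) with local coords to be shifted)
unit <- function(seq, feats = NULL, truth = NULL) {
  list(seq = seq, feats = feats, truth = truth, width = nchar(seq))
}

local_feat <- function(id, kind, lstart, lend, strand, product) {
  data.frame(id = id, kind = kind, lstart = as.integer(lstart),
             lend = as.integer(lend), strand = strand, product = product,
             stringsAsFactors = FALSE)
}

realize_pyl_locus <- function(p, gc, idx) {
  ref <- p$reference_protein %||% rand_protein(300L)
  split <- as.integer(p$split_position %||% floor(nchar(ref) / 2))
  ref_id <- p$ref_id %||% sprintf("pylref_%d", idx)
  pl <- plant_pyl_locus(ref, split, gc)
  fid <- sprintf("pyl_locus_%d", idx)
  feats <- local_feat(fid, "CDS", 1L, nchar(pl$cds_nt), "+",
                      "methyltransferase-like protein (amber readthrough)")
  truth <- list(kind = "pyl_locus", cds_id = fid,
                lstart = 1L, lend = nchar(pl$cds_nt), strand = "+",
                amber_local = nchar(pl$cds_nt) - 2L,
                split_position = split, ref_id = ref_id,
                reference_protein = ref,
                upstream_aa = pl$upstream_aa, extension_aa = pl$extension_aa,
                expected_fusion = pl$expected_fusion)
  list(unit(pl$unit_seq, feats, truth))
}

realize_pyl_cassette <- function(p, gc, idx) {
  lens <- c(pylS = 420L, pylB = 350L, pylC = 380L, pylD = 280L)
  prods <- c(pylS = "pyrrolysyl-tRNA synthetase PylS",
             pylB = "pyrrolysine biosynthesis protein PylB",
             pylC = "pyrrolysine biosynthesis protein PylC",
             pylD = "pyrrolysine biosynthesis protein PylD")
  refs <- p$ref_proteins %||% NULL
  seqs <- character(0); feats <- NULL; pos <- 0L
  gene_ids <- character(0); ref_out <- character(0)
  # pylT: 72 bp tRNA with the literal CTA anticodon at 33..35
  trna <- rand_dna(72L, gc)
  substr(trna, 33L, 35L) <- "CTA"
  tid <- sprintf("pylT_%d", idx)
  seqs <- c(seqs, trna)
  feats <- local_feat(tid, "tRNA", 1L, 72L, "+", "tRNA-Pyl (anticodon CTA)")
  pos <- 72L
  for (g in names(lens)) {
    ref <- if (!is.null(refs) && g %in% names(refs)) refs[[g]] else rand_protein(lens[[g]])
    nt <- paste0(back_translate(ref, gc), "TAA")
    gap <- rand_dna(20L, gc)
    gid <- sprintf("%s_%d", g, idx)
    feats <- rbind(feats, local_feat(gid, "CDS", pos + 21L, pos + 20L + nchar(nt),
                                     "+", prods[[g]]))
    seqs <- c(seqs, gap, nt)
    pos <- pos + 20L + nchar(nt)
    gene_ids[g] <- gid; ref_out[g] <- ref
  }
  truth <- list(kind = "pyl_cassette", pylT_id = tid, gene_ids = as.list(gene_ids),
                ref_proteins = as.list(ref_out))
  list(unit(paste(seqs, collapse = ""), feats, truth))
}

realize_orb_pair <- function(p, gc, idx, screen) {
  core <- toupper(p$core %||% orb_core_default())
  spacing <- as.integer(p$spacing %||% 39L)
  orientation <- p$orientation %||% "inverted"
  distance <- as.integer(p$distance %||% 2000L)
  if (spacing < 1L) stop("orb_pair plant: spacing must be >= 1")
  w <- nchar(core)
  hit2 <- if (orientation == "inverted") revcomp(core) else core
  spacer <- screen(function() rand_dna(spacing - 1L, gc))
  gap <- screen(function() rand_dna(distance, gc))
  gene_aa <- rand_protein(409L)
  gene_nt <- paste0(back_translate(gene_aa, gc), "TAA")
  gid <- sprintf("cdc6_%d", idx)
  lstart_gene <- w + spacing + w + distance + 1L
  feats <- local_feat(gid, "CDS", lstart_gene, lstart_gene + nchar(gene_nt) - 1L,
                      "+", "replication initiator protein Orc1/Cdc6.1")
  truth <- list(kind = "orb_pair", core = core,
                hit1 = list(lstart = 1L, lend = w, strand = "+"),
                hit2 = list(lstart = w + spacing, lend = 2L * w + spacing - 1L,
                            strand = if (orientation == "inverted") "-" else "+"),
                spacing = spacing, orientation = orientation,
                cdc6_id = gid, distance = distance)
  list(unit(paste0(core, spacer, hit2, gap, gene_nt), feats, truth))
}

realize_crispr_array <- function(p, gc, idx, screen) {
  dr <- toupper(p$dr %||% DR_ALVUS)
  n_spacers <- as.integer(p$n_spacers %||% 12L)
  smin <- as.integer(p$spacer_len_min %||% 25L)
  smax <- as.integer(p$spacer_len_max %||% 28L)
  stopifnot(n_spacers >= 1L, smin <= smax)
  lens <- sample(seq.int(smin, smax), n_spacers, replace = TRUE)
  spacers <- vapply(lens, function(l) screen(function() rand_dna(l, gc)), "")
  parts <- character(2L * n_spacers + 1L)
  parts[seq(1L, 2L * n_spacers + 1L, 2L)] <- dr
  parts[seq(2L, 2L * n_spacers, 2L)] <- spacers
  seqs <- paste(parts, collapse = "")
  w <- nchar(dr)
  rep_start <- cumsum(c(1L, w + lens))
  truth <- list(kind = "crispr_array", dr = dr, n_spacers = n_spacers,
                spacers = spacers,
                repeat_lstart = rep_start, repeat_lend = rep_start + w - 1L)
  list(unit(seqs, NULL, truth))
}

realize_rrna_set <- function(p, gc, idx) {
  arrangement <- p$arrangement %||% "scattered"
  lens <- c(`rRNA-16S` = 1500L, `rRNA-23S` = 2900L, `rRNA-5S` = 120L)
  mk <- function(kind, tag) {
    nt <- rand_dna(lens[[kind]], gc)
    id <- sprintf("rrna_%s_%d", tag, idx)
    list(nt = nt, feat = local_feat(id, kind, 1L, nchar(nt), "+",
                                    rrna_product[[kind]]), id = id)
  }
  s16 <- mk("rRNA-16S", "16S"); s23 <- mk("rRNA-23S", "23S")
  s5a <- mk("rRNA-5S", "5Sa"); s5b <- mk("rRNA-5S", "5Sb")
  if (arrangement == "operonic") {
    its1 <- rand_dna(99L, gc); its2 <- rand_dna(50L, gc)
    f23 <- s23$feat; f23$lstart <- 1500L + 99L + 1L; f23$lend <- f23$lstart + 2900L - 1L
    f5 <- s5a$feat; f5$lstart <- f23$lend + 50L + 1L; f5$lend <- f5$lstart + 120L - 1L
    op <- unit(paste0(s16$nt, its1, s23$nt, its2, s5a$nt),
               rbind(s16$feat, f23, f5),
               list(kind = "rrna_set", arrangement = "operonic",
                    ids = c(s16$id, s23$id, s5a$id, s5b$id)))
    list(op, unit(s5b$nt, s5b$feat, NULL))
  } else {
    list(unit(s16$nt, s16$feat,
              list(kind = "rrna_set", arrangement = "scattered",
                   ids = c(s16$id, s23$id, s5a$id, s5b$id))),
         unit(s23$nt, s23$feat, NULL),
         unit(s5a$nt, s5a$feat, NULL),
         unit(s5b$nt, s5b$feat, NULL))
  }
}

## ---- screening -----------------------------------------------------------

# A regenerating screen: the background must carry no accidental copy of a
# planted CRISPR DR (exact, either strand) and no 22-mer within Hamming
# distance 1 of a planted ORB core (either strand), so planted-recovery
# tests are exact.
make_screen <- function(cores, drs) {
  cores <- unique(toupper(cores)); drs <- unique(toupper(drs))
  pats <- c(lapply(cores, function(x) list(p = x, mm = 1L)),
            lapply(drs, function(x) list(p = x, mm = 0L)))
  pats <- c(pats, lapply(pats, function(q) list(p = revcomp(q$p), mm = q$mm)))
  ok <- function(s) {
    if (!length(pats) || !nzchar(s)) return(TRUE)
    d <- Biostrings::DNAString(s)
    for (q in pats) {
      if (nchar(q$p) > nchar(s)) next
      if (Biostrings::countPattern(q$p, d, max.mismatch = q$mm) > 0L) return(FALSE)
    }
    TRUE
  }
  function(gen) {
    for (i in 1:100) {
      s <- gen()
      if (ok(s)) return(s)
    }
    stop("synthetic generator: could not sample a collision-free segment")
  }
}

## ---- stop-codon quota ----------------------------------------------------

# largest-remainder allocation, then a seeded shuffle
stop_quota <- function(n, stop_usage) {
  raw <- n * stop_usage
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  sample(rep(names(stop_usage), times = base))
}

## ---- generator -----------------------------------------------------------

#' Generate a synthetic annotated genome with planted signals
#'
#' Deterministic for a fixed config (byte-identical FASTA/GFF3/truth).
#' Realized coding density is within a fraction of a gene of the target by
#' construction; realized stop-codon usage matches the configured fractions
#' by quota allocation.
#'
#' @param config A \code{\link{synth_config}}.
#' @return List with elements \code{genome} (\code{genome_record}),
#'   \code{features} (\code{feature_set}), \code{truth} (list of per-plant
#'   truth entries plus background bookkeeping), \code{config}.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  L <- config$genome_length
  gc <- config$gc_fraction

  cores <- character(0); drs <- character(0)
  for (p in config$planted) {
    if (p$kind == "orb_pair") cores <- c(cores, toupper(p$core %||% orb_core_default()))
    if (p$kind == "crispr_array") drs <- c(drs, toupper(p$dr %||% DR_ALVUS))
  }
  screen <- make_screen(cores, drs)

  # planted units
  units <- list()
  counts <- c(pyl_locus = 0L, pyl_cassette = 0L, orb_pair = 0L,
              crispr_array = 0L, rrna_set = 0L)
  for (p in config$planted) {
    counts[p$kind] <- counts[p$kind] + 1L
    idx <- counts[p$kind]
    u <- switch(p$kind,
      pyl_locus = realize_pyl_locus(p, gc, idx),
      pyl_cassette = realize_pyl_cassette(p, gc, idx),
      orb_pair = realize_orb_pair(p, gc, idx, screen),
      crispr_array = realize_crispr_array(p, gc, idx, screen),
      rrna_set = realize_rrna_set(p, gc, idx))
    units <- c(units, u)
  }
  planted_cover <- sum(vapply(units, function(u) {
    if (is.null(u$feats)) 0L else sum(u$feats$lend - u$feats$lstart + 1L)
  }, integer(1)))
  planted_width <- sum(vapply(units, `[[`, integer(1), "width"))
  if (planted_width >= L) {
    stop("generate_genome: planted footprint (", planted_width,
         " bp) exceeds genome_length (", L, " bp)")
  }

  # background genes to reach the target coding cover
  need <- round(config$target_coding_density * L) - planted_cover
  if (need < 0) stop("generate_genome: planted features alone exceed the coding target")
  shape <- 1.8
  lens <- integer(0); tot <- 0L
  while (tot < need) {
    l <- 3L * max(30L, round(stats::rgamma(1, shape = shape,
                                           scale = config$mean_cds_length / shape) / 3))
    if (tot + l > need) l <- max(90L, 3L * round((need - tot) / 3))
    lens <- c(lens, l); tot <- tot + l
  }
  n_genes <- length(lens)
  if (planted_width + tot >= L) {
    stop("generate_genome: cannot fit ", tot, " bp of background genes plus ",
         planted_width, " bp of planted blocks into ", L, " bp; ",
         "lower target_coding_density or enlarge the genome")
  }
  stops <- stop_quota(n_genes, config$stop_usage)
  starts <- sample(c("ATG", "GTG", "TTG"), n_genes, replace = TRUE,
                   prob = c(0.84, 0.11, 0.05))
  sense <- sense_codons()
  wts <- codon_gc_weight(sense, gc)
  bg_units <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    n_int <- lens[i] / 3L - 2L
    nt <- screen(function() {
      paste0(starts[i], paste(sample(sense, n_int, replace = TRUE, prob = wts),
                              collapse = ""), stops[i])
    })
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") nt_g <- revcomp(nt) else nt_g <- nt
    bg_units[[i]] <- unit(nt_g,
                          local_feat(sprintf("bg"), "CDS", 1L, lens[i], strand,
                                     "hypothetical protein"),
                          NULL)
  }

  units <- c(units, bg_units)
  units <- units[sample(length(units))]
  n_units <- length(units)

  # intergenic gaps: exponential-ish, rescaled to close the genome exactly
  total_gap <- L - planted_width - tot
  u <- stats::rexp(n_units + 1L)
  gaps <- as.integer(u / sum(u) * total_gap)
  short <- total_gap - sum(gaps)
  if (short > 0L) {
    add <- sample(n_units + 1L, short, replace = short > n_units + 1L)
    for (a in add) gaps[a] <- gaps[a] + 1L
  }

  # assemble
  parts <- character(2L * n_units + 1L)
  feat_rows <- list(); truths <- list()
  pos <- 0L; bg_i <- 0L
  for (i in seq_len(n_units)) {
    g <- screen(function() rand_dna(gaps[i], gc))
    parts[2L * i - 1L] <- g
    pos <- pos + gaps[i]
    uu <- units[[i]]
    parts[2L * i] <- uu$seq
    if (!is.null(uu$feats)) {
      f <- uu$feats
      if (identical(f$id[1], "bg")) {
        bg_i <- bg_i + 1L
        f$id <- sprintf("gene_%04d", bg_i)
      }
      f$start <- f$lstart + pos; f$end <- f$lend + pos
      feat_rows[[length(feat_rows) + 1L]] <-
        f[, c("id", "kind", "start", "end", "strand", "product")]
    }
    if (!is.null(uu$truth)) {
      tr <- shift_truth(uu$truth, pos)
      truths[[length(truths) + 1L]] <- tr
    }
    pos <- pos + uu$width
  }
  parts[2L * n_units + 1L] <- screen(function() rand_dna(gaps[n_units + 1L], gc))
  sequence <- paste(parts, collapse = "")
  stopifnot(nchar(sequence) == L)

  feats <- do.call(rbind, feat_rows)
  fs <- feature_set(config$genome_id, feats, L)
  genome <- genome_record(config$genome_id, sequence, config$topology)

  truth <- list(
    genome_id = config$genome_id,
    planted = truths,
    n_background_genes = n_genes,
    stop_assignment = table(stops),
    target_coding_density = config$target_coding_density,
    coding_cover = planted_cover + tot
  )
  list(genome = genome, features = fs, truth = truth, config = config)
}

# shift all *_local / lstart coordinates in a truth entry by an offset
shift_truth <- function(tr, off) {
  sh <- function(x) x + off
  switch(tr$kind,
    pyl_locus = {
      tr$cds_start <- sh(tr$lstart); tr$cds_end <- sh(tr$lend)
      tr$amber_position <- sh(tr$amber_local)
      tr$lstart <- tr$lend <- tr$amber_local <- NULL
      tr
    },
    orb_pair = {
      for (h in c("hit1", "hit2")) {
        tr[[h]]$start <- sh(tr[[h]]$lstart); tr[[h]]$end <- sh(tr[[h]]$lend)
        tr[[h]]$lstart <- tr[[h]]$lend <- NULL
      }
      tr
    },
    crispr_array = {
      tr$repeat_start <- sh(tr$repeat_lstart); tr$repeat_end <- sh(tr$repeat_lend)
      tr$start <- tr$repeat_start[1]; tr$end <- tr$repeat_end[length(tr$repeat_end)]
      tr$repeat_lstart <- tr$repeat_lend <- NULL
      tr
    },
    tr
  )
}

#' Write a generated genome to disk (FASTA + GFF3 + truth JSON)
#'
#' @param gen Result of \code{\link{generate_genome}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synthetic <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- gen$genome$id
  fa <- file.path(dir, paste0(id, ".fasta"))
  gff <- file.path(dir, paste0(id, ".gff3"))
  tj <- file.path(dir, paste0(id, ".truth.json"))
  write_genome_fasta(gen$genome, fa)
  write_gff3(gen$features, gff, genome = gen$genome)
  truth <- gen$truth
  truth$stop_assignment <- as.list(truth$stop_assignment)
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fasta = fa, gff3 = gff, truth = tj))
}
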