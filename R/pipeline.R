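# Orchestration: run every analysis stage on one genome (plus optional
# proteomes / marker matrix) and write machine-readable reports. All report
# coordinates are 1-based inclusive; the single BED output uses the BED
# convention (0-based half-open), stated in its header.

#' Assemble a pipeline configuration
#'
#' @param genome Path to a FASTA (with \code{gff}) or GenBank file, or a
#'   \code{genome_record}.
#' @param gff Optional GFF3 annotation path (or a \code{feature_set}).
#' @param refdb Optional protein FASTA path or named vector (Pyl stage).
#' @param proteomes Optional list of >= 2 \code{\link{proteome}} objects or
#'   protein FASTA paths (orthology stage; 3 enable the Venn partition).
#' @param marker_matrix Optional presence-matrix TSV path or logical matrix.
#' @param marker_groups Optional group TSV path or \code{taxon_groups}.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the report (the stages are deterministic).
#' @param pyl,orb,crispr,homology,origin_window,max_operon_gap Stage
#'   parameter blocks / values (module defaults when NULL).
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(genome, gff = NULL, refdb = NULL, proteomes = NULL,
                            marker_matrix = NULL, marker_groups = NULL,
                            out_dir = "methacomp_out", seed = 1L,
                            pyl = NULL, orb = NULL, crispr = NULL,
                            homology = NULL, origin_window = 10000L,
                            max_operon_gap = 500L) {
  structure(list(genome = genome, gff = gff, refdb = refdb,
                 proteomes = proteomes, marker_matrix = marker_matrix,
                 marker_groups = marker_groups, out_dir = out_dir,
                 seed = as.integer(seed),
                 pyl = pyl %||null% pyl_params(),
                 orb = orb %||null% orb_motif(),
                 crispr = crispr %||null% crispr_params(),
                 homology = homology %||null% homology_params(),
                 origin_window = origin_window,
                 max_operon_gap = max_operon_gap),
            class = "pipeline_config")
}

`%||null%` <- function(a, b) if (is.null(a)) b else a

resolve_genome <- function(config) {
  g <- config$genome
  if (inherits(g, "genome_record")) {
    return(list(genome = g, features = config$gff))
  }
  stopifnot(is.character(g), file.exists(g))
  if (grepl("\\.(gb|gbk|gbff|genbank)$", g, ignore.case = TRUE)) {
    recs <- read_genome(g, "genbank")
    feats <- attr(recs, "features")
    return(list(genome = recs[[1]],
                features = if (!is.null(feats)) feats[[1]] else NULL))
  }
  recs <- read_genome(g, "fasta")
  feats <- config$gff
  if (is.character(feats)) {
    feats <- read_gff3(feats, genome_id = recs[[1]]$id,
                       genome_length = recs[[1]]$length)
  }
  list(genome = recs[[1]], features = feats)
}

write_tsv_report <- function(df, path, header_comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Runs, as inputs permit: genome statistics, amber-readthrough (Pyl)
#' scanning, ORB/origin mapping, CRISPR detection, orthology (>= 2
#' proteomes; 3 for the Venn partition) and marker classification. Writes a
#' JSON summary plus per-stage TSV/GFF3/FASTA/BED artifacts to
#' \code{config$out_dir}. Deterministic: identical config gives a
#' byte-identical JSON summary.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return The summary list, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- resolve_genome(config)
  genome <- gm$genome; features <- gm$features
  summary <- list(schema = "methacomp-report/1",
                  seed = config$seed,
                  genome_id = genome$id)

  if (!is.null(features)) {
    gs <- genome_summary(genome, features)
    su <- stop_codon_usage(genome, features)
    ro <- rrna_organization(features, config$max_operon_gap)
    summary$stats <- list(
      genome_size = gs$genome_size,
      gc_fraction = round(gs$gc_fraction, 6),
      coding_fraction = round(gs$coding_fraction, 6),
      intergenic_mean = round(gs$intergenic_mean, 3),
      intergenic_sd = round(gs$intergenic_sd, 3),
      cds_mean_length = round(gs$cds_mean_length, 3),
      cds_median_length = gs$cds_median_length,
      gene_count = as.list(gs$gene_count),
      stop_usage = list(TAA = round(su$fraction_TAA, 6),
                        TAG = round(su$fraction_TAG, 6),
                        TGA = round(su$fraction_TGA, 6),
                        n_cds = su$n_cds),
      rrna = list(classification = ro$classification, order = ro$order)
    )
  } else {
    gcf <- sum(Biostrings::letterFrequency(
      Biostrings::DNAString(genome$sequence), c("G", "C"))) / genome$length
    summary$stats <- list(genome_size = genome$length,
                          gc_fraction = round(gcf, 6))
  }

  if (!is.null(features) && !is.null(config$refdb)) {
    refdb <- config$refdb
    if (is.character(refdb) && length(refdb) == 1L && file.exists(refdb)) {
      refdb <- read_protein_fasta(refdb)
    }
    cands <- detect_readthrough_candidates(genome, features, refdb, config$pyl)
    cass <- detect_pyl_cassette(genome, features, refdb)
    write_tsv_report(
      as.data.frame(cands)[, c("cds_id", "amber_genome_position", "ref_id",
                               "upstream_identity", "extension_identity",
                               "n_ambers")],
      file.path(config$out_dir, "pyl_candidates.tsv"),
      "amber readthrough candidates; coordinates 1-based inclusive")
    if (nrow(cands)) {
      write_protein_fasta(
        stats::setNames(cands$fused_protein, cands$cds_id),
        file.path(config$out_dir, "pyl_fusions.faa"))
    }
    summary$pyl <- list(
      n_candidates = nrow(cands),
      candidate_ids = as.list(cands$cds_id),
      cassette = list(pylT = cass$pylT$present, pylS = cass$pylS$present,
                      pylB = cass$pylB$present, pylC = cass$pylC$present,
                      pylD = cass$pylD$present, complete = cass$complete)
    )
  }

  hits <- scan_motif(genome, config$orb)
  pairs <- pair_hits(hits)
  write_orb_bed(hits, genome, file.path(config$out_dir, "orb_hits.bed"))
  write_tsv_report(as.data.frame(pairs),
                   file.path(config$out_dir, "orb_pairs.tsv"),
                   "ORB motif pairs; coordinates 1-based inclusive")
  summary$orb <- list(n_hits = nrow(hits), n_pairs = nrow(pairs))
  if (!is.null(features)) {
    orig <- withCallingHandlers(
      call_origin(pairs, features, config$origin_window),
      warning = function(w) invokeRestart("muffleWarning"))
    write_tsv_report(as.data.frame(orig),
                     file.path(config$out_dir, "origin_candidates.tsv"),
                     "origin candidates; coordinates 1-based inclusive")
    summary$orb$n_origin_candidates <- nrow(orig)
    summary$orb$origin_genes <- as.list(unique(orig$gene_id))
  }

  arrays <- find_arrays(genome, config$crispr)
  summary$crispr <- list(
    n_arrays = length(arrays),
    arrays = lapply(arrays, function(a) {
      s <- array_summary(a)
      s[c("dr_length", "dr_consensus", "n_spacers", "spacer_len_min",
          "spacer_len_max", "start", "end")]
    })
  )
  if (length(arrays)) {
    spacers <- unlist(lapply(seq_along(arrays), function(i) {
      stats::setNames(arrays[[i]]$spacers,
                      sprintf("array%d_spacer%02d", i,
                              seq_along(arrays[[i]]$spacers)))
    }))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(spacers),
                                file.path(config$out_dir, "crispr_spacers.fasta"))
    reps <- do.call(rbind, lapply(seq_along(arrays), function(i) {
      r <- arrays[[i]]$repeats; r$array <- i; r
    }))
    write_tsv_report(reps, file.path(config$out_dir, "crispr_repeats.tsv"),
                     "CRISPR repeat units; coordinates 1-based inclusive")
  }

  if (!is.null(config$proteomes) && length(config$proteomes) >= 2L) {
    ps <- lapply(seq_along(config$proteomes), function(i) {
      p <- config$proteomes[[i]]
      if (inherits(p, "proteome")) p
      else proteome(names(config$proteomes)[i] %||null% sprintf("proteome%d", i),
                    read_protein_fasta(p))
    })
    if (length(ps) >= 3L) {
      vp <- venn_partition(ps[[1]], ps[[2]], ps[[3]], config$homology)
      summary$orthology <- list(
        cells = as.list(stats::setNames(as.integer(vp$counts[1, ]),
                                        colnames(vp$counts))),
        core_size = unname(vp$core_size))
      utils::write.table(vp$counts,
                         file.path(config$out_dir, "venn_counts.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    } else {
      bh <- best_hits(ps[[1]], ps[[2]], config$homology)
      summary$orthology <- list(n_best_hits = nrow(bh))
      write_tsv_report(bh, file.path(config$out_dir, "best_hits.tsv"),
                       "best hits (query proteome 1 vs subject proteome 2)")
    }
  }

  if (!is.null(config$marker_matrix) && !is.null(config$marker_groups)) {
    m <- config$marker_matrix
    if (is.character(m)) m <- read_presence_matrix(m)
    g <- config$marker_groups
    if (is.character(g)) g <- read_taxon_groups(g)
    mc <- classify_matrix(m, g)
    summary$markers <- list(summary = as.list(mc$summary))
    write_tsv_report(
      data.frame(family = names(mc$category),
                 category = ifelse(is.na(mc$category), "none",
                                   as.character(mc$category))),
      file.path(config$out_dir, "marker_categories.tsv"),
      "phyletic marker categories (1-6 or none)")
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

write_orb_bed <- function(hits, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ORB motif hits; BED convention: 0-based half-open", con)
  if (nrow(hits)) {
    bed <- data.frame(chrom = genome$id, start = hits$start - 1L,
                      end = hits$end,
                      name = sprintf("orb_%03d", seq_len(nrow(hits))),
                      score = hits$mismatches, strand = hits$strand)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Simulate one or more synthetic genomes to disk
#'
#' Wraps \code{\link{generate_genome}} for a list of configs and writes
#' FASTA + GFF3 + truth JSON per genome.
#'
#' @param configs A \code{\link{synth_config}} or list of them.
#' @param out_dir Output directory.
#' @return Named list of generation results, invisibly.
#' @export
simulate_genomes <- function(configs, out_dir) {
  if (inherits(configs, "synth_config")) configs <- list(configs)
  out <- lapply(configs, function(cf) {
    gen <- generate_genome(cf)
    write_synthetic(gen, out_dir)
    gen
  })
  names(out) <- vapply(out, function(g) g$genome$id, "")
  invisible(out)
}
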