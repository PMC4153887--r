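# Shared configuration for the analysis scripts.
#
# The campaign simulates a trio of annotated genomes whose parameter
# envelopes follow the three sequenced Methanomassiliicoccales
# representatives ("Ca. M. alvus" Mx1201, "Ca. M. intestinalis" Mx1,
# M. luminyensis B10): genome size ratio, GC, coding density ~89%, mean CDS
# ~900 bp, and their contrasting stop-codon usage (amber ~1.6% / ~7% /
# ~11.3%). Sizes are scaled to 1/8 of the real chromosomes so the whole
# workflow runs in minutes; every downstream statistic that depends on
# counts (not on absolute genome size) is unaffected by the scaling.

suppressPackageStartupMessages(library(methacomp))

SEED <- 20260918L
RESULTS <- "results"
SIM_DIR <- file.path(RESULTS, "simulated")

trio_profiles <- list(
  alvus        = list(length = 208000L, gc = 0.556,
                      stops = c(TAA = 0.17, TAG = 0.016, TGA = 0.814),
                      rrna = "scattered"),
  intestinalis = list(length = 241000L, gc = 0.413,
                      stops = c(TAA = 0.45, TAG = 0.07, TGA = 0.48),
                      rrna = "scattered"),
  luminyensis  = list(length = 327000L, gc = 0.605,
                      stops = c(TAA = 0.14, TAG = 0.113, TGA = 0.747),
                      rrna = "scattered")
)

trio_config <- function(name, k) {
  pr <- trio_profiles[[name]]
  set.seed(SEED + 500L + k)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ref <- paste0("M", paste(sample(aa20, 199, TRUE), collapse = ""))
  synth_config(
    seed = SEED + k, genome_length = pr$length, gc_fraction = pr$gc,
    target_coding_density = 0.89, mean_cds_length = 900,
    stop_usage = pr$stops, genome_id = paste0("synth_", name),
    planted = list(
      plant_spec("pyl_locus", reference_protein = ref, split_position = 100L,
                 ref_id = paste0("mtase_", name)),
      plant_spec("pyl_cassette"),
      plant_spec("orb_pair"),
      plant_spec("crispr_array", n_spacers = 12L),
      plant_spec("rrna_set", arrangement = pr$rrna)
    ))
}

# generate (or re-load from cache within one session) the simulated trio
load_trio <- function() {
  lapply(stats::setNames(nm = names(trio_profiles)), function(nm) {
    k <- match(nm, names(trio_profiles))
    generate_genome(trio_config(nm, k))
  })
}

write_result_tsv <- function(df, file, comment) {
  dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(RESULTS, file), "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", file.path(RESULTS, file))
}
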