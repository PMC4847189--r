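# ---- configuration loading ---------------------------------------------

#' Load a simulation configuration from YAML
#'
#' The YAML document holds overrides for [sim_config()] arguments; named
#' mappings (`arrays`, `occupancy`, `transcription`, `genes`,
#' `fibre_counts`) are converted to the native list/vector forms. Unknown
#' keys are an error, listing the offending names.
#'
#' @param path YAML file.
#' @return a [sim_config()].
#' @export
config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(sim_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("occupancy", "transcription", "genes", "fibre_counts")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$monomers)) {
    raw$monomers <- as.data.frame(lapply(raw$monomers, unlist),
                                  stringsAsFactors = FALSE)
  }
  if (!is.null(raw$slot_blot)) {
    raw$slot_blot <- as.data.frame(lapply(raw$slot_blot, unlist),
                                   stringsAsFactors = FALSE)
  }
  do.call(sim_config, raw)
}

# ---- pipeline ----------------------------------------------------------

#' Run the full synthetic analysis pipeline
#'
#' simulate -> map -> enrich -> consensus -> RNA counts -> classify ->
#' call/filter peaks -> quantify fibres and slot blots, writing every stage
#' output plus a run manifest (seed, configuration snapshot, md5 checksum
#' per output file) under `out_dir`. Re-running with the same configuration
#' reproduces all outputs byte-identically.
#'
#' @param config a [sim_config()] or the path to a YAML overrides file.
#' @param out_dir output directory, created if needed.
#' @param criteria peak filter criteria, see [peak_filter_criteria()].
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) list with the in-memory stage results: `sim`,
#'   `enrichment`, `consensus` (`base_freq_matrix`), `gc_percent`,
#'   `rna_counts`, `classification`, `class_summary`, `peaks_raw`,
#'   `peaks_kept`, `fibre_calls`, `fibre_summary`, `slot`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, criteria = peak_filter_criteria(),
                         quiet = FALSE) {
  cfg <- if (is.character(config)) config_from_yaml(config) else config
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  p <- function(...) file.path(out_dir, ...)

  # -- simulate
  say("simulate", "genome, reads, fibres, slot blot")
  sim <- simulate_genome(cfg)
  alpha <- resolve_alpha(sim)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chrSim = sim$genome)), p("genome.fa"))
  write.table(sim$annotation, p("annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_panel_fasta(sim$panel, p("panel.fa"))
  reads_ip <- simulate_reads(sim, "ip", alpha = alpha)
  reads_input <- simulate_reads(sim, "input", alpha = alpha)
  reads_rna <- simulate_reads(sim, "rna")
  write_fastq(reads_ip, p("reads_ip.fastq"))
  write_fastq(reads_input, p("reads_input.fastq"))
  write_fastq(reads_rna, p("reads_rna.fastq"))
  fibres <- simulate_fibres(cfg)
  write_fibre_traces(fibres, p("fibres"))
  slot <- simulate_slot_blot(cfg)
  write.table(slot, p("slot_blot.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(seed = cfg$seed, alpha = alpha,
                expected_ratios = as.list(
                  expected_enrichment_ratios(sim$annotation, alpha)),
                fibre_truth = vapply(fibres, attr, character(1),
                                     "truth_class"))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  # -- map
  say("map", sprintf("%d IP + %d input reads against %d panel entries",
                     nrow(reads_ip), nrow(reads_input), nrow(sim$panel)))
  mcfg <- mapper_config()
  map_ip <- map_readset(reads_ip, sim$panel, mcfg)
  map_input <- map_readset(reads_input, sim$panel, mcfg)
  write_hits(map_ip$hits, p("hits_ip.tsv"))
  write_hits(map_input$hits, p("hits_input.tsv"))

  # -- enrichment
  say("enrich", "normalised IP/input ratios")
  enr <- enrichment_table(map_ip, map_input, sim$panel)
  write_enrichment(enr, p("enrichment.tsv"))

  # -- consensus of the most enriched tandem family
  tand <- enr$entry[sim$panel$is_tandem[match(enr$entry, sim$panel$name)]]
  top <- tand[which.max(enr$ratio[match(tand, enr$entry)])]
  say("consensus", paste("base-frequency matrix for", top))
  lm_top <- sim$panel$monomer_length[sim$panel$name == top]
  mat <- build_base_matrix(map_ip$hits[map_ip$hits$entry == top, ],
                           reads_ip, entry = top, monomer_length = lm_top)
  write_base_matrix(mat, p("consensus_matrix.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(
    setNames(mat$consensus, paste0(top, "_consensus"))), p("consensus.fa"))
  gc_pct <- gc_content(mat$consensus)

  # -- RNA window counts
  ann <- sim$annotation
  gene_rows <- ann[ann$kind == "gene", , drop = FALSE]
  rna_counts <- NULL
  if (nrow(gene_rows) > 0) {
    gl <- unique(gene_rows$end - gene_rows$start)
    if (length(gl) == 1L) {
      say("rna", sprintf("counting on %d-bp windows", gl))
      gene_seqs <- setNames(substring(sim$genome, gene_rows$start + 1L,
                                      gene_rows$end), gene_rows$family)
      sat <- sim$panel[sim$panel$is_tandem &
                         2L * sim$panel$monomer_length == gl, , drop = FALSE]
      wp <- rna_window_panel(gene_seqs,
                             setNames(sat$sequence, sat$name))
      rna_counts <- count_rna_windows(reads_rna, wp, mcfg)
      write.table(rna_counts, p("rna_counts.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  # -- region classification
  say("classify", "annotated repeat regions by family")
  rep_rows <- ann[ann$kind %in% c("array", "interspersed"), , drop = FALSE]
  reg_seqs <- setNames(substring(sim$genome, rep_rows$start + 1L, rep_rows$end),
                       sprintf("%s:%d-%d", rep_rows$chrom, rep_rows$start,
                               rep_rows$end))
  cls <- classify_regions(reg_seqs, sim$panel, mcfg)
  cls$true_family <- rep_rows$family
  write.table(cls, p("classification.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cls_sum <- summarize_peaks(data.frame(region = cls$region), cls)

  # -- domain calling + stringent filter
  say("peaks", "window domain calling and stringent filtering")
  G <- nchar(sim$genome)
  cov_ip <- coverage_track(reads_ip, G, cfg$read_length)
  cov_in <- coverage_track(reads_input, G, cfg$read_length)
  pk <- call_domains(cov_ip, cov_in, read_length = cfg$read_length,
                     total_ip = nrow(reads_ip), total_input = nrow(reads_input))
  kept <- filter_peaks(pk, criteria)
  write.table(pk, p("domains_raw.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(kept, p("domains_filtered.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # -- fibres and slot blot
  say("fibres", "segmentation and pattern classification")
  fib <- classify_fibres(fibres)
  fib_sum <- summarize_fibres(fib$class)
  write.table(fib, p("fibre_calls.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fib_sum, p("fibre_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sr <- slot_ratio(slot$idv_ip, slot$idv_input, slot$background[1])
  slot_out <- cbind(slot, sr)
  write.table(slot_out, p("slot_ratios.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # -- manifest
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    tool = "satcen",
    version = as.character(utils::packageVersion("satcen")),
    seed = cfg$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    peak_criteria = unclass(criteria),
    config = cfg_snapshot(cfg),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(sim = sim, enrichment = enr, consensus = mat,
                 gc_percent = gc_pct, rna_counts = rna_counts,
                 classification = cls, class_summary = cls_sum,
                 peaks_raw = pk, peaks_kept = kept, fibre_calls = fib,
                 fibre_summary = fib_sum, slot = slot_out,
                 manifest = manifest, out_dir = out_dir))
}

# JSON-serialisable configuration snapshot
cfg_snapshot <- function(cfg) {
  x <- unclass(cfg)
  x$monomers <- as.list(x$monomers)
  x$slot_blot <- as.list(x$slot_blot)
  x
}
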