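#' Run the analysis pipeline
#'
#' Wires the stages together: `simulate` (synthetic genome with truth),
#' `date_ltrs` (per-element ages + landscape), `rip_scan` (window table,
#' merged regions as BED and GFF3) and `stats` (composition and LTR-type
#' tables), executed in dependency order on either a simulated genome or
#' user-supplied FASTA/GFF3. Every run writes a `manifest.json` recording
#' the effective configuration, the seed, and an MD5 digest of each output
#' file; identical configuration and inputs give byte-identical outputs.
#' Partial outputs are removed if a stage fails.
#'
#' Configuration is a YAML file or an equivalent nested list. Top-level
#' keys: `seed` (integer), `genome` (path to FASTA), `annotations` (path
#' to GFF3), and one block per stage to run: `simulate` (fields of
#' [sim_config()]; element cohorts under `elements` as lists of
#' [element_spec()] fields), `date_ltrs` (`rate`, `bin_width`, `model`),
#' `rip_scan` (`window`, `step`, `product_min`, `substrate_max`), `stats`
#' (`TRUE` or `{}`). Unknown keys are an error naming the key. When a
#' `simulate` block is present its outputs feed the later stages;
#' otherwise `genome`/`annotations` must be given.
#'
#' @param config Path to a YAML config file, or a nested list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @return Invisibly, a list with `outputs` (named file paths) and
#'   `manifest` (path to the manifest).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("seed", "genome", "annotations", "simulate", "date_ltrs",
             "rip_scan", "stats")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("invalid config key: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  on_fail <- function(e) {
    unlink(file.path(out_dir, basename(outputs)))
    stop(e)
  }
  tryCatch({
    genome <- NULL; ann <- NULL
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      sc$seed <- config$seed %||% sc$seed %||% 1L
      els <- lapply(sc$elements %||% list(), function(e)
        do.call(element_spec, e))
      sc$elements <- els
      sim <- simulate_genome(do.call(sim_config, sc))
      genome <- sim$genome
      ann <- sim$annotations
      outputs <- c(outputs, write_simulation(sim, out_dir))
    } else {
      if (is.null(config$genome)) stop("missing input: genome")
      if (!file.exists(config$genome))
        stop("missing input file: ", config$genome)
      genome <- read_genome(config$genome)
      if (!is.null(config$annotations)) {
        if (!file.exists(config$annotations))
          stop("missing input file: ", config$annotations)
        ann <- read_annotations(config$annotations, genome)
      }
    }
    if (!is.null(config$date_ltrs)) {
      dl <- config$date_ltrs
      if (is.null(ann)) stop("date_ltrs requires annotations")
      ages <- date_elements(genome, ann$elements,
                            rate = dl$rate %||% 1.02e-9,
                            model = dl$model %||% "JC")
      p_ages <- file.path(out_dir, "element_ages.tsv")
      write_age_table(ages, p_ages)
      land <- build_landscape(ages, bin_width_K = dl$bin_width %||% 0.01)
      p_land <- file.path(out_dir, "landscape.tsv")
      write.table(land, p_land, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, ages = p_ages, landscape = p_land)
    }
    if (!is.null(config$rip_scan)) {
      rs <- config$rip_scan
      scan <- scan_rip(genome, window = rs$window %||% 1000L,
                       step = rs$step %||% 500L,
                       thresholds = rip_thresholds(
                         product_min = rs$product_min %||% 1.61,
                         substrate_max = rs$substrate_max %||% 0.53))
      p_w <- file.path(out_dir, "rip_windows.tsv")
      p_b <- file.path(out_dir, "rip_regions.bed")
      p_g <- file.path(out_dir, "rip_regions.gff3")
      write_rip_windows(scan, p_w)
      write_rip_bed(scan, p_b)
      write_rip_gff3(scan, p_g, genome)
      outputs <- c(outputs, rip_windows = p_w, rip_bed = p_b, rip_gff3 = p_g)
    }
    if (!is.null(config$stats)) {
      rep_ <- composition_report(genome, genes = ann$genes,
                                 repeats = ann$repeats)
      p_c <- file.path(out_dir, "composition.tsv")
      write.table(
        data.frame(key = c("genome_size_bp", "gc_pct", "coding_gc_pct",
                           "coding_pct", "repeat_total_pct"),
                   value = c(rep_$genome_size, rep_$gc_pct,
                             rep_$coding_gc_pct, rep_$coding_pct,
                             rep_$repeat_total_pct)),
        p_c, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, composition = p_c)
      if (!is.null(ann) && nrow(ann$elements)) {
        lt <- ltr_type_table(ann$elements$superfamily,
                             ann$elements$end - ann$elements$start + 1)
        p_l <- file.path(out_dir, "ltr_types.tsv")
        write.table(lt, p_l, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, ltr_types = p_l)
      }
    }
    manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(config = config, seed = config$seed,
           files = as.list(tools::md5sum(unname(outputs)))),
      manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(outputs = outputs, manifest = manifest))
  }, error = on_fail)
}
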