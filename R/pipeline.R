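default_config <- function() {
  list(
    paths = list(reference = NULL, spike_ins = NULL, reads = NULL,
                 sample_sheet = NULL, out_dir = "trnacharge_out",
                 titration_design = NULL, decay_design = NULL),
    preprocess = list(umi_len = 10L, min_len = 39L, downsample_cap = 2e6,
                      umi_pattern = "RNNNNNNNNN"),
    align = list(match = 1L, mismatch = -3L, n_score = 0L, gap_open = 6L,
                 gap_extend = 3L, min_score = 15L),
    masking = list(unique_anno = TRUE, min_mut_freq = 0.3,
                   frac_max_score = 0.9, iterations = 1L,
                   min_transcript_obs = 200L, min_pos_obs = 100L,
                   grid = NULL),
    quantify = list(levels = c("transcript", "anticodon", "amino_acid")),
    halflife = list(n_boot = 1000L),
    seed = 1L)
}

#' Load a pipeline configuration
#'
#' YAML file with one mapping per stage (`paths`, `preprocess`, `align`,
#' `masking`, `quantify`, `halflife`, `seed`); keys not in the default
#' configuration are rejected to catch typos. Values omitted fall back to
#' the defaults.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(user)) {
    if (!is.list(cfg[[sec]])) { cfg[[sec]] <- user[[sec]]; next }
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad) > 0L)
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
    cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
  }
  cfg
}

config_scheme <- function(cfg) {
  a <- cfg$align
  scoring_scheme(a$match, a$mismatch, a$n_score, a$gap_open, a$gap_extend,
                 a$min_score)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the charge tRNA-Seq pipeline end to end
#'
#' Chains the stages on merged single-end reads: load and CCA-normalize
#' the reference, demultiplex by 3' adapter barcode, extract the 5' UMI,
#' length-filter, downsample, mask the reference (fixed parameters or grid
#' search), align every read against every transcript, and emit per-sample
#' charge, RPM and misincorporation tables plus UMI occupancy QC. All
#' outputs are TSV/JSON under `out_dir`; inputs are never mutated; reruns
#' with the same inputs, config and seed are byte-identical.
#'
#' @param cfg Configuration list from [load_config()].
#' @return Invisibly, a manifest (named list) of produced files.
#' @export
run_pipeline <- function(cfg) {
  p <- cfg$paths
  if (is.null(p$reference) || is.null(p$reads) || is.null(p$sample_sheet))
    stop("config must set paths$reference, paths$reads and ",
         "paths$sample_sheet")
  dir.create(p$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  scheme <- config_scheme(cfg)

  ref <- load_reference(p$reference, p$spike_ins)
  sheet <- read_sample_sheet(p$sample_sheet)
  barcodes <- barcode_spec(sheet$barcode_id, sheet$search_seq)
  reads <- read_fastq(p$reads)

  demux <- demultiplex(reads, barcodes)
  manifest$demux_stats <- file.path(p$out_dir, "demux_stats.json")
  jsonlite::write_json(as.list(demux$stats), manifest$demux_stats,
                       auto_unbox = TRUE)

  samples <- list()
  for (b in names(demux$assigned)) {
    sub <- demux$assigned[[b]]
    if (nrow(sub) == 0L) next
    eu <- extract_umi(sub, cfg$preprocess$umi_len)
    lf <- length_filter(eu$reads, cfg$preprocess$min_len)
    kept <- downsample(lf$reads, cfg$preprocess$downsample_cap,
                       seed = cfg$seed)
    sid <- sheet$sample_id[match(b, sheet$barcode_id)]
    kept$sample_id <- sid
    samples[[sid]] <- kept
    fq <- kept
    fq$read_id <- paste0(fq$read_id, " UMI:", fq$umi)
    path_fq <- file.path(p$out_dir, paste0("sample_", sid, ".fastq"))
    write_fastq(fq, path_fq)
    manifest[[paste0("fastq_", sid)]] <- path_fq
  }
  pooled <- do.call(rbind, samples)
  rownames(pooled) <- NULL

  m <- cfg$masking
  if (!is.null(m$grid)) {
    gs <- grid_search_masking(pooled, ref, m$grid, scheme,
                              m$min_transcript_obs, m$min_pos_obs)
    ref <- gs$ref
    manifest$grid_search <- write_tsv(gs$table,
                                      file.path(p$out_dir,
                                                "grid_search.tsv"))
  } else if (m$iterations > 0L) {
    ref <- iterate_masking(pooled, ref,
                           masking_params(m$unique_anno, m$min_mut_freq,
                                          m$frac_max_score, m$iterations,
                                          m$min_transcript_obs,
                                          m$min_pos_obs), scheme)
  }
  manifest$mask <- write_tsv(mask_table(ref),
                             file.path(p$out_dir, "mask.tsv"))
  manifest$masked_reference <- file.path(p$out_dir,
                                         "reference_masked.fasta")
  write_reference(ref, manifest$masked_reference)

  for (sid in names(samples)) {
    smp <- samples[[sid]]
    ann <- align_all(smp, ref, scheme, keep_alignments = FALSE)
    manifest[[paste0("annotations_", sid)]] <-
      write_tsv(ann, file.path(p$out_dir,
                               paste0("annotations_", sid, ".tsv")))
    for (lev in cfg$quantify$levels) {
      manifest[[paste0("charge_", lev, "_", sid)]] <-
        write_tsv(charge_table(ann, lev, ref),
                  file.path(p$out_dir,
                            paste0("charge_", lev, "_", sid, ".tsv")))
      manifest[[paste0("rpm_", lev, "_", sid)]] <-
        write_tsv(rpm_table(ann, smp, lev, ref),
                  file.path(p$out_dir,
                            paste0("rpm_", lev, "_", sid, ".tsv")))
    }
    qc <- umi_qc(smp, cfg$preprocess$umi_pattern)
    manifest[[paste0("umi_qc_", sid)]] <-
      file.path(p$out_dir, paste0("umi_qc_", sid, ".json"))
    jsonlite::write_json(qc, manifest[[paste0("umi_qc_", sid)]],
                         auto_unbox = TRUE, digits = NA)
    prof <- mod_profiles(ann, smp, ref)
    if (!is.null(prof))
      manifest[[paste0("modsignal_", sid)]] <-
        write_tsv(prof, file.path(p$out_dir,
                                  paste0("modsignal_", sid, ".tsv")))
  }

  if (!is.null(p$titration_design) && file.exists(p$titration_design)) {
    tit <- read.table(p$titration_design, header = TRUE, sep = "\t")
    ser <- titration_series(tit)
    fit <- fit_titration(ser)
    fits_df <- data.frame(transcript_id = fit$transcript_id, F_i = fit$F_i,
                          sse = fit$sse, at_bound = fit$at_bound,
                          identifiable = fit$identifiable)
    manifest$titration_fits <-
      write_tsv(fits_df, file.path(p$out_dir, "titration_fits.tsv"))
    manifest$titration_errors <-
      write_tsv(titration_errors(list(fit), list(ser), seed = cfg$seed),
                file.path(p$out_dir, "titration_errors_by_barcode.tsv"))
  }
  if (!is.null(p$decay_design) && file.exists(p$decay_design)) {
    dec <- read.table(p$decay_design, header = TRUE, sep = "\t")
    if (is.null(dec$group_id)) dec$group_id <- "all"
    manifest$halflife_fits <-
      write_tsv(fit_decay_table(dec, n_boot = cfg$halflife$n_boot,
                                seed = cfg$seed),
                file.path(p$out_dir, "halflife_fits.tsv"))
  }
  manifest$manifest <- file.path(p$out_dir, "manifest.json")
  jsonlite::write_json(lapply(manifest, as.character), manifest$manifest,
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Command-line interface dispatcher
#'
#' Thin shell entry point over the package functions; installed as
#' `inst/cli/trnacharge`. Subcommands: `simulate` (write a miniature
#' synthetic study), `run-all` (full pipeline from a YAML config),
#' `mask`, `titrate`, `halflife`. Exit codes: 0 success, 2 configuration
#' error, 3 data error.
#'
#' @param args Character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Exit code, invisibly.
#' @export
trnacharge_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: trnacharge <command> [options]",
    "commands:",
    "  simulate  --out DIR --seed INT     write a synthetic study",
    "  run-all   --config FILE [--seed INT]  run the full pipeline",
    "  mask      --config FILE            mask the reference only",
    "  titrate   --design TSV --out DIR   fit the titration factor",
    "  halflife  --design TSV --out DIR [--seed INT]  fit decay",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  code <- tryCatch({
    switch(cmd,
      "simulate" = {
        sim_study(opt("--out", "sim_study"),
                  seed = as.integer(opt("--seed", "1")))
        0L
      },
      "run-all" = {
        cfg <- load_config(opt("--config"))
        seed <- opt("--seed")
        if (!is.null(seed)) cfg$seed <- as.integer(seed)
        run_pipeline(cfg)
        0L
      },
      "mask" = {
        cfg <- load_config(opt("--config"))
        cfg$quantify$levels <- character(0)
        run_pipeline(cfg)
        0L
      },
      "titrate" = {
        design <- read.table(opt("--design"), header = TRUE, sep = "\t")
        out <- opt("--out", ".")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        fit <- fit_titration(titration_series(design))
        write_tsv(data.frame(transcript_id = fit$transcript_id,
                             F_i = fit$F_i, sse = fit$sse,
                             at_bound = fit$at_bound,
                             identifiable = fit$identifiable),
                  file.path(out, "titration_fits.tsv"))
        0L
      },
      "halflife" = {
        design <- read.table(opt("--design"), header = TRUE, sep = "\t")
        if (is.null(design$group_id)) design$group_id <- "all"
        out <- opt("--out", ".")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_tsv(fit_decay_table(design,
                                  seed = as.integer(opt("--seed", "1"))),
                  file.path(out, "halflife_fits.tsv"))
        0L
      },
      { message("unknown command: ", cmd, "\n", usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  invisible(code)
}
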