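## One-command orchestration: simulate -> demultiplex -> assemble -> OTU ->
## classify, with a YAML config, per-stage derived seeds and a checksummed
## manifest of every intermediate so that a rerun with the same config is
## byte-identical and each stage is independently rerunnable.

#' Read a pipeline configuration
#'
#' @param path YAML file; relative paths inside the config are resolved
#'   against the config file's directory.
#' @return A config list (class `amplitag_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("sample_sheet", "templates", "refs", "reads")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  structure(cfg, class = "amplitag_config")
}

#' Validate a pipeline configuration
#'
#' All file-existence, invariant and cross-stage consistency problems are
#' reported at once.
#'
#' @param cfg Config list ([read_pipeline_config()] or hand-built).
#' @return Character vector of error messages; empty when the config is ok.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(!is.null(cfg$sample_sheet) && file.exists(cfg$sample_sheet),
       "sample_sheet missing or file not found")
  sim_on <- isTRUE(cfg$simulate$enabled)
  if (sim_on) {
    need(!is.null(cfg$templates) && file.exists(cfg$templates),
         "templates FASTA missing or file not found")
    need(!is.null(cfg$seed), "seed required when simulation is enabled")
    for (s in names(cfg$simulate$profiles)) {
      p <- cfg$simulate$profiles[[s]]
      ab <- unlist(p$members)
      if (abs(sum(ab) - 1) > 1e-9) {
        errs <- c(errs, sprintf(
          "profile %s: abundances sum to %g, must sum to 1", s, sum(ab)))
      }
      if (is.null(p$n_reads) || p$n_reads < 1) {
        errs <- c(errs, sprintf("profile %s: n_reads must be >= 1", s))
      }
    }
  } else {
    need(!is.null(cfg$reads) && file.exists(cfg$reads),
         "reads file missing or file not found (and simulation disabled)")
  }
  asm <- cfg$assemble
  if (!is.null(asm)) {
    ok <- tryCatch({
      do.call(wimseex_params, asm)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) {
      errs <- c(errs, paste0("assemble parameters invalid: ", ok))
    }
  }
  if (!is.null(cfg$otu$count_mode) &&
      !cfg$otu$count_mode %in% c("membership", "remap")) {
    errs <- c(errs, "otu$count_mode must be 'membership' or 'remap'")
  }
  if (isTRUE(cfg$classify$enabled)) {
    need(!is.null(cfg$refs) && file.exists(cfg$refs),
         "refs FASTA missing or file not found (classify enabled)")
  }
  errs
}

## Derive a stage seed from the global seed (stage-name hashed) so adding a
## stage never perturbs earlier stages' random streams.
derive_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 7919L) %% 2147483647L
}

manifest_row <- function(stage, role, path, params = "") {
  data.frame(stage = stage, role = role, file = basename(path),
             md5 = unname(tools::md5sum(path)), params = params,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes simulate (optional), demultiplex, assemble, OTU tabulation and
#' classification in order, writing every intermediate plus a `manifest.tsv`
#' of checksums under the output directory. Rerunning with an identical
#' config reproduces identical checksums.
#'
#' @param cfg Config list or path to a YAML config.
#' @param outdir Output directory (created; overrides `cfg$outdir`).
#' @param seed Global RNG seed (overrides `cfg$seed`).
#' @param overrides Named list merged over the config (one level deep), e.g.
#'   `list(simulate = list(profiles = ...))`.
#' @param quiet Suppress stage log lines.
#' @return Invisibly, a list with `outdir`, `manifest`, `otu_table`, `otus`,
#'   `summary` and (when simulated) `truth`.
#' @export
run_pipeline <- function(cfg, outdir = NULL, seed = NULL,
                         overrides = NULL, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  if (!is.null(overrides)) {
    for (k in names(overrides)) {
      if (is.list(overrides[[k]]) && is.list(cfg[[k]])) {
        for (k2 in names(overrides[[k]])) cfg[[k]][[k2]] <- overrides[[k]][[k2]]
      } else {
        cfg[[k]] <- overrides[[k]]
      }
    }
  }
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$outdir)) stop("no output directory configured",
                                call. = FALSE)
  errs <- validate_config(cfg)
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  log_line <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s: %s",
                                format(Sys.time(), "%H:%M:%S"), stage, msg))
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  sheet <- read_sample_sheet(cfg$sample_sheet)
  manifest[[length(manifest) + 1L]] <-
    manifest_row("input", "sample_sheet", cfg$sample_sheet)

  # --- simulate ---------------------------------------------------------
  truth <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    templates <- read_fasta(cfg$templates)
    profiles <- lapply(names(cfg$simulate$profiles), function(s) {
      p <- cfg$simulate$profiles[[s]]
      community_profile(s, unlist(p$members), p$n_reads)
    })
    model <- do.call(error_model, as.list(cfg$simulate$error_model %||%
                                            list()))
    sim <- simulate_community(profiles, templates, sheet, model,
                              rng_seed = derive_seed(cfg$seed, "simulate"))
    reads_path <- file.path(cfg$outdir, "reads.fastq")
    truth_path <- file.path(cfg$outdir, "truth.tsv")
    write_fastq(sim$reads, reads_path)
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    reads <- sim$reads
    truth <- sim$truth
    manifest[[length(manifest) + 1L]] <-
      manifest_row("simulate", "reads", reads_path,
                   paste0("n=", nrow(reads)))
    manifest[[length(manifest) + 1L]] <-
      manifest_row("simulate", "truth", truth_path)
    log_line("simulate", paste(nrow(reads), "reads"))
  } else {
    reads <- if (grepl("\\.(fastq|fq)(\\.gz)?$", cfg$reads)) {
      read_fastq(cfg$reads)
    } else {
      read_fasta(cfg$reads)
    }
    manifest[[length(manifest) + 1L]] <-
      manifest_row("input", "reads", cfg$reads)
  }

  # --- demultiplex ------------------------------------------------------
  dmx_cfg <- cfg$demux %||% list()
  dmx <- demultiplex(reads, sheet,
                     min_mean_q = dmx_cfg$min_mean_q %||% 20,
                     max_n = dmx_cfg$max_n %||% 0L,
                     primer_mismatches = dmx_cfg$primer_mismatches %||% 0L)
  demux_dir <- file.path(cfg$outdir, "demux")
  dir.create(demux_dir, showWarnings = FALSE)
  for (s in names(dmx$pools)) {
    p <- file.path(demux_dir, paste0(s, ".fastq"))
    if (all(vapply(dmx$pools[[s]]$quals, Negate(is.null), logical(1)))) {
      write_fastq(dmx$pools[[s]], p)
    } else {
      p <- file.path(demux_dir, paste0(s, ".fasta"))
      write_fasta(dmx$pools[[s]], p)
    }
    manifest[[length(manifest) + 1L]] <- manifest_row("demux", s, p)
  }
  sum_path <- file.path(cfg$outdir, "demux_summary.tsv")
  utils::write.table(dmx$summary, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest[[length(manifest) + 1L]] <-
    manifest_row("demux", "summary", sum_path)
  log_line("demux", paste(sum(dmx$summary$count[
    !dmx$summary$category %in% c("UNASSIGNED", "QC_FAIL")]),
    "reads assigned"))

  # --- assemble ---------------------------------------------------------
  params <- do.call(wimseex_params, as.list(cfg$assemble %||% list()))
  contigs <- do.call(rbind, lapply(sheet$sample, function(s) {
    tag <- as.list(sheet[sheet$sample == s, , drop = FALSE])
    assemble_tag(dmx$pools[[s]], tag, params)
  }))
  contig_path <- file.path(cfg$outdir, "contigs.fasta")
  cf <- data.frame(id = contigs$contig_id, bases = contigs$bases,
                   desc = sprintf("support=%d sample=%s", contigs$support,
                                  contigs$sample),
                   stringsAsFactors = FALSE)
  write_fasta(cf, contig_path)
  manifest[[length(manifest) + 1L]] <-
    manifest_row("assemble", "contigs", contig_path,
                 sprintf("min_seed=%d window=%d max_bases=%d",
                         params$min_seed_size, params$window_size,
                         params$max_bases))
  log_line("assemble", paste(nrow(contigs), "contigs"))

  # --- otu --------------------------------------------------------------
  otu_cfg <- cfg$otu %||% list()
  count_mode <- otu_cfg$count_mode %||% "membership"
  otus <- do.call(rbind, lapply(sheet$sample, function(s) {
    tag <- as.list(sheet[sheet$sample == s, , drop = FALSE])
    make_otus(contigs[contigs$sample == s, , drop = FALSE], tag,
              identity_threshold = otu_cfg$identity %||% 0.97)
  }))
  if (is.null(otus) || nrow(otus) == 0L) {
    stop("no OTUs assembled; nothing to tabulate", call. = FALSE)
  }
  totals <- NULL
  if (count_mode == "remap") {
    counts <- integer(0)
    for (s in unique(otus$sample)) {
      cs <- map_reads_to_otus(dmx$pools[[s]],
                              otus[otus$sample == s, , drop = FALSE],
                              min_identity = otu_cfg$map_identity %||% 0.90)
      counts <- c(counts, cs)
    }
    otus$read_count <- as.integer(counts[otus$otu_id])
    totals <- stats::setNames(
      vapply(unique(otus$sample), function(s) nrow(dmx$pools[[s]]),
             integer(1)),
      unique(otus$sample))
  }
  otus <- otus[otus$read_count > 0L, , drop = FALSE]

  # --- classify ---------------------------------------------------------
  if (isTRUE(cfg$classify$enabled)) {
    refs <- read_reference_fasta(cfg$refs)
    hits <- lapply(otus$bases, best_hit, refs = refs)
    otus$closest_match <- vapply(hits, function(h) {
      sprintf("%s (%.1f%%)", h$accession, 100 * h$identity)
    }, character(1))
    hits_path <- file.path(cfg$outdir, "hits.tsv")
    utils::write.table(
      data.frame(otu_id = otus$otu_id,
                 accession = vapply(hits, `[[`, character(1), "accession"),
                 identity = round(vapply(hits, `[[`, numeric(1),
                                         "identity"), 4),
                 label = vapply(hits, `[[`, character(1), "label")),
      hits_path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest[[length(manifest) + 1L]] <-
      manifest_row("classify", "hits", hits_path)
    log_line("classify", paste(nrow(otus), "OTUs classified"))
  }

  otu_fa <- file.path(cfg$outdir, "otus.fasta")
  write_fasta(data.frame(id = otus$otu_id, bases = otus$bases,
                         desc = sprintf("reads=%d sample=%s",
                                        otus$read_count, otus$sample),
                         stringsAsFactors = FALSE), otu_fa)
  table_ <- build_table(otus, totals = totals)
  table_path <- file.path(cfg$outdir, "otu_table.tsv")
  utils::write.table(table_, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest[[length(manifest) + 1L]] <-
    manifest_row("otu", "otus", otu_fa, paste0("count_mode=", count_mode))
  manifest[[length(manifest) + 1L]] <-
    manifest_row("otu", "otu_table", table_path)
  log_line("otu", paste(nrow(otus), "OTUs"))

  manifest <- do.call(rbind, manifest)
  manifest_path <- file.path(cfg$outdir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(outdir = cfg$outdir, manifest = manifest,
                 otu_table = table_, otus = otus, summary = dmx$summary,
                 truth = truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
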