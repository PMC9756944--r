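# Shared readers/writers and the umbrella pipeline. All artifacts are plain
# text (CSV/TSV/BED/FASTA/JSON); every table is written with a JSON sidecar
# schema naming columns and units; all randomness flows from one seed.

#' Read a BED3/BED6 file into a GRanges
#'
#' BED is 0-based half-open; the returned GRanges is 1-based closed.
#' Malformed lines (wrong field count, non-numeric or inverted coordinates)
#' are reported with their line numbers. Strand is preserved when present.
#'
#' @param path BED file path.
#' @return sorted [GenomicRanges::GRanges] with a `name` and `score` column
#'   when the input has 6 fields.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop("malformed BED (fewer than 3 fields) at line(s): ",
         paste(lineno[nf < 3], collapse = ", "), call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  bad <- !is.finite(start0) | !is.finite(end0) | start0 < 0 | start0 >= end0
  if (any(bad)) {
    stop("malformed BED coordinates (need 0 <= start < end) at line(s): ",
         paste(lineno[bad], collapse = ", "), call. = FALSE)
  }
  strand <- rep("*", length(lines))
  name <- rep(NA_character_, length(lines))
  score <- rep(NA_real_, length(lines))
  has6 <- nf >= 6
  if (any(nf >= 4)) name[nf >= 4] <- vapply(parts[nf >= 4], `[[`,
                                            character(1), 4)
  if (any(nf >= 5)) {
    score[nf >= 5] <- suppressWarnings(
      as.numeric(vapply(parts[nf >= 5], `[[`, character(1), 5)))
  }
  if (any(has6)) {
    s6 <- vapply(parts[has6], `[[`, character(1), 6)
    if (!all(s6 %in% c("+", "-", "."))) {
      stop("invalid strand at line(s): ",
           paste(lineno[has6][!s6 %in% c("+", "-", ".")], collapse = ", "),
           call. = FALSE)
    }
    strand[has6] <- ifelse(s6 == ".", "*", s6)
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = name, score = score)
  sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as BED6
#'
#' @param gr a [GenomicRanges::GRanges]; `name`/`score` metadata columns are
#'   used when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  name <- S4Vectors::mcols(gr)$name %||% rep(".", n)
  score <- S4Vectors::mcols(gr)$score %||% rep(0, n)
  name[is.na(name)] <- "."
  score[is.na(score)] <- 0
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(as.character(GenomeInfoDb::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   name, score, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] with duplicate-header checking;
#' an empty file yields an empty set with a warning.
#'
#' @param path FASTA file path.
#' @return a [Biostrings::DNAStringSet] (names are the first word of each
#'   header).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(Biostrings::DNAStringSet())
  }
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA headers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  seqs
}

# Write a data.frame as TSV plus a JSON sidecar schema (column names/units).
write_table_schema <- function(df, path, units = NULL) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  schema <- list(columns = as.list(
    stats::setNames(units %||% rep("unspecified", ncol(df)), names(df))))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles the stage configurations with one master seed; stage seeds are
#' derived deterministically from it. Unknown keys are rejected. Defaults
#' are the published analysis settings (0.6 um/1-gap linking at 30 ms,
#' 3-step mobility window, 69/23/2000 bp windows with log2FC > 2, < 100 bp
#' merging at FDR 0.05, 200 bp coverage bins, 10-min frames and the
#' 16 h / 60 min / 120 min phenotype rules).
#'
#' @param ... overrides for any of the fields listed in the return value.
#' @param path optional YAML file of overrides (a flat or nested list whose
#'   top-level keys match the fields below).
#' @return object of class `run_config` with fields `seed`, `spt_sim`,
#'   `hypha_sim`, `chip_sim`, `growth_sim`, `tracking`, `mobility`,
#'   `mixture_K`, `loc_sigma`, `peaks`, `phenotype`, `windows`, `coverage`.
#' @export
run_config <- function(..., path = NULL) {
  defaults <- list(
    seed = 1L,
    spt_sim = spt_sim_config(),
    hypha_sim = hypha_sim_config(),
    chip_sim = chip_sim_config(),
    growth_sim = growth_sim_config(),
    tracking = tracking_config(),
    mobility = mobility_config(),
    mixture_K = 2L,
    loc_sigma = 0,
    peaks = peak_detect_config(),
    phenotype = phenotype_rules(),
    windows = window_config(),
    coverage = coverage_config())
  overrides <- list(...)
  if (!is.null(path)) {
    overrides <- utils::modifyList(yaml::read_yaml(path), overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "run_config")
}

#' Run the full synthetic-data pipeline
#'
#' Executes the stages in dependency order on freshly simulated inputs --
#' PALM tracking + diffusion mixture + mobility classes, hyphal focus
#' detection + distance metrics + phenotypes, sliding-window differential
#' binding + coverage, growth-curve fit -- and writes all artifacts (TSV
#' with JSON sidecar schemas, BED, FASTA, JSON summaries) plus a manifest
#' with parameter echo and content hashes to `out_dir`. Stage seeds derive
#' from `config$seed`, so a rerun with the same config is bit-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; existing files overwritten).
#' @param chip_fragment_files optional named vector of BED paths: use these
#'   fragment files for the ChIP stage instead of simulating (names are
#'   sample ids). Read errors surface at the ChIP stage; artifacts of the
#'   stages already run are left intact.
#' @param chip_conditions condition label per fragment file (required with
#'   `chip_fragment_files`).
#' @param chip_genome_fasta FASTA path supplying contig lengths (and AT
#'   annotation) for user-provided fragments.
#' @return the manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         chip_fragment_files = NULL, chip_conditions = NULL,
                         chip_genome_fasta = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # analysis stages (EM restarts, multi-start fits) also draw from the RNG;
  # pin the session stream so reruns are bit-identical, then restore it
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old_rng <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old_rng, envir = globalenv()), add = TRUE)
  set.seed(config$seed + 7L)
  seeds <- config$seed + c(spt = 101L, hypha = 202L, chip = 303L,
                           growth = 404L)
  params <- list(seed = config$seed)

  # --- PALM stage
  spt_cfg <- config$spt_sim; spt_cfg$seed <- seeds[["spt"]]
  sim <- simulate_spt(spt_cfg)
  write_table_schema(sim$localizations, file.path(out_dir, "localizations.tsv"),
                     units = c("id", "frame", "um", "um", "a.u."))
  tracks <- link_tracks(sim$localizations, config$tracking)
  write_table_schema(tracks, file.path(out_dir, "tracks.tsv"),
                     units = c("id", "frame", "um", "um", "id"))
  fit <- fit_diffusion_mixture(tracks, K = config$mixture_K,
                               dt = config$tracking$dt,
                               loc_sigma = config$loc_sigma)
  mob <- classify_mobility(tracks, fit, config$mobility)
  jsonlite::write_json(
    list(D_app_um2_s = fit$D_app, weights = fit$weights, logL = fit$logL,
         mean_D_app_um2_s = fit$mean_D_app,
         mobility_fractions = as.list(mob$fractions)),
    file.path(out_dir, "diffusion_fit.json"), auto_unbox = TRUE, digits = NA)
  write_table_schema(mob$classes, file.path(out_dir, "mobility.tsv"),
                     units = c("id", "steps", "class"))

  # --- hyphal stage
  hy_cfg <- config$hypha_sim; hy_cfg$seed <- seeds[["hypha"]]
  hsim <- simulate_hyphae(hy_cfg)
  foci <- detect_foci_all(hsim$profiles, config$peaks)
  write_table_schema(foci, file.path(out_dir, "foci.tsv"),
                     units = c("id", "frame", "um", "a.u.", "ratio"))
  tf <- track_foci(foci, frame_interval = hy_cfg$frame_interval)
  write_table_schema(tf$events, file.path(out_dir, "duplication_events.tsv"),
                     units = c("id", "frame", "id", "id", "id"))
  write_table_schema(as.data.frame(tf$tip_distance),
                     file.path(out_dir, "duplication_heatmap.tsv"),
                     units = rep("um", ncol(tf$tip_distance)))
  phen <- vapply(split(hsim$hyphae, hsim$hyphae$hypha_id), function(h) {
    classify_phenotype(h, config$phenotype,
                       is_branch = any(!is.na(h$parent_id)))
  }, character(1))
  write_table_schema(data.frame(hypha_id = names(phen), phenotype = phen),
                     file.path(out_dir, "phenotypes.tsv"),
                     units = c("id", "class"))

  # --- ChIP stage
  if (is.null(chip_fragment_files)) {
    chip_cfg <- config$chip_sim; chip_cfg$seed <- seeds[["chip"]]
    csim <- simulate_chip(chip_cfg)
    Biostrings::writeXStringSet(csim$genome, file.path(out_dir, "genome.fasta"))
    for (nm in names(csim$fragments)) {
      write_bed(csim$fragments[[nm]],
                file.path(out_dir, paste0("fragments_", nm, ".bed")))
    }
    frag_list <- csim$fragments
    chip_conditions <- csim$samples$condition
    genome <- csim$genome
    seqlens <- GenomeInfoDb::seqlengths(frag_list[[1]])
  } else {
    if (is.null(chip_conditions) || is.null(chip_genome_fasta)) {
      stop("user fragments need `chip_conditions` and `chip_genome_fasta`",
           call. = FALSE)
    }
    genome <- read_fasta(chip_genome_fasta)
    seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
    frag_list <- lapply(chip_fragment_files, read_bed)
  }
  diff <- chip_differential(frag_list, chip_conditions,
                            seqlengths = seqlens,
                            config = config$windows, genome = genome)
  reg <- diff$regions
  reg_df <- data.frame(contig = as.character(GenomeInfoDb::seqnames(reg)),
                       start = GenomicRanges::start(reg) - 1L,
                       end = GenomicRanges::end(reg),
                       as.data.frame(S4Vectors::mcols(reg)))
  write_table_schema(reg_df, file.path(out_dir, "regions.tsv"))
  cov <- binned_coverage(frag_list, seqlens, config$coverage)
  write_table_schema(cov, file.path(out_dir, "coverage.tsv"))

  # --- growth stage
  gr_cfg <- config$growth_sim; gr_cfg$seed <- seeds[["growth"]]
  gsim <- simulate_growth(gr_cfg)
  write_table_schema(gsim, file.path(out_dir, "growth_od.tsv"))
  gfit <- fit_growth_table(gsim)
  jsonlite::write_json(
    list(b = gfit$b, d = gfit$d, e_h = gfit$e, se = as.list(gfit$se),
         sigma = gfit$sigma, converged = gfit$converged),
    file.path(out_dir, "growth_fit.json"), auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = "hyphachrom",
    version = as.character(utils::packageVersion("hyphachrom")),
    seed = config$seed, stage_seeds = as.list(seeds), parameters = params,
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))),
           bytes = file.size(file.path(out_dir, f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
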