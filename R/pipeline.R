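#' Mine a genomic window across many alignment datasets
#'
#' The end-to-end pipeline: for every dataset in the manifest, read the SAM
#' file, apply the quality filter and the window read-pair filter, compute
#' per-base depth over the region, and write a per-position depth TXT; then
#' collapse all datasets into a composite signal (bedGraph), call expressed
#' segments (BED), extract splice junctions (BED), and write a run log with
#' the package version, parameters, and per-dataset input/kept read counts.
#' On any failure, partial outputs are removed.
#'
#' @param manifest Manifest tibble (columns `dataset_id`, `path`,
#'   `group_label`) or path to a manifest TSV; see [read_manifest()].
#' @param region Target [genomic_region()] or `"chrom:start-end"` string.
#' @param out_dir Output directory, created if needed.
#' @param min_q Phred quality threshold. Default 20.
#' @param require_both_mates Pair policy for [filter_region_pairs()].
#' @param min_depth,min_len,max_gap Segment-caller parameters.
#' @param normalize Per-dataset per-million scaling before collapsing.
#' @param verbose Emit progress messages. Default `TRUE`.
#' @return Invisibly, a list: `composite`, `segments`, `junctions`,
#'   `dataset_stats` (tibble of input/kept counts), `paths` (all artifacts).
#' @export
mine_coverage <- function(manifest, region, out_dir,
                          min_q = 20, require_both_mates = FALSE,
                          min_depth = 2, min_len = 50, max_gap = 10,
                          normalize = FALSE, verbose = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(region)) region <- parse_region(region)
  stopifnot(inherits(region, "genomic_region"))
  if (nrow(manifest) == 0) stop("no datasets in manifest", call. = FALSE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  say <- function(...) if (verbose) message(...)

  on_fail <- function(e) {
    unlink(written)
    stop("mining failed (partial outputs removed): ", conditionMessage(e),
         call. = FALSE)
  }

  tryCatch({
    covs <- vector("list", nrow(manifest))
    all_kept <- vector("list", nrow(manifest))
    stats <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$dataset_id[i]
      path <- manifest$path[i]
      if (!file.exists(path)) {
        stop("dataset '", id, "': file not found: ", path, call. = FALSE)
      }
      recs <- read_sam(path)
      n_in <- nrow(recs)
      kept <- recs |>
        filter_quality(min_q = min_q) |>
        filter_region_pairs(region, require_both = require_both_mates)
      covs[[i]] <- compute_depth(kept, region, dataset_id = id)
      all_kept[[i]] <- kept
      stats[[i]] <- tibble::tibble(dataset_id = id,
                                   group_label = manifest$group_label[i],
                                   reads_in = n_in, reads_kept = nrow(kept))
      depth_path <- file.path(out_dir, paste0(id, ".depth.txt"))
      write_depth_txt(covs[[i]], depth_path)
      written <- c(written, depth_path)
      say("dataset ", id, ": ", nrow(kept), "/", n_in, " reads kept")
    }
    dataset_stats <- dplyr::bind_rows(stats)

    composite <- collapse_coverage(covs, normalize = normalize)
    segments <- call_segments(composite, min_depth = min_depth,
                              min_len = min_len, max_gap = max_gap)
    junctions <- extract_junctions(dplyr::bind_rows(all_kept))

    paths <- list(
      composite = file.path(out_dir, "composite.bedgraph"),
      segments = file.path(out_dir, "segments.bed"),
      junctions = file.path(out_dir, "junctions.bed"),
      log = file.path(out_dir, "run_log.txt"),
      depth = file.path(out_dir, paste0(manifest$dataset_id, ".depth.txt"))
    )
    write_bedgraph(composite, paths$composite, value = "total_depth")
    write_segments_bed(segments, paths$segments)
    write_junctions_bed(junctions, paths$junctions)
    written <- c(written, paths$composite, paths$segments, paths$junctions)

    log_lines <- c(
      paste0("covmine version: ", as.character(utils::packageVersion("covmine"))),
      sprintf("region: %s:%d-%d", region$chrom, region$start, region$end),
      sprintf("min_q: %s | require_both_mates: %s | normalize: %s",
              min_q, require_both_mates, normalize),
      sprintf("caller: min_depth=%s min_len=%s max_gap=%s",
              min_depth, min_len, max_gap),
      sprintf("datasets: %d", nrow(manifest)),
      sprintf("%s [%s]: %d/%d reads kept", dataset_stats$dataset_id,
              dataset_stats$group_label, dataset_stats$reads_kept,
              dataset_stats$reads_in),
      sprintf("segments called: %d | junctions: %d", nrow(segments), nrow(junctions))
    )
    readr::write_lines(log_lines, paths$log)

    say(nrow(segments), " segment(s) called; ", nrow(junctions), " junction(s)")
    invisible(list(composite = composite, segments = segments,
                   junctions = junctions, dataset_stats = dataset_stats,
                   paths = paths))
  }, error = on_fail)
}

#' Conservation report for a gapped alignment
#'
#' Runs the windowed identity scan of the reference row against every other
#' row, calls conserved segments at the identity criterion, and (optionally)
#' writes per-pair TSV reports.
#'
#' @param aln A [gapped_alignment()] or path to an aligned FASTA file.
#' @param threshold Identity threshold, default 0.70.
#' @param window Window width in alignment columns, default 50.
#' @param out_dir Optional output directory for TSV reports.
#' @param reference Reference row (passed to [gapped_alignment()] when `aln`
#'   is a path).
#' @return A tibble of conserved segments with a `species` column naming the
#'   non-reference row of each pair.
#' @export
conservation_report <- function(aln, threshold = 0.70, window = 50,
                                out_dir = NULL, reference = 1) {
  if (is.character(aln)) aln <- gapped_alignment(aln, reference = reference)
  ref <- aln$reference
  others <- setdiff(seq_along(aln$rows), ref)
  out <- purrr::map(others, function(i) {
    ids <- window_identity(aln, rows = c(ref, i), window = window)
    segs <- call_conserved(ids, threshold = threshold, window = window)
    if (nrow(segs) > 0) segs$species <- aln$names[i]
    else segs$species <- character(0)
    segs
  }) |> dplyr::bind_rows()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out, file.path(out_dir, "conserved_segments.tsv"))
  }
  out
}
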