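## End-to-end orchestration: simulate a dilution series, call fusions per
## sample, build the detection table and estimate the limit of detection.
## The command-line entry point (inst/scripts/wgbsfuse.R) is a thin
## wrapper over these functions.

#' Simulate a dilution series and estimate the limit of detection
#'
#' Runs the full chain on synthetic data: for each fusion fraction and
#' replicate, simulate a WGBS read set, write and re-read the oracle
#' alignments, call the fusion, and record a binary detection outcome;
#' then fit the probit LoD model to the resulting table.
#'
#' @param fractions Fusion-positive fractions in percent (0 rows act as
#'   negative controls).
#' @param replicates Replicates per fraction.
#' @param depth Simulated mean coverage over the gene intervals.
#' @param seed Global seed; per-sample seeds are derived from it.
#' @param genome Optional `"toy_genome"` (default: a compact 6 kb toy
#'   genome so the series stays desk-scale).
#' @param confidence Detection probability defining the LoD.
#' @param mode Split-pair mate placement mode, see [classify_pair()].
#' @param out_dir Optional directory for per-sample artifacts and summary
#'   tables; omitted, everything stays in memory.
#' @return List with `detection` (the dilution table: `fraction`, `n`,
#'   `detected`), `calls` (per-sample call tables) and `lod` (a
#'   `"probit_lod"` fit, or `NULL` if unidentifiable).
#' @export
run_pipeline <- function(fractions = c(0, 2, 5, 10, 20, 50, 100),
                         replicates = 3L, depth = 30, seed = 1L,
                         genome = NULL, confidence = 0.95,
                         mode = "lenient", out_dir = NULL) {
  if (is.null(genome))
    genome <- make_toy_reference(lengths = c(3000L, 3000L), seed = seed)
  g <- genome$genes
  allele <- plant_fusion(genome, (g$start[1] + g$end[1]) %/% 2L,
                         (g$start[2] + g$end[2]) %/% 2L)
  target <- genome_targets(genome)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- list()
  rows <- list()
  k <- 0L
  for (fi in seq_along(fractions)) {
    det <- 0L
    for (r in seq_len(replicates)) {
      k <- k + 1L
      cfg <- sim_config(fraction = fractions[fi] / 100, depth = depth,
                        seed = seed * 10000L + k)
      sim <- simulate_reads(genome, allele, cfg)
      sam <- tempfile(fileext = ".sam")
      emit_oracle_sam(sim, sam)
      call <- call_fusion(sam, target, mode = mode)
      unlink(sam)
      det <- det + as.integer(call$detected)
      calls[[sprintf("f%g_r%d", fractions[fi], r)]] <- as.data.frame(call)
    }
    rows[[fi]] <- data.frame(fraction = fractions[fi], n = replicates,
                             detected = det)
  }
  detection <- do.call(rbind, rows)
  lod <- tryCatch(probit_lod(detection, confidence = confidence),
                  error = function(e) NULL)
  if (!is.null(out_dir)) {
    utils::write.table(detection, file.path(out_dir, "detection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls_df <- do.call(rbind, Map(cbind, sample = names(calls), calls))
    utils::write.table(calls_df, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(fractions = fractions, replicates = replicates,
                     depth = depth, seed = seed, confidence = confidence,
                     mode = mode,
                     package_version = as.character(utils::packageVersion("wgbsfuse")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(lod))
      jsonlite::write_json(
        list(intercept = lod$coefficients[["intercept"]],
             slope = lod$coefficients[["slope"]], lod = lod$lod,
             confidence = lod$confidence, converged = lod$converged),
        file.path(out_dir, "lod.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  list(detection = detection, calls = calls, lod = lod)
}

#' Write a fusion call as TSV tables and a JSON summary
#'
#' @param call A `"fusion_call"`.
#' @param prefix Output path prefix; writes `<prefix>_call.tsv`,
#'   `<prefix>_breakpoints.tsv` and `<prefix>_summary.json`.
#' @return Invisibly, the written paths.
#' @export
write_call <- function(call, prefix) {
  stopifnot(inherits(call, "fusion_call"))
  paths <- paste0(prefix, c("_call.tsv", "_breakpoints.tsv", "_summary.json"))
  utils::write.table(as.data.frame(call), paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(call$breakpoints, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(target = paste0(call$target$geneA$name, "--", call$target$geneB$name),
         split = call$split_count, discordant = call$discordant_count,
         total = call$total_count, detected = call$detected,
         n_breakpoints = nrow(call$breakpoints),
         min_mapq = call$min_mapq, mode = call$mode),
    paths[3], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
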