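#' Build a pipeline configuration
#'
#' Bundles everything one reproducible run needs: the simulation config (or
#' paths to pre-computed inputs), caller profiles, filter thresholds,
#' annotation parameters and the output directory. The stage list must be a
#' prefix of the canonical order; a run can stop early but never skip a
#' stage.
#'
#' @param sim a [simulation_config()].
#' @param profiles named list of three [hmm_params()].
#' @param thresholds a [filter_thresholds()].
#' @param promoter_bp promoter window for [annotate_cnvs()].
#' @param weights evidence weights for [prioritize()].
#' @param outdir directory for intermediate and final tables (created on
#'   demand); `NULL` keeps everything in memory.
#' @param stages prefix of `pipeline_stages()` to execute.
#' @param stratify_caller control-filter stratification, see
#'   [control_overlap_filter()].
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            profiles = caller_profiles(),
                            thresholds = filter_thresholds(),
                            promoter_bp = 2000L,
                            weights = evidence_weights(),
                            outdir = NULL,
                            stages = pipeline_stages(),
                            stratify_caller = TRUE) {
  canonical <- pipeline_stages()
  if (!identical(stages, canonical[seq_along(stages)])) {
    stop("configuration error: stages must be a prefix of ",
         paste(canonical, collapse = " -> "), call. = FALSE)
  }
  structure(list(sim = sim, profiles = profiles, thresholds = thresholds,
                 promoter_bp = promoter_bp, weights = weights,
                 outdir = outdir, stages = stages,
                 stratify_caller = stratify_caller),
            class = "pipeline_config")
}

#' Canonical stage order of the discovery pipeline
#' @return character vector of stage names.
#' @export
pipeline_stages <- function() {
  c("simulate", "call", "sample_qc", "call_qc", "control_overlap",
    "consensus", "annotate", "size_filter", "frequency_filter", "prioritize")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [simulation_config()] / [filter_thresholds()] field names under
#' top-level blocks `simulation:`, `thresholds:`, and scalar keys
#' `promoter_bp`, `outdir`, `stratify_caller`, `seed`.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(y$seed)) sim_args$seed <- y$seed
  if (!is.null(sim_args$chromosomes)) {
    sim_args$chromosomes <- do.call(rbind, lapply(sim_args$chromosomes,
                                                  as.data.frame))
  }
  sim <- do.call(simulation_config, sim_args)
  th <- do.call(filter_thresholds, y$thresholds %||% list())
  pipeline_config(sim = sim, thresholds = th,
                  promoter_bp = y$promoter_bp %||% 2000L,
                  outdir = y$outdir,
                  stratify_caller = y$stratify_caller %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the CNV discovery pipeline end to end
#'
#' Canonical order: simulate, call (three profiles), sample QC, call QC,
#' control-containment exclusion, three-caller consensus, gene/promoter
#' annotation with the gene-content filter, size filter, frequency-database
#' filter, prioritization. All intermediate call sets and filter traces are
#' kept in the report (and written as TSV when `outdir` is set), so every
#' input call's fate is auditable stage by stage.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"run_report"`: `layout`, `truth`, `qc` (sample QC
#'   table), `stage_counts` (data.frame stage/n_in/n_out), `callsets` (per
#'   stage), `candidates` (final ranked table), `traces`, `seed`, `version`,
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  th <- config$thresholds
  traces <- list()
  counts <- list()
  note <- function(stage, n_in, n_out) {
    counts[[length(counts) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)
    message(sprintf("[%s] %d -> %d", stage, n_in, n_out))
  }

  state <- new.env(parent = emptyenv())
  finish <- function() {
    report <- list(
      layout = state$layout, truth = state$truth, cohort = state$cohort,
      genes = state$genes, freq_db = state$freq_db, evidence = state$evidence,
      qc = state$qc, stage_counts = do.call(rbind, counts),
      consensus = state$consensus, candidates = state$candidates,
      traces = traces, seed = sim$seed,
      version = as.character(utils::packageVersion("cnvsieve")),
      config = config
    )
    class(report) <- "run_report"
    if (!is.null(config$outdir)) write_report(report, config$outdir)
    report
  }
  wants <- function(stage) stage %in% config$stages

  layout <- state$layout <- make_genome(sim)
  truth <- state$truth <- plant_truth(layout, sim)
  cohort <- state$cohort <- simulate_intensities(layout, truth, sim)
  genes <- state$genes <- make_gene_annotation(layout, truth, sim)
  freq_db <- state$freq_db <- make_frequency_db(layout, truth, sim)
  evidence <- state$evidence <- synthetic_evidence(genes, truth, sim)
  note("simulate", length(cohort), length(cohort))
  if (!wants("call")) return(finish())

  callsets <- run_three_callers(cohort, layout, config$profiles)
  note("call", length(cohort), sum(vapply(callsets, nrow, integer(1))))
  if (!wants("sample_qc")) return(finish())

  metrics <- intensity_metrics(cohort, layout)
  qc <- state$qc <- sample_qc(callsets, metrics, th)
  pass_ids <- qc$sample_id[qc$passed]
  callsets <- lapply(callsets, function(cs) {
    cs[cs$sample_id %in% pass_ids, , drop = FALSE]
  })
  note("sample_qc", nrow(qc), sum(qc$passed))
  if (!wants("call_qc")) return(finish())

  cohort_tag <- vapply(cohort, `[[`, character(1), "cohort")
  case_ids <- names(cohort)[cohort_tag == "case"]

  qc_out <- lapply(callsets, call_qc, thresholds = th)
  callsets <- lapply(qc_out, `[[`, "calls")
  traces$call_qc <- do.call(rbind, lapply(qc_out, `[[`, "trace"))
  note("call_qc", sum(vapply(qc_out, function(x) nrow(x$calls) +
                               sum(x$trace$decision == "removed"), integer(1))),
       sum(vapply(callsets, nrow, integer(1))))
  if (!wants("control_overlap")) return(finish())

  split_cohort <- function(cs) {
    list(case = cs[cs$sample_id %in% case_ids, , drop = FALSE],
         control = cs[!cs$sample_id %in% case_ids, , drop = FALSE])
  }
  control_calls <- do.call(rbind, lapply(callsets,
                                         function(cs) split_cohort(cs)$control))
  ctrl_out <- lapply(callsets, function(cs) {
    cc <- split_cohort(cs)
    control_overlap_filter(cc$case, control_calls, th,
                           stratify_caller = config$stratify_caller)
  })
  case_callsets <- lapply(ctrl_out, `[[`, "calls")
  traces$control_overlap <- do.call(rbind, lapply(ctrl_out, `[[`, "trace"))
  note("control_overlap",
       sum(vapply(callsets, function(cs) nrow(split_cohort(cs)$case),
                  integer(1))),
       sum(vapply(case_callsets, nrow, integer(1))))
  if (!wants("consensus")) return(finish())

  cons <- consensus_intersect(case_callsets)
  traces$consensus <- cons$trace
  state$consensus <- cons$consensus
  note("consensus", sum(vapply(case_callsets, nrow, integer(1))),
       nrow(cons$consensus))
  if (!wants("annotate")) return(finish())

  annotated <- annotate_cnvs(cons$consensus, genes, config$promoter_bp)
  gc_out <- gene_content_filter(annotated)
  annotated <- gc_out$annotated
  traces$gene_content <- gc_out$trace
  note("annotate", nrow(cons$consensus), length(annotated))
  if (!wants("size_filter")) return(finish())

  surv <- do.call(rbind, lapply(annotated, `[[`, "cnv"))
  if (is.null(surv)) surv <- cons$consensus[0, , drop = FALSE]
  sz <- size_filter(surv, th)
  traces$size_filter <- sz$trace
  note("size_filter", nrow(surv), nrow(sz$cnvs))
  keep_keys <- consensus_key(sz$cnvs)
  annotated <- annotated[vapply(annotated, function(a)
    consensus_key(a$cnv) %in% keep_keys, logical(1))]

  if (!wants("frequency_filter")) return(finish())
  fr <- frequency_filter(sz$cnvs, freq_db, th)
  traces$frequency_filter <- fr$trace
  note("frequency_filter", nrow(sz$cnvs), nrow(fr$cnvs))
  keep_keys <- consensus_key(fr$cnvs)
  annotated <- annotated[vapply(annotated, function(a)
    consensus_key(a$cnv) %in% keep_keys, logical(1))]
  class(annotated) <- "annotated_cnvs"

  if (!wants("prioritize")) return(finish())
  candidates <- state$candidates <- suppressWarnings(
    prioritize(annotated, evidence, config$weights))
  note("prioritize", length(annotated), nrow(candidates))

  finish()
}

# helper: flags for synthetic genes inside planted events, so the simulated
# run exercises prioritization; one gene per ultra-rare event gets an
# expression flag
synthetic_evidence <- function(genes, truth, config) {
  rng <- local_rng(config$seed, "evidence")
  ur <- truth[truth$label == "ultra_rare", , drop = FALSE]
  ur <- ur[!duplicated(paste(ur$chrom, ur$start, ur$end)), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ur))) {
    g <- genes[genes$chrom == ur$chrom[i] & genes$start >= ur$start[i] &
                 genes$end <= ur$end[i], , drop = FALSE]
    if (!nrow(g)) next
    sym <- g$symbol[rng$sample_int(nrow(g), 1L)]
    lut <- rng$runif(1) < 0.5
    rows[[length(rows) + 1L]] <- data.frame(
      symbol = sym,
      embryonic_lower_urinary_tract_expression = lut,
      embryonic_kidney_expression = !lut,
      urorectal_phenotype_report = FALSE,
      prior_disease_association = FALSE,
      note = "synthetic evidence", stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(symbol = character(0),
                      embryonic_lower_urinary_tract_expression = logical(0),
                      embryonic_kidney_expression = logical(0),
                      urorectal_phenotype_report = logical(0),
                      prior_disease_association = logical(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  utils::write.table(report$qc, p("sample_qc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$stage_counts, p("stage_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$consensus, p("consensus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$candidates, p("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_trace(report$traces, p("filter_trace.tsv"))
  utils::write.table(report$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("cnvsieve run (seed ", x$seed, ")\n", sep = "")
  print(x$stage_counts, row.names = FALSE)
  cat("final candidates:", nrow(x$candidates), "\n")
  invisible(x)
}

#' Export an LRR/BAF plot of a region for visual review
#'
#' Renders the probe-level LogR ratio and B-allele frequency of one sample
#' over a region, with the region boundaries marked — the pipeline's stand-in
#' for interactive signal inspection of surviving calls. The renderer uses
#' fixed device settings so identical inputs give identical image bytes.
#'
#' @param sample intensity sample.
#' @param chrom,start,end region (1-based inclusive).
#' @param layout genome layout.
#' @param path output PNG path.
#' @param pad bp of flanking context shown on either side.
#' @return `path`, invisibly.
#' @export
plot_call <- function(sample, chrom, start, end, layout, path, pad = 2e5) {
  if (!chrom %in% names(layout$probes)) {
    stop("unknown chromosome in region: ", chrom, call. = FALSE)
  }
  pos <- layout$probes[[chrom]]
  if (!any(pos >= start & pos <= end)) {
    stop("region ", chrom, ":", start, "-", end, " contains no probes",
         call. = FALSE)
  }
  win <- which(pos >= start - pad & pos <= end + pad)
  grDevices::png(path, width = 900, height = 600, res = 96)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  x <- pos[win] / 1e6
  graphics::plot(x, sample$lrr[[chrom]][win], pch = 16, cex = 0.5,
                 col = "grey30", ylim = c(-1.5, 1.5), xlab = "",
                 ylab = "LogR ratio",
                 main = paste0(sample$sample_id, "  ", chrom, ":", start,
                               "-", end))
  graphics::abline(h = 0, col = "grey70")
  graphics::abline(v = c(start, end) / 1e6, col = "red3", lty = 2)
  graphics::plot(x, sample$baf[[chrom]][win], pch = 16, cex = 0.5,
                 col = "grey30", ylim = c(0, 1), xlab = paste0("chr", chrom,
                 " position (Mb)"), ylab = "B-allele freq")
  graphics::abline(h = c(0, 1 / 3, 0.5, 2 / 3, 1), col = "grey85")
  graphics::abline(v = c(start, end) / 1e6, col = "red3", lty = 2)
  invisible(path)
}
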