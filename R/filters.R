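#' Classify the relation of a query interval to another interval
#'
#' Vectorized over the second interval. Categories: `EXACT` (both endpoints
#' equal), `CASE_WITHIN_OTHER` (query contained in other, not exact),
#' `OTHER_WITHIN_CASE` (other contained in query, not exact), `PARTIAL`
#' (overlap without containment), `NONE`. This is the semantics behind the
#' exclusion rules "overlapping exactly or completely within": only EXACT and
#' CASE_WITHIN_OTHER ever exclude a query CNV; partial overlap never does.
#'
#' @param q_start,q_end query interval (1-based inclusive).
#' @param o_start,o_end other interval(s), vectors.
#' @return character vector of relation labels.
#' @export
interval_relation <- function(q_start, q_end, o_start, o_end) {
  out <- rep("NONE", length(o_start))
  ov <- q_start <= o_end & o_start <= q_end
  exact <- ov & q_start == o_start & q_end == o_end
  within <- ov & !exact & o_start <= q_start & q_end <= o_end
  contains <- ov & !exact & q_start <= o_start & o_end <= q_end
  out[ov] <- "PARTIAL"
  out[contains] <- "OTHER_WITHIN_CASE"
  out[within] <- "CASE_WITHIN_OTHER"
  out[exact] <- "EXACT"
  out
}

#' Default filter thresholds
#'
#' The quality and rarity thresholds of the cascade, quoted as strict
#' exclusions, so the boundary-complement values are kept: a call with log10
#' Bayes factor exactly 30, 4 probes, length exactly 50 kb, or a sample with
#' call rate exactly 0.98 all pass.
#'
#' @param min_log_bf calls with confidence below this are removed.
#' @param min_probes_exclusive calls with `n_probes <=` this are removed.
#' @param min_call_rate samples below this call rate fail QC.
#' @param cnv_count_sd_mult a sample fails QC when its CNV count exceeds the
#'   cohort mean plus this many population SDs.
#' @param control_carrier_exclusive a case call is removed when more than this
#'   many distinct control samples contain it exactly or completely (default
#'   1, i.e. two or more carriers exclude).
#' @param min_length_bp consensus CNVs shorter than this are removed.
#' @return list of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_log_bf = 30,
                              min_probes_exclusive = 3L,
                              min_call_rate = 0.98,
                              cnv_count_sd_mult = 2,
                              control_carrier_exclusive = 1L,
                              min_length_bp = 50000L) {
  th <- list(min_log_bf = min_log_bf,
             min_probes_exclusive = as.integer(min_probes_exclusive),
             min_call_rate = min_call_rate,
             cnv_count_sd_mult = cnv_count_sd_mult,
             control_carrier_exclusive = as.integer(control_carrier_exclusive),
             min_length_bp = as.integer(min_length_bp))
  if (!all(vapply(th, function(x) is.finite(as.numeric(x)), logical(1)))) {
    stop("configuration error: all thresholds must be finite", call. = FALSE)
  }
  class(th) <- "filter_thresholds"
  th
}

new_trace <- function(keys, stage, kept, reason) {
  data.frame(call_key = keys, stage = rep(stage, length(keys)),
             decision = ifelse(kept, "kept", "removed"),
             reason = reason, stringsAsFactors = FALSE)
}

#' Per-sample quality control
#'
#' A sample fails when (i) its intensity call rate is below
#' `min_call_rate`, (ii) its called sex disagrees with the recorded sex, or
#' (iii) its total CNV count across callers exceeds the cohort mean plus
#' `cnv_count_sd_mult` population standard deviations. The count rule needs
#' at least two samples; with fewer it is skipped with a warning.
#'
#' @param callsets named list `caller_id -> call set` for the cohort.
#' @param metrics per-sample metrics from [intensity_metrics()] (columns
#'   sample_id, call_rate, recorded_sex, sex_called).
#' @param thresholds a [filter_thresholds()].
#' @return data.frame: sample_id, call_rate, sex_called, cnv_count, passed,
#'   reasons (comma-separated rule names, empty iff passed).
#' @export
sample_qc <- function(callsets, metrics, thresholds = filter_thresholds()) {
  all_calls <- do.call(rbind, c(unname(callsets), list(empty_callset())))
  counts <- table(factor(all_calls$sample_id, levels = metrics$sample_id))
  cnv_count <- as.integer(counts[metrics$sample_id])
  reasons <- vector("list", nrow(metrics))
  low_rate <- metrics$call_rate < thresholds$min_call_rate
  sex_bad <- metrics$sex_called != metrics$recorded_sex
  for (i in which(low_rate)) reasons[[i]] <- c(reasons[[i]], "call_rate")
  for (i in which(sex_bad)) reasons[[i]] <- c(reasons[[i]], "sex_mismatch")
  if (nrow(metrics) >= 2L) {
    mu <- mean(cnv_count)
    sd_pop <- sqrt(mean((cnv_count - mu)^2))
    cut <- mu + thresholds$cnv_count_sd_mult * sd_pop
    for (i in which(cnv_count > cut)) {
      reasons[[i]] <- c(reasons[[i]], "cnv_count_outlier")
    }
  } else {
    warning("fewer than 2 samples: CNV-count outlier rule skipped")
  }
  data.frame(
    sample_id = metrics$sample_id,
    call_rate = metrics$call_rate,
    sex_called = metrics$sex_called,
    cnv_count = cnv_count,
    passed = lengths(reasons) == 0L,
    reasons = vapply(reasons, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Per-call quality control
#'
#' Removes calls with log10 Bayes factor below `min_log_bf` (strict: exactly
#' 30 is kept) or with `n_probes <= min_probes_exclusive` (a 4-probe call is
#' kept).
#'
#' @param calls call-set data.frame.
#' @param thresholds a [filter_thresholds()].
#' @return list `(calls, trace)`: the surviving calls and the filter trace.
#' @export
call_qc <- function(calls, thresholds = filter_thresholds()) {
  if (nrow(calls) && anyNA(calls$confidence)) {
    stop("validation error: call with missing confidence", call. = FALSE)
  }
  keep <- calls$confidence >= thresholds$min_log_bf &
    calls$n_probes > thresholds$min_probes_exclusive
  reason <- rep("", nrow(calls))
  reason[calls$confidence < thresholds$min_log_bf] <- "low_bayes_factor"
  few <- calls$n_probes <= thresholds$min_probes_exclusive
  reason[few] <- ifelse(nzchar(reason[few]),
                        paste0(reason[few], ",too_few_probes"),
                        "too_few_probes")
  reason[keep] <- "passed_call_qc"
  list(calls = calls[keep, , drop = FALSE],
       trace = new_trace(call_key(calls), "call_qc", keep, reason))
}

# distinct control samples whose same-type same-caller calls contain each
# case call exactly or completely; IRanges type="within" matches exactly the
# EXACT / CASE_WITHIN_OTHER relation set
count_containing_carriers <- function(case_calls, control_calls) {
  n_carriers <- integer(nrow(case_calls))
  if (!nrow(case_calls) || !nrow(control_calls)) return(n_carriers)
  for (chrom in unique(case_calls$chrom)) {
    qi <- which(case_calls$chrom == chrom)
    si <- which(control_calls$chrom == chrom)
    if (!length(si)) next
    q <- IRanges::IRanges(case_calls$start[qi], case_calls$end[qi])
    s <- IRanges::IRanges(control_calls$start[si], control_calls$end[si])
    hits <- IRanges::findOverlaps(q, s, type = "within")
    if (!length(hits)) next
    df <- data.frame(q = S4Vectors::queryHits(hits),
                     carrier = control_calls$sample_id[si][S4Vectors::subjectHits(hits)])
    agg <- tapply(df$carrier, df$q, function(x) length(unique(x)))
    n_carriers[qi[as.integer(names(agg))]] <- as.integer(agg)
  }
  n_carriers
}

#' Exclude case calls contained in the control cohort
#'
#' A case call is removed when more than `control_carrier_exclusive` distinct
#' control samples have at least one call of the same type, from the same
#' caller, that the case call overlaps exactly or lies completely within.
#' Deletions and duplications are filtered independently, and each calling
#' program's call set is filtered against that program's control calls
#' (`stratify_caller = FALSE` pools controls across callers instead). Partial
#' overlap never excludes.
#'
#' @param case_calls,control_calls call-set data.frames.
#' @param thresholds a [filter_thresholds()].
#' @param stratify_caller match control carriers within the same caller only
#'   (default TRUE, the per-program reading).
#' @return list `(calls, trace)`.
#' @export
control_overlap_filter <- function(case_calls, control_calls,
                                   thresholds = filter_thresholds(),
                                   stratify_caller = TRUE) {
  n <- nrow(case_calls)
  carriers <- integer(n)
  strata <- if (stratify_caller) {
    paste(case_calls$caller_id, case_calls$type)
  } else {
    case_calls$type
  }
  ctrl_strata <- if (stratify_caller) {
    paste(control_calls$caller_id, control_calls$type)
  } else {
    control_calls$type
  }
  for (st in unique(strata)) {
    qi <- which(strata == st)
    si <- which(ctrl_strata == st)
    carriers[qi] <- count_containing_carriers(
      case_calls[qi, , drop = FALSE], control_calls[si, , drop = FALSE]
    )
  }
  keep <- carriers <= thresholds$control_carrier_exclusive
  reason <- ifelse(keep, "not_in_controls",
                   sprintf("contained_in_%d_controls", carriers))
  list(calls = case_calls[keep, , drop = FALSE],
       trace = new_trace(call_key(case_calls), "control_overlap", keep, reason))
}

#' Intersect calls across exactly three callers
#'
#' A consensus event exists for a (sample, chromosome, type) when the three
#' callers each contribute one call and all three pairwise overlap (for 1-D
#' intervals this guarantees a non-empty triple intersection). Matching is
#' greedy left-to-right: each caller's calls are consumed in positional order
#' and every source call joins at most one consensus event. The consensus
#' interval is the triple intersection — the most conservative span all three
#' programs agree on — and confidence/probe support are the minima over the
#' three sources.
#'
#' @param callsets named list of exactly three call-set data.frames.
#' @return list `(consensus, trace)`: `consensus` has columns sample_id,
#'   chrom, start, end, type, copy_number (from the first caller's source
#'   call), min_confidence, min_n_probes, union_start, union_end, and one
#'   source-interval column per caller; `trace` records, per input call,
#'   whether it joined a consensus event.
#' @export
consensus_intersect <- function(callsets) {
  if (length(callsets) != 3L) {
    stop("configuration error: consensus requires exactly 3 callers, got ",
         length(callsets), call. = FALSE)
  }
  caller_ids <- vapply(callsets, function(cs) {
    if (nrow(cs)) cs$caller_id[1] else NA_character_
  }, character(1))
  ids <- names(callsets)
  if (is.null(ids)) ids <- caller_ids
  used <- lapply(callsets, function(cs) logical(nrow(cs)))
  keys <- lapply(callsets, function(cs) paste(cs$sample_id, cs$chrom, cs$type))
  out <- list()
  groups <- unique(unlist(keys))
  for (g in groups) {
    idx <- lapply(seq_len(3L), function(k) {
      i <- which(keys[[k]] == g)
      i[order(callsets[[k]]$start[i])]
    })
    if (any(lengths(idx) == 0L)) next
    for (ia in idx[[1L]]) {
      a <- callsets[[1L]][ia, ]
      found <- FALSE
      for (ib in idx[[2L]]) {
        if (used[[2L]][ib]) next
        b <- callsets[[2L]][ib, ]
        if (b$start > a$end || a$start > b$end) next
        for (ic in idx[[3L]]) {
          if (used[[3L]][ic]) next
          cc <- callsets[[3L]][ic, ]
          if (cc$start > a$end || a$start > cc$end) next
          if (cc$start > b$end || b$start > cc$end) next
          s <- max(a$start, b$start, cc$start)
          e <- min(a$end, b$end, cc$end)
          used[[1L]][ia] <- TRUE; used[[2L]][ib] <- TRUE; used[[3L]][ic] <- TRUE
          row <- data.frame(
            sample_id = a$sample_id, chrom = a$chrom, start = s, end = e,
            type = a$type, copy_number = a$copy_number,
            min_confidence = min(a$confidence, b$confidence, cc$confidence),
            min_n_probes = min(a$n_probes, b$n_probes, cc$n_probes),
            union_start = min(a$start, b$start, cc$start),
            union_end = max(a$end, b$end, cc$end),
            stringsAsFactors = FALSE
          )
          row[[paste0("src_", ids[1])]] <- paste0(a$start, "-", a$end)
          row[[paste0("src_", ids[2])]] <- paste0(b$start, "-", b$end)
          row[[paste0("src_", ids[3])]] <- paste0(cc$start, "-", cc$end)
          out[[length(out) + 1L]] <- row
          found <- TRUE
          break
        }
        if (found) break
      }
    }
  }
  consensus <- if (length(out)) do.call(rbind, out) else data.frame(
    sample_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), type = character(0), copy_number = integer(0),
    min_confidence = numeric(0), min_n_probes = integer(0),
    union_start = integer(0), union_end = integer(0), stringsAsFactors = FALSE
  )
  if (nrow(consensus)) {
    consensus <- consensus[order(consensus$sample_id, consensus$chrom,
                                 consensus$start, method = "radix"), ,
                           drop = FALSE]
    rownames(consensus) <- NULL
  }
  traces <- lapply(seq_len(3L), function(k) {
    cs <- callsets[[k]]
    new_trace(call_key(cs), "consensus",
              used[[k]], ifelse(used[[k]], "in_consensus", "missing_caller"))
  })
  list(consensus = consensus, trace = do.call(rbind, traces))
}

consensus_key <- function(cnvs) {
  if (!nrow(cnvs)) return(character(0))
  paste(cnvs$sample_id, "consensus", cnvs$chrom, cnvs$start, cnvs$end,
        cnvs$type, sep = "|")
}

#' Remove CNVs shorter than the size threshold
#'
#' Length is `end - start + 1` on the (consensus) interval; the strict
#' "< 50 kb" reading keeps a CNV of exactly 50,000 bp.
#'
#' @param cnvs consensus (or call-set) data.frame.
#' @param thresholds a [filter_thresholds()].
#' @return list `(cnvs, trace)`.
#' @export
size_filter <- function(cnvs, thresholds = filter_thresholds()) {
  len <- cnvs$end - cnvs$start + 1L
  keep <- len >= thresholds$min_length_bp
  reason <- ifelse(keep, "length_ok",
                   sprintf("shorter_than_%d_bp", thresholds$min_length_bp))
  keys <- if ("min_confidence" %in% names(cnvs)) consensus_key(cnvs) else call_key(cnvs)
  list(cnvs = cnvs[keep, , drop = FALSE],
       trace = new_trace(keys, "size_filter", keep, reason))
}

#' Remove CNVs present in a frequency database
#'
#' A CNV is removed when at least one database record of compatible type
#' (same type, or BOTH) overlaps it exactly or contains it completely —
#' the same containment semantics as the control filter, so a CNV that merely
#' brushes a catalogued variant, or strictly contains a smaller one, survives.
#'
#' @param cnvs consensus data.frame.
#' @param db frequency records from [read_frequency_db()].
#' @param thresholds a [filter_thresholds()] (unused fields ignored; present
#'   for interface symmetry).
#' @return list `(cnvs, trace)`.
#' @export
frequency_filter <- function(cnvs, db, thresholds = filter_thresholds()) {
  n <- nrow(cnvs)
  hit <- logical(n)
  if (n && nrow(db)) {
    for (i in seq_len(n)) {
      cand <- db[db$chrom == cnvs$chrom[i] &
                   (db$type == cnvs$type[i] | db$type == "BOTH"), , drop = FALSE]
      if (!nrow(cand)) next
      rel <- interval_relation(cnvs$start[i], cnvs$end[i], cand$start, cand$end)
      hit[i] <- any(rel %in% c("EXACT", "CASE_WITHIN_OTHER"))
    }
  }
  keep <- !hit
  reason <- ifelse(keep, "not_in_frequency_db", "in_frequency_db")
  keys <- if ("min_confidence" %in% names(cnvs)) consensus_key(cnvs) else call_key(cnvs)
  list(cnvs = cnvs[keep, , drop = FALSE],
       trace = new_trace(keys, "frequency_filter", keep, reason))
}

#' Serialize filter traces as TSV
#' @param traces data.frame (or list of data.frames) of trace records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(traces, path) {
  if (is.list(traces) && !is.data.frame(traces)) {
    traces <- do.call(rbind, traces)
  }
  utils::write.table(traces, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
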