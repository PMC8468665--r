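#' Plant ground-truth copy-number events in a cohort
#'
#' Assigns every event of `config$event_spec` to concrete genomic coordinates
#' and carriers. Ultra-rare events go to distinct case samples (one carrier per
#' event by default); common polymorphisms are placed once and copied to all
#' their carriers at identical coordinates, the way a segregating structural
#' polymorphism appears across a population. Events are restricted to
#' autosomes so the male X (simulated hemizygous) never collides with planted
#' signal, must span at least 4 probes, and are non-overlapping within any one
#' sample.
#'
#' @param layout a [make_genome()] layout.
#' @param config the [simulation_config()] used for the layout.
#' @return data.frame of class `"truth_events"` with columns `sample_id`,
#'   `chrom`, `start`, `end` (1-based inclusive bp), `copy_number`, `cohort`
#'   (`case`/`control`), `label` (`ultra_rare`/`common_polymorphism`).
#' @export
plant_truth <- function(layout, config = simulation_config()) {
  stopifnot(inherits(layout, "genome_layout"))
  rng <- local_rng(config$seed, "truth")
  autosomes <- setdiff(layout$chromosomes$name, "X")
  if (!length(autosomes)) autosomes <- layout$chromosomes$name
  chr_len <- stats::setNames(layout$chromosomes$length, layout$chromosomes$name)

  case_ids <- sprintf("case_%03d", seq_len(config$n_cases))
  control_ids <- sprintf("ctrl_%03d", seq_len(config$n_controls))
  # per-sample occupied intervals, to keep events within a sample disjoint
  occupied <- new.env(parent = emptyenv())
  overlaps_existing <- function(sid, chrom, start, end) {
    key <- paste0(sid, "|", chrom)
    iv <- occupied[[key]]
    if (is.null(iv)) return(FALSE)
    any(start <= iv$end & iv$start <= end)
  }
  mark <- function(sid, chrom, start, end) {
    key <- paste0(sid, "|", chrom)
    occupied[[key]] <- rbind(occupied[[key]],
                             data.frame(start = start, end = end))
  }

  next_case <- 1L
  rows <- list()
  for (spec_i in seq_along(config$event_spec)) {
    ev <- config$event_spec[[spec_i]]
    n_case <- ev$n_case_carriers
    n_ctrl <- ev$n_control_carriers
    if (n_case > config$n_cases || n_ctrl > config$n_controls) {
      stop("placement error: event spec ", spec_i,
           " needs more carriers than the cohort holds", call. = FALSE)
    }
    if (identical(ev$label, "ultra_rare")) {
      carriers_case <- case_ids[seq.int(next_case, length.out = n_case)]
      next_case <- next_case + n_case
      carriers_ctrl <- character(0)
    } else {
      carriers_case <- if (n_case > 0) rng$sample(case_ids, n_case) else character(0)
      carriers_ctrl <- if (n_ctrl > 0) rng$sample(control_ids, n_ctrl) else character(0)
    }
    carriers <- c(carriers_case, carriers_ctrl)
    cohorts <- c(rep("case", length(carriers_case)),
                 rep("control", length(carriers_ctrl)))

    placed <- FALSE
    for (attempt in seq_len(200L)) {
      chrom <- if (length(autosomes) == 1L) autosomes else rng$sample(autosomes, 1L)
      len <- as.integer(round(rng$runif(1, ev$length_range[1],
                                        ev$length_range[2])))
      if (len > chr_len[[chrom]]) next
      start <- as.integer(floor(rng$runif(1, 1, chr_len[[chrom]] - len + 1)))
      end <- start + len - 1L
      n_pr <- sum(layout$probes[[chrom]] >= start & layout$probes[[chrom]] <= end)
      if (n_pr < 4L) next
      if (any(vapply(carriers, overlaps_existing, logical(1),
                     chrom = chrom, start = start, end = end))) next
      for (k in seq_along(carriers)) {
        mark(carriers[k], chrom, start, end)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = carriers[k], chrom = chrom,
          start = start, end = end,
          copy_number = as.integer(ev$copy_number),
          cohort = cohorts[k], label = ev$label,
          stringsAsFactors = FALSE
        )
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("placement error: could not place event spec ", spec_i,
           " (label=", ev$label, ", cn=", ev$copy_number, ") without overlap",
           call. = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else data.frame(
    sample_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), copy_number = integer(0), cohort = character(0),
    label = character(0), stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  class(truth) <- c("truth_events", "data.frame")
  truth
}

# canonical LRR level per copy-number state; CN0 collapses far below the
# dynamic range, duplications compress (log2(3/2), ~log2(4/2) shrunk by
# saturation)
.lrr_state_means <- c(`0` = -3.0, `1` = -0.60, `2` = 0.0, `3` = 0.40, `4` = 0.68)

# BAF cluster centres and weights per copy number; weights are binomial(cn,
# 1/2) genotype frequencies; CN0 has no genotype signal (uniform noise)
.baf_clusters <- function(cn) {
  if (cn == 0L) return(NULL)
  k <- 0:cn
  list(mean = k / cn, weight = stats::dbinom(k, cn, 0.5))
}

#' Simulate per-probe LRR/BAF intensity signals for a cohort
#'
#' Every sample gets a LogR-ratio and a B-allele-frequency value per probe.
#' The diploid baseline draws LRR around 0; probes inside a planted
#' copy-number event draw around the state mean for that copy number
#' (CN0 -3.0, CN1 -0.60, CN3 +0.40, CN4 +0.68). BAF is drawn from the
#' genotype-cluster mixture of the local copy number (e.g. \{0, 1/2, 1\} for
#' diploid, \{0, 1/3, 2/3, 1\} for a trisomic segment), clipped to \[0, 1\].
#' Samples with recorded sex "M" are hemizygous (CN1) across chromosome "X".
#' A `missing_rate` fraction of probes is set to NA in both tracks.
#'
#' @param layout a [make_genome()] layout.
#' @param truth [plant_truth()] output (may be empty).
#' @param config the matching [simulation_config()].
#' @return list of class `"intensity_cohort"`: one element per sample, each a
#'   list with `sample_id`, `cohort`, `recorded_sex`, and per-chromosome
#'   numeric vectors `lrr` and `baf` aligned to `layout$probes`.
#' @export
simulate_intensities <- function(layout, truth, config = simulation_config()) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(config$noise_sd_lrr) || config$noise_sd_lrr <= 0) {
    stop("configuration error: noise_sd_lrr must be > 0", call. = FALSE)
  }
  bad <- !truth$chrom %in% layout$chromosomes$name
  if (any(bad)) {
    stop("truth events on unknown chromosome: ",
         paste(unique(truth$chrom[bad]), collapse = ", "), call. = FALSE)
  }
  rng <- local_rng(config$seed, "intensities")
  ids <- c(sprintf("case_%03d", seq_len(config$n_cases)),
           sprintf("ctrl_%03d", seq_len(config$n_controls)))
  cohorts <- c(rep("case", config$n_cases), rep("control", config$n_controls))
  sexes <- ifelse(rng$runif(length(ids)) < config$male_fraction, "M", "F")

  cohort <- vector("list", length(ids))
  for (si in seq_along(ids)) {
    sid <- ids[si]
    ev_s <- truth[truth$sample_id == sid, , drop = FALSE]
    lrr <- list(); baf <- list()
    for (chrom in layout$chromosomes$name) {
      pos <- layout$probes[[chrom]]
      cn <- rep(2L, length(pos))
      if (chrom == "X" && sexes[si] == "M") cn[] <- 1L
      ev_c <- ev_s[ev_s$chrom == chrom, , drop = FALSE]
      for (k in seq_len(nrow(ev_c))) {
        inside <- pos >= ev_c$start[k] & pos <= ev_c$end[k]
        cn[inside] <- ev_c$copy_number[k]
      }
      l <- rng$rnorm(length(pos), mean = .lrr_state_means[as.character(cn)],
                     sd = config$noise_sd_lrr)
      b <- numeric(length(pos))
      for (state in unique(cn)) {
        idx <- which(cn == state)
        cl <- .baf_clusters(state)
        if (is.null(cl)) {
          b[idx] <- rng$runif(length(idx))
        } else {
          centre <- cl$mean[1L + rng$sample_int(length(cl$mean), length(idx),
                                                replace = TRUE,
                                                prob = cl$weight) - 1L]
          b[idx] <- rng$rnorm(length(idx), mean = centre, sd = config$baf_sd)
        }
      }
      b <- pmin(pmax(b, 0), 1)
      if (config$missing_rate > 0) {
        miss <- rng$runif(length(pos)) < config$missing_rate
        l[miss] <- NA_real_
        b[miss] <- NA_real_
      }
      lrr[[chrom]] <- l
      baf[[chrom]] <- b
    }
    cohort[[si]] <- list(sample_id = sid, cohort = cohorts[si],
                         recorded_sex = sexes[si], lrr = lrr, baf = baf)
  }
  names(cohort) <- ids
  class(cohort) <- "intensity_cohort"
  cohort
}

#' Per-sample intensity quality metrics
#'
#' Computes the call rate (fraction of probes with observed intensities) and
#' calls sex from the mean LogR ratio over chromosome "X" probes: a
#' hemizygous X sits around one copy (mean LRR near -0.6), so a mean below
#' -0.25 is called male. Consumed by [sample_qc()].
#'
#' @param cohort an `intensity_cohort`.
#' @param layout the matching genome layout.
#' @param male_lrr_cut X-LRR mean below which sex is called "M".
#' @return data.frame: `sample_id`, `cohort`, `recorded_sex`, `call_rate`,
#'   `sex_called`.
#' @export
intensity_metrics <- function(cohort, layout, male_lrr_cut = -0.25) {
  rows <- lapply(cohort, function(s) {
    all_lrr <- unlist(s$lrr, use.names = FALSE)
    call_rate <- mean(!is.na(all_lrr))
    sex_called <- "unknown"
    if ("X" %in% names(s$lrr)) {
      mx <- mean(s$lrr[["X"]], na.rm = TRUE)
      if (is.finite(mx)) sex_called <- if (mx < male_lrr_cut) "M" else "F"
    }
    data.frame(sample_id = s$sample_id, cohort = s$cohort,
               recorded_sex = s$recorded_sex, call_rate = call_rate,
               sex_called = sex_called, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emulate caller-specific boundary jitter and false positives
#'
#' Post-hoc perturbation of a call set that mimics how independent calling
#' programs disagree: every boundary is shifted by up to
#' `config$caller_jitter_probes` probe positions (staying inside the call's
#' chromosome), and false-positive calls are injected per sample at
#' `config$caller_fp_rate`. Intended for stress-testing the consensus and
#' overlap filters; the HMM caller itself never applies it.
#'
#' @param calls a call-set data.frame (see [empty_callset()]).
#' @param layout genome layout the calls live on.
#' @param config a [simulation_config()]; only the jitter/FP fields are used.
#' @param seed integer seed for the perturbation stream.
#' @return a perturbed call-set data.frame.
#' @export
apply_caller_artifacts <- function(calls, layout, config = simulation_config(),
                                   seed = config$seed) {
  rng <- local_rng(seed, "artifacts")
  if (nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      pos <- layout$probes[[calls$chrom[i]]]
      j <- config$caller_jitter_probes
      if (j > 0) {
        s_idx <- findInterval(calls$start[i], pos)
        e_idx <- findInterval(calls$end[i], pos)
        s_idx <- max(1L, min(length(pos), s_idx + rng$sample_int(2L * j + 1L, 1L) - j - 1L))
        e_idx <- max(s_idx, min(length(pos), e_idx + rng$sample_int(2L * j + 1L, 1L) - j - 1L))
        calls$start[i] <- pos[s_idx]
        calls$end[i] <- pos[e_idx]
        calls$n_probes[i] <- e_idx - s_idx + 1L
      }
    }
  }
  samples <- unique(calls$sample_id)
  fp <- list()
  for (sid in samples) {
    if (rng$runif(1) < config$caller_fp_rate) {
      chrom <- rng$sample(layout$chromosomes$name, 1L)
      pos <- layout$probes[[chrom]]
      i0 <- rng$sample_int(length(pos) - 5L, 1L)
      cn <- rng$sample(c(1L, 3L), 1L)
      fp[[length(fp) + 1L]] <- data.frame(
        sample_id = sid, caller_id = calls$caller_id[1],
        chrom = chrom, start = pos[i0], end = pos[i0 + 4L],
        type = if (cn < 2L) "DEL" else "DUP", copy_number = cn,
        n_probes = 5L, confidence = 35, stringsAsFactors = FALSE
      )
    }
  }
  out <- rbind(calls, do.call(rbind, fp))
  sort_calls(out)
}
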