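# Independent brute-force oracles and random-instance generators.
# These deliberately avoid the package's interval index / greedy machinery:
# every oracle is a direct transcription of the filtering rule.

rand_calls <- function(n, samples, callers = "c1", chroms = c("1", "2"),
                       types = c("DEL", "DUP"), max_pos = 1e6) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(5e4, n, replace = TRUE)
  type <- sample(types, n, replace = TRUE)
  data.frame(
    sample_id = sample(samples, n, replace = TRUE),
    caller_id = sample(callers, n, replace = TRUE),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    type = type,
    copy_number = ifelse(type == "DEL", 1L, 3L),
    n_probes = sample(4:60, n, replace = TRUE),
    confidence = round(runif(n, 0, 100), 3),
    stringsAsFactors = FALSE
  )
}

# rule transcription: keep iff confidence >= 30 and n_probes >= 4
oracle_call_qc <- function(calls, th = filter_thresholds()) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    keep[i] <- calls$confidence[i] >= th$min_log_bf &&
      calls$n_probes[i] > th$min_probes_exclusive
  }
  calls[keep, , drop = FALSE]
}

oracle_relation <- function(qs, qe, os, oe) {
  if (qe < os || oe < qs) return("NONE")
  if (qs == os && qe == oe) return("EXACT")
  if (os <= qs && qe <= oe) return("CASE_WITHIN_OTHER")
  if (qs <= os && oe <= qe) return("OTHER_WITHIN_CASE")
  "PARTIAL"
}

# O(cases x controls) double loop over the containment rule
oracle_control_filter <- function(case_calls, control_calls, th,
                                  stratify_caller = TRUE) {
  keep <- logical(nrow(case_calls))
  for (i in seq_len(nrow(case_calls))) {
    carriers <- character(0)
    for (j in seq_len(nrow(control_calls))) {
      if (control_calls$chrom[j] != case_calls$chrom[i]) next
      if (control_calls$type[j] != case_calls$type[i]) next
      if (stratify_caller &&
          control_calls$caller_id[j] != case_calls$caller_id[i]) next
      rel <- oracle_relation(case_calls$start[i], case_calls$end[i],
                             control_calls$start[j], control_calls$end[j])
      if (rel %in% c("EXACT", "CASE_WITHIN_OTHER")) {
        carriers <- union(carriers, control_calls$sample_id[j])
      }
    }
    keep[i] <- length(carriers) <= th$control_carrier_exclusive
  }
  case_calls[keep, , drop = FALSE]
}

# exhaustive triple enumeration + greedy selection in lexicographic order of
# (a.start, b.start, c.start) within each (sample, chrom, type) group
oracle_consensus <- function(callsets) {
  keys <- lapply(callsets, function(cs) paste(cs$sample_id, cs$chrom, cs$type))
  groups <- unique(unlist(keys))
  rows <- list()
  for (g in groups) {
    ia <- which(keys[[1]] == g); ib <- which(keys[[2]] == g)
    ic <- which(keys[[3]] == g)
    if (!length(ia) || !length(ib) || !length(ic)) next
    triples <- expand.grid(a = ia, b = ib, c = ic)
    ok <- logical(nrow(triples))
    for (t in seq_len(nrow(triples))) {
      a <- callsets[[1]][triples$a[t], ]
      b <- callsets[[2]][triples$b[t], ]
      cc <- callsets[[3]][triples$c[t], ]
      ok[t] <- a$start <= b$end && b$start <= a$end &&
        a$start <= cc$end && cc$start <= a$end &&
        b$start <= cc$end && cc$start <= b$end
    }
    triples <- triples[ok, , drop = FALSE]
    o <- order(callsets[[1]]$start[triples$a], callsets[[2]]$start[triples$b],
               callsets[[3]]$start[triples$c])
    triples <- triples[o, , drop = FALSE]
    used_a <- used_b <- used_c <- integer(0)
    for (t in seq_len(nrow(triples))) {
      if (triples$a[t] %in% used_a || triples$b[t] %in% used_b ||
          triples$c[t] %in% used_c) next
      used_a <- c(used_a, triples$a[t]); used_b <- c(used_b, triples$b[t])
      used_c <- c(used_c, triples$c[t])
      a <- callsets[[1]][triples$a[t], ]
      b <- callsets[[2]][triples$b[t], ]
      cc <- callsets[[3]][triples$c[t], ]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = a$sample_id, chrom = a$chrom,
        start = max(a$start, b$start, cc$start),
        end = min(a$end, b$end, cc$end), type = a$type,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out)) return(out)
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_frequency_filter <- function(cnvs, db) {
  keep <- logical(nrow(cnvs))
  for (i in seq_len(nrow(cnvs))) {
    hit <- FALSE
    for (j in seq_len(nrow(db))) {
      if (db$chrom[j] != cnvs$chrom[i]) next
      if (!(db$type[j] == cnvs$type[i] || db$type[j] == "BOTH")) next
      rel <- oracle_relation(cnvs$start[i], cnvs$end[i], db$start[j], db$end[j])
      if (rel %in% c("EXACT", "CASE_WITHIN_OTHER")) { hit <- TRUE; break }
    }
    keep[i] <- !hit
  }
  cnvs[keep, , drop = FALSE]
}

# full path enumeration of the HMM objective, grown position by position
# (every one of the 5^n paths scored; no max-product recursion involved)
oracle_best_path_score <- function(emis, params) {
  n <- ncol(emis)
  log_stay <- log(params$stay_prob)
  log_move <- log((1 - params$stay_prob) / 4)
  init <- rep(log_move, 5); init[3] <- log_stay
  scores <- init + emis[, 1]
  last <- 1:5
  for (t in seq_len(n)[-1]) {
    m <- length(scores)
    new_scores <- numeric(5 * m)
    new_last <- integer(5 * m)
    for (k in 1:5) {
      slot <- seq.int((k - 1) * m + 1, k * m)
      new_scores[slot] <- scores + ifelse(last == k, log_stay, log_move) +
        emis[k, t]
      new_last[slot] <- k
    }
    scores <- new_scores
    last <- new_last
  }
  max(scores)
}

# score of one specific state path under the same objective
path_score <- function(path, emis, params) {
  log_stay <- log(params$stay_prob)
  log_move <- log((1 - params$stay_prob) / 4)
  init <- rep(log_move, 5); init[3] <- log_stay
  s <- init[path[1] + 1L] + emis[path[1] + 1L, 1]
  for (t in seq_along(path)[-1]) {
    s <- s + (if (path[t] == path[t - 1]) log_stay else log_move) +
      emis[path[t] + 1L, t]
  }
  s
}

# minimal single-chromosome cohort builder for caller tests
tiny_layout <- function(n_probes = 100, spacing = 5000, chrom = "1") {
  layout <- list(
    chromosomes = data.frame(name = chrom, length = (n_probes + 1) * spacing,
                             stringsAsFactors = FALSE),
    probes = stats::setNames(list(as.integer(seq(spacing, by = spacing,
                                                 length.out = n_probes))),
                             chrom)
  )
  class(layout) <- "genome_layout"
  layout
}

# direct signal synthesis on a layout: diploid baseline with optional events
# list(chrom, start, end, cn)
tiny_sample <- function(layout, events = list(), noise_lrr = 0.1,
                        noise_baf = 0.03, sample_id = "s1", seed = 1) {
  set.seed(seed)
  means <- c(`0` = -3, `1` = -0.6, `2` = 0, `3` = 0.4, `4` = 0.68)
  lrr <- list(); baf <- list()
  for (chrom in layout$chromosomes$name) {
    pos <- layout$probes[[chrom]]
    cn <- rep(2L, length(pos))
    for (ev in events) {
      if (ev$chrom != chrom) next
      cn[pos >= ev$start & pos <= ev$end] <- ev$cn
    }
    lrr[[chrom]] <- rnorm(length(pos), means[as.character(cn)], noise_lrr)
    b <- numeric(length(pos))
    for (i in seq_along(pos)) {
      k <- if (cn[i] == 0) NA else rbinom(1, cn[i], 0.5)
      centre <- if (is.na(k)) runif(1) else k / max(cn[i], 1)
      b[i] <- min(max(rnorm(1, centre, noise_baf), 0), 1)
    }
    baf[[chrom]] <- b
  }
  list(sample_id = sample_id, cohort = "case", recorded_sex = "F",
       lrr = lrr, baf = baf)
}
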