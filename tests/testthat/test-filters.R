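test_that("interval relations cover the five-way taxonomy", {
  expect_identical(interval_relation(100, 200, 100, 200), "EXACT")
  expect_identical(interval_relation(100, 200, 90, 250), "CASE_WITHIN_OTHER")
  expect_identical(interval_relation(100, 200, 100, 250), "CASE_WITHIN_OTHER")
  expect_identical(interval_relation(100, 200, 120, 180), "OTHER_WITHIN_CASE")
  expect_identical(interval_relation(100, 200, 150, 250), "PARTIAL")
  expect_identical(interval_relation(100, 200, 201, 300), "NONE")
  # vectorized over the second interval
  expect_identical(
    interval_relation(100, 200, c(100, 90, 150), c(200, 250, 250)),
    c("EXACT", "CASE_WITHIN_OTHER", "PARTIAL")
  )
  # randomized agreement with the scalar rule transcription
  set.seed(31)
  for (i in 1:200) {
    q <- sort(sample.int(100, 2)); o <- sort(sample.int(100, 2))
    expect_identical(interval_relation(q[1], q[2], o[1], o[2]),
                     oracle_relation(q[1], q[2], o[1], o[2]))
  }
})

test_that("sample QC applies the call-rate, sex and count-outlier rules", {
  metrics <- data.frame(
    sample_id = sprintf("s%d", 1:5),
    cohort = "case",
    recorded_sex = c("F", "F", "M", "F", "F"),
    call_rate = c(0.979, 0.99, 0.99, 0.98, 0.995),
    sex_called = c("F", "F", "F", "F", "F"),
    stringsAsFactors = FALSE
  )
  counts <- c(5, 5, 5, 5, 25)
  calls <- do.call(rbind, lapply(1:5, function(i) {
    df <- rand_calls(counts[i], samples = metrics$sample_id[i])
    df$start <- df$start + seq_len(nrow(df)) * 1000L  # keep records unique
    df$end <- df$start + 100L
    df
  }))
  qc <- sample_qc(list(c1 = calls), metrics)
  expect_identical(qc$cnv_count, as.integer(counts))
  # call_rate 0.979 < 0.98 fails; 0.98 passes exactly
  expect_false(qc$passed[1])
  expect_match(qc$reasons[1], "call_rate")
  expect_true(qc$passed[4])
  # recorded M but diploid X: sex mismatch
  expect_false(qc$passed[3])
  expect_match(qc$reasons[3], "sex_mismatch")
  # counts {5,5,5,5,25}: mean 9, population SD 8 -> 25 <= 25 kept
  expect_true(qc$passed[5])

  # 6-sample cohort {5,5,5,5,5,40}: mean 10.83, population SD 13.04,
  # cutoff 36.9 -> the 40-call sample is an outlier
  metrics2 <- data.frame(
    sample_id = sprintf("t%d", 1:6), cohort = "case", recorded_sex = "F",
    call_rate = 0.99, sex_called = "F", stringsAsFactors = FALSE
  )
  counts2 <- c(5, 5, 5, 5, 5, 40)
  calls2 <- do.call(rbind, lapply(1:6, function(i) {
    df <- rand_calls(counts2[i], samples = metrics2$sample_id[i])
    df$start <- df$start + seq_len(nrow(df)) * 1000L
    df$end <- df$start + 100L
    df
  }))
  qc2 <- sample_qc(list(c1 = calls2), metrics2)
  expect_false(qc2$passed[6])
  expect_match(qc2$reasons[6], "cnv_count_outlier")
  expect_true(all(qc2$passed[1:5]))

  expect_warning(sample_qc(list(c1 = empty_callset()), metrics[1, ]),
                 "fewer than 2 samples")
})

test_that("call QC keeps the boundary-complement values", {
  base <- rand_calls(4, samples = "s1")
  base$confidence <- c(29.99, 30.0, 50, 50)
  base$n_probes <- c(50L, 4L, 3L, 4L)
  base$start <- c(1e3L, 2e5L, 4e5L, 6e5L)
  base$end <- base$start + 1000L
  out <- call_qc(base)
  expect_identical(out$trace$decision, c("removed", "kept", "removed", "kept"))
  expect_identical(nrow(out$calls), 2L)

  na_calls <- base
  na_calls$confidence[1] <- NA
  expect_error(call_qc(na_calls), "missing confidence")
})

test_that("call QC equals a brute-force predicate scan on random calls", {
  set.seed(51)
  calls <- rand_calls(1000, samples = sprintf("s%02d", 1:20),
                      callers = c("a", "b", "c"))
  calls <- calls[!duplicated(cnvsieve:::call_key(calls)), ]
  got <- call_qc(calls)$calls
  want <- oracle_call_qc(calls)
  expect_identical(got, want)
  # idempotence and subset
  again <- call_qc(got)$calls
  expect_identical(again, got)
})

test_that("control-containment filter follows the worked examples", {
  mk <- function(sid, start, end, caller = "c1", type = "DUP") {
    data.frame(sample_id = sid, caller_id = caller, chrom = "1",
               start = start, end = end, type = type,
               copy_number = if (type == "DUP") 3L else 1L, n_probes = 10L,
               confidence = 60, stringsAsFactors = FALSE)
  }
  case <- mk("p1", 100000L, 200000L)
  # identical DUP in two distinct controls -> removed
  out <- control_overlap_filter(case, rbind(mk("cA", 100000L, 200000L),
                                            mk("cB", 100000L, 200000L)))
  expect_identical(nrow(out$calls), 0L)
  expect_match(out$trace$reason, "contained_in_2_controls")
  # containing call in one control only -> kept
  out <- control_overlap_filter(case, mk("cA", 90000L, 250000L))
  expect_identical(nrow(out$calls), 1L)
  # partial overlap never excludes, no matter how many carriers
  many <- do.call(rbind, lapply(sprintf("c%02d", 1:10), mk,
                                start = 150000L, end = 250000L))
  out <- control_overlap_filter(case, many)
  expect_identical(nrow(out$calls), 1L)
  # same-type same-caller stratification: DEL controls cannot exclude a DUP
  dels <- rbind(mk("cA", 100000L, 200000L, type = "DEL"),
                mk("cB", 100000L, 200000L, type = "DEL"))
  out <- control_overlap_filter(case, dels)
  expect_identical(nrow(out$calls), 1L)
  other_caller <- rbind(mk("cA", 100000L, 200000L, caller = "c2"),
                        mk("cB", 100000L, 200000L, caller = "c2"))
  out <- control_overlap_filter(case, other_caller)
  expect_identical(nrow(out$calls), 1L)
  out <- control_overlap_filter(case, other_caller, stratify_caller = FALSE)
  expect_identical(nrow(out$calls), 0L)
})

test_that("control-containment filter equals the O(n^2) brute force", {
  set.seed(61)
  th <- filter_thresholds()
  for (rep_i in 1:3) {
    cases <- rand_calls(500, samples = sprintf("p%02d", 1:25),
                        callers = c("a", "b"))
    controls <- rand_calls(2000, samples = sprintf("k%03d", 1:100),
                           callers = c("a", "b"))
    got <- control_overlap_filter(cases, controls, th)$calls
    want <- oracle_control_filter(cases, controls, th)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("consensus intersects the three callers' intervals", {
  mk <- function(caller, start, end, sid = "p1") {
    data.frame(sample_id = sid, caller_id = caller, chrom = "1",
               start = start, end = end, type = "DUP", copy_number = 3L,
               n_probes = 10L, confidence = 40 + start / 1e4,
               stringsAsFactors = FALSE)
  }
  cs <- list(a = mk("a", 100000L, 200000L),
             b = mk("b", 150000L, 250000L),
             c = mk("c", 120000L, 220000L))
  out <- consensus_intersect(cs)
  expect_identical(nrow(out$consensus), 1L)
  expect_identical(out$consensus$start, 150000L)
  expect_identical(out$consensus$end, 200000L)
  expect_identical(out$consensus$union_start, 100000L)
  expect_identical(out$consensus$union_end, 250000L)
  expect_equal(out$consensus$min_confidence, min(sapply(cs, `[[`, "confidence")))

  # an event seen by only two callers produces no consensus
  cs2 <- list(a = mk("a", 100000L, 200000L), b = mk("b", 150000L, 250000L),
              c = mk("c", 500000L, 600000L))
  out2 <- consensus_intersect(cs2)
  expect_identical(nrow(out2$consensus), 0L)
  expect_true(all(out2$trace$reason == "missing_caller"))

  expect_error(consensus_intersect(cs[1:2]), "configuration error")
})

test_that("consensus equals exhaustive triple enumeration on jittered calls", {
  set.seed(71)
  for (rep_i in 1:40) {
    n_ev <- sample(1:4, 1)
    base_start <- sort(sample.int(8e5, n_ev)) + c(0, cumsum(rep(2e5, n_ev - 1)))
    sets <- lapply(c("a", "b", "c"), function(cal) {
      keep <- runif(n_ev) < 0.8
      if (!any(keep)) keep[1] <- TRUE
      st <- base_start[keep] + sample(-2e4:2e4, sum(keep), replace = TRUE)
      data.frame(sample_id = "p1", caller_id = cal, chrom = "1",
                 start = st, end = st + 1e5L +
                   sample(-1e4:1e4, sum(keep), replace = TRUE),
                 type = "DUP", copy_number = 3L, n_probes = 10L,
                 confidence = 50, stringsAsFactors = FALSE)
    })
    names(sets) <- c("a", "b", "c")
    got <- consensus_intersect(sets)$consensus
    want <- oracle_consensus(sets)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got[, c("sample_id", "chrom", "start", "end", "type")],
                       want)
    }
  }
})

test_that("size filter keeps 50 kb and the published fixture lengths", {
  mk <- function(len) {
    data.frame(sample_id = "p1", chrom = "1", start = 1e5L,
               end = 1e5L + len - 1L, type = "DUP", copy_number = 3L,
               min_confidence = 60, min_n_probes = 12L,
               union_start = 1e5L, union_end = 1e5L + len - 1L,
               stringsAsFactors = FALSE)
  }
  out <- size_filter(rbind(mk(49999L), mk(50000L)))
  expect_identical(nrow(out$cnvs), 1L)
  expect_identical(out$cnvs$end - out$cnvs$start + 1L, 50000L)

  fx <- size_filter(validated_dup_fixture()$calls)
  expect_identical(nrow(fx$cnvs), 3L)

  empty <- size_filter(validated_dup_fixture()$calls[0, ])
  expect_identical(nrow(empty$cnvs), 0L)
  expect_identical(nrow(empty$trace), 0L)
})

test_that("frequency filter removes contained CNVs only", {
  cnv <- data.frame(sample_id = "p1", chrom = "1", start = 100000L,
                    end = 200000L, type = "DUP", copy_number = 3L,
                    min_confidence = 60, min_n_probes = 12L,
                    union_start = 100000L, union_end = 200000L,
                    stringsAsFactors = FALSE)
  db_exact <- data.frame(chrom = "1", start = 100000L, end = 200000L,
                         type = "DUP", source_id = "v1",
                         stringsAsFactors = FALSE)
  expect_identical(nrow(frequency_filter(cnv, db_exact)$cnvs), 0L)
  # CNV strictly containing a smaller record survives
  db_small <- transform(db_exact, start = 120000L, end = 180000L)
  expect_identical(nrow(frequency_filter(cnv, db_small)$cnvs), 1L)
  # BOTH matches either type; DEL does not match a DUP
  db_both <- transform(db_exact, type = "BOTH", start = 90000L, end = 210000L)
  expect_identical(nrow(frequency_filter(cnv, db_both)$cnvs), 0L)
  db_del <- transform(db_exact, type = "DEL")
  expect_identical(nrow(frequency_filter(cnv, db_del)$cnvs), 1L)
})

test_that("frequency filter equals the brute-force scan on random inputs", {
  set.seed(81)
  for (rep_i in 1:3) {
    n <- 200
    start <- sample.int(1e6, n)
    cnvs <- data.frame(
      sample_id = sample(sprintf("p%d", 1:10), n, replace = TRUE),
      chrom = sample(c("1", "2"), n, replace = TRUE),
      start = start, end = start + sample.int(1e5, n),
      type = sample(c("DEL", "DUP"), n, replace = TRUE),
      copy_number = 3L, min_confidence = 50, min_n_probes = 10L,
      union_start = start, union_end = start + 1000L,
      stringsAsFactors = FALSE
    )
    m <- 300
    dstart <- sample.int(1e6, m)
    db <- data.frame(
      chrom = sample(c("1", "2"), m, replace = TRUE),
      start = dstart, end = dstart + sample.int(2e5, m),
      type = sample(c("DEL", "DUP", "BOTH"), m, replace = TRUE),
      source_id = sprintf("v%d", seq_len(m)), stringsAsFactors = FALSE
    )
    got <- frequency_filter(cnvs, db)$cnvs
    want <- oracle_frequency_filter(cnvs, db)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("filters are pure subsets with total traces", {
  set.seed(91)
  calls <- rand_calls(300, samples = sprintf("p%d", 1:10))
  calls <- calls[!duplicated(cnvsieve:::call_key(calls)), ]
  out <- call_qc(calls)
  expect_identical(nrow(out$trace), nrow(calls))
  expect_identical(sum(out$trace$decision == "kept"), nrow(out$calls))
  expect_true(all(cnvsieve:::call_key(out$calls) %in%
                    cnvsieve:::call_key(calls)))

  controls <- rand_calls(500, samples = sprintf("k%d", 1:30))
  out2 <- control_overlap_filter(calls, controls)
  expect_identical(nrow(out2$trace), nrow(calls))
  # idempotence: filtering the survivors again changes nothing
  out3 <- control_overlap_filter(out2$calls, controls)
  expect_identical(out3$calls, out2$calls)
})
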