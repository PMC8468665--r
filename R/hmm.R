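#' Hidden Markov model parameters for CNV segmentation
#'
#' Five hidden states, one per copy number 0-4. Emissions combine a Gaussian
#' LogR-ratio density (state mean per copy number; the homozygous-deletion
#' state uses a 3x wider SD to absorb signal collapse) with the
#' B-allele-frequency genotype-cluster mixture of that copy number, weighted
#' `baf_weight` : `1 - baf_weight` on the log scale. Transitions are
#' distance-independent: `stay_prob` on the diagonal, the remainder split
#' uniformly across the other four states.
#'
#' @param caller_id label stamped on every call this parameter set produces.
#' @param state_means named numeric vector of LRR means for copy numbers
#'   "0".."4".
#' @param lrr_sd emission SD of the LRR track (log2-ratio units).
#' @param baf_sd emission SD around each BAF cluster.
#' @param stay_prob self-transition probability, strictly in (0, 1).
#' @param baf_weight weight of the BAF log-density in the emission, in
#'   \[0, 1\].
#' @return list of class `"hmm_params"`.
#' @export
hmm_params <- function(caller_id,
                       state_means = .lrr_state_means,
                       lrr_sd = 0.2,
                       baf_sd = 0.05,
                       stay_prob = 0.995,
                       baf_weight = 0.3) {
  if (!is.numeric(stay_prob) || stay_prob <= 0 || stay_prob >= 1) {
    stop("configuration error: stay_prob must be strictly in (0, 1)",
         call. = FALSE)
  }
  if (lrr_sd <= 0) stop("configuration error: lrr_sd must be > 0", call. = FALSE)
  if (baf_weight < 0 || baf_weight > 1) {
    stop("configuration error: baf_weight must be in [0, 1]", call. = FALSE)
  }
  if (length(state_means) != 5L ||
      !identical(names(state_means), c("0", "1", "2", "3", "4"))) {
    stop("configuration error: state_means must cover copy numbers 0-4",
         call. = FALSE)
  }
  structure(list(caller_id = caller_id, state_means = state_means,
                 lrr_sd = lrr_sd, baf_sd = baf_sd, stay_prob = stay_prob,
                 baf_weight = baf_weight),
            class = "hmm_params")
}

#' Three caller-like parameter profiles
#'
#' One HMM run under three presets stands in for running three independent
#' CNV calling programs: a partition-style caller (segment-happy, LRR-driven),
#' a QuantiSNP-style caller (BAF-heavy, conservative transitions) and a
#' PennCNV-style caller (balanced). The presets differ in `stay_prob`,
#' `lrr_sd` and `baf_weight` only, so their call sets genuinely disagree at
#' noisy boundaries.
#'
#' @return named list of three [hmm_params()] objects with distinct
#'   `caller_id`s.
#' @export
caller_profiles <- function() {
  list(
    `partition-like` = hmm_params("partition-like", lrr_sd = 0.22,
                                  stay_prob = 0.99, baf_weight = 0.15),
    `quanti-like` = hmm_params("quanti-like", lrr_sd = 0.18,
                               stay_prob = 0.999, baf_weight = 0.45),
    `penn-like` = hmm_params("penn-like", lrr_sd = 0.20,
                             stay_prob = 0.995, baf_weight = 0.30)
  )
}

# per-probe LRR and BAF log-density matrices (5 states x n observed probes);
# missing values contribute 0 in either track
track_loglik <- function(lrr, baf, params) {
  n <- length(lrr)
  ll_lrr <- matrix(0, nrow = 5L, ncol = n)
  ll_baf <- matrix(0, nrow = 5L, ncol = n)
  for (s in 0:4) {
    sd_s <- if (s == 0L) 3 * params$lrr_sd else params$lrr_sd
    l_lrr <- stats::dnorm(lrr, params$state_means[[as.character(s)]], sd_s,
                          log = TRUE)
    cl <- .baf_clusters(s)
    if (is.null(cl)) {
      l_baf <- rep(0, n)  # CN0: BAF uninformative, uniform density on [0,1]
    } else {
      dens <- rep(0, n)
      for (k in seq_along(cl$mean)) {
        dens <- dens + cl$weight[k] *
          stats::dnorm(baf, cl$mean[k], params$baf_sd)
      }
      l_baf <- log(pmax(dens, 1e-300))
    }
    l_lrr[is.na(l_lrr)] <- 0
    l_baf[is.na(l_baf)] <- 0
    ll_lrr[s + 1L, ] <- l_lrr
    ll_baf[s + 1L, ] <- l_baf
  }
  list(lrr = ll_lrr, baf = ll_baf)
}

# decoder emission: convex combination of the two tracks, so baf_weight tunes
# how much a profile trusts allele-frequency structure over raw intensity
emission_loglik <- function(lrr, baf, params) {
  tl <- track_loglik(lrr, baf, params)
  (1 - params$baf_weight) * tl$lrr + params$baf_weight * tl$baf
}

# Viterbi over one chromosome's observed probes. Returns the copy-number path.
# Ties in the backtracking pointers are broken toward the diploid state, which
# favors fewer and shorter calls.
viterbi_path <- function(emis, params) {
  n <- ncol(emis)
  if (n == 0L) return(integer(0))
  log_stay <- log(params$stay_prob)
  log_move <- log((1 - params$stay_prob) / 4)
  # state preference order for tie-breaking: diploid first
  pref <- c(3L, 1L, 2L, 4L, 5L)
  init <- rep(log_move, 5L)
  init[3L] <- log_stay
  delta <- init + emis[, 1L]
  psi <- matrix(0L, nrow = 5L, ncol = n)
  for (t in seq_len(n)[-1L]) {
    new_delta <- numeric(5L)
    for (s in 1:5) {
      cand <- delta + log_move
      cand[s] <- delta[s] + log_stay
      best <- pref[which.max(cand[pref])]
      psi[s, t] <- best
      new_delta[s] <- cand[best] + emis[s, t]
    }
    delta <- new_delta
  }
  path <- integer(n)
  path[n] <- pref[which.max(delta[pref])]
  if (n > 1L) {
    for (t in seq.int(n, 2L)) path[t - 1L] <- psi[path[t], t]
  }
  path - 1L  # copy numbers
}

#' Segment one sample into copy-number calls
#'
#' Runs the five-state Viterbi decoder per chromosome on the sample's
#' LRR/BAF tracks and reports maximal runs of non-diploid states as calls.
#' Probes with missing intensities are skipped; the transition simply spans
#' them, and a chromosome with no observed probes yields no calls. Each call
#' carries the probe count of the run and the log10 Bayes factor from
#' [score_call()].
#'
#' @param sample one element of an `intensity_cohort`.
#' @param layout the genome layout the sample was simulated/measured on.
#' @param params an [hmm_params()] object.
#' @return call-set data.frame, sorted, non-overlapping within the sample.
#' @export
viterbi_segment <- function(sample, layout, params) {
  rows <- list()
  for (chrom in layout$chromosomes$name) {
    pos <- layout$probes[[chrom]]
    lrr <- sample$lrr[[chrom]]
    baf <- sample$baf[[chrom]]
    if (length(lrr) != length(pos) || length(baf) != length(pos)) {
      stop("input error: intensity arrays not aligned to layout on chromosome ",
           chrom, call. = FALSE)
    }
    obs <- which(!(is.na(lrr) & is.na(baf)))
    if (!length(obs)) next
    emis <- emission_loglik(lrr[obs], baf[obs], params)
    path <- viterbi_path(emis, params)
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values != 2L)) {
      i0 <- obs[starts[k]]; i1 <- obs[ends[k]]
      cn <- r$values[k]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample$sample_id, caller_id = params$caller_id,
        chrom = chrom, start = pos[i0], end = pos[i1],
        type = cn_to_type(cn), copy_number = cn,
        n_probes = r$lengths[k], confidence = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else empty_callset()
  if (nrow(calls)) {
    calls$confidence <- vapply(seq_len(nrow(calls)), function(i) {
      score_call(calls[i, ], sample, layout, params)
    }, numeric(1))
  }
  sort_calls(calls)
}

#' Log10 Bayes factor of a call against the diploid hypothesis
#'
#' Sums, over the observed probes inside the call, the log10 joint
#' likelihood of the LRR and BAF observations under the called copy-number
#' state minus the log10 joint likelihood under copy number 2. The two
#' tracks enter the score unweighted (the full evidence both carry), unlike
#' the decoder's emission where `baf_weight` only shapes the segmentation's
#' state preference. The noise scales are estimated from the sample itself
#' (see [estimate_noise()]) rather than taken from the caller profile, so a
#' clean sample yields sharper evidence than a noisy one for the same
#' segment — the behavior of likelihood-ratio scores in production callers.
#' Diploid data never favors a CNV in expectation (score <= 0) and the
#' quality threshold of 30 bans weakly supported calls.
#'
#' @param call one call-set row.
#' @param sample the intensity sample the call was made on.
#' @param layout genome layout.
#' @param params the [hmm_params()] used for calling.
#' @return scalar log10 Bayes factor.
#' @export
score_call <- function(call, sample, layout, params) {
  pos <- layout$probes[[call$chrom]]
  lrr <- sample$lrr[[call$chrom]]
  baf <- sample$baf[[call$chrom]]
  idx <- which(pos >= call$start & pos <= call$end & !(is.na(lrr) & is.na(baf)))
  if (!length(idx)) {
    stop("input error: call covers no observed probes", call. = FALSE)
  }
  ns <- estimate_noise(lrr, baf)
  sparams <- params
  sparams$lrr_sd <- ns$lrr_sd
  sparams$baf_sd <- ns$baf_sd
  tl <- track_loglik(lrr[idx], baf[idx], sparams)
  joint <- tl$lrr + tl$baf
  (sum(joint[call$copy_number + 1L, ]) - sum(joint[3L, ])) / log(10)
}

#' Estimate a sample's intensity noise on one chromosome
#'
#' Robust scale estimates used by [score_call()]: the LRR SD is the median
#' absolute deviation of the observed LogR ratios (CNV segments are a small
#' minority of probes, so the MAD tracks the diploid baseline), and the BAF
#' SD is the MAD-about-zero of each probe's distance to its nearest diploid
#' cluster (0, 1/2 or 1). Both are floored at 0.01 to keep densities proper
#' on degenerate noise-free input.
#'
#' @param lrr,baf numeric vectors of one chromosome's observed intensities.
#' @return list with `lrr_sd` and `baf_sd`.
#' @export
estimate_noise <- function(lrr, baf) {
  lrr <- lrr[!is.na(lrr)]
  baf <- baf[!is.na(baf)]
  lrr_sd <- if (length(lrr) > 1) stats::mad(lrr) else 0
  d <- pmin(abs(baf), abs(baf - 0.5), abs(1 - baf))
  baf_sd <- if (length(d) > 1) stats::mad(d, center = 0) else 0
  list(lrr_sd = max(lrr_sd, 0.01), baf_sd = max(baf_sd, 0.01))
}

#' Call a cohort under the three caller profiles
#'
#' Applies [viterbi_segment()] to every sample once per profile. The three
#' resulting call sets cover identical samples and differ only through the
#' profiles' parameters; no post-hoc jitter or false-positive injection is
#' applied here (see [apply_caller_artifacts()] for that emulation mode).
#'
#' @param cohort an `intensity_cohort` (or any list of intensity samples).
#' @param layout genome layout.
#' @param profiles named list of [hmm_params()]; default [caller_profiles()].
#' @return named list `caller_id -> call-set data.frame`.
#' @export
run_three_callers <- function(cohort, layout, profiles = caller_profiles()) {
  ids <- vapply(profiles, `[[`, character(1), "caller_id")
  if (anyDuplicated(ids)) {
    stop("configuration error: duplicate caller_id in profiles", call. = FALSE)
  }
  out <- lapply(profiles, function(p) {
    calls <- lapply(cohort, viterbi_segment, layout = layout, params = p)
    sort_calls(do.call(rbind, c(calls, list(empty_callset()))))
  })
  names(out) <- ids
  out
}
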