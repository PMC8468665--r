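#' Build a simulation configuration
#'
#' Collects every knob of the synthetic case-control cohort generator in one
#' validated list. The defaults describe the study conditions the rest of the
#' package is exercised under: a desk-scale three-chromosome genome carrying
#' roughly 2,000 probes at a median spacing near 4.59 kb, 40 cases and 200
#' controls, three ultra-rare planted case duplications of at least 50 kb and
#' five common copy-number polymorphisms shared across controls.
#'
#' @param seed integer seed; identical seed + config give bit-identical output.
#' @param n_cases,n_controls cohort sizes.
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#'   Chromosome "X" (if present) is simulated at copy number 1 in males.
#' @param n_probes total probe count, split across chromosomes by length.
#' @param noise_sd_lrr Gaussian noise SD of the LogR ratio, log2-ratio units.
#' @param baf_sd Gaussian SD around each B-allele-frequency cluster.
#' @param missing_rate per-probe probability that a sample's LRR and BAF are
#'   missing (no-call), in \[0, 1).
#' @param event_spec list of planted-event specifications; see
#'   [default_event_spec()].
#' @param caller_jitter_probes boundary jitter (in probes) used only by the
#'   caller-artifact emulation mode, see [apply_caller_artifacts()].
#' @param caller_fp_rate per-sample false-positive call rate for the same
#'   emulation mode, in \[0, 1).
#' @param male_fraction fraction of samples with recorded sex "M".
#'
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cases = 40L,
                              n_controls = 200L,
                              chromosomes = data.frame(
                                name = c("1", "2", "X"),
                                length = c(4e6, 3.2e6, 2e6),
                                stringsAsFactors = FALSE
                              ),
                              n_probes = 2000L,
                              noise_sd_lrr = 0.15,
                              baf_sd = 0.04,
                              missing_rate = 0.01,
                              event_spec = default_event_spec(),
                              caller_jitter_probes = 2L,
                              caller_fp_rate = 0.02,
                              male_fraction = 0.5) {
  cfg <- list(
    seed = as.integer(seed),
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    chromosomes = chromosomes,
    n_probes = as.integer(n_probes),
    noise_sd_lrr = noise_sd_lrr,
    baf_sd = baf_sd,
    missing_rate = missing_rate,
    event_spec = event_spec,
    caller_jitter_probes = as.integer(caller_jitter_probes),
    caller_fp_rate = caller_fp_rate,
    male_fraction = male_fraction
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Default planted-event specification
#'
#' Three ultra-rare duplications (one case carrier each, no controls) whose
#' length ranges mirror the hundreds-of-kb to tens-of-kb span of validated
#' microduplications, plus five common polymorphisms each shared by several
#' controls and a couple of cases, so the control-containment filter has real
#' work to do.
#'
#' @return list of event specifications; each has fields `label`
#'   (`"ultra_rare"` or `"common_polymorphism"`), `copy_number` (0, 1, 3 or 4),
#'   `length_range` (2-vector, bp), `n_case_carriers`, `n_control_carriers`.
#' @export
default_event_spec <- function() {
  ur <- function(lo, hi) {
    list(label = "ultra_rare", copy_number = 3L,
         length_range = c(lo, hi), n_case_carriers = 1L,
         n_control_carriers = 0L)
  }
  poly <- function(cn) {
    list(label = "common_polymorphism", copy_number = cn,
         length_range = c(6e4, 1.2e5), n_case_carriers = 2L,
         n_control_carriers = 8L)
  }
  c(
    list(ur(8e5, 9e5), ur(1.2e5, 1.5e5), ur(6e4, 8e4)),
    list(poly(3L), poly(1L), poly(3L), poly(1L), poly(3L))
  )
}

validate_simulation_config <- function(cfg) {
  stop_cfg <- function(msg) stop("configuration error: ", msg, call. = FALSE)
  if (!is.data.frame(cfg$chromosomes) ||
      !all(c("name", "length") %in% names(cfg$chromosomes))) {
    stop_cfg("chromosomes must be a data.frame with columns name, length")
  }
  if (any(cfg$chromosomes$length <= 0)) {
    stop_cfg("non-positive chromosome length")
  }
  if (anyDuplicated(cfg$chromosomes$name)) stop_cfg("duplicate chromosome names")
  if (cfg$n_probes <= 0) stop_cfg("non-positive probe count")
  if (cfg$n_cases < 0 || cfg$n_controls < 0) stop_cfg("negative cohort size")
  for (r in c("missing_rate", "caller_fp_rate")) {
    v <- cfg[[r]]
    if (!is.numeric(v) || v < 0 || v >= 1) stop_cfg(paste(r, "must be in [0, 1)"))
  }
  if (!is.numeric(cfg$male_fraction) || cfg$male_fraction < 0 ||
      cfg$male_fraction > 1) {
    stop_cfg("male_fraction must be in [0, 1]")
  }
  for (ev in cfg$event_spec) {
    if (!ev$label %in% c("ultra_rare", "common_polymorphism")) {
      stop_cfg("event label must be ultra_rare or common_polymorphism")
    }
    if (!ev$copy_number %in% c(0L, 1L, 3L, 4L)) {
      stop_cfg("planted copy_number must be in {0, 1, 3, 4}")
    }
    if (any(ev$length_range <= 0) || ev$length_range[1] > ev$length_range[2]) {
      stop_cfg("event length_range must be positive and ordered")
    }
  }
  invisible(cfg)
}

#' Generate a genome layout of chromosomes and probe positions
#'
#' Probes are laid out on a jittered regular grid so the median adjacent-probe
#' spacing tracks total length / probe count, emulating the quasi-uniform
#' marker grid of a genotyping BeadChip. Positions are 1-based, strictly
#' increasing and unique within each chromosome.
#'
#' @param config a [simulation_config()].
#' @return A list of class `"genome_layout"` with elements `chromosomes`
#'   (data.frame name/length) and `probes` (named list of sorted integer
#'   position vectors).
#' @export
make_genome <- function(config = simulation_config()) {
  validate_simulation_config(config)
  chroms <- config$chromosomes
  total_len <- sum(chroms$length)
  # probes split proportionally to chromosome length, at least 4 each
  n_by_chr <- pmax(4L, round(config$n_probes * chroms$length / total_len))
  rng <- local_rng(config$seed, "genome")
  probes <- stats::setNames(vector("list", nrow(chroms)), chroms$name)
  for (i in seq_len(nrow(chroms))) {
    n <- n_by_chr[i]
    L <- chroms$length[i]
    spacing <- L / (n + 1)
    pos <- round(spacing * seq_len(n) +
                   rng$rnorm(n, sd = 0.15 * spacing))
    pos <- sort(unique(pmin.int(pmax.int(pos, 1), L)))
    # jitter collisions are rare at 15% spacing sd; pad deterministically if any
    while (length(pos) < n) {
      gaps <- which(diff(pos) > 1)
      if (!length(gaps)) break
      g <- gaps[1]
      pos <- sort(c(pos, pos[g] + (pos[g + 1] - pos[g]) %/% 2))
    }
    probes[[chroms$name[i]]] <- as.integer(pos)
  }
  layout <- list(chromosomes = chroms, probes = probes)
  class(layout) <- "genome_layout"
  layout
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosomes,",
      sum(lengths(x$probes)), "probes\n")
  for (i in seq_len(nrow(x$chromosomes))) {
    nm <- x$chromosomes$name[i]
    cat(sprintf("  %s  %9d bp  %5d probes\n", nm, x$chromosomes$length[i],
                length(x$probes[[nm]])))
  }
  invisible(x)
}

# Scoped RNG: every generator stage draws from its own stream derived from
# (seed, tag) so adding draws in one stage never perturbs another.
local_rng <- function(seed, tag) {
  sub <- (as.numeric(seed) * 1000003 + sum(utf8ToInt(tag)) * 7919) %% 2147483647
  env <- new.env(parent = emptyenv())
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(sub))
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    s
  }
  draw <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
        rm(".Random.seed", envir = globalenv())
      out
    }
  }
  list(
    rnorm = draw(stats::rnorm),
    runif = draw(stats::runif),
    rbinom = draw(stats::rbinom),
    sample = draw(base::sample),
    sample_int = draw(base::sample.int)
  )
}
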