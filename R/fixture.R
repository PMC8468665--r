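#' Worked-example fixture: three validated microduplications
#'
#' A self-contained bundle reproducing the three qPCR-confirmed
#' microduplications of the study this pipeline models — dup5q23.2
#' (852,734 bp, de novo), dup10q23.31 (131,276 bp) and dup1p36.21
#' (65,758 bp) — at synthetic coordinates chosen so each 1-based inclusive
#' length matches the published span exactly. The gene annotation places
#' every reported symbol inside its duplication with the narrated biotype
#' (e.g. four protein-coding and four non-coding entries in dup5q23.2, the
#' microRNA MIR107 in dup10q23.31), and the evidence table carries the
#' embryonic mouse urinary-tract expression flags (Sncaip and Slc16a12 /
#' Mir107 in the developing kidney and metanephros, Fblim1 in the embryonic
#' urethra).
#'
#' @return list with elements `calls` (three consensus-style DUP rows),
#'   `genes` (gene-model data.frame) and `evidence` (evidence table).
#' @export
validated_dup_fixture <- function() {
  span <- function(chrom, start, len) {
    c(chrom = chrom, start = start, end = start + len - 1)
  }
  iv5 <- list(chrom = "5", start = 121000001L, len = 852734L)
  iv10 <- list(chrom = "10", start = 91000001L, len = 131276L)
  iv1 <- list(chrom = "1", start = 15000001L, len = 65758L)
  mk_call <- function(sid, iv) {
    data.frame(
      sample_id = sid, chrom = iv$chrom, start = iv$start,
      end = iv$start + iv$len - 1L, type = "DUP", copy_number = 3L,
      min_confidence = 120, min_n_probes = as.integer(round(iv$len / 4590)),
      union_start = iv$start, union_end = iv$start + iv$len - 1L,
      stringsAsFactors = FALSE
    )
  }
  calls <- rbind(mk_call("100243", iv5), mk_call("100295", iv10),
                 mk_call("100009", iv1))

  # genes laid inside each duplication; offsets/sizes are synthetic, biotypes
  # follow the published per-interval narrative
  gene <- function(symbol, iv, offset, len, biotype, strand = "+") {
    data.frame(symbol = symbol, chrom = iv$chrom,
               start = iv$start + as.integer(offset),
               end = iv$start + as.integer(offset) + as.integer(len) - 1L,
               strand = strand, biotype = biotype, stringsAsFactors = FALSE)
  }
  genes <- rbind(
    gene("LINC02201", iv5, 20000, 30000, "lncRNA"),
    gene("LOC101927357", iv5, 80000, 20000, "lncRNA"),
    gene("LOC105379152", iv5, 140000, 15000, "lncRNA"),
    gene("MGC32805/PPIC", iv5, 200000, 18000, "other_noncoding"),
    gene("PRDM6", iv5, 280000, 60000, "protein_coding"),
    gene("SNCAIP", iv5, 420000, 90000, "protein_coding", "-"),
    gene("SNX2", iv5, 600000, 50000, "protein_coding"),
    gene("SNX24", iv5, 720000, 60000, "protein_coding"),
    gene("MIR107", iv10, 30000, 100, "miRNA", "-"),
    gene("PANK1", iv10, 40000, 35000, "protein_coding"),
    gene("SLC16A12", iv10, 90000, 30000, "protein_coding", "-"),
    gene("SLC25A34-AS1", iv1, 5000, 4000, "antisense", "-"),
    gene("FBLIM1", iv1, 12000, 12000, "protein_coding"),
    gene("PLEKHM2", iv1, 28000, 14000, "protein_coding"),
    gene("SLC25A34", iv1, 45000, 6000, "protein_coding", "-"),
    gene("TMEM82", iv1, 55000, 8000, "protein_coding")
  )

  evidence <- data.frame(
    symbol = c("SNCAIP", "FBLIM1", "SLC16A12", "MIR107"),
    embryonic_lower_urinary_tract_expression = c(FALSE, TRUE, FALSE, FALSE),
    embryonic_kidney_expression = c(TRUE, TRUE, TRUE, TRUE),
    urorectal_phenotype_report = c(FALSE, FALSE, FALSE, FALSE),
    prior_disease_association = c(TRUE, FALSE, TRUE, TRUE),
    note = c("expressed in developing kidney at E15.5; CKD association",
             "strong expression in embryonic urethra at E15.5",
             "expressed in early embryonic kidney at E17.5",
             "expressed in embryonic metanephros at E12.5"),
    stringsAsFactors = FALSE
  )
  list(calls = calls, genes = genes, evidence = evidence)
}

#' Build a synthetic frequency database matching a truth set
#'
#' Emulates a DGV-style catalogue: every planted common polymorphism appears
#' as a record at its exact coordinates (common variation is, by
#' construction, catalogued), plus `n_background` random records scattered
#' over the genome. Planted ultra-rare events never enter the database.
#'
#' @param layout genome layout.
#' @param truth [plant_truth()] output.
#' @param config the matching [simulation_config()].
#' @param n_background random background records to add.
#' @return frequency-record data.frame (chrom/start/end/type/source_id).
#' @export
make_frequency_db <- function(layout, truth, config = simulation_config(),
                              n_background = 30L) {
  rng <- local_rng(config$seed, "freqdb")
  poly <- truth[truth$label == "common_polymorphism", , drop = FALSE]
  poly <- poly[!duplicated(paste(poly$chrom, poly$start, poly$end)), ,
               drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(poly))) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = poly$chrom[i], start = poly$start[i], end = poly$end[i],
      type = cn_to_type(poly$copy_number[i]),
      source_id = sprintf("synthdgv_poly_%d", i), stringsAsFactors = FALSE
    )
  }
  ur <- truth[truth$label == "ultra_rare", , drop = FALSE]
  chr_len <- stats::setNames(layout$chromosomes$length, layout$chromosomes$name)
  k <- 0L
  while (k < n_background) {
    chrom <- rng$sample(layout$chromosomes$name, 1L)
    len <- round(rng$runif(1, 2e4, 2e5))
    if (len >= chr_len[[chrom]]) next
    start <- floor(rng$runif(1, 1, chr_len[[chrom]] - len + 1))
    end <- start + len - 1
    # ultra-rare loci are by definition absent from the catalogue: background
    # records are sampled clear of them, otherwise a record could contain a
    # (slightly trimmed) call on a planted event and discard genuine signal
    ur_c <- ur[ur$chrom == chrom, , drop = FALSE]
    if (nrow(ur_c) && any(start <= ur_c$end & ur_c$start <= end)) next
    k <- k + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = start, end = end,
      type = rng$sample(c("DEL", "DUP", "BOTH"), 1L),
      source_id = sprintf("synthdgv_bg_%d", k), stringsAsFactors = FALSE
    )
  }
  db <- do.call(rbind, rows)
  db <- db[order(db$chrom, db$start, db$end, method = "radix"), , drop = FALSE]
  rownames(db) <- NULL
  db
}

#' Build a synthetic gene annotation matching a truth set
#'
#' Places one to three genes inside every planted ultra-rare event (so
#' genuine candidates survive the gene-content filter) and scatters
#' background genes across the genome. Biotypes are drawn mostly
#' protein-coding with a non-coding minority; symbols are synthetic.
#'
#' @param layout genome layout.
#' @param truth [plant_truth()] output.
#' @param config the matching [simulation_config()].
#' @param n_background background gene count.
#' @return gene-model data.frame.
#' @export
make_gene_annotation <- function(layout, truth, config = simulation_config(),
                                 n_background = 40L) {
  rng <- local_rng(config$seed, "genes")
  biotypes <- c("protein_coding", "lncRNA", "miRNA", "antisense",
                "other_noncoding")
  chr_len <- stats::setNames(layout$chromosomes$length, layout$chromosomes$name)
  rows <- list()
  gi <- 0L
  ur <- truth[truth$label == "ultra_rare", , drop = FALSE]
  ur <- ur[!duplicated(paste(ur$chrom, ur$start, ur$end)), , drop = FALSE]
  for (i in seq_len(nrow(ur))) {
    n_g <- 1L + rng$sample_int(3L, 1L) - 1L
    len_ev <- ur$end[i] - ur$start[i] + 1L
    for (j in seq_len(n_g)) {
      g_len <- max(500L, round(rng$runif(1, 0.05, 0.2) * len_ev))
      g_start <- ur$start[i] +
        floor(rng$runif(1, 0, max(1, len_ev - g_len)))
      gi <- gi + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        symbol = sprintf("SYNG%04d", gi), chrom = ur$chrom[i],
        start = as.integer(g_start),
        end = as.integer(min(g_start + g_len - 1L, ur$end[i])),
        strand = rng$sample(c("+", "-"), 1L),
        biotype = rng$sample(biotypes, 1L,
                             prob = c(0.6, 0.15, 0.05, 0.05, 0.15)),
        stringsAsFactors = FALSE
      )
    }
  }
  for (k in seq_len(n_background)) {
    chrom <- rng$sample(layout$chromosomes$name, 1L)
    g_len <- round(rng$runif(1, 2e3, 5e4))
    g_start <- floor(rng$runif(1, 1, chr_len[[chrom]] - g_len))
    gi <- gi + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      symbol = sprintf("SYNG%04d", gi), chrom = chrom,
      start = as.integer(g_start), end = as.integer(g_start + g_len - 1L),
      strand = rng$sample(c("+", "-"), 1L),
      biotype = rng$sample(biotypes, 1L,
                           prob = c(0.6, 0.15, 0.05, 0.05, 0.15)),
      stringsAsFactors = FALSE
    )
  }
  validate_genes(do.call(rbind, rows))
}
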