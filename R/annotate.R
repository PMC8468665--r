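#' Annotate CNVs with gene and promoter content
#'
#' For every gene overlapping a CNV, records the coverage class:
#' `full` (gene body contained in the CNV), `partial` (nonzero body overlap
#' without containment), or `promoter_only` (no body overlap, but the
#' `promoter_bp` window upstream of the transcription start site — strand
#' aware — overlaps the CNV). Genes are reported at most once per CNV, in
#' positional order.
#'
#' @param cnvs consensus data.frame (one or more rows).
#' @param genes gene models (see [read_genes()]).
#' @param promoter_bp promoter window upstream of the TSS, default 2,000 bp.
#' @return list of class `"annotated_cnvs"`: per CNV a list with `cnv` (the
#'   row), `gene_hits` (data.frame symbol/biotype/coverage), `biotype_counts`
#'   (gene-body hits per biotype, promoter-only counted separately as
#'   `promoter_only`), and `priority_score` (NA until [prioritize()]).
#' @export
annotate_cnvs <- function(cnvs, genes, promoter_bp = 2000L) {
  genes <- validate_genes(genes)
  out <- lapply(seq_len(nrow(cnvs)), function(i) {
    cnv <- cnvs[i, , drop = FALSE]
    g <- genes[genes$chrom == cnv$chrom, , drop = FALSE]
    hits <- NULL
    if (nrow(g)) {
      body_ov <- g$start <= cnv$end & cnv$start <= g$end
      full <- body_ov & cnv$start <= g$start & g$end <= cnv$end
      prom_start <- ifelse(g$strand == "+", g$start - promoter_bp, g$end + 1L)
      prom_end <- ifelse(g$strand == "+", g$start - 1L, g$end + promoter_bp)
      prom_ov <- !body_ov & prom_start <= cnv$end & cnv$start <= prom_end &
        prom_start <= prom_end
      coverage <- rep(NA_character_, nrow(g))
      coverage[body_ov] <- "partial"
      coverage[full] <- "full"
      coverage[prom_ov] <- "promoter_only"
      sel <- !is.na(coverage)
      hits <- data.frame(symbol = g$symbol[sel], biotype = g$biotype[sel],
                         coverage = coverage[sel], start = g$start[sel],
                         stringsAsFactors = FALSE)
      hits <- hits[order(hits$start), c("symbol", "biotype", "coverage"),
                   drop = FALSE]
      rownames(hits) <- NULL
    }
    if (is.null(hits)) {
      hits <- data.frame(symbol = character(0), biotype = character(0),
                         coverage = character(0), stringsAsFactors = FALSE)
    }
    list(cnv = cnv, gene_hits = hits,
         biotype_counts = count_biotypes_one(hits),
         priority_score = NA_integer_)
  })
  class(out) <- "annotated_cnvs"
  out
}

count_biotypes_one <- function(hits) {
  biotypes <- c("protein_coding", "lncRNA", "miRNA", "antisense",
                "other_noncoding")
  body <- hits[hits$coverage %in% c("full", "partial"), , drop = FALSE]
  counts <- table(factor(body$biotype, levels = biotypes))
  out <- as.integer(counts)
  names(out) <- biotypes
  c(out, promoter_only = sum(hits$coverage == "promoter_only"))
}

#' Count annotated genes per biotype
#'
#' Gene-body hits (full or partial coverage) are counted per biotype;
#' promoter-only hits are tallied separately under `promoter_only`. Given a
#' list, counts are summed across CNVs.
#'
#' @param annotated an `annotated_cnvs` list or one of its elements.
#' @return named integer vector of counts.
#' @export
count_biotypes <- function(annotated) {
  if (!is.null(annotated$gene_hits)) {
    return(annotated$biotype_counts)
  }
  Reduce(`+`, lapply(annotated, `[[`, "biotype_counts"))
}

#' Keep only CNVs that touch a gene or promoter
#'
#' Implements the gene-content requirement: a CNV survives when it has at
#' least one gene hit of any coverage class (promoter-only counts). A CNV in
#' a gene desert is removed.
#'
#' @param annotated an `annotated_cnvs` list.
#' @return list `(annotated, trace)`.
#' @export
gene_content_filter <- function(annotated) {
  keep <- vapply(annotated, function(a) nrow(a$gene_hits) > 0L, logical(1))
  keys <- vapply(annotated, function(a) consensus_key(a$cnv), character(1))
  kept <- annotated[keep]
  class(kept) <- "annotated_cnvs"
  list(annotated = kept,
       trace = new_trace(keys, "gene_content", keep,
                         ifelse(keep, "has_gene_or_promoter", "gene_desert")))
}

#' Default evidence weights for prioritization
#'
#' Embryonic lower-urinary-tract expression is the strongest signal for a
#' bladder-outflow phenotype and weighs double; embryonic kidney expression,
#' a reported urorectal phenotype, and a prior disease association each add
#' one.
#'
#' @return named numeric vector of weights.
#' @export
evidence_weights <- function() {
  c(embryonic_lower_urinary_tract_expression = 2,
    embryonic_kidney_expression = 1,
    urorectal_phenotype_report = 1,
    prior_disease_association = 1)
}

#' Rank annotated CNVs by gene-evidence score
#'
#' Each gene's score is the weighted sum of its evidence flags; a CNV scores
#' the maximum over its genes (any coverage class). The result is a stable
#' descending sort by (priority_score, length), ties broken by genomic
#' position. Evidence rows whose symbol matches no annotated gene are ignored
#' with a warning.
#'
#' @param annotated an `annotated_cnvs` list.
#' @param evidence evidence table from [read_evidence()] (may be empty/NULL).
#' @param weights named weights, default [evidence_weights()].
#' @return data.frame: one row per CNV with sample_id, chrom, start, end,
#'   type, length, n_genes, top_gene, priority_score, genes
#'   (comma-separated symbols).
#' @export
prioritize <- function(annotated, evidence = NULL,
                       weights = evidence_weights()) {
  flags <- names(evidence_weights())
  gene_score <- function(sym) {
    if (is.null(evidence) || !nrow(evidence)) return(0)
    row <- evidence[evidence$symbol == sym, , drop = FALSE]
    if (!nrow(row)) return(0)
    sum(vapply(flags, function(f) {
      if (isTRUE(row[[f]][1])) weights[[f]] else 0
    }, numeric(1)))
  }
  if (!is.null(evidence) && nrow(evidence)) {
    all_syms <- unique(unlist(lapply(annotated, function(a) a$gene_hits$symbol)))
    unknown <- setdiff(evidence$symbol, all_syms)
    if (length(unknown)) {
      warning("evidence symbols not in annotation, ignored: ",
              paste(unknown, collapse = ", "))
    }
  }
  rows <- lapply(annotated, function(a) {
    scores <- vapply(a$gene_hits$symbol, gene_score, numeric(1))
    best <- if (length(scores)) max(scores) else 0
    top <- if (length(scores) && best > 0) {
      a$gene_hits$symbol[which.max(scores)]
    } else NA_character_
    data.frame(
      sample_id = a$cnv$sample_id, chrom = a$cnv$chrom,
      start = a$cnv$start, end = a$cnv$end, type = a$cnv$type,
      length = a$cnv$end - a$cnv$start + 1L,
      n_genes = nrow(a$gene_hits), top_gene = top,
      priority_score = best,
      genes = paste(a$gene_hits$symbol, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      type = character(0), length = integer(0),
                      n_genes = integer(0), top_gene = character(0),
                      priority_score = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE)
  }
  o <- order(-out$priority_score, -out$length, out$chrom, out$start,
             method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
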