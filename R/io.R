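#' An empty CNV call set
#'
#' The package-wide tabular form of a call set: one row per called segment.
#' Coordinates are 1-based inclusive; chromosome names carry no "chr" prefix;
#' `type` is DEL for copy number < 2 and DUP for > 2; `confidence` is the
#' log10 Bayes factor of the call against the diploid hypothesis.
#'
#' @param cohort optional cohort tag ("case" or "control") stored as an
#'   attribute.
#' @return zero-row data.frame with the canonical call-set columns.
#' @export
empty_callset <- function(cohort = NULL) {
  df <- data.frame(
    sample_id = character(0), caller_id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), type = character(0),
    copy_number = integer(0), n_probes = integer(0), confidence = numeric(0),
    stringsAsFactors = FALSE
  )
  if (!is.null(cohort)) attr(df, "cohort") <- cohort
  df
}

.callset_cols <- c("sample_id", "caller_id", "chrom", "start", "end", "type",
                   "copy_number", "n_probes", "confidence")

cn_to_type <- function(cn) ifelse(cn < 2L, "DEL", "DUP")

sort_calls <- function(calls) {
  if (!nrow(calls)) return(calls)
  o <- order(calls$sample_id, calls$caller_id, calls$chrom, calls$start,
             calls$end, method = "radix")
  out <- calls[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

call_key <- function(calls) {
  if (!nrow(calls)) return(character(0))
  paste(calls$sample_id, calls$caller_id, calls$chrom, calls$start, calls$end,
        calls$type, sep = "|")
}

#' Validate a call-set data.frame
#'
#' Checks the structural invariants of a call set and fails loudly instead of
#' repairing: required columns present, start <= end, type consistent with
#' copy number, n_probes >= 1, no duplicate records.
#'
#' @param calls candidate data.frame.
#' @param where label used in error messages (e.g. a file path).
#' @return the validated data.frame, invisibly.
#' @export
validate_callset <- function(calls, where = "callset") {
  err <- function(line, msg) {
    stop("validation error in ", where,
         if (!is.na(line)) paste0(" (record ", line, ")"), ": ", msg,
         call. = FALSE)
  }
  missing_cols <- setdiff(.callset_cols, names(calls))
  if (length(missing_cols)) {
    err(NA, paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(calls)) return(invisible(calls))
  bad <- which(calls$start > calls$end)
  if (length(bad)) err(bad[1], "start > end")
  bad <- which(!calls$type %in% c("DEL", "DUP"))
  if (length(bad)) err(bad[1], paste("unknown type token:", calls$type[bad[1]]))
  bad <- which(cn_to_type(calls$copy_number) != calls$type)
  if (length(bad)) {
    err(bad[1], sprintf("type %s inconsistent with copy_number %d",
                        calls$type[bad[1]], calls$copy_number[bad[1]]))
  }
  bad <- which(calls$n_probes < 1L)
  if (length(bad)) err(bad[1], "n_probes < 1")
  dup <- which(duplicated(call_key(calls)))
  if (length(dup)) err(dup[1], "duplicate record")
  invisible(calls)
}

.native_header <- "#cnvsieve callset v1"

#' Read a CNV call set
#'
#' Two dialects: `native_tsv` (the package's own versioned TSV, written by
#' [write_callset()]) and `penncnv_rawcnv` (the whitespace-delimited
#' `.rawcnv` line format of PennCNV, e.g.
#' `chr1:100001-200000 numsnp=25 length=100,000 state5,cn=3 sampleA
#' startsnp=rs1 endsnp=rs2`). Leading "chr" prefixes are stripped; all
#' invariant violations are rejected with the offending line number.
#'
#' @param path file to read.
#' @param dialect `"native_tsv"` or `"penncnv_rawcnv"`.
#' @param caller_id caller tag assigned to rawcnv calls (the format carries
#'   none); default `"penncnv"`.
#' @return a validated, sorted call-set data.frame.
#' @export
read_callset <- function(path, dialect = c("native_tsv", "penncnv_rawcnv"),
                         caller_id = "penncnv") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "native_tsv") {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    if (!length(body)) return(empty_callset())
    df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                            colClasses = c(sample_id = "character",
                                           caller_id = "character",
                                           chrom = "character"),
                            stringsAsFactors = FALSE)
    extra <- setdiff(names(df), .callset_cols)
    df <- df[, c(.callset_cols, extra), drop = FALSE]
    df$chrom <- sub("^chr", "", df$chrom)
    validate_callset(df, where = path)
    sort_calls(df)
  } else {
    read_rawcnv(path, caller_id)
  }
}

read_rawcnv <- function(path, caller_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    err <- function(msg) stop("validation error in ", path, " (line ", i,
                              "): ", msg, call. = FALSE)
    if (length(tok) < 5L) err("too few fields for a rawcnv record")
    m <- regmatches(tok[1],
                    regexec("^(chr)?([^:]+):([0-9]+)-([0-9]+)$", tok[1]))[[1]]
    if (!length(m)) err(paste("cannot parse region:", tok[1]))
    chrom <- m[3]; start <- as.integer(m[4]); end <- as.integer(m[5])
    if (start > end) err("start > end")
    grab <- function(prefix) {
      hit <- grep(paste0("^", prefix, "="), tok, value = TRUE)
      if (!length(hit)) return(NA_character_)
      sub(paste0("^", prefix, "="), "", hit[1])
    }
    numsnp <- suppressWarnings(as.integer(grab("numsnp")))
    if (is.na(numsnp)) err("missing numsnp= field")
    state_tok <- grep("^state[0-9]+,cn=[0-9]+$", tok, value = TRUE)
    if (!length(state_tok)) err("missing stateN,cn= field")
    cn <- as.integer(sub("^state[0-9]+,cn=", "", state_tok[1]))
    conf <- suppressWarnings(as.numeric(grab("conf")))
    keyval <- grepl("=", tok, fixed = TRUE) | grepl(":", tok, fixed = TRUE)
    sample_tok <- tok[!keyval]
    sid <- if (length(sample_tok)) sample_tok[1] else err("missing sample field")
    rows[[i]] <- data.frame(
      sample_id = sid, caller_id = caller_id, chrom = chrom,
      start = start, end = end, type = cn_to_type(cn),
      copy_number = cn, n_probes = numsnp,
      confidence = if (is.na(conf)) NA_real_ else conf,
      stringsAsFactors = FALSE
    )
  }
  df <- if (length(rows)) do.call(rbind, rows) else empty_callset()
  validate_callset(df, where = path)
  sort_calls(df)
}

#' Write a CNV call set as native TSV
#'
#' Versioned header line, fixed column order, confidence printed with
#' `%.10g` so a write/read/write cycle is byte-identical. Extra columns
#' beyond the canonical nine are preserved.
#'
#' @param calls call-set data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_callset <- function(calls, path) {
  validate_callset(calls)
  calls <- sort_calls(calls)
  extra <- setdiff(names(calls), .callset_cols)
  calls <- calls[, c(.callset_cols, extra), drop = FALSE]
  fmt <- calls
  fmt$confidence <- ifelse(is.na(calls$confidence), "NA",
                           sprintf("%.10g", calls$confidence))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.native_header, con)
  utils::write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention: `(start - 1, end)`. The name column is
#' `sample|caller|type` for call sets, stable-sorted by (chrom, start). An
#' empty input yields a file holding only the header comment.
#'
#' @param calls call set (or any data.frame with chrom/start/end, plus
#'   optional sample_id/caller_id/type for the name column).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED (0-based half-open) export", con)
  if (nrow(calls)) {
    nm <- if (all(c("sample_id", "caller_id", "type") %in% names(calls))) {
      paste(calls$sample_id, calls$caller_id, calls$type, sep = "|")
    } else rep(".", nrow(calls))
    df <- data.frame(chrom = calls$chrom, start = calls$start - 1L,
                     end = calls$end, name = nm, stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path BED file (0-based half-open); comment lines ignored.
#' @return data.frame with 1-based inclusive chrom/start/end/name.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(text = lines, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         "character"),
                          col.names = c("chrom", "start", "end", "name"),
                          stringsAsFactors = FALSE)
  df$chrom <- sub("^chr", "", df$chrom)
  df$start <- df$start + 1L
  df
}

#' Read a CNV frequency database (DGV-style TSV)
#'
#' Expects a TSV with header columns chrom/start/end/type/source_id.
#' Type tokens are normalized: loss or deletion to DEL, gain or duplication
#' to DUP, gain+loss to BOTH (BOTH matches either case type in
#' [frequency_filter()]). Overlapping records are kept as-is, never merged.
#'
#' @param path TSV file.
#' @return sorted data.frame of frequency records.
#' @export
read_frequency_db <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character",
                                         type = "character",
                                         source_id = "character"),
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "type", "source_id")
  if (!all(need %in% names(df))) {
    stop("validation error in ", path, ": columns must be ",
         paste(need, collapse = "/"), call. = FALSE)
  }
  df$chrom <- sub("^chr", "", df$chrom)
  df$type <- normalize_cnv_type(df$type, where = path)
  bad <- which(df$start > df$end)
  if (length(bad)) {
    stop("validation error in ", path, " (row ", bad[1], "): start > end",
         call. = FALSE)
  }
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

normalize_cnv_type <- function(x, where = "input") {
  out <- character(length(x))
  low <- tolower(x)
  out[low %in% c("del", "loss", "deletion")] <- "DEL"
  out[low %in% c("dup", "gain", "duplication")] <- "DUP"
  out[low %in% c("both", "gain+loss", "loss+gain", "complex")] <- "BOTH"
  bad <- which(out == "")
  if (length(bad)) {
    stop("validation error in ", where, " (row ", bad[1],
         "): unknown type token: ", x[bad[1]], call. = FALSE)
  }
  out
}

#' Read a gene annotation
#'
#' Native format: TSV with columns symbol/chrom/start/end/strand/biotype
#' (1-based inclusive). GFF3 is read through `rtracklayer`, taking the gene
#' symbol from the `Name` (falling back to `gene_name`/`ID`) attribute and
#' the biotype from `biotype`/`gene_biotype`/`gene_type`.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"gff3"`; guessed from the extension by default.
#' @return data.frame of gene models, validated (unique symbols, start <= end,
#'   known biotypes).
#' @export
read_genes <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c(symbol = "character",
                                           chrom = "character",
                                           strand = "character",
                                           biotype = "character"),
                            stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    }
    gr <- rtracklayer::import(path)
    gr <- gr[as.character(gr$type) %in% c("gene", "ncRNA_gene", "miRNA_gene")]
    mc <- S4Vectors::mcols(gr)
    pick <- function(cands) {
      for (c0 in cands) if (c0 %in% names(mc)) return(as.character(mc[[c0]]))
      rep(NA_character_, length(gr))
    }
    df <- data.frame(
      symbol = pick(c("Name", "gene_name", "ID")),
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      biotype = pick(c("biotype", "gene_biotype", "gene_type")),
      stringsAsFactors = FALSE
    )
  }
  validate_genes(df, where = path)
}

validate_genes <- function(df, where = "gene annotation") {
  need <- c("symbol", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(df))) {
    stop("validation error in ", where, ": columns must include ",
         paste(need, collapse = "/"), call. = FALSE)
  }
  df$chrom <- sub("^chr", "", df$chrom)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  known <- c("protein_coding", "lncRNA", "miRNA", "antisense", "other_noncoding")
  df$biotype[!df$biotype %in% known] <- "other_noncoding"
  if (any(df$start > df$end)) {
    stop("validation error in ", where, ": gene with start > end", call. = FALSE)
  }
  if (anyDuplicated(df$symbol)) {
    stop("validation error in ", where, ": duplicate gene symbol", call. = FALSE)
  }
  df <- df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a gene annotation as the native TSV
#' @param genes gene-model data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-evidence table
#'
#' TSV with columns symbol, four 0/1 flags
#' (`embryonic_lower_urinary_tract_expression`, `embryonic_kidney_expression`,
#' `urorectal_phenotype_report`, `prior_disease_association`) and a free-text
#' `note`.
#'
#' @param path TSV file.
#' @return data.frame with logical flag columns.
#' @export
read_evidence <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(symbol = "character"),
                          stringsAsFactors = FALSE)
  flags <- c("embryonic_lower_urinary_tract_expression",
             "embryonic_kidney_expression", "urorectal_phenotype_report",
             "prior_disease_association")
  if (!all(c("symbol", flags) %in% names(df))) {
    stop("validation error in ", path, ": evidence table needs symbol + ",
         "the four flag columns", call. = FALSE)
  }
  for (f in flags) df[[f]] <- as.logical(as.integer(df[[f]]))
  if (!"note" %in% names(df)) df$note <- ""
  df
}

#' Write an intensity cohort as long-format TSV
#'
#' One row per (sample, probe): sample_id, chrom, pos, lrr, baf.
#' @param cohort an `intensity_cohort`.
#' @param layout the matching genome layout.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intensities <- function(cohort, layout, path) {
  rows <- lapply(cohort, function(s) {
    do.call(rbind, lapply(names(layout$probes), function(chrom) {
      data.frame(sample_id = s$sample_id, chrom = chrom,
                 pos = layout$probes[[chrom]],
                 lrr = s$lrr[[chrom]], baf = s$baf[[chrom]],
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
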