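# Universe file IO. All TSVs carry a header comment stating the coordinate
# convention; FASTA via Biostrings; bedGraph via rtracklayer.

.write_tsv <- function(df, path, comment = "# coordinates: 0-based half-open") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a synthetic universe to a directory
#'
#' Emits genes.tsv, transcripts.bed (BED12-like), constraints.tsv,
#' promoters.fasta, conservation.bedGraph, expression.tsv, samples.tsv,
#' paralogues.tsv, variants.tsv, domains.tsv, db_membership.tsv,
#' xci_calls.tsv, chrom_info.tsv and truth.json. All coordinates are 0-based
#' half-open; FASTA records are keyed by gene symbol.
#'
#' @param universe List from [generate_universe()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  .write_tsv(universe$genes, p("genes.tsv"))
  tx <- universe$transcripts
  bed <- data.frame(
    chrom = tx$chromosome, chromStart = tx$tx_start, chromEnd = tx$tx_end,
    name = tx$transcript_id, score = 0, strand = tx$strand,
    thickStart = tx$tx_start, thickEnd = tx$tx_end, itemRgb = "0",
    blockCount = vapply(strsplit(tx$cds_starts, ","), length, integer(1)),
    blockSizes = mapply(function(s, e) paste(
      as.numeric(strsplit(e, ",")[[1]]) - as.numeric(strsplit(s, ",")[[1]]),
      collapse = ","), tx$cds_starts, tx$cds_ends, USE.NAMES = FALSE),
    blockStarts = mapply(function(s, st) paste(
      as.numeric(strsplit(s, ",")[[1]]) - st, collapse = ","),
      tx$cds_starts, tx$tx_start, USE.NAMES = FALSE),
    symbol = tx$symbol, mane_select = tx$mane_select, appris = tx$appris,
    length = tx$length, stringsAsFactors = FALSE)
  .write_tsv(bed, p("transcripts.bed"))
  .write_tsv(universe$constraints, p("constraints.tsv"),
             "# per-transcript constraint metrics")
  if (length(universe$promoters)) {
    seqs <- Biostrings::DNAStringSet(universe$promoters)
    Biostrings::writeXStringSet(seqs, p("promoters.fasta"))
  } else file.create(p("promoters.fasta"))
  cons <- universe$conservation
  if (nrow(cons)) {
    gr <- GenomicRanges::GRanges(cons$chrom,
                                 IRanges::IRanges(cons$start + 1, cons$end),
                                 score = cons$score)
    rtracklayer::export(gr, p("conservation.bedGraph"), format = "bedGraph")
  } else file.create(p("conservation.bedGraph"))
  expr <- as.data.frame(universe$expression)
  expr <- cbind(symbol = rownames(universe$expression), expr)
  .write_tsv(expr, p("expression.tsv"), "# TPM, genes x samples")
  .write_tsv(universe$samples, p("samples.tsv"), "# sample metadata")
  .write_tsv(universe$paralogues, p("paralogues.tsv"),
             "# percent identities in [0,100]")
  .write_tsv(universe$variants, p("variants.tsv"),
             "# deleteriousness scores are scaled PHRED-like")
  .write_tsv(universe$domains, p("domains.tsv"), "# amino-acid counts")
  .write_tsv(universe$db_membership, p("db_membership.tsv"),
             "# long format: one row per gene x database")
  .write_tsv(universe$xci_calls, p("xci_calls.tsv"), "# per-study XCI calls")
  .write_tsv(universe$chrom_info, p("chrom_info.tsv"))
  jsonlite::write_json(list(genes = universe$truth$genes,
                            seed = universe$truth$seed),
                       p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list.files(dir, full.names = TRUE))
}

#' Read a universe directory written by [write_universe()]
#' @param dir Directory path.
#' @return Universe list in the in-memory layout of [generate_universe()].
#' @export
read_universe <- function(dir) {
  p <- function(f) file.path(dir, f)
  bed <- .read_tsv(p("transcripts.bed"))
  abs_starts <- mapply(function(bs, st) paste(
    as.numeric(strsplit(as.character(bs), ",")[[1]]) + st, collapse = ","),
    bed$blockStarts, bed$chromStart, USE.NAMES = FALSE)
  abs_ends <- mapply(function(bs, sz, st) paste(
    as.numeric(strsplit(as.character(bs), ",")[[1]]) + st +
      as.numeric(strsplit(as.character(sz), ",")[[1]]), collapse = ","),
    bed$blockStarts, bed$blockSizes, bed$chromStart, USE.NAMES = FALSE)
  transcripts <- data.frame(
    transcript_id = bed$name, symbol = bed$symbol, chromosome = bed$chrom,
    strand = bed$strand, tx_start = bed$chromStart, tx_end = bed$chromEnd,
    mane_select = bed$mane_select, appris = bed$appris, length = bed$length,
    cds_starts = abs_starts, cds_ends = abs_ends, stringsAsFactors = FALSE)
  promoters <- character(0)
  if (file.size(p("promoters.fasta")) > 0) {
    ss <- Biostrings::readDNAStringSet(p("promoters.fasta"))
    promoters <- stats::setNames(as.character(ss), names(ss))
  }
  conservation <- data.frame(chrom = character(0), start = numeric(0),
                             end = numeric(0), score = numeric(0))
  if (file.size(p("conservation.bedGraph")) > 0) {
    gr <- rtracklayer::import(p("conservation.bedGraph"), format = "bedGraph")
    conservation <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1, end = GenomicRanges::end(gr),
      score = gr$score, stringsAsFactors = FALSE)
  }
  exprdf <- .read_tsv(p("expression.tsv"))
  expression <- as.matrix(exprdf[, -1, drop = FALSE])
  rownames(expression) <- exprdf$symbol
  genes <- .read_tsv(p("genes.tsv"))
  genes$synopsis[is.na(genes$synopsis)] <- ""
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  list(genes = genes, transcripts = transcripts,
       constraints = .read_tsv(p("constraints.tsv")), promoters = promoters,
       conservation = conservation, expression = expression,
       samples = .read_tsv(p("samples.tsv")),
       paralogues = .read_tsv(p("paralogues.tsv")),
       variants = .read_tsv(p("variants.tsv")),
       domains = .read_tsv(p("domains.tsv")),
       db_membership = .read_tsv(p("db_membership.tsv")),
       xci_calls = .read_tsv(p("xci_calls.tsv")),
       chrom_info = .read_tsv(p("chrom_info.tsv")), truth = truth)
}
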