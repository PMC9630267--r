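#' Default phenotype term lists
#'
#' Seed term lists for free-text matching of neurologic clinical-synopsis
#' features. Each element is a character vector of case-insensitive phrases;
#' matching is plain substring search with no negation handling. The lists can
#' be replaced by a YAML file via [read_phenotype_terms()].
#'
#' @return Named list of character vectors, one per phenotype flag.
#' @export
default_phenotype_terms <- function() {
  list(
    intellectual_disability = c("intellectual disability",
                                "mental retardation",
                                "cognitive impairment",
                                "global developmental delay"),
    seizures = c("seizures", "epilepsy", "epileptic encephalopathy",
                 "infantile spasms"),
    language = c("impaired language development", "language delay",
                 "absent speech", "speech delay"),
    motor = c("impaired motor development", "motor delay",
              "delayed walking"),
    spasticity = c("spasticity", "spastic paraplegia", "spastic tetraplegia"),
    ataxia = c("ataxia", "gait ataxia", "cerebellar atrophy")
  )
}

#' Read phenotype term lists from a YAML file
#'
#' A template matching the defaults ships at
#' `system.file("extdata", "phenotype_terms.yaml", package = "xpredict")`.
#'
#' @param path Path to a YAML file mapping flag names to phrase lists.
#' @return Named list of character vectors.
#' @export
read_phenotype_terms <- function(path) {
  lst <- yaml::read_yaml(path)
  lapply(lst, as.character)
}

#' Match phenotype terms in a clinical-synopsis neurologic section
#'
#' Flags a phenotype if any of its phrases occurs case-insensitively as a
#' substring of the text. `neurologic_any` is true iff the neurologic section
#' is non-empty. Substring matching has no negation handling ("no seizures
#' reported" still sets the seizures flag); this is a documented limitation of
#' free-text synopsis mining.
#'
#' @param synopsis_text Free text of the neurologic section ("" if absent).
#' @param term_lists Named list of phrase vectors
#'   (default [default_phenotype_terms()]).
#' @return Named logical vector: `neurologic_any` plus one flag per term list.
#' @export
match_phenotype_terms <- function(synopsis_text,
                                  term_lists = default_phenotype_terms()) {
  stopifnot(length(synopsis_text) == 1)
  if (any(!vapply(term_lists, length, integer(1))))
    stop("input error: empty term list")
  txt <- tolower(synopsis_text)
  flags <- vapply(term_lists, function(phrases) {
    any(vapply(tolower(phrases), function(p) grepl(p, txt, fixed = TRUE),
               logical(1)))
  }, logical(1))
  c(neurologic_any = nchar(trimws(synopsis_text)) > 0, flags)
}

#' Select the canonical transcript of a gene
#'
#' Priority: (i) the MANE Select transcript if one exists; (ii) the longest
#' APPRIS-annotated transcript; (iii) the only transcript if exactly one
#' exists. Equal-length APPRIS ties break lexicographically on transcript id,
#' so the choice is invariant to input order.
#'
#' @param transcripts data.frame with columns `transcript_id`, `symbol`,
#'   `mane_select`, `appris`, `length` (one gene only).
#' @return The selected row of `transcripts`.
#' @export
select_canonical_transcript <- function(transcripts) {
  stopifnot(nrow(transcripts) >= 1)
  if (length(unique(transcripts$symbol)) != 1)
    stop("input error: transcripts from more than one gene")
  mane <- transcripts[transcripts$mane_select, , drop = FALSE]
  if (nrow(mane) >= 1) {
    mane <- mane[order(-mane$length, mane$transcript_id), , drop = FALSE]
    return(mane[1, , drop = FALSE])
  }
  app <- transcripts[transcripts$appris, , drop = FALSE]
  if (nrow(app) >= 1) {
    app <- app[order(-app$length, app$transcript_id), , drop = FALSE]
    return(app[1, , drop = FALSE])
  }
  if (nrow(transcripts) == 1) return(transcripts)
  stop("selection error: no MANE or APPRIS transcript for gene ",
       transcripts$symbol[1])
}

#' Flag genes with close paralogues
#'
#' Computes the given percentile (default 95th, linear interpolation between
#' order statistics) of target and query percent identity over all hits
#' separately; a gene is flagged iff it has at least one hit with both metrics
#' strictly above their thresholds.
#'
#' @param hits data.frame with columns `query`, `target_pct`, `query_pct`.
#' @param percentile Percentile in (0, 100).
#' @param genes Optional character vector of gene symbols to report on
#'   (defaults to the queries present in `hits`).
#' @return Named logical vector over `genes`.
#' @export
flag_close_paralogues <- function(hits, percentile = 95, genes = NULL) {
  if (percentile <= 0 || percentile >= 100)
    stop("input error: percentile must be in (0, 100)")
  if (is.null(genes)) genes <- unique(hits$query)
  out <- stats::setNames(rep(FALSE, length(genes)), genes)
  if (is.null(hits) || nrow(hits) == 0) return(out)
  thr_t <- stats::quantile(hits$target_pct, percentile / 100, type = 7,
                           names = FALSE)
  thr_q <- stats::quantile(hits$query_pct, percentile / 100, type = 7,
                           names = FALSE)
  close <- hits$target_pct > thr_t & hits$query_pct > thr_q
  flagged <- unique(hits$query[close])
  out[names(out) %in% flagged] <- TRUE
  out
}

#' Consensus X-inactivation category across studies
#'
#' Seven categories from per-study calls in `{escape, non_escape, variable}`:
#' fewer than `min_studies` calls gives `not_available`; a modal "variable"
#' call gives `variable`; equal escape and non-escape counts give
#' `discordant`; otherwise the majority side is `high_conf_*` when all or
#' all-but-one studies agree, `low_conf_*` when only a strict plurality does.
#'
#' @param calls Character vector of study calls for one gene.
#' @param min_studies Minimum number of reporting studies (default 2).
#' @return One of `high_conf_escape`, `high_conf_non_escape`,
#'   `low_conf_escape`, `low_conf_non_escape`, `variable`, `discordant`,
#'   `not_available`.
#' @export
consensus_xci <- function(calls, min_studies = 2) {
  valid <- c("escape", "non_escape", "variable")
  if (length(calls) && !all(calls %in% valid))
    stop("input error: unknown XCI call label: ",
         paste(setdiff(calls, valid), collapse = ", "))
  total <- length(calls)
  if (total < min_studies) return("not_available")
  e <- sum(calls == "escape"); ne <- sum(calls == "non_escape")
  v <- sum(calls == "variable")
  if (v > max(e, ne)) return("variable")
  if (e == ne) return("discordant")
  side <- if (e > ne) "escape" else "non_escape"
  winner <- max(e, ne)
  conf <- if (winner >= total - 1) "high_conf" else "low_conf"
  paste(conf, side, sep = "_")
}

#' Pre-classify genes into the 10 training subgroups
#'
#' Crosses disorder class `{C, PMT, ND}` with brain association
#' `{b, nb}` (not applicable to no-disorder genes) and LoF-homozygote
#' tolerance `{i, t}`, yielding the 10 labels
#' `Cbi, Cbt, Cnbi, Cnbt, PMTbi, PMTbt, PMTnbi, PMTnbt, NDi, NDt`.
#' Training positives are `Cbi` (confirmed brain-disorder, LoF-intolerant);
#' negatives are `NDt` (no-disorder, LoF-tolerant / dispensable).
#'
#' @param genes data.frame with columns `symbol`, `disorder_class`
#'   (`confirmed`/`PMT`/`no_disorder`), `brain_flag` (logical, `NA` for
#'   no-disorder genes) and `lof_tolerant` (logical).
#' @return Named character vector of subgroup labels keyed by symbol.
#' @export
preclassify <- function(genes) {
  cls <- c(confirmed = "C", PMT = "PMT", no_disorder = "ND")[
    genes$disorder_class]
  if (any(is.na(cls)))
    stop("validation error: unknown disorder_class")
  nd <- genes$disorder_class == "no_disorder"
  if (any(!is.na(genes$brain_flag[nd])))
    stop("validation error: brain_flag set on a no_disorder gene: ",
         paste(genes$symbol[nd & !is.na(genes$brain_flag)], collapse = ", "))
  if (any(is.na(genes$brain_flag[!nd])))
    stop("validation error: brain_flag missing on a disorder/PMT gene")
  brain <- ifelse(nd, "", ifelse(genes$brain_flag, "b", "nb"))
  lof <- ifelse(genes$lof_tolerant, "t", "i")
  stats::setNames(paste0(cls, brain, lof), genes$symbol)
}

#' Annotate a gene universe
#'
#' Runs the annotation stage on raw universe tables: phenotype-term matching
#' on the synopsis text, canonical transcript selection, close-paralogue
#' flagging, XCI consensus and the 10-subgroup pre-classification.
#'
#' @param universe List as returned by [generate_universe()] (or
#'   [read_universe()]).
#' @param term_lists Phenotype term lists.
#' @param paralogue_percentile Percentile for [flag_close_paralogues()].
#' @return data.frame of annotated genes (one row per gene) with phenotype
#'   flags, `brain_flag`, `canonical_transcript`, `close_paralogue`,
#'   `xci_consensus` and `subgroup`.
#' @export
annotate_genes <- function(universe,
                           term_lists = default_phenotype_terms(),
                           paralogue_percentile = 95) {
  g <- universe$genes
  if (nrow(g) == 0) {
    g$brain_flag <- logical(0); g$subgroup <- character(0)
    return(g)
  }
  flag_names <- c("neurologic_any", names(term_lists))
  flags <- t(vapply(g$synopsis, match_phenotype_terms,
                    FUN.VALUE = logical(length(flag_names)),
                    term_lists = term_lists, USE.NAMES = FALSE))
  colnames(flags) <- flag_names
  flags[!g$cs_available, ] <- FALSE
  out <- cbind(g[setdiff(names(g), "synopsis")], as.data.frame(flags))
  out$brain_flag <- ifelse(g$disorder_class == "no_disorder", NA,
                           out$neurologic_any)
  canon <- vapply(split(universe$transcripts, universe$transcripts$symbol),
                  function(tx) select_canonical_transcript(tx)$transcript_id,
                  character(1))
  out$canonical_transcript <- canon[out$symbol]
  cp <- flag_close_paralogues(universe$paralogues, paralogue_percentile,
                              genes = out$symbol)
  out$close_paralogue <- unname(cp[out$symbol])
  xci <- vapply(split(universe$xci_calls$call, universe$xci_calls$gene),
                consensus_xci, character(1))
  out$xci_consensus <- ifelse(out$chromosome == "chrX",
                              unname(xci[out$symbol]), NA)
  out$xci_consensus[out$chromosome == "chrX" &
                      is.na(out$xci_consensus)] <- "not_available"
  out$subgroup <- unname(preclassify(out))
  rownames(out) <- NULL
  out
}
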