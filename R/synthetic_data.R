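#' Default per-feature generative effects
#'
#' One entry per feature of [feature_schema()], giving the distribution family
#' and per-class parameters used to plant class structure in synthetic data.
#' Families: `"beta"` (params mean, concentration, scale — bounded scores),
#' `"normal"` (mean, sd — Z-scores), `"lognormal"` (meanlog, sdlog — expression
#' levels, lengths), `"poisson"` (lambda — counts). Defaults encode the
#' qualitative contrasts seen between confirmed disorder genes and dispensable
#' genes: lower LOEUF, higher misZ, higher exon/promoter conservation, broader
#' expression (lower tau), longer CDS, fewer close paralogues.
#'
#' @return Named list keyed by feature name; each element has `family` and
#'   `params` (a list with elements `confirmed`, `PMT`, `no_disorder`).
#' @export
default_feature_effects <- function() {
  fx <- function(family, confirmed, PMT, no_disorder) {
    list(family = family,
         params = list(confirmed = confirmed, PMT = PMT,
                       no_disorder = no_disorder))
  }
  same <- function(family, p) fx(family, p, p, p)
  eff <- list(
    loeuf          = fx("beta", c(.16, 6, 2), c(.28, 6, 2), c(.45, 6, 2)),
    mis_z          = fx("normal", c(2.2, 1), c(1.2, 1), c(.3, 1)),
    syn_z          = same("normal", c(0, 1)),
    lof_z          = fx("normal", c(4, 1.5), c(2.5, 1.5), c(1, 1.5)),
    pli            = fx("beta", c(.75, 1.2, 1), c(.5, 1.2, 1), c(.3, 1.2, 1)),
    pnull          = fx("beta", c(.12, 2, 1), c(.3, 2, 1), c(.5, 2, 1)),
    prec           = same("beta", c(.5, 2, 1)),
    max_af         = fx("beta", c(.001, 1, 1), c(.003, 1, 1), c(.006, 1, 1)),
    classic_caf    = fx("beta", c(.002, 1, 1), c(.005, 1, 1), c(.008, 1, 1)),
    oe_lof         = fx("beta", c(.125, 6, 2), c(.225, 6, 2), c(.375, 6, 2)),
    oe_lof_lower   = fx("beta", c(.07, 6, 2), c(.14, 6, 2), c(.25, 6, 2)),
    oe_mis         = fx("beta", c(.3, 8, 2), c(.38, 8, 2), c(.45, 8, 2)),
    oe_mis_lower   = fx("beta", c(.24, 8, 2), c(.3, 8, 2), c(.38, 8, 2)),
    oe_mis_upper   = fx("beta", c(.36, 8, 2), c(.45, 8, 2), c(.52, 8, 2)),
    oe_mis_pphen   = fx("beta", c(.22, 8, 2), c(.32, 8, 2), c(.42, 8, 2)),
    oe_syn         = same("beta", c(.5, 10, 2)),
    oe_syn_lower   = same("beta", c(.42, 10, 2)),
    oe_syn_upper   = same("beta", c(.58, 10, 2)),
    obs_lof        = fx("poisson", 8, 15, 25),
    exp_lof        = same("lognormal", c(3.3, .5)),
    obs_mis        = fx("poisson", 120, 160, 200),
    exp_mis        = same("lognormal", c(5.2, .4)),
    obs_syn        = same("poisson", 80),
    exp_syn        = same("lognormal", c(4.4, .4)),
    obs_mis_pphen  = fx("poisson", 30, 45, 60),
    exp_mis_pphen  = same("lognormal", c(4, .4)),
    possible_lof   = same("lognormal", c(5, .4)),
    possible_mis   = same("lognormal", c(7, .3)),
    possible_syn   = same("lognormal", c(6.3, .3)),
    mu_lof         = same("lognormal", c(-13.5, .6)),
    mu_mis         = same("lognormal", c(-12, .5)),
    mu_syn         = same("lognormal", c(-12.5, .5)),
    obs_hom_lof    = fx("poisson", .05, .5, 2),
    exp_hom_lof    = same("lognormal", c(0, .5)),
    n_sites_lof    = fx("poisson", 6, 10, 15),
    exon_score     = fx("beta", c(.92, 14, 1), c(.75, 10, 1), c(.55, 8, 1)),
    promoter_score = fx("beta", c(.8, 10, 1), c(.62, 8, 1), c(.45, 8, 1)),
    tau_1          = fx("beta", c(.35, 8, 1), c(.5, 8, 1), c(.72, 8, 1)),
    tau_2          = fx("beta", c(.35, 8, 1), c(.5, 8, 1), c(.72, 8, 1)),
    tau_all        = fx("beta", c(.35, 8, 1), c(.5, 8, 1), c(.72, 8, 1)),
    cds_length     = fx("lognormal", c(7.6, .5), c(7.3, .5), c(7.1, .6)),
    exon_count     = fx("poisson", 10, 8, 7),
    transcript_length = fx("lognormal", c(8.2, .5), c(8, .5), c(7.8, .6)),
    promoter_cpg   = fx("beta", c(.68, 8, 1), c(.6, 8, 1), c(.55, 8, 1)),
    dist_centromere = same("lognormal", c(11.5, .8)),
    dist_telomere  = same("lognormal", c(11.8, .8)),
    n_paralogues   = fx("poisson", 1.2, 2, 2.5),
    n_close_paralogues = fx("poisson", .08, .25, .4),
    max_target_pct = fx("beta", c(.45, 3, 100), c(.55, 3, 100), c(.62, 3, 100)),
    max_query_pct  = fx("beta", c(.45, 3, 100), c(.55, 3, 100), c(.62, 3, 100)),
    mean_target_pct = fx("beta", c(.4, 4, 100), c(.5, 4, 100), c(.55, 4, 100))
  )
  # expression aggregates share a small set of level/variance families
  adult_mean <- fx("lognormal", c(2, .6), c(1.5, .7), c(.8, .9))
  adult_var  <- fx("lognormal", c(1, .6), c(1, .6), c(1.2, .8))
  dev_mean   <- fx("lognormal", c(2.2, .5), c(1.6, .6), c(.9, .8))
  dev_var    <- same("lognormal", c(1, .6))
  for (nm in grep("^mean_(Cereb|Brain|Nerve|All)_", feature_names(),
                  value = TRUE)) eff[[nm]] <- adult_mean
  for (nm in grep("^var_(Cereb|Brain|Nerve|All)_", feature_names(),
                  value = TRUE)) eff[[nm]] <- adult_var
  for (nm in grep("^mean_(Pre|Post1|Post2|Post)_", feature_names(),
                  value = TRUE)) eff[[nm]] <- dev_mean
  for (nm in grep("^var_(Pre|Post1|Post2|Post)_", feature_names(),
                  value = TRUE)) eff[[nm]] <- dev_var
  eff[feature_names()]
}

.sample_feature <- function(n, entry, class) {
  p <- entry$params[[class]]
  switch(entry$family,
    beta = {
      scale <- if (length(p) >= 3) p[3] else 1
      stats::rbeta(n, p[1] * p[2], (1 - p[1]) * p[2]) * scale
    },
    normal = stats::rnorm(n, p[1], p[2]),
    lognormal = stats::rlnorm(n, p[1], p[2]),
    poisson = stats::rpois(n, p[1]),
    stop("unknown feature family: ", entry$family)
  )
}

.check_proportions <- function(x, field) {
  if (abs(sum(x) - 1) > 1e-9)
    stop("configuration error: proportions in '", field,
         "' sum to ", sum(x), ", not 1")
  if (any(x < 0)) stop("configuration error: negative proportion in '",
                       field, "'")
  invisible(x)
}

#' Configuration of the synthetic gene universe
#'
#' Bundles every knob of the generator: universe size, chromosome and class
#' composition, planted per-feature class effects, promoter composition,
#' per-class variant rates and the seed. All proportion maps must sum to 1.
#'
#' @param n_genes Number of genes to simulate.
#' @param chromosome_weights Named proportions of genes per chromosome.
#' @param class_proportions Named proportions for `confirmed`, `PMT`,
#'   `no_disorder`. Defaults mirror the chromosome-X composition
#'   (205/26/598 of 829 protein-coding genes).
#' @param brain_fraction Fraction of confirmed/PMT genes whose disorder has
#'   neurologic features.
#' @param lof_tolerant_fraction_by_class Named per-class fractions of genes
#'   with at least one homozygous LoF carrier (dispensable).
#' @param feature_effects Per-feature generative effects;
#'   see [default_feature_effects()].
#' @param promoter_gc_by_class List of per-class `c(gc, cpg)` — promoter GC
#'   fraction and CpG observed/expected enrichment.
#' @param variant_rate_by_class Named per-class expected variant counts per kb
#'   of coding sequence.
#' @param hidden_disease_fraction Fraction of no-disorder genes that are
#'   latent disease genes: they keep the `no_disorder` label but draw their
#'   features, variants and database membership from the confirmed-gene
#'   distributions. This is the signal the prediction pipeline exists to
#'   recover; the truth table records the flag.
#' @param chromosome_length Scaled-down chromosome length in bases (positions
#'   are 0-based half-open).
#' @param seed Integer seed; identical configs give byte-identical universes.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genes = 1000,
                         chromosome_weights = c(chr1 = .25, chr2 = .2,
                                                chr3 = .2, chr5 = .15,
                                                chrX = .2),
                         class_proportions = c(confirmed = 205 / 829,
                                               PMT = 26 / 829,
                                               no_disorder = 598 / 829),
                         brain_fraction = .77,
                         lof_tolerant_fraction_by_class =
                           c(confirmed = .05, PMT = .2, no_disorder = .4),
                         feature_effects = default_feature_effects(),
                         promoter_gc_by_class =
                           list(confirmed = c(gc = .5, cpg = .7),
                                PMT = c(gc = .5, cpg = .6),
                                no_disorder = c(gc = .5, cpg = .45)),
                         variant_rate_by_class =
                           c(confirmed = 2, PMT = 1.2, no_disorder = .6),
                         hidden_disease_fraction = .25,
                         chromosome_length = 1e6,
                         seed = 1L) {
  if (n_genes < 0 || n_genes != round(n_genes))
    stop("configuration error: n_genes must be a non-negative integer")
  .check_proportions(chromosome_weights, "chromosome_weights")
  .check_proportions(class_proportions, "class_proportions")
  stopifnot(all(c("confirmed", "PMT", "no_disorder") %in%
                  names(class_proportions)))
  missing_fx <- setdiff(feature_names(), names(feature_effects))
  if (length(missing_fx))
    stop("configuration error: feature_effects lacks entries for: ",
         paste(missing_fx, collapse = ", "))
  structure(list(n_genes = as.integer(n_genes),
                 chromosome_weights = chromosome_weights,
                 class_proportions = class_proportions,
                 brain_fraction = brain_fraction,
                 lof_tolerant_fraction_by_class =
                   lof_tolerant_fraction_by_class,
                 feature_effects = feature_effects,
                 promoter_gc_by_class = promoter_gc_by_class,
                 variant_rate_by_class = variant_rate_by_class,
                 hidden_disease_fraction = hidden_disease_fraction,
                 chromosome_length = chromosome_length,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# First-order Markov sampler: marginal base composition is preserved while the
# C->G transition is scaled so the expected CpG observed/expected ratio equals
# `cpg`. Vectorised across sequences (one pass over positions).
.promoter_block <- function(n, len, gc, cpg) {
  stopifnot(len >= 2, gc > 0, gc < 1, cpg >= 0)
  pC <- gc / 2; pG <- gc / 2; pA <- (1 - gc) / 2; pT <- pA
  pG_after_C <- min(1, cpg * pG)
  pG_other <- max(0, pG * (1 - cpg * pC) / (1 - pC))
  m <- matrix("", n, len)
  base_probs <- c(A = pA, C = pC, G = pG, T = pT)
  m[, 1] <- sample(names(base_probs), n, TRUE, base_probs)
  other <- c("A", "C", "T")
  other_p <- c(pA, pC, pT) / (pA + pC + pT)
  cum <- cumsum(other_p)
  for (j in 2:len) {
    prevC <- m[, j - 1] == "C"
    pg <- ifelse(prevC, pG_after_C, pG_other)
    isG <- stats::runif(n) < pg
    u2 <- stats::runif(n)
    pick <- other[1 + (u2 > cum[1]) + (u2 > cum[2])]
    m[, j] <- ifelse(isG, "G", pick)
  }
  apply(m, 1, paste, collapse = "")
}

#' Generate a promoter-like nucleotide sequence
#'
#' Draws a random sequence over `{A,C,G,T}` whose base composition matches
#' `gc_fraction` and whose expected CpG dinucleotide observed/expected ratio
#' equals `cpg_enrichment` (a first-order Markov construction; marginal base
#' frequencies are preserved exactly in expectation). `cpg_enrichment = 0`
#' yields a sequence with no `"CG"` dinucleotide at all.
#'
#' @param length Sequence length in bases (>= 2).
#' @param gc_fraction Target G+C fraction, in (0, 1).
#' @param cpg_enrichment Target CpG observed/expected ratio (>= 0).
#' @param seed Optional integer seed.
#' @return A single character string.
#' @export
generate_promoter_sequence <- function(length, gc_fraction, cpg_enrichment,
                                       seed = NULL) {
  if (length < 2) stop("input error: length must be >= 2")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("input error: gc_fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  .promoter_block(1L, as.integer(length), gc_fraction, cpg_enrichment)
}

.empty_universe <- function(config) {
  chr0 <- character(0); num0 <- numeric(0); log0 <- logical(0)
  list(
    genes = data.frame(symbol = chr0, chromosome = chr0, tss = num0,
                       strand = chr0, par_flag = log0, disorder_class = chr0,
                       cs_available = log0, lof_tolerant = log0,
                       synopsis = chr0, stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = chr0, symbol = chr0,
                             chromosome = chr0, strand = chr0, tx_start = num0,
                             tx_end = num0, mane_select = log0, appris = log0,
                             length = num0, cds_starts = chr0, cds_ends = chr0,
                             stringsAsFactors = FALSE),
    constraints = data.frame(transcript_id = chr0, symbol = chr0),
    promoters = stats::setNames(character(0), character(0)),
    conservation = data.frame(chrom = chr0, start = num0, end = num0,
                              score = num0),
    expression = matrix(numeric(0), 0, 0),
    samples = data.frame(sample_id = chr0, tissue = chr0, tissue_group = chr0,
                         sex = chr0, age_group = chr0, dataset = chr0,
                         stringsAsFactors = FALSE),
    paralogues = data.frame(query = chr0, target = chr0, target_pct = num0,
                            query_pct = num0),
    variants = data.frame(gene = chr0, type = chr0, source = chr0,
                          score = num0, protein_position = num0,
                          in_domain = log0),
    domains = data.frame(gene = chr0, domain_aa = num0, total_aa = num0),
    db_membership = data.frame(gene = chr0, database = chr0),
    xci_calls = data.frame(gene = chr0, study = chr0, call = chr0),
    chrom_info = data.frame(chrom = names(config$chromosome_weights),
                            length = config$chromosome_length,
                            cen_start = round(.45 * config$chromosome_length),
                            cen_end = round(.55 * config$chromosome_length)),
    truth = list(genes = data.frame(symbol = chr0, class = chr0, brain = log0,
                                    lof_tolerant = log0),
                 seed = config$seed)
  )
}

.adult_tissues <- function() {
  data.frame(
    tissue = c("Cerebellum_1", "Cerebellum_2", "Brain_Cortex",
               "Brain_Hippocampus", "Brain_Amygdala", "Brain_Striatum",
               "Brain_Hypothalamus", "Nerve_Tibial", "Liver", "Heart", "Lung",
               "Kidney", "Muscle", "Skin", "Blood", "Spleen", "Thyroid",
               "Adrenal", "Colon", "Testis"),
    tissue_group = c("cerebellar", "cerebellar", rep("brain", 5), "nerve",
                     rep("other", 12)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic gene universe
#'
#' Produces a mutually consistent set of inputs for the whole pipeline —
#' gene annotations (with a free-text neurologic clinical-synopsis line),
#' transcript models with CDS intervals, per-transcript constraint metrics,
#' promoter sequences of exactly 4,001 bases centred on each TSS, a per-base
#' conservation track covering promoters and coding exons, adult and
#' developmental expression matrices with sex/tissue/age metadata, paralogue
#' hits, per-gene variant and protein-domain tables, XCI study calls, and a
#' truth record of every planted parameter. Identical configs (including the
#' seed) give identical output.
#'
#' @param config A [synth_config()].
#' @return A named list of data frames plus `promoters` (named character
#'   vector), `expression` (gene x sample matrix) and `truth`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_genes
  if (n == 0) return(.empty_universe(config))
  classes <- names(config$class_proportions)
  L <- config$chromosome_length
  cen <- c(round(.45 * L), round(.55 * L))
  chrom_info <- data.frame(chrom = names(config$chromosome_weights),
                           length = L, cen_start = cen[1], cen_end = cen[2],
                           stringsAsFactors = FALSE)

  symbol <- sprintf("G%05d", seq_len(n))
  chromosome <- sample(names(config$chromosome_weights), n, TRUE,
                       config$chromosome_weights)
  class <- sample(classes, n, TRUE, config$class_proportions)
  hidden <- class == "no_disorder" &
    stats::runif(n) < (config$hidden_disease_fraction %||% 0)
  # latent disease genes: labelled no_disorder, features drawn as confirmed
  fclass <- ifelse(hidden, "confirmed", class)
  strand <- sample(c("+", "-"), n, TRUE)
  lof_tolerant <- stats::rbinom(n, 1,
    config$lof_tolerant_fraction_by_class[fclass]) == 1
  brain <- ifelse(class == "no_disorder", NA,
                  stats::rbinom(n, 1, config$brain_fraction) == 1)
  cs_available <- ifelse(class == "no_disorder", FALSE,
                         stats::rbinom(n, 1, .97) == 1)

  # --- transcript models -------------------------------------------------
  fx <- config$feature_effects
  exon_lambda <- vapply(fclass, function(cl) fx$exon_count$params[[cl]][1],
                        numeric(1))
  n_exons <- pmax(2L, stats::rpois(n, exon_lambda))
  tx_list <- vector("list", n)
  gene_meta <- data.frame(symbol = symbol, tss = NA_real_,
                          cds_length = NA_real_, stringsAsFactors = FALSE)
  terms <- default_phenotype_terms()
  synopsis <- character(n)
  for (i in seq_len(n)) {
    ne <- n_exons[i]
    exon_w <- pmax(30L, round(stats::rlnorm(ne, log(130), .4)))
    gaps <- round(stats::runif(ne - 1, 200, 2000))
    rel_start <- cumsum(c(0, exon_w[-ne] + gaps))
    span <- rel_start[ne] + exon_w[ne] + 400
    # place the gene clear of the promoter window, chromosome ends and
    # centromere (TSS must lie outside the centromere interval)
    repeat {
      gstart <- round(stats::runif(1, 2100, L - span - 2100))
      tss <- if (strand[i] == "+") gstart else gstart + span
      if (tss < cen[1] || tss >= cen[2]) break
    }
    starts <- gstart + 200 + rel_start
    ends <- starts + exon_w
    n_tx <- sample(1:3, 1, prob = c(.5, .3, .2))
    has_mane <- stats::runif(1) < .8
    txs <- lapply(seq_len(n_tx), function(k) {
      keep <- if (k == 1) seq_len(ne) else
        sort(sample(seq_len(ne), max(2, ne - sample(1:2, 1))))
      data.frame(
        transcript_id = sprintf("T%05d.%d", i, k),
        symbol = symbol[i], chromosome = chromosome[i], strand = strand[i],
        tx_start = gstart, tx_end = gstart + span,
        mane_select = has_mane && k == 1,
        appris = !has_mane || stats::runif(1) < .5,
        length = sum(exon_w[keep]) + 400,
        cds_starts = paste(starts[keep], collapse = ","),
        cds_ends = paste(ends[keep], collapse = ","),
        stringsAsFactors = FALSE)
    })
    tx_list[[i]] <- do.call(rbind, txs)
    gene_meta$tss[i] <- if (strand[i] == "+") gstart else gstart + span
    gene_meta$cds_length[i] <- sum(exon_w)
    # neurologic clinical-synopsis line: non-empty only for brain disorders
    synopsis[i] <- if (isTRUE(brain[i]) && cs_available[i]) {
      phr <- c(
        if (stats::runif(1) < .6) sample(terms$intellectual_disability, 1),
        if (stats::runif(1) < .5) sample(terms$seizures, 1),
        if (stats::runif(1) < .35) sample(terms$language, 1),
        if (stats::runif(1) < .15) sample(terms$motor, 1),
        if (stats::runif(1) < .1) sample(terms$spasticity, 1),
        if (stats::runif(1) < .1) sample(terms$ataxia, 1))
      if (!length(phr)) phr <- sample(terms$intellectual_disability, 1)
      paste(phr, collapse = "; ")
    } else ""
  }
  transcripts <- do.call(rbind, tx_list)
  par_flag <- chromosome == "chrX" &
    (gene_meta$tss < .03 * L | gene_meta$tss > .97 * L)

  genes <- data.frame(symbol = symbol, chromosome = chromosome,
                      tss = gene_meta$tss, strand = strand,
                      par_flag = par_flag, disorder_class = class,
                      cs_available = cs_available, lof_tolerant = lof_tolerant,
                      synopsis = synopsis, stringsAsFactors = FALSE)

  # --- per-transcript constraint metrics ---------------------------------
  cons_feats <- feature_schema()$feature[feature_schema()$group == "constraint"]
  gene_constraints <- sapply(cons_feats, function(f) {
    v <- numeric(n)
    for (cl in classes) {
      idx <- fclass == cl
      if (any(idx)) v[idx] <- .sample_feature(sum(idx), fx[[f]], cl)
    }
    v
  })
  tx_per_gene <- match(transcripts$symbol, symbol)
  constraints <- data.frame(transcript_id = transcripts$transcript_id,
                            symbol = transcripts$symbol,
                            stringsAsFactors = FALSE)
  first_tx <- !duplicated(transcripts$symbol)
  for (f in cons_feats) {
    v <- gene_constraints[tx_per_gene, f]
    if (f == "loeuf") {
      jit <- stats::runif(nrow(transcripts), .01, .3)
      v <- ifelse(first_tx, v, pmin(2, v + jit))
    } else {
      v <- ifelse(first_tx, v,
                  v * stats::rlnorm(nrow(transcripts), 0, .03))
    }
    constraints[[f]] <- v
  }

  # --- promoters (4,001 bases centred on the TSS) ------------------------
  promoters <- character(n)
  for (cl in classes) {
    idx <- which(fclass == cl)
    if (!length(idx)) next
    p <- config$promoter_gc_by_class[[cl]]
    promoters[idx] <- .promoter_block(length(idx), 4001L, p[["gc"]],
                                      p[["cpg"]])
  }
  names(promoters) <- symbol

  # --- conservation track (segment-constant bedGraph-style) --------------
  cons_mean_exon <- numeric(n); cons_mean_prom <- numeric(n)
  for (cl in classes) {
    idx <- which(fclass == cl)
    if (!length(idx)) next
    cons_mean_exon[idx] <- .sample_feature(length(idx), fx$exon_score, cl)
    cons_mean_prom[idx] <- .sample_feature(length(idx), fx$promoter_score, cl)
  }
  seg_rows <- vector("list", n)
  canon <- transcripts[first_tx, ]
  for (i in seq_len(n)) {
    tss <- gene_meta$tss[i]
    pstart <- tss - 2000; pend <- tss + 2001
    pb <- seq(pstart, pend, by = 50)
    if (pb[length(pb)] < pend) pb <- c(pb, pend)
    cs <- as.numeric(strsplit(canon$cds_starts[i], ",")[[1]])
    ce <- as.numeric(strsplit(canon$cds_ends[i], ",")[[1]])
    eb_start <- numeric(0); eb_end <- numeric(0)
    for (k in seq_along(cs)) {
      b <- seq(cs[k], ce[k], by = 50)
      if (b[length(b)] < ce[k]) b <- c(b, ce[k])
      eb_start <- c(eb_start, b[-length(b)]); eb_end <- c(eb_end, b[-1])
    }
    st <- c(pb[-length(pb)], eb_start)
    en <- c(pb[-1], eb_end)
    mu <- c(rep(cons_mean_prom[i], length(pb) - 1),
            rep(cons_mean_exon[i], length(eb_start)))
    sc <- pmin(1, pmax(1e-4, stats::rnorm(length(mu), mu, .06)))
    seg_rows[[i]] <- data.frame(chrom = chromosome[i], start = st, end = en,
                                score = round(sc, 4),
                                stringsAsFactors = FALSE)
  }
  conservation <- do.call(rbind, seg_rows)

  # --- expression (adult multi-tissue + developmental brain) -------------
  at <- .adult_tissues()
  adult_samples <- expand.grid(tissue = at$tissue, sex = c("F", "M"),
                               rep = 1:2, stringsAsFactors = FALSE)
  adult_samples$tissue_group <- at$tissue_group[match(adult_samples$tissue,
                                                      at$tissue)]
  adult_samples$age_group <- "adult"
  adult_samples$dataset <- "adult"
  dev_samples <- expand.grid(tissue = "brain_dev", sex = c("F", "M"),
                             age_group = c("Pre", "Post1", "Post2"),
                             rep = 1:3, stringsAsFactors = FALSE)
  dev_samples$tissue_group <- "brain_dev"
  dev_samples$dataset <- "devel"
  samples <- rbind(
    adult_samples[c("tissue", "tissue_group", "sex", "age_group", "dataset")],
    dev_samples[c("tissue", "tissue_group", "sex", "age_group", "dataset")])
  samples$sample_id <- sprintf("S%03d", seq_len(nrow(samples)))
  samples <- samples[c("sample_id", "tissue", "tissue_group", "sex",
                       "age_group", "dataset")]

  breadth <- numeric(n); base_expr <- numeric(n)
  for (cl in classes) {
    idx <- which(fclass == cl)
    if (!length(idx)) next
    tau_mu <- fx$tau_all$params[[cl]][1]
    conc <- fx$tau_all$params[[cl]][2]
    breadth[idx] <- stats::rbeta(length(idx), (1 - tau_mu) * conc,
                                 tau_mu * conc)
    lv <- fx$mean_All_F$params[[cl]]
    base_expr[idx] <- stats::rlnorm(length(idx), lv[1], lv[2])
  }
  tissues <- unique(samples$tissue)
  loading <- matrix(0, n, length(tissues), dimnames = list(symbol, tissues))
  for (tj in seq_along(tissues)) {
    active <- stats::rbinom(n, 1, pmin(.999, breadth)) == 1
    loading[, tj] <- ifelse(active, stats::runif(n, .5, 1),
                            stats::runif(n, 0, .03))
  }
  # guarantee at least one expressed tissue per gene
  none <- rowSums(loading > .1) == 0
  if (any(none)) loading[cbind(which(none),
                               sample(seq_along(tissues), sum(none), TRUE))] <-
    stats::runif(sum(none), .5, 1)
  sexmul <- matrix(stats::rlnorm(2 * n, 0, .05), n, 2,
                   dimnames = list(symbol, c("F", "M")))
  expression <- matrix(0, n, nrow(samples),
                       dimnames = list(symbol, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    tj <- match(samples$tissue[j], tissues)
    expression[, j] <- base_expr * loading[, tj] *
      sexmul[, samples$sex[j]] * stats::rlnorm(n, 0, .25)
  }
  expression <- round(expression, 4)

  # --- paralogues ---------------------------------------------------------
  n_par <- stats::rpois(n, vapply(fclass, function(cl)
    fx$n_paralogues$params[[cl]][1], numeric(1)))
  pq <- rep(symbol, n_par)
  pcl <- rep(fclass, n_par)
  if (length(pq)) {
    tpct <- numeric(length(pq)); mx <- fx$max_target_pct
    for (cl in classes) {
      idx <- which(pcl == cl)
      if (length(idx)) tpct[idx] <- .sample_feature(length(idx), mx, cl)
    }
    qpct <- pmin(100, pmax(0, tpct + stats::rnorm(length(pq), 0, 5)))
    paralogues <- data.frame(query = pq,
                             target = sample(symbol, length(pq), TRUE),
                             target_pct = round(tpct, 2),
                             query_pct = round(qpct, 2),
                             stringsAsFactors = FALSE)
  } else {
    paralogues <- .empty_universe(config)$paralogues
  }

  # --- variants, domains, database membership ----------------------------
  total_aa <- pmax(50, round(gene_meta$cds_length / 3))
  domain_aa <- pmin(total_aa,
                    pmax(0, round(total_aa * stats::rbeta(n, 2.4, 7.6))))
  domains <- data.frame(gene = symbol, domain_aa = domain_aa,
                        total_aa = total_aa, stringsAsFactors = FALSE)
  nv <- stats::rpois(n, config$variant_rate_by_class[fclass] *
                       gene_meta$cds_length / 1000)
  vg <- rep(seq_len(n), nv)
  if (length(vg)) {
    vtype <- sample(c("missense", "LoF", "splicing", "other"), length(vg),
                    TRUE, c(.6, .25, .1, .05))
    score <- ifelse(vtype == "missense", stats::rnorm(length(vg), 26, 5),
             ifelse(vtype == "splicing", stats::rnorm(length(vg), 20, 6),
                    NA_real_))
    ppos <- 1 + floor(stats::runif(length(vg)) * total_aa[vg])
    pdom <- pmin(1, domain_aa[vg] / total_aa[vg] *
                   ifelse(fclass[vg] == "confirmed", 1.5, 1.1))
    in_dom <- stats::rbinom(length(vg), 1, pdom) == 1
    variants <- data.frame(
      gene = symbol[vg], type = vtype,
      source = sample(c("curated-DB-1", "curated-DB-2", "cohort"),
                      length(vg), TRUE, c(.45, .35, .2)),
      score = round(score, 2), protein_position = ppos, in_domain = in_dom,
      stringsAsFactors = FALSE)
  } else {
    variants <- .empty_universe(config)$variants
  }
  dbs <- paste0("DB_", LETTERS[1:7])
  db_p <- c(confirmed = .5, PMT = .35, no_disorder = .15)[fclass]
  member <- lapply(seq_len(n), function(i) {
    k <- stats::rbinom(1, length(dbs), db_p[i] / 2.2)
    if (k == 0) return(NULL)
    data.frame(gene = symbol[i], database = sample(dbs, k),
               stringsAsFactors = FALSE)
  })
  db_membership <- do.call(rbind, member)
  if (is.null(db_membership))
    db_membership <- .empty_universe(config)$db_membership

  # --- XCI study calls (chrX genes) ---------------------------------------
  xg <- which(chromosome == "chrX")
  xci_rows <- lapply(xg, function(i) {
    ns <- sample(0:7, 1, prob = c(.1, .1, rep(.8 / 6, 6)))
    if (ns == 0) return(NULL)
    truth_call <- if (par_flag[i]) "escape" else
      sample(c("escape", "non_escape", "variable"), 1, prob = c(.15, .75, .1))
    calls <- ifelse(stats::runif(ns) < .85, truth_call,
                    sample(c("escape", "non_escape", "variable"), ns, TRUE))
    data.frame(gene = symbol[i], study = paste0("study", seq_len(ns)),
               call = calls, stringsAsFactors = FALSE)
  })
  xci_calls <- do.call(rbind, xci_rows)
  if (is.null(xci_calls)) xci_calls <- .empty_universe(config)$xci_calls

  truth <- list(
    genes = data.frame(symbol = symbol, class = class, hidden = hidden,
                       lof_tolerant = lof_tolerant, brain = brain,
                       breadth = round(breadth, 4),
                       cons_exon_mean = round(cons_mean_exon, 4),
                       cons_prom_mean = round(cons_mean_prom, 4),
                       base_expr = round(base_expr, 4),
                       stringsAsFactors = FALSE),
    planted_loeuf_mean = stats::setNames(
      vapply(classes, function(cl) {
        p <- fx$loeuf$params[[cl]]; p[1] * p[3]
      }, numeric(1)), classes),
    seed = config$seed)

  list(genes = genes, transcripts = transcripts, constraints = constraints,
       promoters = promoters, conservation = conservation,
       expression = expression, samples = samples, paralogues = paralogues,
       variants = variants, domains = domains, db_membership = db_membership,
       xci_calls = xci_calls, chrom_info = chrom_info, truth = truth)
}

#' Directly simulate an 83-column feature table with planted class effects
#'
#' Samples every feature of [feature_schema()] from the per-class
#' distributions in `feature_effects`, bypassing sequence/track/expression
#' generation. This is the generator used for classifier-scale experiments
#' where only the feature matrix and class labels matter.
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named proportions over
#'   `{confirmed, PMT, no_disorder}` (must sum to 1).
#' @param feature_effects See [default_feature_effects()].
#' @param seed Integer seed.
#' @return List with `features` (data.frame: `symbol` + 83 numeric columns)
#'   and `classes` (data.frame: `symbol`, `class`).
#' @export
simulate_feature_table <- function(n_genes,
                                   class_proportions = c(confirmed = .5,
                                                         PMT = 0,
                                                         no_disorder = .5),
                                   feature_effects = default_feature_effects(),
                                   seed = 1L) {
  .check_proportions(class_proportions, "class_proportions")
  set.seed(seed)
  classes <- names(class_proportions)
  class <- sample(classes, n_genes, TRUE, class_proportions)
  symbol <- sprintf("G%05d", seq_len(n_genes))
  out <- data.frame(symbol = symbol, stringsAsFactors = FALSE)
  for (f in feature_names()) {
    v <- numeric(n_genes)
    for (cl in unique(class)) {
      idx <- class == cl
      v[idx] <- .sample_feature(sum(idx), feature_effects[[f]], cl)
    }
    out[[f]] <- v
  }
  list(features = out,
       classes = data.frame(symbol = symbol, class = class,
                            stringsAsFactors = FALSE))
}
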