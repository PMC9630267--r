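test_that("phenotype term matching is case-insensitive substring search", {
  terms <- default_phenotype_terms()
  f0 <- match_phenotype_terms("", terms)
  expect_false(any(f0))
  f1 <- match_phenotype_terms("Intellectual disability, severe", terms)
  expect_true(f1[["intellectual_disability"]])
  expect_true(f1[["neurologic_any"]])
  expect_false(f1[["seizures"]])
  # no negation handling: a documented limitation of substring matching
  f2 <- match_phenotype_terms("no seizures reported", terms)
  expect_true(f2[["seizures"]])
  expect_error(match_phenotype_terms("x", list(a = character(0))), "empty")
})

test_that("canonical transcript selection follows MANE > longest-APPRIS", {
  tx <- function(id, mane, appris, len)
    data.frame(transcript_id = id, symbol = "G1", mane_select = mane,
               appris = appris, length = len, stringsAsFactors = FALSE)
  # MANE wins over a longer APPRIS transcript
  two <- rbind(tx("t1", TRUE, FALSE, 500), tx("t2", FALSE, TRUE, 900))
  expect_equal(select_canonical_transcript(two)$transcript_id, "t1")
  # longest APPRIS when no MANE
  app <- rbind(tx("a", FALSE, TRUE, 800), tx("b", FALSE, TRUE, 1200))
  expect_equal(select_canonical_transcript(app)$transcript_id, "b")
  # single unflagged transcript is kept
  expect_equal(select_canonical_transcript(tx("only", FALSE, FALSE, 100)
                                           )$transcript_id, "only")
  # equal-length APPRIS tie breaks lexicographically; order-invariant
  tie <- rbind(tx("zz", FALSE, TRUE, 700), tx("aa", FALSE, TRUE, 700))
  expect_equal(select_canonical_transcript(tie)$transcript_id, "aa")
  expect_equal(select_canonical_transcript(tie[2:1, ])$transcript_id, "aa")
  # no MANE, no APPRIS, several transcripts: selection error naming the gene
  bad <- rbind(tx("x", FALSE, FALSE, 1), tx("y", FALSE, FALSE, 2))
  expect_error(select_canonical_transcript(bad), "G1")
  expect_error(select_canonical_transcript(
    rbind(two, within(two, symbol <- "G2"))), "more than one gene")
})

test_that("canonical selection is permutation-invariant", {
  set.seed(4)
  tx <- data.frame(transcript_id = paste0("t", 1:5), symbol = "G",
                   mane_select = FALSE, appris = c(TRUE, TRUE, FALSE, TRUE,
                                                   FALSE),
                   length = c(300, 900, 2000, 900, 50),
                   stringsAsFactors = FALSE)
  picks <- replicate(10, select_canonical_transcript(
    tx[sample(nrow(tx)), ])$transcript_id)
  expect_true(all(picks == "t2"))
})

test_that("close-paralogue flags require both identities above the 95th percentile", {
  expect_equal(flag_close_paralogues(
    data.frame(query = character(0), target_pct = numeric(0),
               query_pct = numeric(0)), genes = c("a", "b")),
    c(a = FALSE, b = FALSE))
  hits <- data.frame(query = sprintf("g%03d", 1:100),
                     target_pct = c(99.9, rep(50, 99)),
                     query_pct = c(99.9, rep(50, 99)),
                     stringsAsFactors = FALSE)
  fl <- flag_close_paralogues(hits)
  expect_true(fl[["g001"]])
  expect_equal(sum(fl), 1)
  # conjunction: one metric above, the other below, is not flagged
  hits2 <- rbind(hits,
                 data.frame(query = "g200", target_pct = 99.5,
                            query_pct = 10))
  expect_false(flag_close_paralogues(hits2)[["g200"]])
  expect_error(flag_close_paralogues(hits, percentile = 101), "percentile")
})

test_that("close-paralogue flags agree with a brute-force double loop", {
  set.seed(21)
  hits <- data.frame(query = sample(sprintf("g%02d", 1:40), 180, TRUE),
                     target_pct = runif(180, 0, 100),
                     query_pct = runif(180, 0, 100),
                     stringsAsFactors = FALSE)
  fast <- flag_close_paralogues(hits, 95)
  thr_t <- quantile(hits$target_pct, .95, type = 7)
  thr_q <- quantile(hits$query_pct, .95, type = 7)
  for (g in names(fast)) {
    slow <- FALSE
    for (i in seq_len(nrow(hits)))
      if (hits$query[i] == g && hits$target_pct[i] > thr_t &&
          hits$query_pct[i] > thr_q) slow <- TRUE
    expect_identical(unname(fast[g]), slow)
  }
})

test_that("XCI consensus categories follow the vote rules", {
  expect_equal(consensus_xci(rep("escape", 6)), "high_conf_escape")
  expect_equal(consensus_xci(c(rep("escape", 5), "non_escape")),
               "high_conf_escape")
  expect_equal(consensus_xci(c(rep("non_escape", 4), rep("escape", 2))),
               "low_conf_non_escape")
  expect_equal(consensus_xci(c(rep("escape", 3), rep("non_escape", 3))),
               "discordant")
  expect_equal(consensus_xci(c(rep("variable", 3), "escape", "non_escape")),
               "variable")
  expect_equal(consensus_xci("escape"), "not_available")
  expect_equal(consensus_xci(character(0)), "not_available")
  expect_error(consensus_xci(c("escape", "maybe")), "unknown")
})

test_that("pre-classification yields the 10-label lattice with disjoint training classes", {
  g <- expand.grid(disorder_class = c("confirmed", "PMT", "no_disorder"),
                   brain_flag = c(TRUE, FALSE, NA),
                   lof_tolerant = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  valid <- (g$disorder_class == "no_disorder") == is.na(g$brain_flag)
  g <- g[valid, ]
  g$symbol <- sprintf("g%02d", seq_len(nrow(g)))
  lab <- preclassify(g)
  expect_equal(length(unique(lab)), 10)
  expect_equal(unname(lab[g$disorder_class == "confirmed" & g$brain_flag &
                            !g$lof_tolerant]), "Cbi")
  expect_equal(unname(lab[g$disorder_class == "no_disorder" &
                            g$lof_tolerant]), "NDt")
  expect_equal(unname(lab[g$disorder_class == "PMT" & !g$brain_flag &
                            g$lof_tolerant]), "PMTnbt")
  expect_length(intersect(names(lab)[lab == "Cbi"],
                          names(lab)[lab == "NDt"]), 0)
  bad <- data.frame(symbol = "x", disorder_class = "no_disorder",
                    brain_flag = TRUE, lof_tolerant = TRUE)
  expect_error(preclassify(bad), "brain_flag")
})

test_that("the shipped phenotype term file parses to the default lists", {
  path <- system.file("extdata", "phenotype_terms.yaml",
                      package = "xpredict")
  expect_true(nzchar(path))
  expect_identical(read_phenotype_terms(path), default_phenotype_terms())
})

test_that("annotation stage is internally consistent on the shared universe", {
  ann <- shared_annotated()
  u <- shared_universe()
  expect_equal(nrow(ann), nrow(u$genes))
  # phenotype flags all false without clinical synopsis
  expect_true(all(!ann$neurologic_any[!ann$cs_available]))
  # no-disorder genes have NA brain flag and ND subgroups
  nd <- ann$disorder_class == "no_disorder"
  expect_true(all(is.na(ann$brain_flag[nd])))
  expect_true(all(ann$subgroup[nd] %in% c("NDi", "NDt")))
  # XCI consensus only on chrX
  expect_true(all(is.na(ann$xci_consensus[ann$chromosome != "chrX"])))
  expect_true(all(!is.na(ann$xci_consensus[ann$chromosome == "chrX"])))
})
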