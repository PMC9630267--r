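test_that("an empty universe is returned without error", {
  u <- generate_universe(synth_config(n_genes = 0))
  expect_equal(nrow(u$genes), 0)
  expect_equal(nrow(u$transcripts), 0)
  expect_equal(length(u$promoters), 0)
  expect_equal(nrow(u$variants), 0)
})

test_that("invalid proportions are rejected naming the offending field", {
  expect_error(synth_config(class_proportions = c(confirmed = .5, PMT = .2,
                                                  no_disorder = .2)),
               "class_proportions")
  expect_error(synth_config(chromosome_weights = c(chr1 = .7, chrX = .4)),
               "chromosome_weights")
})

test_that("identical seeds give identical universes", {
  u1 <- generate_universe(synth_config(n_genes = 60, seed = 7))
  u2 <- generate_universe(synth_config(n_genes = 60, seed = 7))
  expect_identical(u1, u2)
  u3 <- generate_universe(synth_config(n_genes = 60, seed = 8))
  expect_false(identical(u1$genes$tss, u3$genes$tss))
})

test_that("planted class-conditional feature locations are recovered", {
  fx <- default_feature_effects()
  # plant LOEUF means 0.2 (confirmed) vs 0.9 (no_disorder)
  fx$loeuf$params$confirmed <- c(.1, 6, 2)
  fx$loeuf$params$no_disorder <- c(.45, 6, 2)
  sim <- simulate_feature_table(5000, c(confirmed = .5, PMT = 0,
                                        no_disorder = .5),
                                feature_effects = fx, seed = 11)
  for (cl in c("confirmed", "no_disorder")) {
    v <- sim$features$loeuf[sim$classes$class == cl]
    planted <- if (cl == "confirmed") .2 else .9
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - planted), 3 * se)
  }
  # directional contrasts for the other planted signals
  by_cl <- split(sim$features, sim$classes$class)
  expect_gt(mean(by_cl$confirmed$mis_z), mean(by_cl$no_disorder$mis_z))
  expect_gt(mean(by_cl$confirmed$exon_score),
            mean(by_cl$no_disorder$exon_score))
  expect_lt(mean(by_cl$confirmed$tau_all), mean(by_cl$no_disorder$tau_all))
})

test_that("universe constraint table carries the planted LOEUF contrast", {
  u <- shared_universe()
  per_gene <- tapply(u$constraints$loeuf, u$constraints$symbol, min)
  cls <- u$truth$genes$class[match(names(per_gene), u$truth$genes$symbol)]
  expect_gt(mean(per_gene[cls == "no_disorder"]),
            mean(per_gene[cls == "confirmed"]))
})

test_that("promoter sequences hit the requested GC and CpG targets", {
  set.seed(5)
  seqs <- replicate(100, generate_promoter_sequence(4000, .5, 1))
  dens <- vapply(seqs, compute_cpg_density, numeric(1))
  expect_lt(abs(mean(dens) - 1), .15)
  gc <- mean(vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]; mean(ch %in% c("G", "C"))
  }, numeric(1)))
  expect_lt(abs(gc - .5), .02)
})

test_that("zero CpG enrichment yields no CG dinucleotide at all", {
  s <- generate_promoter_sequence(5000, .5, 0, seed = 3)
  expect_false(grepl("CG", s, fixed = TRUE))
})

test_that("promoter sequence edge cases behave", {
  expect_error(generate_promoter_sequence(1, .5, 1), "length")
  expect_equal(nchar(generate_promoter_sequence(2, .5, 1, seed = 1)), 2)
  expect_true(all(strsplit(generate_promoter_sequence(200, .4, .5,
                                                      seed = 2),
                           "")[[1]] %in% c("A", "C", "G", "T")))
})

test_that("universe outputs are mutually consistent", {
  u <- shared_universe()
  # every gene has at least one transcript and a 4,001-base promoter
  expect_true(all(u$genes$symbol %in% u$transcripts$symbol))
  expect_equal(unname(nchar(u$promoters)), rep(4001, nrow(u$genes)))
  expect_setequal(names(u$promoters), u$genes$symbol)
  # expression covers every gene x sample
  expect_equal(dim(u$expression), c(nrow(u$genes), nrow(u$samples)))
  # conservation covers every CDS base of every canonical transcript
  ft <- shared_features()
  expect_true(all(!is.na(ft$features$exon_score)))
  # truth records the class of every gene
  expect_setequal(u$truth$genes$symbol, u$genes$symbol)
})

test_that("a complete universe yields the 83-column table with no missingness", {
  ft <- shared_features()
  expect_equal(ncol(ft$features), 84)
  expect_identical(colnames(ft$features)[-1], feature_names())
  expect_equal(sum(ft$mask), 0)
})

test_that("universe round-trips through the directory format", {
  u <- generate_universe(synth_config(n_genes = 25, seed = 13))
  dir <- withr::local_tempdir()
  write_universe(u, dir)
  u2 <- read_universe(dir)
  expect_equal(u2$genes$symbol, u$genes$symbol)
  expect_equal(u2$genes$tss, u$genes$tss)
  expect_identical(u2$promoters, u$promoters)
  expect_equal(u2$transcripts$cds_starts, u$transcripts$cds_starts)
  expect_equal(nrow(u2$conservation), nrow(u$conservation))
  expect_equal(unname(u2$expression), unname(u$expression),
               tolerance = 1e-12)
  ft1 <- assemble_feature_table(u)
  ft2 <- assemble_feature_table(u2)
  expect_equal(ft2$features, ft1$features, tolerance = 1e-10)
})
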