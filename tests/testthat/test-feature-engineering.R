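test_that("RPKM to TPM normalisation", {
  expect_equal(unname(rpkm_to_tpm(matrix(7))), matrix(1e6))
  expect_equal(as.numeric(rpkm_to_tpm(matrix(c(1, 3)))), c(25e4, 75e4))
  expect_equal(as.numeric(rpkm_to_tpm(matrix(c(0, 5)))), c(0, 1e6))
  m <- matrix(runif(20), 5, dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(colSums(rpkm_to_tpm(m)), setNames(rep(1e6, 4),
                                                 paste0("s", 1:4)),
               tolerance = 1e-6)
  m[, 2] <- 0
  expect_error(rpkm_to_tpm(m), "s2")
})

test_that("brain aggregation takes medians over the named tissue sets", {
  v <- c(cb1 = 2, cb2 = 4, b1 = 1, b2 = 2, b3 = 9)
  ab <- aggregate_brain(v, c("cb1", "cb2"), c("b1", "b2", "b3"))
  expect_equal(unname(ab), c(3, 2))
  v5 <- setNames(rep(5, 5), names(v))
  expect_equal(unname(aggregate_brain(v5, c("cb1", "cb2"),
                                      c("b1", "b2", "b3"))), c(5, 5))
  expect_error(aggregate_brain(v, c("cb1", "missing"), "b1"), "missing")
  expect_error(aggregate_brain(v, c("cb1", "b1"), c("b1", "b2")), "overlap")
})

test_that("tau matches the hand formula and its limits", {
  expect_equal(compute_tau(rep(7, 5)), 0)
  one <- c(10, 0, 0, 0)
  expect_equal(compute_tau(one), 1)
  # log-transformed profile proportional to [1, .5, .25, .25] -> tau = 2/3
  prof <- 2^(c(1, .5, .25, .25) * 8) - 1
  expect_equal(compute_tau(prof), 2 / 3, tolerance = 1e-12)
  expect_true(is.na(compute_tau(c(0, 0, 0))))
  expect_error(compute_tau(5), "2 tissues")
})

test_that("tau is scale-invariant on the log profile and permutation-invariant", {
  set.seed(8)
  for (i in 1:25) {
    v <- rexp(sample(3:12, 1), 1 / 50)
    logs <- log2(v + 1)
    t1 <- compute_tau(v)
    expect_equal(compute_tau(2^(logs * 3) - 1), t1, tolerance = 1e-9)
    expect_equal(compute_tau(sample(v)), t1)
    expect_gte(t1, 0); expect_lte(t1, 1)
  }
  # oracle equality on enumerated 4-tissue profiles
  grid <- expand.grid(a = c(0, 1, 10), b = c(0, 5), c = c(2, 100),
                      d = c(0, 1))
  for (i in seq_len(nrow(grid))) {
    tpm <- as.numeric(grid[i, ])
    if (max(tpm) == 0) next
    expect_equal(compute_tau(tpm), oracle_tau(tpm))
  }
})

test_that("CpG density matches manual counts and the degenerate rule", {
  expect_equal(compute_cpg_density("AACGTT"), 1 / (1 * 1) * 6)
  expect_equal(compute_cpg_density("CGCGCG"), 3 / (3 * 3) * 6)
  expect_true(is.na(compute_cpg_density("AATTAA")))
  expect_error(compute_cpg_density("A"), "length")
})

test_that("CpG density equals brute-force dinucleotide enumeration", {
  set.seed(17)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(2:60, 1), TRUE),
               collapse = "")
    expect_identical(compute_cpg_density(s), oracle_cpg(s))
  }
})

test_that("conservation scoring averages per base over the interval union", {
  trk <- data.frame(start = 0:3, end = 1:4, score = c(0, 0, 1, 1))
  expect_equal(conservation_score(trk, data.frame(start = 0, end = 4)), .5)
  expect_equal(conservation_score(
    data.frame(start = 0, end = 10, score = 1),
    data.frame(start = 2, end = 7)), 1)
  # split intervals equal the merged interval
  expect_equal(conservation_score(trk, data.frame(start = c(0, 2),
                                                  end = c(2, 4))),
               conservation_score(trk, data.frame(start = 0, end = 4)))
  # uncovered bases are excluded, not scored 0
  gap <- data.frame(start = c(0, 8), end = c(4, 10), score = c(.2, .8))
  expect_equal(conservation_score(gap, data.frame(start = 0, end = 10)),
               (4 * .2 + 2 * .8) / 6)
  expect_error(conservation_score(gap, data.frame(start = 4, end = 8)),
               "zero covered")
  expect_error(conservation_score(gap, data.frame(start = 5, end = 5)),
               "invalid interval")
})

test_that("conservation of disjoint intervals is the coverage-weighted mean", {
  set.seed(30)
  trk <- data.frame(start = seq(0, 990, 10), end = seq(10, 1000, 10),
                    score = runif(100))
  iv <- data.frame(start = c(5, 300, 720), end = c(95, 410, 900))
  per <- vapply(seq_len(nrow(iv)), function(i)
    conservation_score(trk, iv[i, ]), numeric(1))
  w <- iv$end - iv$start
  expect_equal(conservation_score(trk, iv), sum(per * w) / sum(w),
               tolerance = 1e-12)
})

test_that("positional features resolve the arm correctly", {
  expect_equal(unname(positional_features(10, c(100, 200), c(0, 1000))),
               c(90, 10))
  expect_equal(unname(positional_features(500, c(100, 200), c(0, 1000))),
               c(300, 500))
  expect_equal(unname(positional_features(200, c(100, 200),
                                          c(0, 1000)))[1], 0)
  expect_error(positional_features(150, c(100, 200), c(0, 1000)),
               "centromere")
})

test_that("constraint metrics come from the lowest-LOEUF transcript", {
  u <- shared_universe()
  ft <- shared_features()
  agg <- tapply(u$constraints$loeuf, u$constraints$symbol, min)
  expect_equal(ft$features$loeuf,
               as.numeric(agg[ft$features$symbol]))
  expect_error(assemble_feature_table(
    within(u, genes <- rbind(genes, genes[1, ]))), "duplicate")
})

test_that("undefined tau propagates to the mask only", {
  u <- generate_universe(synth_config(n_genes = 30, seed = 77))
  u$expression[3, ] <- 0   # silence one gene everywhere
  ft <- assemble_feature_table(u)
  sym <- rownames(u$expression)[3]
  row <- ft$features[ft$features$symbol == sym, ]
  expect_true(is.na(row$tau_1) && is.na(row$tau_2) && is.na(row$tau_all))
  masked <- colnames(ft$mask)[ft$mask[sym, ]]
  expect_setequal(masked, c("tau_1", "tau_2", "tau_all"))
  expect_equal(sum(ft$mask) , 3)
})
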