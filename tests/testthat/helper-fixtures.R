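# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env()

shared_universe <- function() {
  if (is.null(.fixtures$u))
    .fixtures$u <- generate_universe(synth_config(n_genes = 150, seed = 42))
  .fixtures$u
}

shared_annotated <- function() {
  if (is.null(.fixtures$ann))
    .fixtures$ann <- annotate_genes(shared_universe())
  .fixtures$ann
}

shared_features <- function() {
  if (is.null(.fixtures$ft))
    .fixtures$ft <- assemble_feature_table(shared_universe(),
                                           shared_annotated())
  .fixtures$ft
}

# independent two-sided Fisher p: plain choose() enumeration over all tables
# with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  supp <- lo:hi
  probs <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  obs <- probs[supp == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# independent CpG density: character-by-character dinucleotide scan
oracle_cpg <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  n_c <- sum(chars == "C"); n_g <- sum(chars == "G")
  if (n_c == 0 || n_g == 0) return(NA_real_)
  n_cg <- sum(chars[-n] == "C" & chars[-1] == "G")
  n_cg / (n_c * n_g) * n
}

# independent tau: literal formula evaluation
oracle_tau <- function(tpm) {
  v <- log2(tpm + 1)
  x <- v / max(v)
  sum(1 - x) / (length(v) - 1)
}
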