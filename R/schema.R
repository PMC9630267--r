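#' The 83-column feature schema
#'
#' Returns the canonical schema of the per-gene feature table used throughout
#' the package: 83 named numeric features in six groups. The composition
#' mirrors the feature families used for X-linked disorder-gene prediction:
#' 35 population-constraint metrics (gnomAD-style), 2 nucleotide-conservation
#' scores, 35 expression features stratified by sex (19 adult multi-tissue,
#' 16 developmental brain), 4 gene-structure attributes, 2 chromosomal-position
#' distances and 5 paralogue summaries.
#'
#' @return A data.frame with columns `feature` and `group`, one row per
#'   feature, in canonical column order.
#' @export
#' @examples
#' nrow(feature_schema())  # 83
feature_schema <- function() {
  constraint <- c(
    "loeuf", "mis_z", "syn_z", "lof_z", "pli", "pnull", "prec",
    "max_af", "classic_caf",
    "oe_lof", "oe_lof_lower", "oe_mis", "oe_mis_lower", "oe_mis_upper",
    "oe_mis_pphen", "oe_syn", "oe_syn_lower", "oe_syn_upper",
    "obs_lof", "exp_lof", "obs_mis", "exp_mis", "obs_syn", "exp_syn",
    "obs_mis_pphen", "exp_mis_pphen",
    "possible_lof", "possible_mis", "possible_syn",
    "mu_lof", "mu_mis", "mu_syn",
    "obs_hom_lof", "exp_hom_lof", "n_sites_lof"
  )
  conservation <- c("exon_score", "promoter_score")
  adult <- c(
    as.vector(outer(c("mean", "var"),
                    as.vector(outer(c("Cereb", "Brain", "Nerve", "All"),
                                    c("F", "M"), paste, sep = "_")),
                    paste, sep = "_")),
    "tau_1", "tau_2", "tau_all"
  )
  devel <- as.vector(outer(c("mean", "var"),
                           as.vector(outer(c("Pre", "Post1", "Post2", "Post"),
                                           c("F", "M"), paste, sep = "_")),
                           paste, sep = "_"))
  structure <- c("cds_length", "exon_count", "transcript_length", "promoter_cpg")
  position <- c("dist_centromere", "dist_telomere")
  paralogue <- c("n_paralogues", "n_close_paralogues",
                 "max_target_pct", "max_query_pct", "mean_target_pct")
  data.frame(
    feature = c(constraint, conservation, adult, devel, structure, position,
                paralogue),
    group = rep(c("constraint", "conservation", "expression_adult",
                  "expression_devel", "structure", "position", "paralogue"),
                times = c(length(constraint), length(conservation),
                          length(adult), length(devel), length(structure),
                          length(position), length(paralogue))),
    stringsAsFactors = FALSE
  )
}

#' @rdname feature_schema
#' @export
feature_names <- function() feature_schema()$feature
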