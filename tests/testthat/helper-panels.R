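# In-code builders for the five-SNP instrument panel and variants of it,
# so tests can perturb alleles/signs without touching the packaged files.

panel_table <- function(name, scale = c(hcy = "linear", t2d = "lnor",
                                        glucose = "linear",
                                        insulin = "linear")[[name]]) {
  trait <- if (name == "hcy") "exposure" else name
  read_summary_table(panel_fixture(name), scale = scale, trait = trait)
}

# a small synthetic two-SNP association table built from raw numbers
mini_assoc <- function(betas, ses, scale = "linear", trait = "trait",
                       alleles = NULL, eafs = NULL) {
  m <- length(betas)
  snp_assoc(data.frame(
    rsid = sprintf("rs%d", seq_len(m)),
    gene = rep(NA_character_, m),
    effect_allele = if (is.null(alleles)) rep("A", m) else alleles,
    eaf = if (is.null(eafs)) rep(NA_real_, m) else eafs,
    beta = betas, se = ses, p = rep(NA_real_, m),
    stringsAsFactors = FALSE), scale = scale, trait = trait)
}

# flip a stated record to its other allele: the reported association is the
# same, expressed for the unreported allele; the new base avoids both the
# current base and its complement so no strand ambiguity is introduced
flip_record <- function(df, rsid, new_allele = NULL) {
  i <- which(df$rsid == rsid)
  if (is.null(new_allele)) {
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    cur <- df$effect_allele[i]
    new_allele <- setdiff(c("A", "C", "G", "T"), c(cur, comp[[cur]]))[1]
  }
  df$beta[i] <- -df$beta[i]
  df$eaf[i] <- 1 - df$eaf[i]
  df$effect_allele[i] <- new_allele
  df
}

numeric_cols <- function(assoc) {
  as.data.frame(assoc)[, c("rsid", "eaf", "beta", "se")]
}
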