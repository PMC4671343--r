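VALID_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Construct a per-SNP association table
#'
#' A `snp_assoc` is a data frame holding one SNP-trait association per row:
#' rsid, locus label, effect allele, effect-allele frequency, per-allele
#' effect (`beta`), its standard error, and p-value. The trait scale
#' (`"linear"` for continuous traits, `"lnor"` for log odds ratios of a
#' binary trait) travels with the table as an attribute so downstream
#' estimators can refuse to exponentiate a linear effect.
#'
#' @param df data frame with columns `rsid`, `effect_allele`, `beta`, `se`
#'   and optionally `gene`, `eaf`, `p`.
#' @param scale `"linear"` or `"lnor"`.
#' @param trait trait name carried into reports.
#' @return a `snp_assoc` data frame.
#' @export
snp_assoc <- function(df, scale = c("linear", "lnor"), trait = "trait") {
  scale <- match.arg(scale)
  mandatory <- c("rsid", "effect_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("summary table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$gene)) df$gene <- NA_character_
  if (is.null(df$eaf)) df$eaf <- NA_real_
  if (is.null(df$p)) df$p <- NA_real_
  df <- df[, c("rsid", "gene", "effect_allele", "eaf", "beta", "se", "p")]
  df$rsid <- as.character(df$rsid)
  df$gene <- as.character(df$gene)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  validate_snp_assoc(df)
  structure(df, scale = scale, trait = trait,
            class = c("snp_assoc", "data.frame"))
}

validate_snp_assoc <- function(df) {
  dup <- unique(df$rsid[duplicated(df$rsid)])
  if (length(dup) > 0) {
    stop("duplicated rsid(s) in summary table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_allele <- !(df$effect_allele %in% c(VALID_BASES, "OTHER", "other"))
  if (any(bad_allele)) {
    stop("invalid effect allele for ",
         paste(df$rsid[bad_allele], collapse = ", "),
         " (must be one of A/C/G/T)", call. = FALSE)
  }
  if (any(!is.finite(df$beta))) {
    stop("non-finite beta for ",
         paste(df$rsid[!is.finite(df$beta)], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$se) | df$se <= 0)) {
    stop("standard errors must be > 0; offending rsid(s): ",
         paste(df$rsid[!is.finite(df$se) | df$se <= 0], collapse = ", "),
         call. = FALSE)
  }
  eaf_bad <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  if (any(eaf_bad)) {
    stop("effect-allele frequencies must lie in (0, 1); offending rsid(s): ",
         paste(df$rsid[eaf_bad], collapse = ", "), call. = FALSE)
  }
  p_bad <- !is.na(df$p) & (df$p <= 0 | df$p > 1)
  if (any(p_bad)) {
    stop("p-values must lie in (0, 1]; offending rsid(s): ",
         paste(df$rsid[p_bad], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read a GWAS summary-statistics table
#'
#' Reads the tab-separated summary-statistic dialect used throughout the
#' package: a mandatory header naming at least `rsid`, `effect_allele`,
#' `beta`, `se`, with optional `gene`, `eaf`, `p` columns. `"."` or an
#' empty field denotes a missing optional value. Row order is preserved.
#'
#' @param path file path.
#' @param scale trait scale, `"linear"` or `"lnor"`.
#' @param trait trait name; defaults to the file name without extension.
#' @param or_input if `TRUE` the `beta` column holds odds ratios and is
#'   converted to the lnOR scale by natural log at load time (the `se`
#'   column must already be on the log scale, as GWAS consortia report it).
#' @return a [snp_assoc] table.
#' @export
read_summary_table <- function(path, scale = c("linear", "lnor"),
                               trait = NULL, or_input = FALSE) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("no such summary table: ", path, call. = FALSE)
  if (is.null(trait)) trait <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           na.strings = c(".", "", "NA"),
                           check.names = FALSE, fileEncoding = "UTF-8")
  mandatory <- c("rsid", "effect_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("summary table ", basename(path), " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("beta", "se", "eaf", "p")) {
    if (is.null(raw[[col]])) next
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(num))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at data row ",
           bad[1], " of ", basename(path), call. = FALSE)
    }
    raw[[col]] <- num
  }
  if (nrow(raw) == 0) {
    raw <- data.frame(rsid = character(), gene = character(),
                      effect_allele = character(), eaf = numeric(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  }
  if (or_input) {
    if (scale != "lnor") {
      stop("or_input = TRUE only makes sense for an lnOR-scale trait",
           call. = FALSE)
    }
    if (any(raw$beta <= 0)) {
      stop("odds ratios must be positive to take logs; offending row ",
           which(raw$beta <= 0)[1], call. = FALSE)
    }
    raw$beta <- log(raw$beta)
  }
  snp_assoc(raw, scale = scale, trait = trait)
}

#' Write a summary-statistics table
#'
#' Writes the same tab-separated dialect [read_summary_table()] reads,
#' with numeric fields at full double precision so a write/read round trip
#' is exact. Missing optional values are written as `"."`.
#'
#' @param x a [snp_assoc] table.
#' @param path output file path.
#' @export
write_summary_table <- function(x, path) {
  out <- as.data.frame(x)
  fmt <- function(v) ifelse(is.na(v), ".", sprintf("%.17g", v))
  out$eaf <- fmt(out$eaf)
  out$beta <- fmt(out$beta)
  out$se <- fmt(out$se)
  out$p <- fmt(out$p)
  out$gene <- ifelse(is.na(out$gene), ".", out$gene)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

flip_assoc <- function(df, idx) {
  df$beta[idx] <- -df$beta[idx]
  df$eaf[idx] <- ifelse(is.na(df$eaf[idx]), NA_real_, 1 - df$eaf[idx])
  df$effect_allele[idx] <- "other"
  df
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns one exposure table and one or more outcome tables to the
#' exposure-increasing allele, the convention under which all score and
#' Wald-ratio estimation here operates. SNPs are matched by exact rsid;
#' the harmonized set is the intersection, ordered as in the exposure
#' table. Any SNP whose exposure beta is negative is flipped (beta
#' negated, EAF complemented, effect allele re-labelled `"other"` because
#' the non-effect allele is not carried in this dialect), and an outcome
#' record is flipped identically whenever its stated effect allele
#' disagrees with the harmonized exposure allele. Alleles are assumed
#' forward-strand; a complementary-base disagreement (possible strand
#' mismatch) is flipped with a warning.
#'
#' @param exposure a [snp_assoc] table for the exposure.
#' @param outcomes a single [snp_assoc] table or a named list of them.
#' @return an `instrument_set`: list with elements `snps` (rsid order),
#'   `exposure`, `outcomes` (named list), `exposure_name`, and `flips`
#'   (a data frame logging every flip and drop).
#' @export
harmonize <- function(exposure, outcomes = list()) {
  if (inherits(exposure, "instrument_set") && length(outcomes) == 0) {
    return(harmonize(exposure$exposure, exposure$outcomes))
  }
  stopifnot(inherits(exposure, "snp_assoc"))
  if (inherits(outcomes, "snp_assoc")) {
    outcomes <- stats::setNames(list(outcomes), attr(outcomes, "trait"))
  }
  if (length(outcomes) > 0 && is.null(names(outcomes))) {
    names(outcomes) <- vapply(outcomes, attr, "", "trait")
  }

  log_rows <- list()
  note <- function(rsid, table, action) {
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      rsid = rsid, table = table, action = action, stringsAsFactors = FALSE)
  }

  exp_df <- as.data.frame(exposure)
  original_allele <- stats::setNames(exp_df$effect_allele, exp_df$rsid)
  neg <- which(exp_df$beta < 0)
  if (length(neg) > 0) {
    for (i in neg) note(exp_df$rsid[i], "exposure", "flipped_to_increasing_allele")
    exp_df <- flip_assoc(exp_df, neg)
  }

  keep <- exp_df$rsid
  harmonized_outcomes <- list()
  for (nm in names(outcomes)) {
    out_df <- as.data.frame(outcomes[[nm]])
    missing <- setdiff(keep, out_df$rsid)
    if (length(missing) > 0) {
      warning("outcome '", nm, "' is missing rsid(s) ",
              paste(missing, collapse = ", "),
              "; they are dropped from the instrument set", call. = FALSE)
      for (r in missing) note(r, nm, "dropped_missing_in_outcome")
      keep <- setdiff(keep, missing)
    }
  }
  if (length(keep) == 0 && length(outcomes) > 0) {
    stop("no rsid is shared between the exposure and every outcome table",
         call. = FALSE)
  }
  exp_df <- exp_df[match(keep, exp_df$rsid), , drop = FALSE]
  rownames(exp_df) <- NULL

  for (nm in names(outcomes)) {
    out_df <- as.data.frame(outcomes[[nm]])
    out_df <- out_df[match(keep, out_df$rsid), , drop = FALSE]
    rownames(out_df) <- NULL
    disagree <- which(out_df$effect_allele != exp_df$effect_allele)
    for (i in disagree) {
      exp_allele <- exp_df$effect_allele[i]
      out_allele <- out_df$effect_allele[i]
      orig <- original_allele[[out_df$rsid[i]]]
      if (exp_allele %in% VALID_BASES && out_allele %in% VALID_BASES &&
          COMPLEMENT[[exp_allele]] == out_allele) {
        warning("rsid ", out_df$rsid[i], " in outcome '", nm,
                "': effect allele ", out_allele,
                " is the base-complement of the exposure allele ", exp_allele,
                "; assuming forward strand and flipping to the other allele",
                call. = FALSE)
      } else if (exp_allele == "other" && out_allele != orig &&
                 out_allele %in% VALID_BASES) {
        # exposure was sign-flipped so its harmonized allele is unnamed; an
        # outcome allele differing from the originally reported one is taken
        # to already sit on the exposure-increasing allele
        next
      }
      note(out_df$rsid[i], nm, "flipped_to_exposure_allele")
      out_df <- flip_assoc(out_df, i)
      # a flipped outcome record now refers to the same (unnamed) allele as
      # a flipped exposure record; label it to match
      out_df$effect_allele[i] <- exp_df$effect_allele[i]
    }
    harmonized_outcomes[[nm]] <- structure(
      out_df, scale = attr(outcomes[[nm]], "scale"), trait = nm,
      class = c("snp_assoc", "data.frame"))
  }

  exposure_h <- structure(exp_df, scale = attr(exposure, "scale"),
                          trait = attr(exposure, "trait"),
                          class = c("snp_assoc", "data.frame"))
  stopifnot(all(exposure_h$beta >= 0))
  flips <- if (length(log_rows) > 0) {
    do.call(rbind, log_rows)
  } else {
    data.frame(rsid = character(), table = character(), action = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(snps = keep,
                 exposure = exposure_h,
                 outcomes = harmonized_outcomes,
                 exposure_name = attr(exposure, "trait"),
                 flips = flips),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", length(x$snps), "SNPs, exposure '",
      x$exposure_name, "'\n", sep = "")
  cat("Outcomes:", if (length(x$outcomes) > 0)
    paste(names(x$outcomes), collapse = ", ") else "(none)", "\n")
  if (nrow(x$flips) > 0) {
    cat("Harmonization actions:\n")
    print(x$flips, row.names = FALSE)
  } else {
    cat("Harmonization actions: none (tables already aligned)\n")
  }
  invisible(x)
}

#' Path to a packaged summary-statistics fixture
#'
#' The five-SNP homocysteine instrument panel and its outcome associations
#' (type 2 diabetes on the lnOR scale, fasting glucose in mmol/L, ln
#' fasting insulin), transcribed from the published genome-wide
#' meta-analyses that the panel was drawn from.
#'
#' @param name one of `"hcy"`, `"t2d"`, `"glucose"`, `"insulin"`.
#' @return file path inside the installed package.
#' @export
panel_fixture <- function(name = c("hcy", "t2d", "glucose", "insulin")) {
  name <- match.arg(name)
  system.file("extdata", paste0("table1_", name, ".tsv"),
              package = "hcymr", mustWork = TRUE)
}
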