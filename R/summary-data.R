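VALID_BASES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistics dataset
#'
#' A `summary_dataset` holds one association record per variant for a single
#' trait: identifier, genomic position, effect and other allele, effect-allele
#' frequency, per-allele effect size (`beta`, in SD units for quantitative
#' traits and log-odds for binary traits), its standard error, two-sided
#' p-value, and per-variant sample size.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'   `eaf` may be `NA` (frequency-free sources); all other fields must pass
#'   the per-record invariants (see Details).
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_total total sample size of the study. Defaults to the maximum
#'   per-variant `n`.
#' @param n_cases number of cases (binary traits only), must be `< n_total`.
#'
#' @details Per-record invariants: alleles are single bases A/C/G/T and
#'   differ from each other; `se > 0`; `eaf` in (0,1) when present;
#'   `pvalue` in (0,1]; `pos >= 1`; `n > 0`. `variant_id` must be unique.
#'
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_name, trait_type = c("quantitative", "binary"),
                            n_total = NULL, n_cases = NULL) {
  trait_type <- match.arg(trait_type)
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pvalue", "n")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[required]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  bad <- invalid_record_mask(records)
  if (any(bad)) {
    stop(sum(bad), " record(s) violate summary-statistic invariants; ",
         "use read_summary_stats() for tolerant filtering")
  }
  if (anyDuplicated(records$variant_id)) stop("variant_id values must be unique")
  if (is.null(n_total)) {
    n_total <- if (nrow(records) > 0) max(records$n) else 0L
  }
  if (!is.null(n_cases)) {
    if (trait_type != "binary") stop("n_cases only meaningful for binary traits")
    if (n_cases >= n_total) stop("n_cases must be smaller than n_total")
  }
  rownames(records) <- NULL
  structure(
    list(trait_name = as.character(trait_name), trait_type = trait_type,
         records = records, n_total = as.numeric(n_total),
         n_cases = if (is.null(n_cases)) NULL else as.numeric(n_cases)),
    class = "summary_dataset"
  )
}

# TRUE for rows violating the VariantRecord invariants; NA eaf is tolerated.
invalid_record_mask <- function(records) {
  with(records, {
    bad_allele <- !(effect_allele %in% VALID_BASES) |
      !(other_allele %in% VALID_BASES) |
      effect_allele == other_allele
    bad_num <- is.na(beta) | is.na(se) | se <= 0 |
      is.na(pvalue) | pvalue <= 0 | pvalue > 1 |
      is.na(pos) | pos < 1 | is.na(n) | n <= 0
    bad_eaf <- !is.na(eaf) & (eaf <= 0 | eaf >= 1)
    bad_allele | bad_num | bad_eaf | is.na(variant_id) | variant_id == ""
  })
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s), %d variants, n_total = %s%s\n",
              x$trait_name, x$trait_type, nrow(x$records),
              format(x$n_total, big.mark = ","),
              if (!is.null(x$n_cases)) sprintf(" (%s cases)", format(x$n_cases, big.mark = ",")) else ""))
  invisible(x)
}

#' @export
length.summary_dataset <- function(x) nrow(x$records)

#' Gene region with flank
#'
#' Closed 1-based interval on a chromosome plus a symmetric flank; the
#' effective cis window is `[start - flank, end + flank]`, both ends
#' inclusive. Typical use: a drug-target gene footprint with a 10 kb flank
#' for lipid-GWAS instruments or a 100 kb flank for pQTL/eQTL instruments
#' where power is limited.
#'
#' @param chrom chromosome label (character).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param flank non-negative flank in base pairs (default 0).
#' @return An object of class `gene_region`.
#' @export
gene_region <- function(chrom, start, end, flank = 0) {
  start <- as.numeric(start); end <- as.numeric(end); flank <- as.numeric(flank)
  if (is.na(start) || is.na(end) || start > end) stop("require start <= end")
  if (is.na(flank) || flank < 0) stop("flank must be >= 0")
  structure(list(chrom = as.character(chrom), start = start, end = end, flank = flank),
            class = "gene_region")
}

#' @export
print.gene_region <- function(x, ...) {
  cat(sprintf("<gene_region> %s:%s-%s (flank %s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$flank, big.mark = ",")))
  invisible(x)
}

#' Test which positions fall in a flanked region
#' @param region a [gene_region()].
#' @param chrom,pos vectors of chromosome labels and positions.
#' @return logical vector.
#' @export
in_region <- function(region, chrom, pos) {
  stopifnot(inherits(region, "gene_region"))
  chrom == region$chrom & pos >= (region$start - region$flank) &
    pos <= (region$end + region$flank)
}

default_column_map <- function() {
  c(variant_id = "variant_id", chrom = "chromosome", pos = "base_pair_location",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "effect_allele_frequency", beta = "beta", se = "standard_error",
    pvalue = "p_value", n = "n")
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Expects a header row; columns are located through `column_map`, a named
#' character vector mapping internal field names to file column names. The
#' default map follows GWAS-SSF-like naming (`variant_id`, `chromosome`,
#' `base_pair_location`, `effect_allele`, `other_allele`,
#' `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`).
#' Rows violating the record invariants (zero SE, out-of-range p or eaf,
#' non-ACGT alleles, ...) are dropped with a warning reporting the count.
#' A missing `eaf` column is tolerated (frequencies become `NA`, which
#' disables frequency-based palindromic resolution in [harmonize()]).
#'
#' @param path file path.
#' @param column_map named character vector; see Details. Only names present
#'   in the default map are used; omitted names fall back to the default.
#' @inheritParams summary_dataset
#' @return A [summary_dataset()].
#' @export
read_summary_stats <- function(path, trait_name = basename(path),
                               trait_type = c("quantitative", "binary"),
                               column_map = default_column_map(),
                               n_total = NULL, n_cases = NULL) {
  trait_type <- match.arg(trait_type)
  full_map <- default_column_map()
  full_map[names(column_map)] <- column_map
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  optional <- "eaf"
  need <- setdiff(names(full_map), optional)
  absent <- need[!(full_map[need] %in% names(raw))]
  if (length(absent) > 0) {
    stop("mandatory column(s) not found in ", path, ": ",
         paste(full_map[absent], collapse = ", "))
  }
  records <- data.frame(variant_id = as.character(raw[[full_map["variant_id"]]]),
                        chrom = as.character(raw[[full_map["chrom"]]]),
                        pos = as.numeric(raw[[full_map["pos"]]]),
                        effect_allele = toupper(as.character(raw[[full_map["effect_allele"]]])),
                        other_allele = toupper(as.character(raw[[full_map["other_allele"]]])),
                        eaf = if (full_map["eaf"] %in% names(raw)) as.numeric(raw[[full_map["eaf"]]]) else NA_real_,
                        beta = as.numeric(raw[[full_map["beta"]]]),
                        se = as.numeric(raw[[full_map["se"]]]),
                        pvalue = as.numeric(raw[[full_map["pvalue"]]]),
                        n = as.numeric(raw[[full_map["n"]]]),
                        stringsAsFactors = FALSE)
  bad <- invalid_record_mask(records)
  if (any(bad)) {
    warning(sum(bad), " of ", nrow(records),
            " rows rejected (invariant violations) while reading ", path)
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no valid rows in ", path)
  summary_dataset(records, trait_name = trait_name, trait_type = trait_type,
                  n_total = n_total, n_cases = n_cases)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Uses the same default GWAS-SSF-like column names that
#' [read_summary_stats()] expects, so a write/read round trip reproduces the
#' dataset's records exactly.
#'
#' @param dataset a [summary_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(dataset, path) {
  stopifnot(inherits(dataset, "summary_dataset"))
  out <- dataset$records
  names(out) <- default_column_map()[names(out)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

complement_allele <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effect sizes to the exposure's effect allele for every
#' variant present in both datasets (matching on `variant_id`). When the
#' outcome reports the opposite allele orientation, the outcome beta is
#' negated and its frequency replaced by `1 - eaf`. When the outcome appears
#' on the complementary strand (and `allow_strand_flip` is `TRUE`), its
#' alleles are complemented before alignment. Palindromic variants (A/T or
#' G/C) cannot be strand-resolved from alleles alone: they are aligned by
#' frequency when both frequencies are informative, and dropped whenever
#' either frequency lies within `0.5 +/- palindromic_eaf_window` (or is
#' missing). Variants whose allele pairs are incompatible under every
#' orientation are discarded with a warning.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param palindromic_eaf_window half-width `w` of the ambiguity window:
#'   palindromic variants with eaf in `[0.5 - w, 0.5 + w]` on either side
#'   are dropped. Default 0.08, a conventional conservative choice.
#' @param allow_strand_flip attempt complementary-strand resolution
#'   (default `TRUE`).
#' @return A data.frame of class `harmonized_instruments` with one row per
#'   matched (non-incompatible) variant: `variant_id`, `beta_exp`, `se_exp`,
#'   `eaf_exp`, `beta_out`, `se_out`, `eaf_out`, and `action`
#'   (`"none"`, `"swapped"`, `"strand_flipped"`, `"dropped_palindromic"`).
#'   Estimators operate on rows whose action is not `"dropped_palindromic"`;
#'   [retained_instruments()] extracts them. The number of allele-incompatible
#'   matches is stored in attribute `n_incompatible`.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08,
                      allow_strand_flip = TRUE) {
  stopifnot(inherits(exposure, "summary_dataset"), inherits(outcome, "summary_dataset"))
  if (nrow(exposure$records) == 0 || nrow(outcome$records) == 0) {
    stop("both datasets must be non-empty")
  }
  w <- palindromic_eaf_window
  ex <- exposure$records
  ou <- outcome$records
  shared <- intersect(ex$variant_id, ou$variant_id)
  if (length(shared) == 0) stop("no shared variants between exposure and outcome")
  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]

  n <- length(shared)
  action <- character(n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  keep <- rep(TRUE, n)

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (pal[i]) {
      # outcome allele pair must be the same palindromic pair, else incompatible
      same_pair <- (ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x)
      if (!same_pair) { keep[i] <- FALSE; next }
      ambiguous <- is.na(ex$eaf[i]) || is.na(ou$eaf[i]) ||
        abs(ex$eaf[i] - 0.5) <= w || abs(ou$eaf[i] - 0.5) <= w
      if (ambiguous) { action[i] <- "dropped_palindromic"; next }
      # frequency-based orientation: effect alleles agree iff both eafs sit
      # on the same side of 0.5
      aligned <- (ex$eaf[i] < 0.5) == (ou$eaf[i] < 0.5)
      oriented_as_stated <- ea_y == ea_x && oa_y == oa_x
      if (aligned == oriented_as_stated) {
        action[i] <- "none"
      } else {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
        action[i] <- "swapped"
      }
      next
    }
    if (ea_y == ea_x && oa_y == oa_x) {
      action[i] <- "none"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "swapped"
    } else if (allow_strand_flip &&
               complement_allele(ea_y) == ea_x && complement_allele(oa_y) == oa_x) {
      action[i] <- "strand_flipped"
    } else if (allow_strand_flip &&
               complement_allele(ea_y) == oa_x && complement_allele(oa_y) == ea_x) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "strand_flipped"
    } else {
      keep[i] <- FALSE
    }
  }
  n_incompatible <- sum(!keep)
  if (n_incompatible > 0) {
    warning(n_incompatible, " variant(s) discarded: allele pairs incompatible ",
            "between exposure and outcome")
  }
  out <- data.frame(variant_id = shared,
                    beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
                    beta_out = beta_out, se_out = ou$se, eaf_out = eaf_out,
                    action = action, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) stop("no instruments matchable between the datasets")
  structure(out, class = c("harmonized_instruments", "data.frame"),
            n_incompatible = n_incompatible)
}

#' Retained (non-dropped) harmonized instruments
#' @param h a `harmonized_instruments` data.frame from [harmonize()].
#' @return The subset of rows usable for estimation.
#' @export
retained_instruments <- function(h) {
  stopifnot(inherits(h, "harmonized_instruments"))
  h[h$action != "dropped_palindromic", , drop = FALSE]
}
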