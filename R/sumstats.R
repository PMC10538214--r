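#' GWAS summary-statistics tables
#'
#' A `sumstats` object is a validated data frame of per-variant association
#' summaries for one trait, one row per variant, with columns
#' `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`. Betas are on the log-odds scale for binary
#' traits and in standard-deviation units for continuous traits; `eaf` is
#' the effect-allele frequency and may be missing (`NA`).
#'
#' @param df data frame carrying the columns above (`chrom`/`pos` optional).
#' @param trait trait label stored as an attribute.
#' @return A `sumstats` data frame. Rows failing validation are removed and
#'   reported in the `rejects` attribute (a data frame of `line`, `variant_id`,
#'   `reason`), never silently dropped.
#' @export
sumstats <- function(df, trait = "trait") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos")) if (is.null(df[[col]])) df[[col]] <- NA
  mandatory <- c("variant_id", "effect_allele", "other_allele", "eaf",
                 "beta", "se", "pval", "n")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  reason <- vapply(seq_len(nrow(df)), function(i) {
    r <- character(0)
    if (is.na(df$variant_id[i]) || !nzchar(df$variant_id[i]))
      r <- c(r, "missing variant id")
    if (!(df$effect_allele[i] %in% c("A", "C", "G", "T")) ||
        !(df$other_allele[i] %in% c("A", "C", "G", "T")))
      r <- c(r, "non-ACGT allele")
    else if (df$effect_allele[i] == df$other_allele[i])
      r <- c(r, "identical alleles")
    if (is.na(df$beta[i]) || !is.finite(df$beta[i]))
      r <- c(r, "missing beta")
    if (is.na(df$se[i]) || !is.finite(df$se[i]) || df$se[i] <= 0)
      r <- c(r, "nonpositive se")
    if (is.na(df$pval[i]) || df$pval[i] <= 0 || df$pval[i] > 1)
      r <- c(r, "p-value outside (0,1]")
    if (!is.na(df$eaf[i]) && (df$eaf[i] < 0 || df$eaf[i] > 1))
      r <- c(r, "eaf outside [0,1]")
    if (is.na(df$n[i]) || df$n[i] <= 0)
      r <- c(r, "nonpositive n")
    paste(r, collapse = "; ")
  }, character(1))

  bad <- nzchar(reason)
  rejects <- data.frame(line = which(bad) + 1L,
                        variant_id = df$variant_id[bad],
                        reason = reason[bad],
                        stringsAsFactors = FALSE)
  orig_line <- which(!bad) + 1L
  df <- df[!bad, , drop = FALSE]

  # duplicate ids: keep the smallest p-value (ties: first in p-then-id order)
  if (anyDuplicated(df$variant_id)) {
    ord <- order(df$pval, df$variant_id)
    dup <- ord[duplicated(df$variant_id[ord])]
    rejects <- rbind(rejects, data.frame(
      line = orig_line[dup], variant_id = df$variant_id[dup],
      reason = "duplicate variant_id (kept smallest p)",
      stringsAsFactors = FALSE))
    df <- df[-dup, , drop = FALSE]
  }

  df <- df[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
               "eaf", "beta", "se", "pval", "n")]
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            trait = trait, rejects = rejects)
}

#' Default summary-statistics column map
#'
#' Maps the package's standard field names to the column headers of the
#' default tab-separated dialect. Supply a modified copy to [read_sumstats()]
#' for files using other headers (e.g. GWAS-SSF's `standard_error`,
#' `effect_allele_frequency`, `p_value`).
#' @export
default_column_map <- function() {
  c(variant_id = "variant_id", chrom = "chromosome", pos = "position",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n")
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' @param path path to a UTF-8, tab-separated file with a header row.
#' @param column_map named character vector mapping standard field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column headers. `chrom`/`pos`
#'   may be absent; the other eight are mandatory.
#' @param trait trait label.
#' @param missing token representing missing values (default `"NA"`).
#' @return A [sumstats] object; invalid rows are reported via the `rejects`
#'   attribute with their line number and reason.
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          trait = NULL, missing = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = missing,
                           check.names = FALSE)
  map <- default_column_map()
  map[names(column_map)] <- column_map
  mandatory <- setdiff(names(map), c("chrom", "pos"))
  absent <- mandatory[!(map[mandatory] %in% names(raw))]
  if (length(absent) > 0) {
    stop("configuration error: mapped column(s) not in file: ",
         paste(map[absent], collapse = ", "))
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(map)) {
    df[[field]] <- if (map[[field]] %in% names(raw)) raw[[map[[field]]]] else NA
  }
  out <- sumstats(df, trait = trait %||% basename(path))
  nrej <- nrow(attr(out, "rejects"))
  if (nrej > 0) {
    message(nrej, " row(s) of ", basename(path),
            " failed validation; see attr(x, \"rejects\")")
  }
  out
}

#' Write summary statistics in the default tab-separated dialect
#'
#' Values are printed with 17 significant digits so that
#' `read_sumstats(write_sumstats(x))` reproduces `x` exactly.
#'
#' @param records a [sumstats] object (or conforming data frame).
#' @param path output path.
#' @param missing token written for missing values.
#' @export
write_sumstats <- function(records, path, missing = "NA") {
  map <- default_column_map()
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), missing, formatC(x, digits = 17, format = "g"))
    else ifelse(is.na(x), missing, as.character(x))
  }
  out <- data.frame(row.names = seq_len(nrow(records)))
  for (field in names(map)) out[[map[[field]]]] <- fmt(records[[field]])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(unname(map), collapse = "\t"), con)
  if (nrow(out) > 0) {
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics for '", attr(x, "trait"), "': ",
      nrow(x), " variants", sep = "")
  nrej <- NROW(attr(x, "rejects"))
  if (nrej > 0) cat(" (", nrej, " rejected rows)", sep = "")
  cat("\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}
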