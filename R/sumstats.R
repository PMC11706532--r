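# Canonical per-SNP association table ("summary statistics") and its I/O.
#
# The table is an ordinary tibble with class "sumstats" prepended and a
# provenance log of filter steps stored in attr(x, "steps").  Canonical
# columns (lowercase in the tibble, uppercase in the on-disk TSV):
#   chrom, pos, rsid, ea, nea, beta, se, p, eaf

CANONICAL_FIELDS <- c("chrom", "pos", "rsid", "ea", "nea",
                      "beta", "se", "p", "eaf")
CANONICAL_HEADERS <- c(chrom = "CHR", pos = "POS", rsid = "SNP", ea = "EA",
                       nea = "NEA", beta = "BETA", se = "SE", p = "P",
                       eaf = "EAF")

# common header aliases, matched case-insensitively when no explicit map is given
FIELD_ALIASES <- list(
  chrom = c("chr", "chrom", "chromosome", "#chr", "#chrom"),
  pos   = c("pos", "bp", "position", "base_pair_location", "pos_bp"),
  rsid  = c("snp", "rsid", "rs_id", "markername", "marker_name", "variant_id",
            "id", "snpid"),
  ea    = c("ea", "a1", "effect_allele", "allele1", "alt", "eff_allele"),
  nea   = c("nea", "a2", "other_allele", "allele2", "ref",
            "non_effect_allele", "noneffect_allele"),
  beta  = c("beta", "b", "effect", "effect_size", "effectsize", "logor",
            "log_odds"),
  se    = c("se", "stderr", "standard_error", "sebeta", "se_beta"),
  p     = c("p", "pval", "p_value", "pvalue", "p.value", "p_val"),
  eaf   = c("eaf", "af", "freq", "frq", "effect_allele_frequency", "a1freq")
)

new_sumstats <- function(df, steps = NULL) {
  df <- as_tibble(df)
  if (is.null(steps)) {
    steps <- tibble(step = "load", n_before = nrow(df), n_after = nrow(df))
  }
  structure(df, steps = steps,
            class = c("sumstats", class(tibble())))
}

log_step <- function(ss, step, n_before, n_after) {
  steps <- dplyr::bind_rows(
    attr(ss, "steps"),
    tibble(step = step, n_before = as.integer(n_before),
           n_after = as.integer(n_after))
  )
  attr(ss, "steps") <- steps
  ss
}

#' Provenance log of filter steps applied to a summary-statistics table
#'
#' @param ss a `sumstats` table.
#' @return a tibble with columns `step`, `n_before`, `n_after`, one row per
#'   load/cleaning/filter step applied so far.
#' @export
filter_log <- function(ss) {
  attr(ss, "steps") %null% tibble(step = character(),
                                  n_before = integer(), n_after = integer())
}

#' Coerce a data frame to a canonical summary-statistics table
#'
#' Accepts canonical lowercase names (`chrom`, `pos`, `rsid`, `ea`, `nea`,
#' `beta`, `se`, `p`, `eaf`), the uppercase on-disk headers, or any alias the
#' auto-detection in [read_sumstats()] recognizes.  Alleles are uppercased and
#' chromosome labels normalized; absent canonical fields stay absent. Nothing
#' is filtered.
#'
#' @param df a data frame of per-SNP association rows.
#' @param colmap optional named character vector mapping canonical field names
#'   to source column names, e.g. `c(rsid = "MarkerName", p = "P.value")`.
#' @return a `sumstats` tibble.
#' @export
as_sumstats <- function(df, colmap = NULL) {
  df <- as_tibble(df)
  map <- resolve_colmap(names(df), colmap)
  out <- tibble(.rows = nrow(df))
  for (f in names(map)) out[[f]] <- df[[map[[f]]]]
  if ("chrom" %in% names(out)) out$chrom <- normalize_chrom(out$chrom)
  if ("pos" %in% names(out))   out$pos <- as.integer(out$pos)
  if ("rsid" %in% names(out))  out$rsid <- as.character(out$rsid)
  for (f in c("ea", "nea")) {
    if (f %in% names(out)) out[[f]] <- toupper(trimws(as.character(out[[f]])))
  }
  for (f in c("beta", "se", "p", "eaf")) {
    if (f %in% names(out)) out[[f]] <- as.numeric(out[[f]])
  }
  out <- out[intersect(CANONICAL_FIELDS, names(out))]
  new_sumstats(out)
}

# map canonical field -> source column; error on ambiguity / missing headers
resolve_colmap <- function(headers, colmap = NULL) {
  if (!is.null(colmap)) {
    colmap <- unlist(colmap)
    bad <- setdiff(names(colmap), CANONICAL_FIELDS)
    if (length(bad) > 0) {
      abort(paste0("unknown canonical field(s) in colmap: ",
                   paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(names(colmap))) {
      abort("each canonical field may map to at most one source column")
    }
    if (anyDuplicated(colmap)) {
      dup <- colmap[duplicated(colmap)][1]
      abort(paste0("source column '", dup,
                   "' assigned to more than one canonical field"))
    }
    missing <- setdiff(unname(colmap), headers)
    if (length(missing) > 0) {
      abort(paste0("colmap names header(s) not present in file: ",
                   paste(missing, collapse = ", ")))
    }
    return(as.list(colmap))
  }
  lh <- tolower(headers)
  map <- list()
  for (f in CANONICAL_FIELDS) {
    hits <- which(lh %in% c(f, tolower(CANONICAL_HEADERS[[f]]),
                            FIELD_ALIASES[[f]]))
    if (length(hits) > 1) {
      abort(paste0("ambiguous columns for field '", f, "': ",
                   paste(headers[hits], collapse = ", "),
                   "; supply an explicit colmap"))
    }
    if (length(hits) == 1) map[[f]] <- headers[hits]
  }
  used <- unlist(map)
  if (anyDuplicated(used)) {
    dup <- used[duplicated(used)][1]
    abort(paste0("header '", dup, "' matches more than one canonical field; ",
                 "supply an explicit colmap"))
  }
  map
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads TSV/CSV/whitespace-delimited files (optionally gzip-compressed),
#' maps source headers onto the canonical schema, normalizes chromosome
#' labels and uppercases alleles.  Rows are kept in file order and nothing is
#' filtered; cleaning is a separate, explicit step ([clean_sumstats()]).
#'
#' @param path path to the file.
#' @param colmap optional named character vector, canonical field ->
#'   source header (see [as_sumstats()]). When omitted, common aliases
#'   (A1/A2, BP, pval, ...) are auto-detected; ambiguous matches are an error.
#' @param na tokens treated as missing.
#' @return a `sumstats` tibble with the provenance log initialized.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tEA\tNEA\tBETA\tSE\tP",
#'              "rs1\tA\tG\t0.1\t0.02\t5e-8"), f)
#' read_sumstats(f)
#' @export
read_sumstats <- function(path, colmap = NULL, na = c("NA", "", ".", "NaN")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.gz$", path)) {
    lines <- readLines(gzfile(path))
    df <- data.table::fread(text = lines, na.strings = na,
                            data.table = FALSE, showProgress = FALSE)
  } else {
    df <- data.table::fread(path, na.strings = na, data.table = FALSE,
                            showProgress = FALSE)
  }
  as_sumstats(df, colmap = colmap)
}

#' Write a summary-statistics table as canonical 9-column TSV
#'
#' Always writes the full canonical header (CHR, POS, SNP, EA, NEA, BETA, SE,
#' P, EAF); absent fields are written as NA so a round trip through
#' [read_sumstats()] reproduces the table field-for-field.
#'
#' @param ss a `sumstats` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- as_tibble(ss)
  for (f in CANONICAL_FIELDS) if (!f %in% names(out)) out[[f]] <- NA
  out <- out[CANONICAL_FIELDS]
  names(out) <- unname(CANONICAL_HEADERS[CANONICAL_FIELDS])
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat("# Summary statistics:", nrow(x), "SNPs,",
      paste(intersect(CANONICAL_FIELDS, names(x)), collapse = ", "), "\n")
  NextMethod()
}
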