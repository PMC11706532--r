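# Variant map: rsid <-> (chrom, pos) lookup loaded from a .bim file or TSV.
# A user-supplied stand-in for a full dbSNP-style reference; no network access.

#' Read a variant map from a .bim file or TSV
#'
#' A variant map associates rsids with genomic coordinates (and alleles) for
#' use by [fill_coordinates()].  Accepted inputs: a PLINK `.bim` file
#' (6 whitespace-separated columns: chrom, rsid, cM, pos, A1, A2) or any
#' delimited file with headers mappable to `rsid`, `chrom`, `pos` (plus
#' optional `ref`/`a1` and `alt`/`a2`).
#'
#' @param path path to the file; `.bim` extension triggers headerless parsing.
#' @return a tibble with columns `rsid`, `chrom`, `pos`, `a1`, `a2`,
#'   deduplicated to unique rsid and unique (chrom, pos), class `variant_map`.
#' @export
read_variant_map <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.bim$", path)) {
    df <- data.table::fread(path, header = FALSE, data.table = FALSE,
                            showProgress = FALSE,
                            col.names = c("chrom", "rsid", "cm", "pos",
                                          "a1", "a2"))
  } else {
    df <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
    names(df) <- tolower(names(df))
    names(df)[names(df) == "ref"] <- "a1"
    names(df)[names(df) == "alt"] <- "a2"
    need <- c("rsid", "chrom", "pos")
    if (!all(need %in% names(df))) {
      abort("variant map TSV must have rsid, chrom and pos columns")
    }
    if (!"a1" %in% names(df)) df$a1 <- NA_character_
    if (!"a2" %in% names(df)) df$a2 <- NA_character_
  }
  vm <- tibble(rsid = as.character(df$rsid),
               chrom = normalize_chrom(df$chrom),
               pos = as.integer(df$pos),
               a1 = toupper(as.character(df$a1)),
               a2 = toupper(as.character(df$a2)))
  vm <- vm[!duplicated(vm$rsid), ]
  vm <- vm[!duplicated(paste(vm$chrom, vm$pos)), ]
  structure(vm, class = c("variant_map", class(tibble())))
}

#' Fill missing coordinates from rsids, or rsids from coordinates
#'
#' Fill-only semantics: rows that already carry the target fields are left
#' untouched. Rows whose lookup key finds no match in the map are counted in
#' the report and either dropped or retained with missing fields.
#'
#' @param ss a `sumstats` table.
#' @param vm a `variant_map` from [read_variant_map()] (or a tibble with
#'   `rsid`, `chrom`, `pos`).
#' @param direction `"rsid_to_pos"` (fill `chrom`/`pos` from `rsid`) or
#'   `"pos_to_rsid"` (fill `rsid` from `chrom` + `pos`).
#' @param drop_unmatched drop rows whose key has no match in the map
#'   (default `FALSE`: retain with missing fields).
#' @return the updated `sumstats` table; the number of unmatched rows is
#'   recorded in [filter_log()] and in attribute `"fill_report"`.
#' @export
fill_coordinates <- function(ss, vm,
                             direction = c("rsid_to_pos", "pos_to_rsid"),
                             drop_unmatched = FALSE) {
  direction <- match.arg(direction)
  if (nrow(vm) == 0) abort("variant map is empty")
  n0 <- nrow(ss)
  if (direction == "rsid_to_pos") {
    if (!"rsid" %in% names(ss)) abort("rsid column required for rsid_to_pos")
    if (!"chrom" %in% names(ss)) ss$chrom <- NA_character_
    if (!"pos" %in% names(ss)) ss$pos <- NA_integer_
    need <- is.na(ss$chrom) | is.na(ss$pos)
    idx <- match(ss$rsid, vm$rsid)
    hit <- need & !is.na(idx)
    ss$chrom[hit] <- vm$chrom[idx[hit]]
    ss$pos[hit] <- vm$pos[idx[hit]]
    unmatched <- need & is.na(idx)
  } else {
    if (!all(c("chrom", "pos") %in% names(ss))) {
      abort("chrom and pos columns required for pos_to_rsid")
    }
    if (!"rsid" %in% names(ss)) ss$rsid <- NA_character_
    need <- is.na(ss$rsid)
    key_ss <- paste(normalize_chrom(ss$chrom), ss$pos)
    key_vm <- paste(vm$chrom, vm$pos)
    idx <- match(key_ss, key_vm)
    hit <- need & !is.na(idx)
    ss$rsid[hit] <- vm$rsid[idx[hit]]
    unmatched <- need & is.na(idx)
  }
  if (drop_unmatched && any(unmatched)) {
    steps <- attr(ss, "steps"); cls <- class(ss)
    ss <- ss[!unmatched, , drop = FALSE]
    attr(ss, "steps") <- steps; class(ss) <- cls
  }
  ss <- log_step(ss, paste0("fill_coordinates[", direction, "]"), n0, nrow(ss))
  attr(ss, "fill_report") <- tibble(
    direction = direction, filled = sum(hit), unmatched = sum(unmatched),
    dropped = if (drop_unmatched) sum(unmatched) else 0L)
  ss
}
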