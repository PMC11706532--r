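# Native PLINK 1 binary fileset (.bed/.bim/.fam) reader and writer.
#
# .bed layout (SNP-major, mode 0x01): magic 0x6C 0x1B, mode byte, then for
# each variant ceiling(n_samples/4) bytes; two bits per sample starting at
# the low-order bits of each byte:
#   00 = homozygous A1 (dosage 2 copies of A1), 01 = missing,
#   10 = heterozygous (1),                      11 = homozygous A2 (0).
# The dosage matrix stores the count of the A1 allele.

# byte-value -> 4 dosages lookup, built once at load time
.bed_decode_table <- local({
  codes <- c(2L, NA_integer_, 1L, 0L)   # 00, 01, 10, 11
  tab <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    for (s in 0:3) {
      tab[b + 1, s + 1] <- codes[bitwAnd(bitwShiftR(b, 2 * s), 3L) + 1]
    }
  }
  tab
})

new_ref_panel <- function(variants, dosage, fam) {
  stopifnot(ncol(dosage) == nrow(variants))
  structure(list(variants = as_tibble(variants),
                 dosage = dosage,
                 fam = as_tibble(fam)),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("# Reference panel:", nrow(x$fam), "samples x",
      nrow(x$variants), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Read a PLINK 1 binary genotype fileset
#'
#' Parses `prefix.bed` / `prefix.bim` / `prefix.fam` into a reference-panel
#' object holding variant metadata and an n_samples x n_variants dosage
#' matrix of A1-allele counts (0, 1, 2 or NA for missing).  Filesets split by
#' chromosome are supported through a `{chr}` placeholder in the prefix
#' (e.g. `"panel_chr{chr}"`): every existing chromosome file is read and the
#' variants merged in chromosome order.
#'
#' @param prefix fileset path without extension, optionally containing
#'   `{chr}`.
#' @return a `ref_panel`: list with `variants` (tibble: rsid, chrom, pos,
#'   a1, a2, cm), `dosage` (matrix, samples x variants, dimnames set to
#'   sample ids and rsids), and `fam` (tibble of the .fam columns).
#' @export
read_plink <- function(prefix) {
  if (grepl("\\{chr\\}", prefix)) {
    prefixes <- vapply(VALID_CHROMS, function(ch) sub("\\{chr\\}", ch, prefix),
                       character(1))
    prefixes <- prefixes[file.exists(paste0(prefixes, ".bed"))]
    if (length(prefixes) == 0) {
      abort(paste0("no fileset matches pattern: ", prefix))
    }
    panels <- lapply(prefixes, read_plink)
    ids <- lapply(panels, function(p) p$fam$iid)
    if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
      abort("per-chromosome filesets have differing sample sets")
    }
    return(new_ref_panel(
      variants = dplyr::bind_rows(lapply(panels, `[[`, "variants")),
      dosage = do.call(cbind, lapply(panels, `[[`, "dosage")),
      fam = panels[[1]]$fam))
  }
  for (ext in c(".bed", ".bim", ".fam")) {
    if (!file.exists(paste0(prefix, ext))) {
      abort(paste0("missing fileset member: ", prefix, ext))
    }
  }
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           data.table = FALSE, showProgress = FALSE,
                           col.names = c("chrom", "rsid", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = list(character = c(1, 2, 5, 6)))
  variants <- tibble(rsid = bim$rsid, chrom = normalize_chrom(bim$chrom),
                     pos = as.integer(bim$pos), a1 = toupper(bim$a1),
                     a2 = toupper(bim$a2), cm = as.numeric(bim$cm))
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           data.table = FALSE, showProgress = FALSE,
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  n <- nrow(fam)
  m <- nrow(variants)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK 1 .bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) {
    abort("only SNP-major .bed files are supported (mode byte != 0x01)")
  }
  body <- raw[-(1:3)]
  if (length(body) != m * bytes_per_snp) {
    abort(sprintf(".bed byte count %d inconsistent with %d samples x %d variants",
                  length(body), n, m))
  }
  # decode all bytes at once, reshape, trim padding samples
  dec <- .bed_decode_table[as.integer(body) + 1L, , drop = FALSE]
  # dec rows follow byte order: for variant j, bytes (j-1)*B+1 .. j*B, each
  # byte contributing 4 consecutive samples
  full <- matrix(t(dec), nrow = bytes_per_snp * 4, ncol = m)
  dosage <- full[seq_len(n), , drop = FALSE]
  dimnames(dosage) <- list(as.character(fam$iid), variants$rsid)
  new_ref_panel(variants, dosage, fam)
}

#' Write a reference panel as a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: encodes the dosage matrix in SNP-major mode
#' with zero padding bits, so `read_plink(write_plink(p, f))` is a fixed
#' point and writing a freshly read fileset reproduces its `.bed` bytes.
#'
#' @param panel a `ref_panel`.
#' @param prefix output path without extension.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  variants <- panel$variants
  fam <- panel$fam
  n <- nrow(fam)
  m <- nrow(variants)
  bytes_per_snp <- ceiling(n / 4)
  # dosage -> 2-bit code: 2->00, NA->01, 1->10, 0->11
  d <- panel$dosage
  code <- matrix(0L, nrow = n, ncol = m)
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  padded <- matrix(0L, nrow = bytes_per_snp * 4, ncol = m)
  padded[seq_len(n), ] <- code
  shifts <- rep(c(0L, 2L, 4L, 6L), bytes_per_snp)
  shifted <- padded * bitwShiftL(1L, shifts)   # value << shift
  grp <- rep(seq_len(bytes_per_snp), each = 4)
  bytes <- apply(shifted, 2, function(col) {
    as.integer(rowsum(col, grp))
  })
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.integer(bytes)), con)
  cm <- if ("cm" %in% names(variants)) variants$cm else 0
  bim <- data.frame(variants$chrom, variants$rsid, cm, variants$pos,
                    variants$a1, variants$a2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  data.table::fwrite(as.data.frame(fam), paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(prefix)
}
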