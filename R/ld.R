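# Pairwise linkage disequilibrium from panel dosages, and proxy search.

# index (integer) or rsid (character) -> column index
resolve_variant <- function(panel, x) {
  if (is.character(x)) {
    i <- match(x, panel$variants$rsid)
    if (is.na(i)) abort(paste0("variant not in panel: ", x))
    i
  } else {
    i <- as.integer(x)
    if (i < 1 || i > nrow(panel$variants)) abort("variant index out of range")
    i
  }
}

#' Signed LD between two panel variants
#'
#' Pearson correlation of A1-allele dosages over pairwise-complete samples.
#' The sign of `r` tells whether the two variants' A1 alleles travel together
#' (`r > 0`) or oppose (`r < 0`), which callers use to align effect
#' directions when substituting proxies.
#'
#' @param panel a `ref_panel`.
#' @param i,j variant rsids (character) or column indices (integer).
#' @return a tibble with one row: `r` (signed, in \[-1, 1\]), `r2`,
#'   `n` (pairwise-complete sample count).
#' @export
ld_r <- function(panel, i, j) {
  i <- resolve_variant(panel, i)
  j <- resolve_variant(panel, j)
  x <- panel$dosage[, i]
  y <- panel$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) abort("fewer than 2 pairwise-complete samples")
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) {
    abort("monomorphic variant: correlation undefined")
  }
  r <- cor(x, y)
  tibble(r = r, r2 = r^2, n = sum(ok))
}

# LD of one target column against a set of columns; NA where undefined
ld_with_target <- function(panel, target_idx, cand_idx) {
  x <- panel$dosage[, target_idx]
  vapply(cand_idx, function(j) {
    y <- panel$dosage[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    xs <- x[ok]; ys <- y[ok]
    if (var(xs) == 0 || var(ys) == 0) return(NA_real_)
    cor(xs, ys)
  }, numeric(1))
}

#' Find proxy variants for a target SNP
#'
#' Searches candidate variants on the target's chromosome within a distance
#' window, keeps those in LD above the threshold, and orders them by
#' descending r-squared (ties by distance, then rsid).  Each proxy carries
#' the signed `r` so callers can align effect direction.
#'
#' @param panel a `ref_panel` providing LD.
#' @param target rsid of the SNP to be proxied.
#' @param candidates character vector of candidate rsids (e.g. variants
#'   available in the outcome data); defaults to all panel variants.
#' @param r2_min minimum r-squared (default 0.8).
#' @param window_kb search window half-width in kilobases (default 500).
#' @return a tibble (`rsid`, `r`, `r2`, `distance`, `a1`, `a2`), best proxy
#'   first, with attribute `"status"`: `"ok"`, or `"no-target"` when the
#'   target is absent from the panel (empty result).
#' @export
find_proxies <- function(panel, target, candidates = NULL,
                         r2_min = 0.8, window_kb = 500) {
  empty <- tibble(rsid = character(), r = numeric(), r2 = numeric(),
                  distance = integer(), a1 = character(), a2 = character())
  ti <- match(target, panel$variants$rsid)
  if (is.na(ti)) {
    attr(empty, "status") <- "no-target"
    return(empty)
  }
  v <- panel$variants
  candidates <- candidates %null% v$rsid
  cand_idx <- which(v$rsid %in% candidates & v$rsid != target &
                    v$chrom == v$chrom[ti] &
                    abs(v$pos - v$pos[ti]) <= window_kb * 1000)
  if (length(cand_idx) == 0) {
    attr(empty, "status") <- "ok"
    return(empty)
  }
  r_all <- ld_with_target(panel, ti, cand_idx)
  keep_idx <- cand_idx[!is.na(r_all) & r_all^2 >= r2_min]
  r_keep <- r_all[!is.na(r_all) & r_all^2 >= r2_min]
  out <- tibble(rsid = v$rsid[keep_idx], r = r_keep, r2 = r_keep^2,
                distance = abs(v$pos[keep_idx] - v$pos[ti]),
                a1 = v$a1[keep_idx], a2 = v$a2[keep_idx])
  out <- out[order(-out$r2, out$distance, out$rsid), ]
  attr(out, "status") <- "ok"
  out
}
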