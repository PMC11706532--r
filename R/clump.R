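# Greedy p-value-ordered LD clumping against a reference panel.

#' LD-clump a summary-statistics table
#'
#' Greedy index-variant selection: candidates with `p <= p1` are visited in
#' ascending p order (ties by position then rsid); each unclaimed candidate
#' becomes an index and claims every unclaimed variant with `p <= p2` within
#' `kb` kilobases having r-squared >= `r2` with it.  The result contains the
#' index variants only, in their original row order, with the input's column
#' set preserved.  Variants not resolvable in the panel can neither claim
#' nor be claimed; they are dropped with their own report step.
#'
#' Defaults follow the values in wide use for human GWAS: genome-wide index
#' significance `p1 = 5e-8`, claim regardless of secondary p (`p2 = 1`),
#' `r2 = 0.01`, `kb = 250`.
#'
#' @param ss a `sumstats` table with `rsid` and `p`.
#' @param panel a `ref_panel`.
#' @param p1 index-variant p-value threshold.
#' @param p2 secondary p-value threshold for claimable variants.
#' @param r2 LD threshold.
#' @param kb window half-width in kilobases.
#' @return the clumped `sumstats` table (index variants only). Attributes:
#'   `"clump_report"` (tibble of step/removed/remaining) and
#'   `"clump_members"` (tibble `rsid`, `index_rsid` annotating which index
#'   claimed each non-index variant).
#' @export
ld_clump <- function(ss, panel, p1 = 5e-8, p2 = 1, r2 = 0.01, kb = 250) {
  if (!all(c("rsid", "p") %in% names(ss))) {
    abort("clumping requires rsid and p columns")
  }
  n0 <- nrow(ss)
  v <- panel$variants
  pidx <- match(ss$rsid, v$rsid)
  in_panel <- !is.na(pidx)
  if (n0 > 0 && !any(in_panel)) {
    ss_chr <- if ("chrom" %in% names(ss)) unique(ss$chrom) else character()
    if (length(ss_chr) > 0 && length(intersect(ss_chr, v$chrom)) == 0) {
      abort("chromosome vocabulary mismatch between summary stats and panel")
    }
  }
  work <- tibble(row = seq_len(n0), rsid = ss$rsid, p = ss$p,
                 col = pidx)[in_panel, ]
  work$chrom <- v$chrom[work$col]
  work$pos <- v$pos[work$col]

  cand <- work[!is.na(work$p) & work$p <= p1, ]
  cand <- cand[order(cand$p, cand$pos, cand$rsid), ]
  if (nrow(cand) == 0) {
    warn("no variant passes the index p-value threshold; empty result")
  }
  claimed <- setNames(rep(FALSE, nrow(work)), work$rsid)
  is_index <- claimed
  member_of <- setNames(rep(NA_character_, nrow(work)), work$rsid)
  for (k in seq_len(nrow(cand))) {
    id <- cand$rsid[k]
    if (claimed[id] || is_index[id]) next
    is_index[id] <- TRUE
    near <- which(!claimed & !is_index &
                  work$chrom == cand$chrom[k] &
                  abs(work$pos - cand$pos[k]) <= kb * 1000 &
                  !is.na(work$p) & work$p <= p2)
    if (length(near) > 0) {
      rr <- ld_with_target(panel, cand$col[k], work$col[near])
      take <- near[!is.na(rr) & rr^2 >= r2]
      claimed[take] <- TRUE
      member_of[take] <- id
    }
  }
  index_rows <- work$row[is_index[work$rsid]]
  steps <- attr(ss, "steps"); cls <- class(ss)
  out <- ss[sort(index_rows), , drop = FALSE]
  attr(out, "steps") <- steps; class(out) <- cls
  out <- log_step(out, "clump", n0, nrow(out))
  n_unresolved <- n0 - nrow(work)
  n_claimed <- sum(claimed)
  n_nonsig <- n0 - n_unresolved - n_claimed - length(index_rows)
  attr(out, "clump_report") <- tibble(
    step = c("not_in_panel", "claimed_by_index", "above_p1_unclaimed",
             "index_variants"),
    count = c(n_unresolved, n_claimed, n_nonsig, length(index_rows)))
  attr(out, "clump_members") <- tibble(
    rsid = names(member_of)[claimed],
    index_rsid = unname(member_of[claimed]))
  out
}
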