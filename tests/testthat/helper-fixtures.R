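# fixtures built in code: random harmonized tables, toy panels, tiny files

# a random analysis-ready effect table (already harmonized)
random_h <- function(n, seed, theta = 0.3, pleio_sd = 0) {
  set.seed(seed)
  bx <- rnorm(n, 0.1, 0.04)
  sx <- runif(n, 0.005, 0.02)
  sy <- runif(n, 0.005, 0.02)
  by <- theta * bx + rnorm(n, 0, sy) + rnorm(n, 0, pleio_sd)
  tibble::tibble(rsid = paste0("rs", seq_len(n)),
                 beta_exp = bx, se_exp = sx, beta_out = by, se_out = sy)
}

# a hand-built panel from an explicit dosage matrix (samples x variants)
toy_panel <- function(dosage, chrom = "1", pos = NULL,
                      a1 = NULL, a2 = NULL, rsid = NULL) {
  m <- ncol(dosage)
  n <- nrow(dosage)
  variants <- tibble::tibble(
    rsid = rsid %||% paste0("rs", seq_len(m)),
    chrom = rep(chrom, length.out = m),
    pos = pos %||% (seq_len(m) * 1000L),
    a1 = a1 %||% rep("A", m),
    a2 = a2 %||% rep("G", m),
    cm = 0)
  fam <- tibble::tibble(fid = paste0("F", seq_len(n)),
                        iid = paste0("I", seq_len(n)),
                        pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  dimnames(dosage) <- list(fam$iid, variants$rsid)
  structure(list(variants = variants, dosage = dosage, fam = fam),
            class = "ref_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# independent textbook Pearson correlation (sum formula)
cor_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# independent greedy clumping oracle: straight transcription of the
# algorithm over a precomputed full LD matrix
clump_oracle <- function(ss, panel, p1, p2, r2, kb) {
  v <- panel$variants
  keep <- ss$rsid %in% v$rsid
  tab <- ss[keep, ]
  idx <- match(tab$rsid, v$rsid)
  ldm <- suppressWarnings(
    cor(panel$dosage[, idx, drop = FALSE],
        use = "pairwise.complete.obs"))^2
  pos <- v$pos[idx]; chromv <- v$chrom[idx]
  cand_ord <- order(tab$p, pos, tab$rsid)
  cand_ord <- cand_ord[tab$p[cand_ord] <= p1]
  state <- rep("free", nrow(tab))
  for (i in cand_ord) {
    if (state[i] != "free") next
    state[i] <- "index"
    for (j in seq_len(nrow(tab))) {
      if (state[j] != "free") next
      if (chromv[j] == chromv[i] && abs(pos[j] - pos[i]) <= kb * 1000 &&
          !is.na(tab$p[j]) && tab$p[j] <= p2 &&
          !is.na(ldm[i, j]) && ldm[i, j] >= r2) {
        state[j] <- "claimed"
      }
    }
  }
  sort(tab$rsid[state == "index"])
}
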