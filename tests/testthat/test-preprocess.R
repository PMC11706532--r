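test_that("cleaning applies checks in order and reports each step", {
  ss <- as_sumstats(data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    ea = "A", nea = "G",
    beta = c(0.1, 0.2, 0.3, 0.4, 0.5),
    se = c(0.02, -0.1, 0.03, 0.04, 0.05),
    p = c(0.01, 0.02, 1.5, 0.04, 0.05)))
  out <- clean_sumstats(ss, c("drop_se_nonpositive", "drop_p_out_of_range"))
  expect_equal(nrow(out), 3)
  rep <- attr(out, "cleaning_report")
  expect_equal(rep$removed, c(1L, 1L))
  expect_equal(rep$remaining, c(4L, 3L))
  expect_error(clean_sumstats(ss, "drop_everything"), "unknown check")
})

test_that("duplicate rsids keep the lowest p, ties by first occurrence", {
  ss <- as_sumstats(data.frame(
    rsid = c("rs1", "rs1", "rs2", "rs2"),
    beta = c(1, 2, 3, 4),
    p = c(1e-4, 1e-8, 0.5, 0.5)))
  out <- clean_sumstats(ss, "drop_duplicate_rsid")
  expect_equal(out$beta[out$rsid == "rs1"], 2)   # lower p wins
  expect_equal(out$beta[out$rsid == "rs2"], 3)   # tie -> first occurrence
})

test_that("cleaning is idempotent and monotone in row count", {
  sim <- simulate_gwas_pair(sim_config(n_snps = 60, seed = 5))
  ss <- sim$exposure
  ss$se[3] <- -1
  ss$p[7] <- 2
  ss$ea[11] <- "N"
  once <- clean_sumstats(ss)
  twice <- clean_sumstats(once)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  expect_true(all(attr(twice, "cleaning_report")$removed == 0))
  lg <- filter_log(once)
  expect_true(all(diff(lg$n_after) <= 0))
  # bookkeeping: initial - sum(removed) == final
  rep <- attr(once, "cleaning_report")
  expect_equal(nrow(ss) - sum(rep$removed), nrow(once))
})

test_that("p = 0 is clamped to the floor rather than dropped", {
  ss <- as_sumstats(data.frame(rsid = "rs1", beta = 1, p = 0))
  out <- clean_sumstats(ss, "drop_p_out_of_range")
  expect_equal(nrow(out), 1)
  expect_equal(out$p, 1e-320)
})

test_that("se derivation matches the normal-quantile oracle and is sign-invariant", {
  # oracle: z = qnorm(1 - p/2)
  expect_equal(derive_se(0.1, 0.05), 0.1 / qnorm(0.975), tolerance = 1e-9)
  expect_equal(derive_se(0.1, 0.05), 0.05102, tolerance = 1e-4)
  expect_equal(derive_se(1, 2 * (1 - pnorm(1))), 1.0, tolerance = 1e-9)
  expect_equal(derive_se(-0.2, 0.05), derive_se(0.2, 0.05))
  expect_true(is.na(derive_se(0, 0.5)))      # beta 0, p < 1: non-derivable
  expect_true(is.na(derive_se(0.1, 1.5)))    # p out of range
})

test_that("p derivation matches 2*(1-Phi(z)) with floor and errors on bad se", {
  expect_equal(derive_p(1, 1), 2 * (1 - pnorm(1)), tolerance = 1e-12)
  expect_equal(derive_p(0, 0.1), 1)
  expect_equal(derive_p(100, 1), 1e-320)     # floored, not zero
  expect_error(derive_p(1, -1), "se")
})

test_that("derive_p and derive_se are mutual inverses on their common domain", {
  set.seed(19)
  beta <- rnorm(200, 0, 0.5)
  se <- runif(200, 0.01, 0.5)
  p <- derive_p(beta, se)
  ok <- p > 1e-300 & p < 1           # common domain
  expect_equal(derive_se(beta[ok], p[ok]), se[ok], tolerance = 1e-9)
})

test_that("coordinates fill from a variant map without overwriting", {
  vm_file <- write_tsv_tmp(c("1\trs1\t0\t1000\tA\tG",
                             "2\trs2\t0\t2000\tC\tT"))
  bim <- sub("\\.tsv$", ".bim", vm_file)
  file.rename(vm_file, bim)
  vm <- read_variant_map(bim)
  ss <- as_sumstats(data.frame(rsid = c("rs1", "rs2", "rs9"),
                               beta = c(1, 2, 3)))
  ss$chrom <- c(NA, "5", NA)
  ss$pos <- c(NA_integer_, 999L, NA_integer_)
  out <- fill_coordinates(ss, vm, "rsid_to_pos")
  expect_equal(out$chrom[1], "1")
  expect_equal(out$pos[1], 1000L)
  expect_equal(out$pos[2], 999L)     # fill, never overwrite
  expect_true(is.na(out$pos[3]))
  expect_equal(attr(out, "fill_report")$unmatched, 1L)
  out2 <- fill_coordinates(ss, vm, "rsid_to_pos", drop_unmatched = TRUE)
  expect_equal(nrow(out2), 2)
  # reverse direction
  ss2 <- as_sumstats(data.frame(chrom = "2", pos = 2000L, beta = 1))
  out3 <- fill_coordinates(ss2, vm, "pos_to_rsid")
  expect_equal(out3$rsid, "rs2")
  expect_error(fill_coordinates(ss, vm[0, ], "rsid_to_pos"), "empty")
})

test_that("liftover maps through chain blocks and drops gap positions", {
  chain <- write_tsv_tmp(c(
    "chain 1000 chr1 10000 + 999 2000 chr1 20000 + 4999 6000 1",
    "1001", "",
    # two-block chain with a 10 bp gap on chr2
    "chain 900 chr2 10000 + 100 510 chr2 20000 + 1100 1500 2",
    "200 10 0", "200", ""))
  cm <- read_chain(chain)
  ss <- as_sumstats(data.frame(
    chrom = c("1", "1", "2", "2", "2"),
    pos = c(1500L, 2500L, 150L, 450L, 305L),
    rsid = paste0("rs", 1:5), beta = 1))
  out <- liftover_sumstats(ss, cm)
  # block 1: offset +4000
  expect_equal(out$pos[out$rsid == "rs1"], 5500L)
  # rs2 outside all blocks -> dropped and counted
  expect_false("rs2" %in% out$rsid)
  expect_equal(attr(out, "liftover_report")$unmapped, 2L)
  # chr2 first block: 0-based 149 -> 1100 + 49 -> 1-based 1150
  expect_equal(out$pos[out$rsid == "rs3"], 1150L)
  # after the 10 bp source gap the destination offset grows by 10 less
  expect_equal(out$pos[out$rsid == "rs4"], 1100L + (449 - 100 - 210) + 200 + 1)
  # rs5 falls in the gap (0-based 304, gap is [300,310)) -> dropped
  expect_false("rs5" %in% out$rsid)
})

test_that("liftover agrees with a per-base interval-walking oracle", {
  chain_file <- write_tsv_tmp(c(
    "chain 500 chr3 10000 + 100 430 chr3 9000 + 700 1040 7",
    "100 20 5", "50 30 25", "130", ""))
  cm <- read_chain(chain_file)
  # oracle: walk the chain arithmetic base by base
  walk <- function() {
    m <- list()
    spos <- 100; qpos <- 700
    for (blk in list(c(100, 20, 5), c(50, 30, 25), c(130, 0, 0))) {
      for (i in seq_len(blk[1])) {
        m[[as.character(spos)]] <- qpos
        spos <- spos + 1; qpos <- qpos + 1
      }
      spos <- spos + blk[2]; qpos <- qpos + blk[3]
    }
    m
  }
  oracle <- walk()
  pos0 <- c(100, 150, 199, 205, 220, 169, 250, 260, 429)
  ss <- as_sumstats(data.frame(chrom = "3", pos = as.integer(pos0 + 1),
                               rsid = paste0("v", seq_along(pos0)), beta = 1))
  out <- liftover_sumstats(ss, cm)
  for (k in seq_along(pos0)) {
    expected <- oracle[[as.character(pos0[k])]]
    id <- paste0("v", k)
    if (is.null(expected)) {
      expect_false(id %in% out$rsid)
    } else {
      expect_equal(out$pos[out$rsid == id], as.integer(expected + 1))
    }
  }
})

test_that("minus-strand chains reverse-coordinate correctly", {
  chain_file <- write_tsv_tmp(c(
    "chain 100 chr1 10000 + 1000 1100 chr1 5000 - 2000 2100 9",
    "100", ""))
  cm <- read_chain(chain_file)
  ss <- as_sumstats(data.frame(chrom = "1", pos = 1001L, rsid = "r", beta = 1))
  out <- liftover_sumstats(ss, cm)
  # 0-based source 1000 -> strand-local 2000 -> plus-strand 5000-1-2000
  expect_equal(out$pos, as.integer(5000 - 1 - 2000 + 1))
})

test_that("malformed chain files are rejected", {
  bad <- write_tsv_tmp(c("chain 1 chr1 10 + 0 5", "5"))
  expect_error(read_chain(bad), "malformed")
})

test_that("chain mapping agrees with the rtracklayer liftOver oracle", {
  chain_file <- tempfile(fileext = ".chain")
  writeLines(c(
    "chain 800 chr5 50000 + 2000 2700 chr5 40000 + 9000 9690 3",
    "300 50 40", "340", ""), chain_file)
  cm <- read_chain(chain_file)
  pos <- as.integer(c(2001, 2150, 2300, 2320, 2350, 2500, 2699))
  ss <- as_sumstats(data.frame(chrom = "5", pos = pos,
                               rsid = paste0("v", seq_along(pos)), beta = 1))
  got <- liftover_sumstats(ss, cm)
  ch <- rtracklayer::import.chain(chain_file)
  gr <- GenomicRanges::GRanges("chr5", IRanges::IRanges(pos, width = 1))
  lifted <- rtracklayer::liftOver(gr, ch)
  n_hit <- S4Vectors::elementNROWS(lifted)
  expect_equal(got$rsid, paste0("v", which(n_hit == 1)))
  expect_equal(got$pos,
               GenomicRanges::start(unlist(lifted)))
})
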