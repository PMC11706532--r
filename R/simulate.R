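# Synthetic-data generator: LD-structured reference panels and two-sample
# GWAS summary statistics under a configurable causal/pleiotropy model.
# These defaults define the study conditions every property test runs under.

#' Simulation configuration
#'
#' The generative model: instruments have effects
#' `gamma_i ~ N(0, sigma_gamma^2)` on the exposure; a fraction `pleio_frac`
#' of them are invalid with direct outcome effects
#' `alpha_i ~ N(alpha_mean, alpha_sd^2)`; summary statistics are
#' `beta_exp_i = gamma_i + e_x`, `beta_out_i = theta * gamma_i +
#' alpha_i * [invalid] + e_y` with sampling errors at the GWAS-scale
#' standard errors `se = (2 n maf (1 - maf))^(-1/2)`.  Panels are built from
#' pairs of latent AR(1) Gaussian haplotypes thresholded at the MAF
#' quantile, giving blockwise LD.
#'
#' @param n_samples panel individuals (default 500).
#' @param n_snps number of variants (default 100).
#' @param block_size LD block size in SNPs (default 10).
#' @param rho within-block AR(1) correlation of the latent haplotype
#'   process, in \[0, 1) (default 0.8).
#' @param maf_range range minor-allele frequencies are drawn from
#'   (default c(0.05, 0.5)).
#' @param n_exposure,n_outcome GWAS sample sizes (default 1e5 each).
#' @param theta true causal effect (default 0.2).
#' @param sigma_gamma sd of instrument effects on the exposure
#'   (default 0.05; with the default GWAS size this gives strong
#'   instruments, mean F around 90).
#' @param pleio_frac fraction of invalid instruments in \[0, 1\]
#'   (default 0).
#' @param alpha_mean,alpha_sd direct (pleiotropic) effect distribution of
#'   invalid instruments (defaults 0, 0).
#' @param pleio_directional when `TRUE`, pleiotropic effects act on the
#'   exposure-increasing allele (`alpha_i * sign(gamma_i)`), the form a
#'   nonzero `alpha_mean` makes detectable as an MR-Egger intercept; when
#'   `FALSE` (default) alpha enters additively on the labelled effect
#'   allele, where it biases estimates but cancels under Egger's
#'   orientation by the sign-symmetry of gamma.
#' @param palindromic_frac fraction of variants given a palindromic
#'   allele pair (default 0.2), exercising strand resolution downstream.
#' @param outcome_flip_frac fraction of outcome rows reported on the
#'   opposite allele (swapped ea/nea, negated beta, complemented eaf;
#'   default 0.3), exercising harmonization.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 500, n_snps = 100, block_size = 10,
                       rho = 0.8, maf_range = c(0.05, 0.5),
                       n_exposure = 1e5, n_outcome = 1e5,
                       theta = 0.2, sigma_gamma = 0.05,
                       pleio_frac = 0, alpha_mean = 0, alpha_sd = 0,
                       pleio_directional = FALSE,
                       palindromic_frac = 0.2, outcome_flip_frac = 0.3,
                       seed = 1) {
  if (!(rho >= 0 && rho < 1)) abort("rho must be in [0, 1)")
  if (!(pleio_frac >= 0 && pleio_frac <= 1)) {
    abort("pleio_frac must be in [0, 1]")
  }
  if (!(maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2])) {
    abort("maf_range must lie within (0, 0.5]")
  }
  structure(as.list(environment()), class = "sim_config")
}

# draw an allele pair; palindromic ({A,T} or {C,G}) with given probability
draw_allele_pairs <- function(n, pal_frac) {
  bases <- c("A", "C", "G", "T")
  pal <- runif(n) < pal_frac
  a1 <- character(n); a2 <- character(n)
  pal_choice <- sample(c("AT", "CG"), n, replace = TRUE)
  a1[pal] <- substr(pal_choice[pal], 1, 1)
  a2[pal] <- substr(pal_choice[pal], 2, 2)
  for (k in which(!pal)) {
    repeat {
      pr <- sample(bases, 2)
      if (!is_palindromic(pr[1], pr[2])) break
    }
    a1[k] <- pr[1]; a2[k] <- pr[2]
  }
  list(a1 = a1, a2 = a2)
}

#' Simulate an LD-structured reference panel
#'
#' Within each block of `block_size` SNPs, each of a sample's two haplotypes
#' is a latent AR(1) Gaussian process thresholded at the MAF quantile; the
#' dosage is the sum of the two haplotypes, so adjacent SNPs within a block
#' are in LD controlled by `rho` while blocks are independent.  Variants are
#' named rs1..rsN on chromosome 1, positions spaced 1 kb.
#'
#' @param cfg a [sim_config()].
#' @param prefix optional path; when given the fileset is also written with
#'   [write_plink()].
#' @return a `ref_panel`; attribute `"maf"` stores the generating MAFs.
#' @export
simulate_panel <- function(cfg = sim_config(), prefix = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; m <- cfg$n_snps; bs <- cfg$block_size
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  thr <- qnorm(maf)
  dosage <- matrix(0L, nrow = n, ncol = m)
  starts <- seq(1, m, by = bs)
  for (s in starts) {
    idx <- s:min(s + bs - 1, m)
    k <- length(idx)
    for (hap in 1:2) {
      z <- matrix(0, nrow = n, ncol = k)
      z[, 1] <- rnorm(n)
      if (k > 1) {
        for (j in 2:k) {
          z[, j] <- cfg$rho * z[, j - 1] +
            sqrt(1 - cfg$rho^2) * rnorm(n)
        }
      }
      allele <- sweep(z, 2, thr[idx], "<") * 1L
      dosage[, idx] <- dosage[, idx] + allele
    }
  }
  pairs <- draw_allele_pairs(m, cfg$palindromic_frac)
  variants <- tibble(rsid = paste0("rs", seq_len(m)), chrom = "1",
                     pos = seq_len(m) * 1000L, a1 = pairs$a1, a2 = pairs$a2,
                     cm = 0)
  fam <- tibble(fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
                pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  dimnames(dosage) <- list(fam$iid, variants$rsid)
  panel <- new_ref_panel(variants, dosage, fam)
  attr(panel, "maf") <- maf
  if (!is.null(prefix)) write_plink(panel, prefix)
  panel
}

#' Simulate a two-sample GWAS summary-statistics pair with known truth
#'
#' Generates exposure and outcome summary statistics for the same variants
#' under the model described in [sim_config()].  When a panel is supplied
#' its variants, allele pairs and empirical allele frequencies are reused
#' (A1 is the effect allele); otherwise variants are drawn fresh.  A
#' configurable fraction of outcome rows is reported on the opposite allele
#' so harmonization has real work to do.
#'
#' @param cfg a [sim_config()].
#' @param panel optional `ref_panel` whose variants the statistics refer to.
#' @return a list: `exposure` and `outcome` (`sumstats` tables) and `truth`
#'   (list: `theta`, `gamma`, `alpha`, `invalid` (rsids), `flipped` (rsids
#'   of outcome rows reported on the opposite allele)).
#' @examples
#' sim <- simulate_gwas_pair(sim_config(n_snps = 50, seed = 7))
#' head(sim$exposure)
#' sim$truth$theta
#' @export
simulate_gwas_pair <- function(cfg = sim_config(), panel = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  if (!is.null(panel)) {
    v <- panel$variants
    m <- nrow(v)
    maf <- colMeans(panel$dosage, na.rm = TRUE) / 2
    maf <- pmin(pmax(maf, 1e-3), 1 - 1e-3)
  } else {
    m <- cfg$n_snps
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    pairs <- draw_allele_pairs(m, cfg$palindromic_frac)
    v <- tibble(rsid = paste0("rs", seq_len(m)), chrom = "1",
                pos = seq_len(m) * 1000L, a1 = pairs$a1, a2 = pairs$a2)
  }
  se_x <- 1 / sqrt(2 * cfg$n_exposure * maf * (1 - maf))
  se_y <- 1 / sqrt(2 * cfg$n_outcome * maf * (1 - maf))
  gamma <- rnorm(m, 0, cfg$sigma_gamma)
  n_invalid <- round(cfg$pleio_frac * m)
  invalid <- sample(m, n_invalid)
  alpha <- rep(0, m)
  alpha[invalid] <- rnorm(n_invalid, cfg$alpha_mean, cfg$alpha_sd)
  dir <- if (isTRUE(cfg$pleio_directional)) sign(gamma) else 1
  beta_x <- gamma + rnorm(m, 0, se_x)
  beta_y <- cfg$theta * gamma + dir * alpha + rnorm(m, 0, se_y)

  exposure <- new_sumstats(tibble(
    chrom = v$chrom, pos = v$pos, rsid = v$rsid, ea = v$a1, nea = v$a2,
    beta = beta_x, se = se_x, p = derive_p(beta_x, se_x), eaf = maf))
  flip <- runif(m) < cfg$outcome_flip_frac
  outcome <- new_sumstats(tibble(
    chrom = v$chrom, pos = v$pos, rsid = v$rsid,
    ea = ifelse(flip, v$a2, v$a1), nea = ifelse(flip, v$a1, v$a2),
    beta = ifelse(flip, -beta_y, beta_y), se = se_y,
    p = derive_p(beta_y, se_y), eaf = ifelse(flip, 1 - maf, maf)))
  list(exposure = exposure, outcome = outcome,
       truth = list(theta = cfg$theta, gamma = gamma, alpha = alpha,
                    invalid = v$rsid[invalid], flipped = v$rsid[flip]))
}
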