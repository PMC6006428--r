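#' Simulate a block-correlated expression matrix
#'
#' Emulates an FPKM-scale gene-by-sample matrix containing co-expressed
#' gene modules.  Each module shares a latent standard-normal sample
#' profile; a member gene's log-scale signal is
#' `sqrt(rho) * latent + sqrt(1 - rho) * noise`, so the expected
#' pairwise Pearson correlation between module members is
#' `within_module_corr` (= rho) on the log scale, which is where the
#' co-expression pipeline measures it after its `log2(x + 1)` entry
#' step.  `noise_sd` adds extra independent measurement noise on the
#' log scale, attenuating the realised correlation by
#' `1 / (1 + noise_sd^2)`.  Background genes are independent.  Values
#' are returned on a non-negative FPKM-like scale via `2^x - 1`.
#'
#' @param n_genes total number of genes.
#' @param module_defs named list mapping module name to number of member
#'   genes (modules partition the first `sum(sizes)` genes).
#' @param n_samples number of samples.
#' @param within_module_corr target within-module PCC in `[0, 1]`.
#' @param noise_sd extra log-scale noise sd (default 0).
#' @param seed integer seed.
#' @param log_mean,log_sd location/scale of log2 expression (defaults 5, 2).
#' @return list with `fpkm` (genes x samples matrix, dimnames set),
#'   `modules` (character vector of per-gene module labels,
#'   `"background"` for unassigned genes).
#' @export
simulate_expression <- function(n_genes, module_defs, n_samples,
                                within_module_corr, noise_sd = 0, seed = 1,
                                log_mean = 5, log_sd = 2) {
  rho <- within_module_corr
  if (rho < 0 || rho > 1)
    stop("within_module_corr must lie in [0, 1]")
  sizes <- unlist(module_defs)
  if (sum(sizes) > n_genes)
    stop("modules assign more genes than n_genes")
  withr_seed(seed, {
    lat <- matrix(stats::rnorm(length(sizes) * n_samples), length(sizes))
    x <- matrix(stats::rnorm(n_genes * n_samples), n_genes)
    modules <- rep("background", n_genes)
    g <- 0
    for (m in seq_along(sizes)) {
      idx <- g + seq_len(sizes[m])
      x[idx, ] <- sqrt(rho) * matrix(lat[m, ], sizes[m], n_samples,
                                     byrow = TRUE) +
                  sqrt(1 - rho) * x[idx, ]
      modules[idx] <- names(sizes)[m]
      g <- g + sizes[m]
    }
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                      n_genes)
    log2fpkm <- log_mean + log_sd * x
    fpkm <- pmax(2^log2fpkm - 1, 0)
    dimnames(fpkm) <- list(sprintf("gene%04d", seq_len(n_genes)),
                           sprintf("sample%04d", seq_len(n_samples)))
    list(fpkm = fpkm, modules = stats::setNames(modules, rownames(fpkm)))
  })
}
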