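# Empirical-Bayes negative-binomial two-condition differential expression.
#
# Model: for gene g, normalized counts are NB(r_g, q) with a gene-specific
# size r_g (method of moments) and a probability parameter q drawn from a
# Beta(alpha, beta) prior shared across genes. Under equal expression (EE)
# all samples share one draw of q; under differential expression (DE) each
# condition has its own independent draw. Both marginal likelihoods are
# available in closed beta-negative-binomial form, and an EM over the
# mixture weight pi yields the posterior probability of differential
# expression (PPDE) per gene.

#' Median-of-ratios size factors
#'
#' The DESeq-style estimator: for genes with all-positive counts, the median
#' across genes of count / geometric-mean(count); factors are rescaled to
#' geometric mean 1.
#'
#' @param counts genes x samples matrix of non-negative counts
#' @param pseudo_reference fall back to adding 0.5 to all counts when no
#'   gene is all-positive (default FALSE: error instead)
#' @return numeric vector of per-sample size factors
#' @export
median_ratio_size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  allpos <- rowSums(counts <= 0) == 0
  if (!any(allpos)) {
    if (!pseudo_reference) {
      stop("no gene has positive counts in every sample; rerun with ",
           "pseudo_reference = TRUE")
    }
    counts <- counts + 0.5
    allpos <- rep(TRUE, nrow(counts))
  }
  sub <- counts[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, stats::median)
  sf / exp(mean(log(sf)))
}

#' Fit the empirical-Bayes NB mixture and compute PPDE
#'
#' See the package vignette for the model. Counts are normalized by the
#' size factors (median-of-ratios by default) and rounded; gene-wise NB
#' sizes come from pooled moments; the Beta prior is fitted by moments on
#' the gene-wise probability estimates; the mixture weight is estimated by
#' EM, whose observed-data log-likelihood is checked to be non-decreasing.
#'
#' @param counts genes x samples matrix of non-negative integer counts with
#'   gene-id rownames
#' @param conditions factor/character of length ncol(counts) with exactly
#'   two levels
#' @param size_factors optional per-sample factors (default: estimated)
#' @param max_iter,tol EM iteration cap and convergence tolerance on pi
#' @param ppde_threshold selection threshold used by [select_de()]
#'   (default 1 - 1e-5, the practical reading of "PPDE = 1")
#' @return `DEResult` list: table (gene, PPDE, postFC, selected), pi
#'   (mixing proportion), size_factors, hyperparameters (alpha, beta),
#'   loglik_trace, converged, selected (gene ids), bayes_fdr
#' @export
fit_ppde <- function(counts, conditions, size_factors = NULL,
                     max_iter = 50, tol = 1e-6,
                     ppde_threshold = 1 - 1e-5) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%04d", seq_len(nrow(counts)))
  }
  conditions <- factor(conditions)
  if (nlevels(conditions) != 2) stop("exactly two conditions required")
  if (length(conditions) != ncol(counts)) {
    stop("conditions must match the number of samples")
  }
  if (min(table(conditions)) < 2) stop(">= 2 samples per condition required")
  if (is.null(size_factors)) {
    size_factors <- median_ratio_size_factors(counts,
                                              pseudo_reference = TRUE)
  }
  y <- round(sweep(counts, 2, size_factors, "/"))
  Sn <- ncol(y)
  g1 <- which(conditions == levels(conditions)[1])
  g2 <- which(conditions == levels(conditions)[2])

  m <- rowMeans(y)
  # within-condition variance: between-condition shifts must not inflate
  # the size estimate, or truly DE genes would be absorbed by the EE model
  v1 <- apply(y[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(y[, g2, drop = FALSE], 1, stats::var)
  w1 <- length(g1) - 1L
  w2 <- length(g2) - 1L
  v <- (w1 * v1 + w2 * v2) / (w1 + w2)
  # gene-wise dispersions from so few residual df are wild; shrink them
  # toward the across-gene median (moderated-dispersion convention) so a
  # chance-tight pair of replicates cannot fake strong DE evidence
  df_resid <- w1 + w2
  df_prior <- 4
  phi_raw <- pmax((v - m) / pmax(m^2, 1e-8), 0)
  phi_med <- stats::median(phi_raw[m > 1])
  if (!is.finite(phi_med)) phi_med <- 0.1
  phi <- (df_resid * phi_raw + df_prior * phi_med) / (df_resid + df_prior)
  phi <- pmax(phi, 0.01)
  eps <- 1e-8
  r <- 1 / phi
  r <- pmin(pmax(r, 0.05), 1e6)
  r[m <= 0] <- 0.05

  # Beta prior on q = r / (r + mu) by moments across expressed genes
  q_hat <- r / (r + pmax(m, eps))
  use <- m > 0
  mq <- mean(q_hat[use])
  vq <- stats::var(q_hat[use])
  vq <- min(max(vq, 1e-6), mq * (1 - mq) * 0.999)
  conc <- mq * (1 - mq) / vq - 1
  a0 <- max(mq * conc, 0.01)
  b0 <- max((1 - mq) * conc, 0.01)

  lgroup <- function(idx) {
    # log Beta-NB marginal for a sample group sharing one q draw
    # (binomial-coefficient terms common to f0 and f1 are omitted; they
    #  cancel in the posterior odds)
    Tg <- rowSums(y[, idx, drop = FALSE])
    lbeta(a0 + length(idx) * r, b0 + Tg) - lbeta(a0, b0)
  }
  lf0 <- lgroup(seq_len(Sn))
  lf1 <- lgroup(g1) + lgroup(g2)

  pi_hat <- 0.25
  loglik <- numeric(0)
  converged <- FALSE
  ppde <- rep(NA_real_, nrow(y))
  for (it in seq_len(max_iter)) {
    la <- log(pi_hat) + lf1
    lb <- log1p(-pi_hat) + lf0
    mx <- pmax(la, lb)
    denom <- mx + log(exp(la - mx) + exp(lb - mx))
    ppde <- exp(la - denom)
    loglik <- c(loglik, sum(denom))
    pi_new <- min(max(mean(ppde), 1e-6), 1 - 1e-6)
    if (abs(pi_new - pi_hat) < tol) {
      pi_hat <- pi_new
      converged <- TRUE
      break
    }
    pi_hat <- pi_new
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter, " iterations")
  }

  post_fc <- (rowMeans(y[, g2, drop = FALSE]) + 0.5) /
    (rowMeans(y[, g1, drop = FALSE]) + 0.5)
  tab <- data.frame(gene = rownames(y), PPDE = ppde, postFC = post_fc,
                    stringsAsFactors = FALSE)
  res <- list(table = tab, pi = pi_hat, size_factors = size_factors,
              hyperparameters = c(alpha = a0, beta = b0),
              loglik_trace = loglik, converged = converged,
              ppde_threshold = ppde_threshold)
  sel <- select_de(res, ppde_threshold = ppde_threshold)
  res$selected <- sel$selected
  res$bayes_fdr <- sel$bayes_fdr
  res$table$selected <- res$table$gene %in% sel$selected
  class(res) <- "de_result"
  res
}

#' Select differentially expressed genes by PPDE with a Bayesian FDR cap
#'
#' Genes with PPDE at or above the threshold are selected; if the Bayesian
#' FDR of the selection (mean posterior EE probability, `mean(1 - PPDE)`)
#' exceeds `fdr_cap`, the selection is shrunk from the lowest PPDE upward
#' until the cap is met (so the final set is a PPDE-descending prefix).
#'
#' @param result a `de_result` from [fit_ppde()] (or any list with a
#'   `table` containing gene and PPDE)
#' @param ppde_threshold minimum PPDE (default 1 - 1e-5)
#' @param fdr_cap Bayesian FDR cap (default 0.05)
#' @return list: selected (gene ids), bayes_fdr of the final set
#' @export
select_de <- function(result, ppde_threshold = 1 - 1e-5, fdr_cap = 0.05) {
  tab <- result$table
  ord <- order(-tab$PPDE)
  tab <- tab[ord, , drop = FALSE]
  in_sel <- tab$PPDE >= ppde_threshold
  k <- sum(in_sel)
  while (k > 0 && mean(1 - tab$PPDE[seq_len(k)]) > fdr_cap) {
    k <- k - 1
  }
  if (k == 0) return(list(selected = character(0), bayes_fdr = NA_real_))
  list(selected = tab$gene[seq_len(k)],
       bayes_fdr = mean(1 - tab$PPDE[seq_len(k)]))
}

#' @export
print.de_result <- function(x, ...) {
  cat("Empirical-Bayes NB differential expression\n")
  cat("  genes:", nrow(x$table), " pi:", signif(x$pi, 3), "\n")
  cat("  selected (PPDE >= ", signif(x$ppde_threshold, 6), "): ",
      length(x$selected), ", Bayesian FDR ",
      signif(x$bayes_fdr, 3), "\n", sep = "")
  invisible(x)
}
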