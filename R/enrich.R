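# Fisher exact pathway enrichment of a selected gene set against a
# background (the genes carrying SNPs, in the motivating design).

#' Fisher exact pathway enrichment
#'
#' For each pathway the 2x2 table
#' `[[k, K - k], [n - k, (N - K) - (n - k)]]` is tested (k = selected genes
#' in the pathway, K = selected genes, n = background genes in the pathway,
#' N = background size) with a one-sided (over-representation) Fisher exact
#' test by default. Annotation genes outside the background are dropped with
#' a warning. No multiple-testing correction by default; `correct = "BH"`
#' adds a Benjamini-Hochberg column and flags on the adjusted value.
#'
#' @param selected character vector of selected gene ids (subset of
#'   background)
#' @param background character vector of background gene ids (non-empty)
#' @param annotations named list: pathway id -> character vector of gene ids
#' @param alpha significance level (default 0.05)
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @param correct `"none"` (default) or `"BH"`
#' @return data.frame of `EnrichmentRecord`s: pathway, k, K, n, N, p,
#'   (p_adj,) enriched
#' @export
pathway_enrichment <- function(selected, background, annotations,
                               alpha = 0.05,
                               alternative = c("greater", "two.sided"),
                               correct = c("none", "BH")) {
  alternative <- match.arg(alternative)
  correct <- match.arg(correct)
  background <- unique(background)
  selected <- unique(selected)
  if (length(background) == 0) stop("background gene set is empty")
  if (!all(selected %in% background)) {
    stop("selected genes must be a subset of the background")
  }
  N <- length(background)
  K <- length(selected)
  rows <- lapply(names(annotations), function(pw) {
    genes <- unique(annotations[[pw]])
    inside <- genes %in% background
    if (any(!inside)) {
      warning("pathway ", pw, ": ", sum(!inside),
              " gene(s) outside the background dropped")
      genes <- genes[inside]
    }
    n <- length(genes)
    k <- length(intersect(genes, selected))
    p <- if (alternative == "greater") {
      hypergeom_enrichment_p(k, K, n, N)
    } else {
      tab <- matrix(c(k, K - k, n - k, (N - K) - (n - k)), nrow = 2,
                    byrow = TRUE)
      stats::fisher.test(tab, alternative = alternative)$p.value
    }
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  }
  if (correct == "BH" && nrow(out) > 0) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$enriched <- out$p_adj < alpha
  } else {
    out$enriched <- out$p < alpha
  }
  rownames(out) <- NULL
  out
}

#' One-sided Fisher exact (hypergeometric tail) enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric` with `n` pathway genes among `N`
#' background genes and `K` selected draws — identical to
#' `fisher.test(alternative = "greater")` on the corresponding 2x2 table.
#' Vectorized over its arguments.
#'
#' @param k selected genes in the pathway
#' @param K selected genes total
#' @param n background genes in the pathway
#' @param N background genes total
#' @return p-value(s) in (0, 1]
#' @export
hypergeom_enrichment_p <- function(k, K, n, N) {
  stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set id, description, then member gene ids.
#'
#' @param path file path
#' @return named list of gene-id character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write a GMT gene-set file
#' @param sets named list of gene-id vectors
#' @param path file path
#' @param descriptions optional descriptions (defaults to the set ids)
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}
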