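#' Nei-Gojobori (NG86) synonymous / nonsynonymous site counts
#'
#' Each codon position contributes fractionally to the synonymous site total
#' according to the fraction of its three single-nucleotide mutants that are
#' synonymous; mutants creating a stop codon count as nonsynonymous. Codons
#' containing ambiguous bases (anything outside A/C/G/T) are skipped with a
#' message.
#'
#' @param cds a character string or [Biostrings::DNAString] whose length is a
#'   multiple of 3; no internal stop codons expected
#' @return a list with elements `S` (synonymous sites), `N` (nonsynonymous
#'   sites) and `codons` (number of codons actually counted). `S + N` equals
#'   3 times the counted codons.
#' @examples
#' ng86_site_counts("ATGTTT")  # ATG: S=0; TTT: S=1/3
#' @export
ng86_site_counts <- function(cds) {
  codons <- .split_codons(cds)
  known <- codons %in% names(.GENETIC_CODE)
  if (any(!known)) {
    message("ng86_site_counts: skipping ", sum(!known),
            " codon(s) with ambiguous bases")
  }
  codons <- codons[known]
  syn <- .codon_syn_sites()
  S <- sum(syn[codons])
  list(S = unname(S), N = 3 * length(codons) - unname(S),
       codons = length(codons))
}

#' NG86 pathway-averaged difference counts between two aligned CDSs
#'
#' For each codon pair differing at d positions, the synonymous and
#' nonsynonymous single-step counts are averaged over all d! orderings of the
#' substitution pathway. Pathways whose intermediate codons are stops are
#' excluded from the average; if every pathway passes through a stop, all are
#' retained. Codon pairs containing ambiguous bases are skipped.
#'
#' @param cdsA,cdsB equal-length, in-frame coding sequences
#' @return list with `Ns` (synonymous differences) and `Nn` (nonsynonymous
#'   differences); `Ns + Nn` equals the total pathway-averaged differences.
#' @examples
#' ng86_difference_counts("TTT", "TTC")  # 1 synonymous
#' ng86_difference_counts("TTT", "GTA")  # (0.5, 1.5) over two pathways
#' @export
ng86_difference_counts <- function(cdsA, cdsB) {
  ca <- .split_codons(cdsA)
  cb <- .split_codons(cdsB)
  if (length(ca) != length(cb)) stop("CDS lengths differ")
  known <- ca %in% names(.GENETIC_CODE) & cb %in% names(.GENETIC_CODE)
  diff <- known & ca != cb
  Ns <- 0
  Nn <- 0
  for (i in which(diff)) {
    v <- .codon_pair_diffs_cached(ca[i], cb[i])
    Ns <- Ns + v[["syn"]]
    Nn <- Nn + v[["nonsyn"]]
  }
  list(Ns = Ns, Nn = Nn)
}

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' @param p proportion in `[0, 0.75)`
#' @return `-(3/4) * log(1 - 4p/3)`; `NaN` for p >= 3/4
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NaN)
}

#' Estimate Ka/Ks for a pair of aligned CDSs (NG86)
#'
#' Site counts are averaged over the two sequences; difference counts are
#' pathway-averaged; proportions are Jukes-Cantor corrected. Significance of
#' the Ka/Ks departure from 1 is assessed with a two-sided Fisher exact test
#' on the 2x2 table of rounded synonymous / nonsynonymous differences versus
#' non-differences. A gene is classified `positive` when Ka/Ks > 1 and
#' p < alpha, `purifying` when Ka/Ks < 1 and p < alpha, otherwise
#' `unclassified`. Ks = 0 makes the ratio undefined (`NA`), or infinite when
#' Ka > 0 (flagged; classified positive only when significant).
#'
#' @param cdsA,cdsB aligned coding sequences of equal length
#' @param alpha significance level for the Fisher test (default 0.05)
#' @param gene optional gene id carried into the record
#' @return a one-row data.frame (a `KaKsRecord`): gene, S, N, Ns, Nn, ps, pn,
#'   Ka, Ks, ratio, fisher_p, class, flag
#' @export
kaks_estimate <- function(cdsA, cdsB, alpha = 0.05, gene = NA_character_) {
  scA <- ng86_site_counts(cdsA)
  scB <- ng86_site_counts(cdsB)
  S <- (scA$S + scB$S) / 2
  N <- (scA$N + scB$N) / 2
  dc <- ng86_difference_counts(cdsA, cdsB)
  Ns <- dc$Ns
  Nn <- dc$Nn
  flag <- ""
  if (S <= 0 || N <= 0) {
    return(.kaks_row(gene, S, N, Ns, Nn, NA, NA, NA, NA, NA, NA_real_,
                     "unclassified", "degenerate-sites"))
  }
  ps <- Ns / S
  pn <- Nn / N
  Ka <- jukes_cantor(pn)
  Ks <- jukes_cantor(ps)
  if (is.nan(Ka) || is.nan(Ks)) {
    return(.kaks_row(gene, S, N, Ns, Nn, ps, pn, Ka, Ks, NA, NA_real_,
                     "unclassified", "jc-saturated"))
  }
  tab <- matrix(c(round(Ns), round(S - Ns), round(Nn), round(N - Nn)),
                nrow = 2, byrow = TRUE)
  tab[tab < 0] <- 0
  p <- stats::fisher.test(tab)$p.value
  if (Ks == 0 && Ka == 0) {
    return(.kaks_row(gene, S, N, Ns, Nn, ps, pn, Ka, Ks, NA, p,
                     "unclassified", "no-divergence"))
  }
  if (Ks == 0) {
    cls <- if (p < alpha) "positive" else "unclassified"
    return(.kaks_row(gene, S, N, Ns, Nn, ps, pn, Ka, Ks, Inf, p, cls,
                     "ks-zero"))
  }
  ratio <- Ka / Ks
  cls <- if (p < alpha && ratio > 1) "positive"
         else if (p < alpha && ratio < 1) "purifying"
         else "unclassified"
  if (is.finite(ratio) && ratio > 50) flag <- "ratio-gt-50"
  .kaks_row(gene, S, N, Ns, Nn, ps, pn, Ka, Ks, ratio, p, cls, flag)
}

.kaks_row <- function(gene, S, N, Ns, Nn, ps, pn, Ka, Ks, ratio, p, cls,
                      flag) {
  data.frame(gene = gene, S = S, N = N, Ns = Ns, Nn = Nn,
             ps = ps, pn = pn, Ka = Ka, Ks = Ks, ratio = ratio,
             fisher_p = p, class = cls, flag = flag,
             stringsAsFactors = FALSE)
}

#' Summarise selection classes over a table of Ka/Ks records
#'
#' @param records data.frame with a `class` column (rbind of
#'   [kaks_estimate()] rows)
#' @param alpha unused here (classification happened per record); kept for
#'   interface symmetry
#' @return named list of counts: positive, purifying, unclassified, total
#' @export
classify_selection <- function(records, alpha = 0.05) {
  cls <- factor(records$class,
                levels = c("positive", "purifying", "unclassified"))
  counts <- as.list(table(cls))
  counts <- lapply(counts, as.integer)
  counts$total <- nrow(records)
  counts
}

#' Find open reading frames in a transcript
#'
#' Scans the three forward frames (six with `both_strands = TRUE`). Within
#' each inter-stop segment an ORF runs from the first ATG (or from the
#' transcript start, flagged 5'-partial, when `allow_partial`) to the stop
#' codon inclusive, or to the transcript end. The longest ORF of at least
#' `min_len_codons` codons is returned.
#'
#' @param transcript character or DNAString over A/C/G/T/N
#' @param min_len_codons minimum ORF length in codons (default 100)
#' @param allow_partial allow 5'-partial ORFs lacking an ATG (default TRUE)
#' @param both_strands also scan the reverse complement (default FALSE)
#' @return zero- or one-row data.frame (`OrfRecord`): frame (0-2), strand,
#'   start, end (1-based inclusive on the given transcript), codons,
#'   partial5. `end - start + 1` is a multiple of 3.
#' @export
find_orfs <- function(transcript, min_len_codons = 100, allow_partial = TRUE,
                      both_strands = FALSE) {
  seqs <- list(`+` = toupper(as.character(transcript)))
  if (both_strands) {
    seqs[["-"]] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seqs[["+"]])))
  }
  best <- NULL
  for (strand in names(seqs)) {
    s <- seqs[[strand]]
    n <- nchar(s)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < 1) next
      starts <- frame + seq(1L, by = 3L, length.out = ncod)
      codons <- substring(s, starts, starts + 2L)
      is_stop <- codons %in% .STOP_CODONS
      # segment boundaries: runs between stops (stop included at segment end)
      seg_start <- 1L
      idx_stops <- c(which(is_stop), ncod + 1L)
      for (st in idx_stops) {
        seg <- seq(seg_start, min(st, ncod))
        seg_start <- st + 1L
        if (length(seg) == 0) next
        has_stop <- st <= ncod
        atg <- seg[which(codons[seg] == "ATG")[1]]
        from <- NA_integer_
        partial5 <- FALSE
        if (seg[1] == 1L && allow_partial) {
          if (!is.na(atg) && atg == seg[1]) {
            from <- atg
          } else {
            from <- seg[1]
            partial5 <- !(!is.na(atg) && atg == seg[1])
          }
          # prefer the full segment (longest); an internal ATG start would
          # only shorten it
        } else if (!is.na(atg)) {
          from <- atg
        }
        if (is.na(from)) next
        to <- seg[length(seg)]  # includes the stop codon if present
        len <- to - from + 1L
        if (len < min_len_codons) next
        if (is.null(best) || len > best$codons) {
          best <- data.frame(
            frame = frame, strand = strand,
            start = starts[from], end = starts[to] + 2L,
            codons = len, partial5 = partial5, partial3 = !has_stop,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (is.null(best)) {
    return(data.frame(frame = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      codons = integer(0), partial5 = logical(0),
                      partial3 = logical(0)))
  }
  best
}

#' Build the alternative-consensus CDS by applying fixed variants
#'
#' Substitutes the alternative allele at each variant position; positions
#' outside `[1, nchar(cds)]` are ignored (the trimming convention: variants
#' are applied after the CDS has been cut out of the transcript).
#'
#' @param cds reference coding sequence (character)
#' @param pos integer positions (1-based, CDS coordinates)
#' @param ref,alt reference and alternative alleles (single bases)
#' @return character CDS of identical length with alleles swapped
#' @export
apply_fixed_variants <- function(cds, pos, ref, alt) {
  cds <- toupper(as.character(cds))
  if (length(pos) == 0) return(cds)
  stopifnot(length(pos) == length(ref), length(pos) == length(alt))
  inside <- pos >= 1L & pos <= nchar(cds)
  pos <- pos[inside]; ref <- toupper(ref[inside]); alt <- toupper(alt[inside])
  if (length(pos) == 0) return(cds)
  chars <- strsplit(cds, "")[[1]]
  bad <- chars[pos] != ref
  if (any(bad)) {
    stop("allele mismatch at CDS position(s) ",
         paste(pos[bad], collapse = ", "),
         ": reference base is ", paste(chars[pos[bad]], collapse = ","),
         " but variant table says ", paste(ref[bad], collapse = ","))
  }
  chars[pos] <- alt
  paste(chars, collapse = "")
}

#' Proportion of differing sites between two aligned sequences
#'
#' Gap ('-') and ambiguous positions are excluded pairwise.
#'
#' @param seqA,seqB equal-length aligned sequences
#' @return mismatches / compared sites
#' @export
p_distance <- function(seqA, seqB) {
  a <- strsplit(toupper(as.character(seqA)), "")[[1]]
  b <- strsplit(toupper(as.character(seqB)), "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  ok <- a %in% .BASES & b %in% .BASES
  if (!any(ok)) stop("no comparable sites (all gaps or ambiguous)")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Divergence time from a genetic distance and a substitution rate
#'
#' For mitochondrial COI a commonly applied rate is 2% divergence per million
#' years, so a 6% distance dates a split at roughly 3 Myr.
#'
#' @param distance proportion of differing sites (>= 0)
#' @param rate_per_myr divergence per million years (default 0.02)
#' @return time in millions of years
#' @examples
#' divergence_time(0.06, 0.02)  # 3 Myr
#' @export
divergence_time <- function(distance, rate_per_myr = 0.02) {
  if (rate_per_myr <= 0) stop("rate must be positive")
  if (any(distance < 0)) stop("distance must be non-negative")
  distance / rate_per_myr
}
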