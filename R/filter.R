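# Contaminant and rRNA contig filtering.
#
# The rule mirrors a two-database best-hit screen: contigs are kept only
# with a best hit to the reference transcriptome, and contigs hitting both
# databases are discarded when the reference bitscore does not exceed the
# contaminant bitscore by at least `margin` bits. rRNA-like contigs are
# removed on any hit at or below an e-value cutoff.

#' Filter contigs against reference and contaminant databases
#'
#' A contig is kept iff it has a reference-database hit AND either no
#' contaminant hit (`ref-only-hit`) or a reference bitscore at least
#' `margin` bits above the contaminant bitscore (`margin-pass`). Contigs
#' failing the margin (`margin-fail`), hitting only the contaminant database
#' (`contaminant-only-hit`) or hitting nothing (`no-hit`) are discarded.
#'
#' @param contigs named character vector / DNAStringSet of contigs
#' @param reference_db,contaminant_db named sequence sets (non-empty)
#' @param margin required bitscore difference in bits (default 100)
#' @param scoring an [align_scoring()] object
#' @return data.frame of `FilterDecision`s: contig, kept, reason,
#'   best_ref_bits, best_contam_bits; exactly one row per input contig
#' @export
contaminant_filter <- function(contigs, reference_db, contaminant_db,
                               margin = 100, scoring = align_scoring()) {
  contigs <- .as_named_character(contigs, "contig")
  if (length(reference_db) == 0 || length(contaminant_db) == 0) {
    stop("both databases must be non-empty")
  }
  ref_hits <- search_db(contigs, reference_db, scoring)
  con_hits <- search_db(contigs, contaminant_db, scoring)
  ref_bits <- stats::setNames(ref_hits$bits, ref_hits$query)
  con_bits <- stats::setNames(con_hits$bits, con_hits$query)
  decide <- function(id) {
    rb <- ref_bits[id]
    cb <- con_bits[id]
    has_ref <- !is.na(rb)
    has_con <- !is.na(cb)
    if (!has_ref && !has_con) return(list(FALSE, "no-hit"))
    if (!has_ref) return(list(FALSE, "contaminant-only-hit"))
    if (!has_con) return(list(TRUE, "ref-only-hit"))
    if (rb - cb >= margin) list(TRUE, "margin-pass") else
      list(FALSE, "margin-fail")
  }
  dec <- lapply(names(contigs), decide)
  data.frame(contig = names(contigs),
             kept = vapply(dec, function(d) d[[1]], logical(1)),
             reason = vapply(dec, function(d) d[[2]], character(1)),
             best_ref_bits = unname(ref_bits[names(contigs)]),
             best_contam_bits = unname(con_bits[names(contigs)]),
             stringsAsFactors = FALSE)
}

#' Remove rRNA-like contigs by e-value
#'
#' A contig is removed iff it has any hit to the rRNA database with e-value
#' at or below the cutoff (inclusive).
#'
#' @param contigs named sequences
#' @param rrna_db named rRNA sequence database (non-empty)
#' @param evalue_cutoff inclusive e-value threshold (default 1e-10)
#' @param scoring an [align_scoring()] object
#' @return data.frame: contig, kept, reason (`rrna` for removed, `no-hit`
#'   for kept), best_evalue
#' @export
rrna_filter <- function(contigs, rrna_db, evalue_cutoff = 1e-10,
                        scoring = align_scoring()) {
  contigs <- .as_named_character(contigs, "contig")
  if (length(rrna_db) == 0) stop("rRNA database must be non-empty")
  hits <- search_db(contigs, rrna_db, scoring)
  best_e <- hits$evalue[match(names(contigs), hits$query)]
  removed <- !is.na(best_e) & best_e <= evalue_cutoff
  data.frame(contig = names(contigs), kept = !removed,
             reason = ifelse(removed, "rrna", "no-hit"),
             best_evalue = best_e, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Apply both filters and return the cleaned contig set
#'
#' @inheritParams contaminant_filter
#' @inheritParams rrna_filter
#' @return list: `kept` (named sequences surviving both filters),
#'   `decisions` (combined decision table; the rRNA reason overrides for
#'   contigs failing the rRNA screen)
#' @export
filter_contigs <- function(contigs, reference_db, contaminant_db, rrna_db,
                           margin = 100, evalue_cutoff = 1e-10,
                           scoring = align_scoring()) {
  contigs <- .as_named_character(contigs, "contig")
  dec1 <- contaminant_filter(contigs, reference_db, contaminant_db,
                             margin, scoring)
  surv <- contigs[dec1$kept[match(names(contigs), dec1$contig)]]
  dec2 <- rrna_filter(surv, rrna_db, evalue_cutoff, scoring)
  kept_final <- dec2$contig[dec2$kept]
  decisions <- dec1
  rr <- dec2$contig[!dec2$kept]
  decisions$kept[decisions$contig %in% rr] <- FALSE
  decisions$reason[decisions$contig %in% rr] <- "rrna"
  list(kept = contigs[kept_final], decisions = decisions)
}
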