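# Genotype calling from pileups, fixed inter-clone differences,
# bi-directional consolidation over orthologs, and heterozygosity.

#' Call genotypes from a pileup table
#'
#' Per site, in order: `no_call` when total depth (bases + indels) is below
#' `min_depth`; `indel` when the indel read fraction reaches
#' `het_min_fraction`; `hom_alt` when the top non-reference allele reaches
#' `hom_fraction` of base reads; `het` when the second allele reaches
#' `het_min_fraction` with at least `het_min_reads` reads and the reference
#' allele has at least one read; otherwise `hom_ref`.
#'
#' @param pileup data.frame with columns gene, pos, ref, A, C, G, T, ins,
#'   del (depths >= 0; ref in A/C/G/T)
#' @param min_depth minimum callable depth (default 10)
#' @param hom_fraction fraction of base reads for a homozygous call
#'   (default 0.9)
#' @param het_min_fraction minimum fraction for the second allele / indel
#'   reads (default 0.2)
#' @param het_min_reads minimum reads supporting the second allele
#'   (default 2)
#' @return data.frame of `GenotypeCall`s: gene, pos, ref, class, allele1,
#'   allele2 (NA unless het), depth, alt_depth, ref_depth
#' @export
call_genotypes <- function(pileup, min_depth = 10, hom_fraction = 0.9,
                           het_min_fraction = 0.2, het_min_reads = 2) {
  req <- c("gene", "pos", "ref", "A", "C", "G", "T", "ins", "del")
  if (!all(req %in% names(pileup))) {
    stop("pileup must have columns ", paste(req, collapse = ", "))
  }
  if (!all(pileup$ref %in% .BASES)) {
    stop("unknown reference base(s): ",
         paste(unique(pileup$ref[!pileup$ref %in% .BASES]), collapse = ","))
  }
  bm <- as.matrix(pileup[, .BASES])
  storage.mode(bm) <- "integer"
  indel_d <- pileup$ins + pileup$del
  base_d <- rowSums(bm)
  total <- base_d + indel_d
  ref_idx <- match(pileup$ref, .BASES)
  ref_d <- bm[cbind(seq_len(nrow(bm)), ref_idx)]
  # top and second alleles by depth (ties by base order A<C<G<T)
  ord1 <- max.col(bm, ties.method = "first")
  top_d <- bm[cbind(seq_len(nrow(bm)), ord1)]
  bm2 <- bm
  bm2[cbind(seq_len(nrow(bm)), ord1)] <- -1L
  ord2 <- max.col(bm2, ties.method = "first")
  sec_d <- bm[cbind(seq_len(nrow(bm)), ord2)]
  # top non-reference allele
  bmn <- bm
  bmn[cbind(seq_len(nrow(bm)), ref_idx)] <- -1L
  ordn <- max.col(bmn, ties.method = "first")
  alt_d <- bm[cbind(seq_len(nrow(bm)), ordn)]

  class <- rep("hom_ref", nrow(pileup))
  a1 <- .BASES[ord1]
  a2 <- rep(NA_character_, nrow(pileup))

  frac_top_nonref <- ifelse(base_d > 0, alt_d / base_d, 0)
  frac_sec <- ifelse(base_d > 0, sec_d / base_d, 0)
  is_het <- frac_sec >= het_min_fraction & sec_d >= het_min_reads &
    ref_d >= 1
  class[is_het] <- "het"
  a2[is_het] <- .BASES[ord2][is_het]
  is_hom_alt <- frac_top_nonref >= hom_fraction
  class[is_hom_alt] <- "hom_alt"
  a1[is_hom_alt] <- .BASES[ordn][is_hom_alt]
  a2[is_hom_alt] <- NA_character_
  is_indel <- total > 0 & indel_d / total >= het_min_fraction
  class[is_indel] <- "indel"
  class[total < min_depth] <- "no_call"

  data.frame(gene = pileup$gene, pos = pileup$pos, ref = pileup$ref,
             class = class, allele1 = a1, allele2 = a2, depth = total,
             alt_depth = alt_d, ref_depth = ref_d,
             stringsAsFactors = FALSE)
}

#' Extract fixed (homozygous) differences from one direction of calls
#'
#' Rows are exactly the `hom_alt` calls: sites where the read clone is
#' homozygous for an allele differing from the reference clone's base.
#' Heterozygous, indel and uncalled sites are excluded.
#'
#' @param calls output of [call_genotypes()] for clone-X reads on clone-Y
#'   reference
#' @return data.frame: gene, pos, ref, alt
#' @export
fixed_differences <- function(calls) {
  fx <- calls[calls$class == "hom_alt", , drop = FALSE]
  out <- data.frame(gene = fx$gene, pos = fx$pos, ref = fx$ref,
                    alt = fx$allele1, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Consolidate bi-directional fixed differences over ortholog pairs
#'
#' Keeps rows whose gene belongs to a reciprocal-best-hit pair, maps the
#' B-reference direction onto clone-A (reference) coordinates through the
#' pair's alignment, and reports whether each difference was observed in
#' one or both directions. Rows whose position falls in an alignment gap,
#' or whose alleles disagree between directions, are dropped with a warning.
#'
#' @param table_B_on_A fixed differences from B reads on the A reference
#'   (gene = A id; ref = A allele, alt = B allele)
#' @param table_A_on_B fixed differences from A reads on the B reference
#'   (gene = B id; ref = B allele, alt = A allele)
#' @param pairs an `rbh_pairs` object from [reciprocal_best_hits()]
#' @return `FixedVariantTable` data.frame: geneA, posA, alleleA, geneB,
#'   posB, alleleB, directions ("both", "B_on_A", "A_on_B")
#' @export
consolidate_bidirectional <- function(table_B_on_A, table_A_on_B, pairs) {
  stopifnot(inherits(pairs, "rbh_pairs"))
  pr <- pairs$pairs
  ab <- table_B_on_A[table_B_on_A$gene %in% pr$geneA, , drop = FALSE]
  ba <- table_A_on_B[table_A_on_B$gene %in% pr$geneB, , drop = FALSE]

  ab_rows <- data.frame(geneA = ab$gene,
                        posA = ab$pos, alleleA = ab$ref,
                        geneB = pr$geneB[match(ab$gene, pr$geneA)],
                        posB = NA_integer_, alleleB = ab$alt,
                        dir = "B_on_A", stringsAsFactors = FALSE)

  ba_rows <- NULL
  if (nrow(ba) > 0) {
    geneA <- pr$geneA[match(ba$gene, pr$geneB)]
    posA <- integer(nrow(ba))
    keep <- logical(nrow(ba))
    for (i in seq_len(nrow(ba))) {
      m <- map_position(pairs, geneA[i], ba$pos[i], from = "B")
      if (is.na(m)) {
        keep[i] <- FALSE
      } else {
        posA[i] <- m
        keep[i] <- TRUE
      }
    }
    if (any(!keep)) {
      warning(sum(!keep), " row(s) dropped: position unmappable through ",
              "the ortholog alignment")
    }
    ba <- ba[keep, , drop = FALSE]
    if (nrow(ba) > 0) {
      ba_rows <- data.frame(geneA = geneA[keep], posA = posA[keep],
                            alleleA = ba$alt,
                            geneB = ba$gene, posB = ba$pos,
                            alleleB = ba$ref, dir = "A_on_B",
                            stringsAsFactors = FALSE)
    }
  }

  all_rows <- rbind(ab_rows, ba_rows)
  if (is.null(all_rows) || nrow(all_rows) == 0) {
    return(data.frame(geneA = character(0), posA = integer(0),
                      alleleA = character(0), geneB = character(0),
                      posB = integer(0), alleleB = character(0),
                      directions = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(all_rows$geneA, all_rows$posA)
  merged <- lapply(split(all_rows, key), function(d) {
    if (nrow(d) > 1 &&
        (length(unique(d$alleleA)) > 1 || length(unique(d$alleleB)) > 1)) {
      return(NULL)  # allele conflict between directions
    }
    posB <- d$posB[!is.na(d$posB)]
    data.frame(geneA = d$geneA[1], posA = d$posA[1],
               alleleA = d$alleleA[1], geneB = d$geneB[1],
               posB = if (length(posB)) posB[1] else NA_integer_,
               alleleB = d$alleleB[1],
               directions = if (length(unique(d$dir)) == 2) "both"
                            else d$dir[1],
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(merged, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " site(s) dropped: allele conflict between directions")
  }
  out <- do.call(rbind, merged[!vapply(merged, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(geneA = character(0), posA = integer(0),
                      alleleA = character(0), geneB = character(0),
                      posB = integer(0), alleleB = character(0),
                      directions = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$geneA, out$posA), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Heterozygosity from a clone's own calls on its own reference
#'
#' H = heterozygous calls / callable sites, where callable excludes
#' `no_call` sites (`denominator = "callable"`, the default) or counts every
#' piled-up site (`denominator = "all"`).
#'
#' @param calls output of [call_genotypes()] (self direction)
#' @param clone clone id carried into the estimate
#' @param denominator `"callable"` or `"all"`
#' @return list (`HeterozygosityEstimate`): clone, het_sites, total_sites, H
#' @export
heterozygosity <- function(calls, clone = NA_character_,
                           denominator = c("callable", "all")) {
  denominator <- match.arg(denominator)
  if (nrow(calls) == 0) stop("no sites in call table")
  total <- if (denominator == "callable") {
    sum(calls$class != "no_call")
  } else {
    nrow(calls)
  }
  if (total == 0) stop("zero callable sites")
  het <- sum(calls$class == "het")
  list(clone = clone, het_sites = het, total_sites = total, H = het / total)
}
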