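#' SNP panel of parental haplotypes
#'
#' A `snp_panel` is a data frame with one row per biallelic SNP and columns
#' `chrom`, `pos` (1-based), `ref`, `alt`, the four parental haplotype
#' alleles `m1`, `m2` (maternal) and `p1`, `p2` (paternal) coded 0 = ref,
#' 1 = alt, and logical flags `phased_m`, `phased_p`. For unphased parents
#' the two alleles are stored in arbitrary order with the flag `FALSE`.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param ref,alt allele strings.
#' @param m1,m2,p1,p2 integer haplotype alleles in \{0, 1\}.
#' @param phased_m,phased_p logical; whether the stored allele order is a
#'   true phase for the mother / father.
#' @return a data frame of class `snp_panel`.
#' @export
snp_panel <- function(chrom, pos, ref, alt, m1, m2, p1, p2,
                      phased_m = TRUE, phased_p = TRUE) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    m1 = as.integer(m1), m2 = as.integer(m2),
    p1 = as.integer(p1), p2 = as.integer(p2),
    phased_m = rep_len(as.logical(phased_m), length(pos)),
    phased_p = rep_len(as.logical(phased_p), length(pos)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("snp_panel", "data.frame")
  validate_snp_panel(df)
}

validate_snp_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  alle <- c(panel$m1, panel$m2, panel$p1, panel$p2)
  if (!all(alle %in% c(0L, 1L)))
    stop("haplotype alleles must be coded 0 (ref) or 1 (alt)")
  for (ch in unique(panel$chrom)) {
    p <- panel$pos[panel$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  panel
}

#' Per-embryo B-allele frequencies aligned to a SNP panel
#'
#' @param embryo_id,family_id identifiers.
#' @param baf numeric vector in \[0, 1\] (NA = missing), one value per panel
#'   site, in panel order.
#' @param maternal_age,paternal_age parental ages in years (optional).
#' @return an object of class `embryo_baf`.
#' @export
embryo_baf <- function(embryo_id, family_id, baf,
                       maternal_age = NA_real_, paternal_age = NA_real_) {
  baf <- as.numeric(baf)
  bad <- which(!is.na(baf) & (baf < 0 | baf > 1))
  if (length(bad))
    stop("BAF outside [0,1] at site index ", bad[1])
  structure(
    list(embryo_id = as.character(embryo_id),
         family_id = as.character(family_id),
         baf = baf,
         maternal_age = as.numeric(maternal_age),
         paternal_age = as.numeric(paternal_age)),
    class = "embryo_baf"
  )
}

#' @export
print.embryo_baf <- function(x, ...) {
  cat("<embryo_baf> ", x$embryo_id, " (family ", x$family_id, "): ",
      length(x$baf), " sites, ", sum(is.na(x$baf)), " missing\n", sep = "")
  invisible(x)
}

#' Genetic map
#'
#' Anchors linking physical (bp) to genetic (cM) coordinates, at least two
#' per chromosome, non-decreasing in cM and strictly increasing in bp.
#'
#' @param chrom,pos_bp,pos_cM anchor columns.
#' @return a data frame of class `genetic_map`.
#' @export
genetic_map <- function(chrom, pos_bp, pos_cM) {
  df <- data.frame(chrom = as.character(chrom), pos_bp = as.numeric(pos_bp),
                   pos_cM = as.numeric(pos_cM), stringsAsFactors = FALSE)
  for (ch in unique(df$chrom)) {
    i <- df$chrom == ch
    if (sum(i) < 2) stop("genetic map needs >= 2 anchors on chromosome ", ch)
    if (any(diff(df$pos_bp[i]) <= 0))
      stop("genetic map bp positions must be strictly increasing on ", ch)
    if (any(diff(df$pos_cM[i]) < 0))
      stop("genetic map cM values must be non-decreasing on ", ch)
    if (any(df$pos_cM[i] < 0)) stop("negative cM on ", ch)
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Interpolate genetic-map position
#'
#' Linear interpolation of cM at physical positions; queries beyond the
#' terminal anchors clamp to the terminal cM values.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome label (length 1).
#' @param pos_bp numeric vector of query positions.
#' @return numeric vector of cM positions.
#' @export
interpolate_cM <- function(map, chrom, pos_bp) {
  i <- map$chrom == chrom
  if (!any(i)) stop("chromosome ", chrom, " not in genetic map")
  stats::approx(map$pos_bp[i], map$pos_cM[i], xout = pos_bp,
                rule = 2, ties = "ordered")$y
}

#' Build a uniform-rate genetic map
#'
#' @param chrom chromosome labels.
#' @param length_bp physical length per chromosome.
#' @param length_cM genetic length per chromosome.
#' @return a [genetic_map()] with anchors at 0 and `length_bp`.
#' @export
uniform_genetic_map <- function(chrom, length_bp, length_cM) {
  length_bp <- rep_len(length_bp, length(chrom))
  length_cM <- rep_len(length_cM, length(chrom))
  genetic_map(chrom = rep(chrom, each = 2),
              pos_bp = as.numeric(rbind(1, length_bp)),
              pos_cM = as.numeric(rbind(0, length_cM)))
}

#' Interval track (hotspots, replication timing)
#'
#' 0-based half-open intervals with an optional value column.
#'
#' @param chrom,start,end interval columns (0-based half-open).
#' @param value optional numeric values (bedGraph-style tracks).
#' @return a data frame of class `interval_track`.
#' @export
interval_track <- function(chrom, start, end, value = NULL) {
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop("interval end must exceed start (interval ", bad, ")")
  }
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  df$value <- if (is.null(value)) rep(NA_real_, nrow(df))
              else as.numeric(value)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_track", "data.frame")
  df
}

#' Merge overlapping intervals of a track
#'
#' Values are dropped; used for hotspot occupancy where only coverage
#' matters.
#'
#' @param track an [interval_track()].
#' @return merged [interval_track()].
#' @export
merge_intervals <- function(track) {
  if (nrow(track) == 0) return(track)
  gr <- GenomicRanges::reduce(track_to_granges(track))
  interval_track(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr))
}

# 0-based half-open track -> 1-based closed GRanges
track_to_granges <- function(track) {
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end)
  )
}
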