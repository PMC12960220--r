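#' Read parental genotypes into a SNP panel
#'
#' Accepts a VCF with exactly two samples (mother first, father second,
#' unless `samples` names them) or a 6-column tab-separated table with
#' columns `chrom`, `pos`, `ref`, `alt`, `mother`, `father` holding
#' genotypes such as `0|1` or `0/1`. Sites with missing or non-biallelic
#' genotypes are dropped with a message reporting the count. Phase flags
#' are taken from the `|` separator (VCF) or set per column in the table.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension by default.
#' @param samples for VCF, optional character vector
#'   `c(mother, father)` selecting/ordering the two samples.
#' @return a [snp_panel()].
#' @export
read_parent_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                                  samples = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"

  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt)) || ncol(gt) != 2) {
      if (!is.null(samples) && !is.null(dim(gt)) &&
          all(samples %in% colnames(gt))) {
        gt <- gt[, samples, drop = FALSE]
      } else stop("two parent samples required, found ",
                  if (is.null(dim(gt))) 1 else ncol(gt))
    } else if (!is.null(samples)) {
      if (!all(samples %in% colnames(gt)))
        stop("samples not found in VCF: ",
             paste(setdiff(samples, colnames(gt)), collapse = ", "))
      gt <- gt[, samples, drop = FALSE]
    }
    fix <- vcfR::getFIX(v)
    chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    gm <- gt[, 1]; gf <- gt[, 2]
  } else {
    tb <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "integer",
                                           "character", "character",
                                           "character", "character"))
    need <- c("chrom", "pos", "ref", "alt", "mother", "father")
    if (!all(need %in% names(tb)))
      stop("parent genotype table needs columns: ",
           paste(need, collapse = ", "))
    chrom <- tb$chrom; pos <- tb$pos; ref <- tb$ref; alt <- tb$alt
    gm <- tb$mother; gf <- tb$father
  }

  pg <- function(g) {
    a <- regmatches(g, regexec("^([0-9.])([/|])([0-9.])$", g))
    t(vapply(a, function(x) {
      if (length(x) == 0) c(NA_integer_, NA_integer_, NA)
      else c(suppressWarnings(as.integer(x[2])),
             suppressWarnings(as.integer(x[4])),
             as.integer(x[3] == "|"))
    }, integer(3)))
  }
  am <- pg(gm); af <- pg(gf)
  multi <- grepl(",", alt)
  badal <- apply(cbind(am[, 1:2], af[, 1:2]), 1,
                 function(x) any(!is.na(x) & x > 1))
  keep <- stats::complete.cases(am[, 1:2], af[, 1:2]) & !multi & !badal
  ndrop <- sum(!keep)
  if (ndrop > 0)
    message("dropped ", ndrop, " site(s) with missing or non-biallelic genotypes")
  panel <- snp_panel(chrom[keep], pos[keep], ref[keep], alt[keep],
                     m1 = am[keep, 1], m2 = am[keep, 2],
                     p1 = af[keep, 1], p2 = af[keep, 2],
                     phased_m = am[keep, 3] == 1L,
                     phased_p = af[keep, 3] == 1L)
  panel
}

#' Read embryo B-allele frequencies
#'
#' Long format: columns `embryo_id`, `family_id`, `chrom`, `pos`, `baf`.
#' Wide format: columns `chrom`, `pos` followed by one column per embryo
#' (supply `family_id`). Sites are matched to the panel by `chrom:pos`;
#' values outside \[0, 1\] are an error naming the site, `NA` entries are
#' kept as missing.
#'
#' @param path file path (tab-separated, header line).
#' @param panel the [snp_panel()] the BAF values are keyed to.
#' @param format `"long"` or `"wide"`.
#' @param family_id family identifier for wide tables.
#' @return a list of [embryo_baf()] objects.
#' @export
read_embryo_baf <- function(path, panel, format = c("long", "wide"),
                            family_id = "fam1") {
  format <- match.arg(format)
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  key <- paste(panel$chrom, panel$pos)
  if (format == "long") {
    need <- c("embryo_id", "family_id", "chrom", "pos", "baf")
    if (!all(need %in% names(tb)))
      stop("long BAF table needs columns: ", paste(need, collapse = ", "))
    tb$.key <- paste(tb$chrom, tb$pos)
    unknown <- setdiff(tb$.key, key)
    if (length(unknown))
      stop("BAF site not in panel: ", unknown[1])
    check_baf_range(tb$baf, tb$.key)
    out <- lapply(split(tb, tb$embryo_id), function(d) {
      b <- rep(NA_real_, nrow(panel))
      b[match(d$.key, key)] <- d$baf
      embryo_baf(d$embryo_id[1], d$family_id[1], b)
    })
  } else {
    if (!all(c("chrom", "pos") %in% names(tb)))
      stop("wide BAF table needs chrom and pos columns")
    tb$.key <- paste(tb$chrom, tb$pos)
    unknown <- setdiff(tb$.key, key)
    if (length(unknown))
      stop("BAF site not in panel: ", unknown[1])
    ecols <- setdiff(names(tb), c("chrom", "pos", ".key"))
    out <- lapply(ecols, function(e) {
      check_baf_range(tb[[e]], tb$.key)
      b <- rep(NA_real_, nrow(panel))
      b[match(tb$.key, key)] <- tb[[e]]
      embryo_baf(e, family_id, b)
    })
    names(out) <- ecols
  }
  out
}

check_baf_range <- function(b, sitekey) {
  bad <- which(!is.na(b) & (b < 0 | b > 1))
  if (length(bad))
    stop("BAF outside [0,1] at site ", sitekey[bad[1]])
  invisible(TRUE)
}

#' Read a genetic map from a 3-column table
#'
#' Plain whitespace/tab-separated columns `chrom`, `pos_bp`, `pos_cM` with a
#' header line. Non-monotone cM anchors are an error at load time.
#'
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  tb <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tb) < 3) stop("genetic map needs 3 columns: chrom, pos_bp, pos_cM")
  genetic_map(tb[[1]], tb[[2]], tb[[3]])
}

#' Read a BED or bedGraph interval track
#'
#' Hotspot BED intervals are merged after loading; bedGraph tracks retain
#' their value column. Coordinates stay 0-based half-open.
#'
#' @param path file path.
#' @param kind `"bed"` (hotspots; merged) or `"bedgraph"` (valued track).
#' @return an [interval_track()].
#' @export
read_interval_track <- function(path, kind = c("bed", "bedgraph")) {
  kind <- match.arg(kind)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           sep = "\t", comment.char = "#")
  ncol_need <- if (kind == "bedgraph") 4L else 3L
  if (ncol(raw) < ncol_need)
    stop("expected at least ", ncol_need, " columns in ", kind, " file")
  bad <- which(!(is.numeric(raw[[2]]) & is.numeric(raw[[3]])) |
                 raw[[3]] <= raw[[2]])
  if (length(bad))
    stop("invalid interval (end <= start) at line ", bad[1], " of ", path)
  gr <- rtracklayer::import(path,
                            format = if (kind == "bed") "BED" else "bedGraph")
  tr <- interval_track(as.character(GenomicRanges::seqnames(gr)),
                       GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr),
                       value = if (kind == "bedgraph") gr$score else NULL)
  if (kind == "bed") merge_intervals(tr) else tr
}

#' Call set container
#'
#' Bundles per-chromosome ploidy calls, crossover events and run metadata.
#'
#' @param calls data frame with columns `embryo_id`, `chrom`, `call`,
#'   `origin`, `meiotic_class`, `posterior`, `k`.
#' @param events data frame with columns `embryo_id`, `parent`, `chrom`,
#'   `left`, `right` (1-based flanking informative SNP positions),
#'   `gamma_left`, `gamma_right`.
#' @param meta list of run metadata (seed, version, ...).
#' @return an object of class `callset`.
#' @export
callset <- function(calls, events, meta = list()) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events)) {
    if (!all(events$embryo_id %in% calls$embryo_id))
      stop("crossover event references unknown embryo")
    ek <- paste(events$embryo_id, events$chrom)
    ck <- paste(calls$embryo_id, calls$chrom)
    if (!all(ek %in% ck[calls$call == "disomy"]))
      stop("crossover event on chromosome not called disomic")
  }
  structure(list(calls = calls, events = events, meta = meta),
            class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  cat("<callset> ", length(unique(x$calls$embryo_id)), " embryos, ",
      nrow(x$calls), " chromosome calls, ", nrow(x$events),
      " crossover events\n", sep = "")
  invisible(x)
}

empty_calls <- function() {
  data.frame(embryo_id = character(), chrom = character(),
             call = character(), origin = character(),
             meiotic_class = character(), posterior = numeric(),
             k = integer(), stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(embryo_id = character(), parent = character(),
             chrom = character(), left = integer(), right = integer(),
             gamma_left = numeric(), gamma_right = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a call set to disk
#'
#' Ploidy calls as TSV, crossovers as BED (start = 0-based left flanking
#' informative SNP, end = 0-based right flanking SNP + 1, name =
#' `embryo_id|parent`, score = 1000 x min flank posterior; full-precision
#' flank posteriors in extra columns 7-8), metadata as JSON.
#' `read_callset()` on the output directory round-trips exactly.
#'
#' @param x a [callset()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_callset <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  p_calls <- file.path(out_dir, "ploidy_calls.tsv")
  p_bed <- file.path(out_dir, "crossovers.bed")
  p_meta <- file.path(out_dir, "metadata.json")
  utils::write.table(x$calls, p_calls, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ev <- x$events
  bed <- data.frame(
    chrom = ev$chrom,
    start = as.integer(ev$left) - 1L,
    end = as.integer(ev$right),                 # (right - 1) + 1, 0-based
    name = paste(ev$embryo_id, ev$parent, sep = "|"),
    score = as.integer(round(1000 * pmin(ev$gamma_left, ev$gamma_right))),
    strand = rep(".", nrow(ev)),
    gamma_left = ev$gamma_left,
    gamma_right = ev$gamma_right,
    stringsAsFactors = FALSE
  )
  has_fam <- "family_id" %in% names(ev)
  if (has_fam) bed$family_id <- ev$family_id
  con <- file(p_bed, "w")
  writeLines(paste0("#chrom\tstart\tend\tname\tscore\tstrand",
                    "\tgamma_left\tgamma_right",
                    if (has_fam) "\tfamily_id"), con)
  if (nrow(bed))
    utils::write.table(format(bed, scientific = FALSE, trim = TRUE,
                              digits = 17),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  close(con)
  jsonlite::write_json(x$meta, p_meta, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(calls = p_calls, crossovers = p_bed, metadata = p_meta))
}

#' Read a call set written by [write_callset()]
#'
#' @param dir directory containing `ploidy_calls.tsv`, `crossovers.bed`,
#'   `metadata.json`.
#' @return a [callset()].
#' @export
read_callset <- function(dir) {
  calls <- utils::read.table(file.path(dir, "ploidy_calls.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c(embryo_id = "character",
                                            chrom = "character"))
  lines <- readLines(file.path(dir, "crossovers.bed"))
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines)) {
    bed <- utils::read.table(text = lines, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "integer", "integer",
                                            "character", "integer",
                                            "character", "numeric", "numeric",
                                            "character")[seq_len(
                               length(strsplit(lines[1], "\t")[[1]]))])
    nm <- strsplit(bed[[4]], "|", fixed = TRUE)
    events <- data.frame(
      embryo_id = vapply(nm, `[`, "", 1),
      parent = vapply(nm, `[`, "", 2),
      chrom = bed[[1]],
      left = bed[[2]] + 1L,
      right = bed[[3]],
      gamma_left = bed[[7]],
      gamma_right = bed[[8]],
      stringsAsFactors = FALSE
    )
    if (ncol(bed) >= 9) events$family_id <- bed[[9]]
  } else events <- empty_events()
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  callset(calls, events, meta)
}
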