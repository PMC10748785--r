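## I/O layer: VCF, BED, FASTA, and report writing.  All coordinate
## conversions between the file formats (BED 0-based half-open, VCF 1-based)
## and the internal 1-based inclusive representation happen here and nowhere
## else.

#' Caller dialect for quality-parameter extraction
#'
#' Different variant callers store the variant allele frequency (VAF), depth
#' (DP) and strand bias (STB) under different VCF keys.  A dialect is an
#' ordered lookup plan per parameter; named dialects put the caller's own
#' fields first and then fall back to a generic chain, so a parameter is
#' marked missing (`NA`) only when no recognised source exists.
#'
#' The generic fallback chain is: VAF from `FORMAT/AF`, then `INFO/AF`, then
#' `FORMAT/AD` as alt/(ref+alt), then `INFO/AO,RO`; DP from `FORMAT/DP`, then
#' `INFO/DP`, then the sum of `FORMAT/AD`; STB from `INFO/STB`, then
#' `INFO/SAF,SAR`, then `FORMAT/ADF,ADR`, then `INFO/DP4`; QUAL from the VCF
#' QUAL column; QD from `INFO/QD`, else computed as [compute_qd()].
#'
#' @param name One of `"gatk-hc"`, `"tvc"`, `"lofreq"`, `"deepvariant"`,
#'   `"generic"`.
#' @return A `caller_dialect` object (list of ordered source names).
#' @export
caller_dialect <- function(name = c("generic", "gatk-hc", "tvc", "lofreq",
                                    "deepvariant")) {
  name <- match.arg(name)
  gen_vaf <- c("format_af", "info_af", "format_ad", "info_aoro")
  gen_dp  <- c("format_dp", "info_dp", "format_ad_sum")
  gen_stb <- c("info_stb", "info_safsar", "format_adfadr", "info_dp4")
  plan <- switch(name,
    "gatk-hc"     = list(vaf = c("format_af", "format_ad"),
                         dp  = c("format_dp"), stb = c("format_sb")),
    "tvc"         = list(vaf = c("info_af"), dp = c("info_dp"),
                         stb = c("info_stb", "info_safsar")),
    "lofreq"      = list(vaf = c("info_af"), dp = c("info_dp"),
                         stb = c("info_dp4")),
    "deepvariant" = list(vaf = c("format_vaf", "format_af", "format_ad"),
                         dp  = c("format_dp"), stb = character(0)),
    "generic"     = list(vaf = character(0), dp = character(0),
                         stb = character(0))
  )
  structure(list(name = name,
                 vaf = unique(c(plan$vaf, gen_vaf)),
                 dp  = unique(c(plan$dp, gen_dp)),
                 stb = unique(c(plan$stb, gen_stb))),
            class = "caller_dialect")
}

## ---- VCF reading -----------------------------------------------------------

split_commas <- function(x) {
  if (is.na(x)) return(NA_character_)
  strsplit(x, ",", fixed = TRUE)[[1]]
}

parse_info_string <- function(s) {
  if (is.na(s) || s == "." || s == "") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq > 0) {
      out[[substr(p, 1L, eq - 1L)]] <- split_commas(substr(p, eq + 1L, nchar(p)))
    } else {
      out[[p]] <- TRUE  # flag
    }
  }
  out
}

parse_format_pair <- function(fmt, sample) {
  if (is.na(fmt) || is.na(sample)) return(list())
  keys <- strsplit(fmt, ":", fixed = TRUE)[[1]]
  vals <- strsplit(sample, ":", fixed = TRUE)[[1]]
  out <- list()
  for (i in seq_along(keys)) {
    if (i <= length(vals)) out[[keys[i]]] <- split_commas(vals[i])
  }
  out
}

## Number= declarations from ##INFO/##FORMAT meta lines; used to slice
## per-allele arrays when splitting multi-allelic records.
parse_number_map <- function(meta) {
  m <- regmatches(meta, regexec(
    "^##(INFO|FORMAT)=<ID=([^,>]+),Number=([^,>]+)", meta))
  m <- m[lengths(m) == 4L]
  if (!length(m)) return(list(INFO = character(0), FORMAT = character(0)))
  tab <- do.call(rbind, m)
  list(INFO   = setNames(tab[tab[, 2] == "INFO", 4],   tab[tab[, 2] == "INFO", 3]),
       FORMAT = setNames(tab[tab[, 2] == "FORMAT", 4], tab[tab[, 2] == "FORMAT", 3]))
}

is_symbolic_alt <- function(alts) {
  any(grepl("[][<>]", alts)) || any(alts == "*") || any(alts == ".")
}

#' Read a VCF file into raw records
#'
#' Parses a VCF 4.x file (plain or bgzipped) into a list of raw records, each
#' carrying the parsed INFO map and the first sample's FORMAT map.  Records
#' with symbolic or breakend ALT alleles (`<DEL>`, `N[chr2:123[`, `*`) are
#' skipped with a warning and counted in the returned object.
#'
#' @param path Path to the VCF file.
#' @param dialect A [caller_dialect()] (or a dialect name) used downstream to
#'   resolve quality parameters.
#' @param pass_only Drop records whose FILTER is neither `PASS` nor `.`
#'   (default keeps everything; the FILTER string is retained on each record).
#' @return An object of class `raw_vcf`: a list with `records` (list of
#'   records), `dialect`, `number_map` and `counts` (records read, symbolic
#'   skipped, filtered out).
#' @export
read_vcf <- function(path, dialect = caller_dialect("generic"),
                     pass_only = FALSE) {
  if (is.character(dialect)) dialect <- caller_dialect(dialect)
  if (!file.exists(path)) vb_stop("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  nm <- parse_number_map(v@meta)
  fix <- v@fix
  gt <- v@gt
  has_gt <- !is.null(gt) && ncol(gt) >= 2L
  if (has_gt && ncol(gt) > 2L) {
    vb_warn("multi-sample VCF '%s': using first sample (%s) only",
            basename(path), colnames(gt)[2])
  }
  n_meta <- length(v@meta) + 1L  # meta lines plus #CHROM header
  records <- vector("list", nrow(fix))
  n_symbolic <- 0L; n_filtered <- 0L
  keep <- logical(nrow(fix))
  for (i in seq_len(nrow(fix))) {
    line_no <- n_meta + i
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    ref <- toupper(fix[i, "REF"])
    alt_s <- fix[i, "ALT"]
    if (is.na(pos) || pos < 1L || is.na(ref) || !nzchar(ref) ||
        is.na(alt_s) || !nzchar(alt_s)) {
      vb_stop("malformed VCF record at line %d of %s", line_no, path)
    }
    alts <- toupper(split_commas(alt_s))
    if (is_symbolic_alt(alts)) {
      n_symbolic <- n_symbolic + 1L
      vb_warn("skipping symbolic/breakend ALT at line %d (%s:%s)",
              line_no, fix[i, "CHROM"], fix[i, "POS"])
      next
    }
    if (!is_dna(ref) || !all(is_dna(alts)) || any(alts == ref)) {
      vb_stop("malformed REF/ALT at line %d of %s", line_no, path)
    }
    filt <- fix[i, "FILTER"]
    if (is.na(filt)) filt <- "."
    if (pass_only && !(filt %in% c("PASS", "."))) {
      n_filtered <- n_filtered + 1L
      next
    }
    records[[i]] <- list(
      chrom = unname(fix[i, "CHROM"]), pos = pos,
      id = if (is.na(fix[i, "ID"])) "." else unname(fix[i, "ID"]),
      ref = unname(ref), alts = unname(alts),
      qual = unname(num_or_na(fix[i, "QUAL"])),
      filter = unname(filt),
      info = parse_info_string(fix[i, "INFO"]),
      format = if (has_gt) parse_format_pair(gt[i, 1], gt[i, 2]) else list(),
      line = line_no
    )
    keep[i] <- TRUE
  }
  structure(list(records = records[keep], dialect = dialect, number_map = nm,
                 path = path,
                 counts = list(n_records = sum(keep),
                               n_symbolic_skipped = n_symbolic,
                               n_filtered = n_filtered)),
            class = "raw_vcf")
}

#' @export
print.raw_vcf <- function(x, ...) {
  cat(sprintf("raw_vcf: %d records (%d symbolic skipped, %d filtered) [%s dialect]\n",
              x$counts$n_records, x$counts$n_symbolic_skipped,
              x$counts$n_filtered, x$dialect$name))
  invisible(x)
}

#' Write raw VCF records to a file
#'
#' Serialises a `raw_vcf` object (or a plain list of records) back to VCF 4.2
#' text.  Used by the synthetic generator and for round-trip checks.
#'
#' @param x A `raw_vcf` object or list of raw records.
#' @param path Output path.
#' @param meta Extra meta header lines (character vector, without trailing
#'   newlines).
#' @param sample_name Sample column name when any record carries FORMAT data.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, meta = character(0), sample_name = "SAMPLE") {
  records <- if (inherits(x, "raw_vcf")) x$records else x
  has_fmt <- any(vapply(records, function(r) length(r$format) > 0, logical(1)))
  hdr <- c("##fileformat=VCFv4.2", meta,
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                  if (has_fmt) paste0("\tFORMAT\t", sample_name) else ""))
  fmt_info <- function(info) {
    if (!length(info)) return(".")
    paste(vapply(names(info), function(k) {
      v <- info[[k]]
      if (isTRUE(v)) k else paste0(k, "=", paste(v, collapse = ","))
    }, character(1)), collapse = ";")
  }
  lines <- vapply(records, function(r) {
    base <- paste(r$chrom, r$pos, r$id %||% ".", r$ref,
                  paste(r$alts, collapse = ","),
                  if (is.na(r$qual)) "." else format(r$qual, digits = 8),
                  r$filter %||% ".", fmt_info(r$info), sep = "\t")
    if (has_fmt) {
      if (length(r$format)) {
        base <- paste(base, paste(names(r$format), collapse = ":"),
                      paste(vapply(r$format, paste, character(1),
                                   collapse = ","), collapse = ":"),
                      sep = "\t")
      } else {
        base <- paste(base, "GT", ".", sep = "\t")
      }
    }
    base
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

## ---- parameter resolution --------------------------------------------------

## Source registry: each function resolves one parameter for alt allele `ai`
## (1-based) of a record, returning NA when the source is absent.  `nm` is the
## header Number map; fields declared Number=A/R are sliced accordingly, with
## a fallback to well-known keys when the header is silent.
known_numbers <- c(AF = "A", AO = "A", SAF = "A", SAR = "A", MLEAF = "A",
                   VAF = "A", AD = "R", ADF = "R", ADR = "R",
                   DP = "1", RO = "1", STB = "A", QD = "1", DP4 = "4",
                   SB = "4")

field_number <- function(key, where, nm) {
  decl <- nm[[where]]
  if (!is.null(decl) && key %in% names(decl)) return(unname(decl[[key]]))
  if (key %in% names(known_numbers)) return(unname(known_numbers[[key]]))
  NA_character_
}

get_field <- function(rec, where, key) {
  src <- if (where == "INFO") rec$info else rec$format
  v <- src[[key]]
  if (is.null(v) || isTRUE(v)) return(NULL)
  v
}

## Slice a raw field for alt allele ai given its declared Number.
slice_field <- function(rec, where, key, ai, nm) {
  v <- get_field(rec, where, key)
  if (is.null(v)) return(NA_real_)
  n_alt <- length(rec$alts)
  number <- field_number(key, where, nm)
  vals <- suppressWarnings(as.numeric(v))
  if (identical(number, "A")) {
    if (length(vals) != n_alt) return(NA_real_)
    return(vals[ai])
  }
  if (identical(number, "R")) {
    if (length(vals) != n_alt + 1L) return(NA_real_)
    return(vals[ai + 1L])
  }
  vals[1]
}

param_sources <- list(
  format_af  = function(rec, ai, nm) slice_field(rec, "FORMAT", "AF", ai, nm),
  format_vaf = function(rec, ai, nm) slice_field(rec, "FORMAT", "VAF", ai, nm),
  info_af    = function(rec, ai, nm) slice_field(rec, "INFO", "AF", ai, nm),
  format_ad  = function(rec, ai, nm) {
    ## alt reads over total allelic depth (all alleles)
    ad <- suppressWarnings(as.numeric(get_field(rec, "FORMAT", "AD")))
    if (length(ad) != length(rec$alts) + 1L) return(NA_real_)
    tot <- sum(ad)
    if (is.na(tot) || tot == 0) return(NA_real_)
    ad[ai + 1L] / tot
  },
  info_aoro  = function(rec, ai, nm) {
    ao <- slice_field(rec, "INFO", "AO", ai, nm)
    ro <- suppressWarnings(as.numeric(get_field(rec, "INFO", "RO")))[1]
    if (is.na(ao) || is.na(ro) || ao + ro == 0) return(NA_real_)
    ao / (ao + ro)
  },
  format_dp  = function(rec, ai, nm) slice_field(rec, "FORMAT", "DP", ai, nm),
  info_dp    = function(rec, ai, nm) slice_field(rec, "INFO", "DP", ai, nm),
  format_ad_sum = function(rec, ai, nm) {
    ad <- suppressWarnings(as.numeric(get_field(rec, "FORMAT", "AD")))
    if (!length(ad) || anyNA(ad)) return(NA_real_)
    sum(ad)
  },
  info_stb   = function(rec, ai, nm) slice_field(rec, "INFO", "STB", ai, nm),
  info_safsar = function(rec, ai, nm) {
    saf <- slice_field(rec, "INFO", "SAF", ai, nm)
    sar <- slice_field(rec, "INFO", "SAR", ai, nm)
    strand_fraction(saf, sar)
  },
  format_adfadr = function(rec, ai, nm) {
    adf <- slice_field(rec, "FORMAT", "ADF", ai, nm)
    adr <- slice_field(rec, "FORMAT", "ADR", ai, nm)
    strand_fraction(adf, adr)
  },
  info_dp4   = function(rec, ai, nm) {
    dp4 <- suppressWarnings(as.numeric(get_field(rec, "INFO", "DP4")))
    if (length(dp4) != 4L) return(NA_real_)
    strand_fraction(dp4[3], dp4[4])
  },
  format_sb  = function(rec, ai, nm) {
    sb <- suppressWarnings(as.numeric(get_field(rec, "FORMAT", "SB")))
    if (length(sb) != 4L) return(NA_real_)
    strand_fraction(sb[3], sb[4])
  }
)

strand_fraction <- function(fwd, rev) {
  if (is.na(fwd) || is.na(rev) || fwd + rev == 0) return(NA_real_)
  max(fwd, rev) / (fwd + rev)
}

#' Resolve quality parameters for one alt allele of a raw record
#'
#' Walks the dialect's ordered lookup plan and returns the first resolvable
#' value per parameter.  Parameters with no resolvable source are `NA`
#' (missing), never silently zero.  QD is taken from `INFO/QD` when the
#' caller reports it and computed via [compute_qd()] from QUAL and DP
#' otherwise.
#'
#' @param rec A raw record (element of `read_vcf()$records`).
#' @param ai 1-based alt-allele index.
#' @param dialect A [caller_dialect()].
#' @param number_map Header `Number=` declarations (from the `raw_vcf`).
#' @return Named list `vaf`, `dp`, `stb`, `qual`, `qd`.
#' @export
resolve_params <- function(rec, ai = 1L, dialect = caller_dialect("generic"),
                           number_map = list()) {
  first_hit <- function(sources) {
    for (s in sources) {
      val <- param_sources[[s]](rec, ai, number_map)
      if (!is.na(val)) return(val)
    }
    NA_real_
  }
  vaf <- first_hit(dialect$vaf)
  dp  <- first_hit(dialect$dp)
  stb <- first_hit(dialect$stb)
  qual <- rec$qual %||% NA_real_
  qd <- slice_field(rec, "INFO", "QD", ai, number_map)
  if (is.na(qd)) qd <- compute_qd(qual, dp)
  list(vaf = vaf, dp = dp, stb = stb, qual = qual, qd = qd)
}

## ---- BED -------------------------------------------------------------------

#' Read and merge a BED file of high-confidence regions
#'
#' Reads a 3+ column BED (0-based half-open), merges overlapping and adjacent
#' intervals per chromosome, and records the total number of bases covered.
#'
#' @param path Path to a BED3+ file.
#' @return A `bed_regions` data.frame with columns `chrom`, `start` (0-based
#'   inclusive), `end` (0-based exclusive), sorted, non-overlapping; attribute
#'   `total_bases` holds the summed widths.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) vb_stop("BED file not found: %s", path)
  raw <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3L) vb_stop("BED file %s has fewer than 3 columns", path)
  raw <- raw[, 1:3]
  names(raw) <- c("chrom", "start", "end")
  raw$chrom <- as.character(raw$chrom)
  raw$start <- suppressWarnings(as.integer(raw$start))
  raw$end <- suppressWarnings(as.integer(raw$end))
  if (anyNA(raw$start) || anyNA(raw$end)) {
    vb_stop("non-integer coordinates in BED file %s", path)
  }
  if (any(raw$start >= raw$end)) {
    bad <- which(raw$start >= raw$end)[1]
    vb_stop("BED interval with start >= end at data line %d (%s:%d-%d)",
            bad, raw$chrom[bad], raw$start[bad], raw$end[bad])
  }
  merge_regions(raw)
}

#' Merge a regions data.frame (union of overlapping/adjacent intervals)
#' @param regions data.frame with `chrom`, `start` (0-based), `end` (exclusive).
#' @return A merged `bed_regions` data.frame; attribute `total_bases`.
#' @export
merge_regions <- function(regions) {
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  gr <- GenomicRanges::reduce(gr)  # default also merges abutting intervals
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_bases") <- sum(out$end - out$start)
  class(out) <- c("bed_regions", "data.frame")
  out
}

#' Total bases covered by a merged region set
#' @param regions A `bed_regions` object.
#' @return Integer base count.
#' @export
total_bases <- function(regions) {
  attr(regions, "total_bases") %||% sum(regions$end - regions$start)
}

#' Write regions to BED
#' @param regions A `bed_regions` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- FASTA -----------------------------------------------------------------

#' Open a reference FASTA as a sequence accessor
#'
#' Loads the FASTA (small references are held in memory) and returns an
#' accessor `function(contig, start, len)` giving the uppercase sequence of
#' `len` bases from 1-based position `start`.
#'
#' @param path Path to a FASTA file.
#' @return The accessor function; attribute `lengths` is a named integer
#'   vector of contig lengths.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) vb_stop("FASTA file not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  acc <- function(contig, start, len = 1L) {
    if (!contig %in% names(lens)) {
      vb_stop("contig '%s' not present in reference", contig)
    }
    if (start < 1L || len < 1L || start + len - 1L > lens[[contig]]) {
      vb_stop("coordinates %d..%d out of range for contig '%s' (length %d)",
              start, start + len - 1L, contig, lens[[contig]])
    }
    toupper(as.character(Biostrings::subseq(seqs[[contig]], start, start + len - 1L)))
  }
  attr(acc, "lengths") <- lens
  acc
}

## ---- reports ---------------------------------------------------------------

class_table_cols <- c("chrom", "start", "end", "ref", "alt",
                      "vaf", "dp", "stb", "qual", "qd", "class")

#' Write benchmark reports
#'
#' Writes (a) `metrics.json` with all counts and accuracy metrics, (b) one TSV
#' per call class (`tp.tsv`, `fp.tsv`, `bfn.tsv`, `seqfn.tsv`), and (c)
#' `not_found_in_bam.tsv`, the expected variants for which the read re-check
#' found no supporting evidence.
#'
#' @param metrics A `metric_set` (see [compute_metrics()]).
#' @param calls A classified-call data.frame (see [match_callsets()]).
#' @param out_dir Output directory (created if needed).
#' @param extra Optional named list merged into the JSON report (e.g. a run
#'   manifest).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(metrics, calls, out_dir, extra = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    vb_stop("cannot write to output directory: %s", out_dir)
  }
  payload <- c(unclass(metrics), extra %||% list())
  json_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  slice <- function(df) {
    df <- df[, intersect(class_table_cols, names(df)), drop = FALSE]
    df
  }
  tabs <- list(
    tp    = calls[calls$class == "TP", , drop = FALSE],
    fp    = calls[calls$class == "FP", , drop = FALSE],
    bfn   = calls[calls$class == "FN" & calls$fn_subtype == "b-FN", , drop = FALSE],
    seqfn = calls[calls$class == "FN" & calls$fn_subtype == "seq-FN", , drop = FALSE]
  )
  paths <- c(metrics = json_path)
  labels <- c(tp = "TP", fp = "FP", bfn = "b-FN", seqfn = "seq-FN")
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- tabs[[nm]]
    df$class <- rep(labels[[nm]], nrow(df))
    write.table(slice(df), p, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
    paths[nm] <- p
  }
  nf <- tabs$seqfn
  nf$class <- rep("seq-FN", nrow(nf))
  p <- file.path(out_dir, "not_found_in_bam.tsv")
  write.table(slice(nf), p, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  paths["not_found_in_bam"] <- p
  invisible(paths)
}
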