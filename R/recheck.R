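## Read-evidence re-check of false negatives.  Every FN is looked up in the
## aligned reads (BAM/SAM, or a readcount table produced elsewhere) and split
## into
##   b-FN  (bioinformatic FN): supporting reads exist -> callable in
##          principle under relaxed caller parameters;
##   seq-FN (sequencing FN):   no read support -> unrecoverable
##          bioinformatically.
## b-FN sites get caller-independent parameters (VAF, DP, STB) derived from
## the pileup, which is what makes the maximum theoretical recall and the
## downstream parameter analysis possible.

#' Re-check policy
#'
#' @param min_alt_reads Minimum alt-supporting reads for a FN to count as
#'   bioinformatic (default 1: existence of support).
#' @param min_base_quality Minimum Phred base quality for a base to count
#'   (default 0).
#' @param min_mapping_quality Minimum mapping quality for a read to count
#'   (default 0).
#' @return A `recheck_policy` list.
#' @export
recheck_policy <- function(min_alt_reads = 1L, min_base_quality = 0L,
                           min_mapping_quality = 0L) {
  stopifnot(min_alt_reads >= 1L, min_base_quality >= 0L,
            min_mapping_quality >= 0L)
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality)),
            class = "recheck_policy")
}

## ---- alignment sources -----------------------------------------------------

#' Open aligned reads (BAM or SAM) for site re-checking
#'
#' SAM text is converted, sorted and indexed into a scratch directory via
#' Rsamtools; BAM input is indexed if no index is present.
#'
#' @param path Path to a `.bam` or `.sam` file.
#' @return An `alignment_source` object usable with [readcount_site()].
#' @export
bam_source <- function(path) {
  if (!file.exists(path)) vb_stop("alignment file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                             indexDestination = TRUE))
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai"))) Rsamtools::indexBam(bam)
  }
  structure(list(bam = bam), class = c("bam_alignments", "alignment_source"))
}

#' Open a readcount table as a drop-in substitute for BAM access
#'
#' The table is tab-separated with no header: `chrom`, 1-based `pos`
#' (the canonical `start` of the variant the site describes), reference base,
#' total `depth`, then one or more allele fields `code:count:fwd:rev`, where
#' `code` is `=` for reference-supporting reads, a base (or base run) for
#' SNV/MNV alleles, `+SEQ` for an insertion and `-SEQ` for a deletion.
#'
#' @param path Path to the readcount TSV.
#' @return An `alignment_source` object usable with [readcount_site()].
#' @export
readcount_source <- function(path) {
  if (!file.exists(path)) vb_stop("readcount file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad)) vb_stop("malformed readcount line %d", bad[1])
  tab <- lapply(parts, function(p) {
    list(chrom = p[1], pos = as.integer(p[2]), ref = p[3],
         depth = as.integer(p[4]), alleles = p[-(1:4)])
  })
  keys <- vapply(tab, function(r) paste0(r$chrom, ":", r$pos), character(1))
  structure(list(sites = setNames(tab, keys)),
            class = c("readcount_table", "alignment_source"))
}

## Allele code of a canonical variant in the readcount dialect.
allele_code <- function(cv) {
  switch(cv$vclass,
         INS = paste0("+", cv$alt),
         DEL = paste0("-", cv$ref),
         cv$alt)
}

#' Pileup read counts at one variant site
#'
#' Counts, by strand, the reads supporting the canonical alt allele and the
#' reference at the variant's site.  For SNV/MNV sites a read supports alt
#' when its aligned bases across the variant interval equal the alt allele;
#' a deletion requires the read's alignment to delete exactly the canonical
#' interval; an insertion requires the read to insert exactly the canonical
#' sequence after the anchor base.  Duplicate, secondary, supplementary and
#' unmapped alignments are excluded, as are reads below the mapping-quality
#' floor and bases below the base-quality floor.  Depth is the number of
#' retained reads spanning the anchor position.
#'
#' @param variant One-row canonical data.frame.
#' @param alignments An `alignment_source` ([bam_source()] or
#'   [readcount_source()]).
#' @param policy A [recheck_policy()].
#' @return A `site_readcount` list: `depth`, `alt_fwd`, `alt_rev`,
#'   `ref_fwd`, `ref_rev`.
#' @export
readcount_site <- function(variant, alignments, policy = recheck_policy()) {
  UseMethod("readcount_site", alignments)
}

site_readcount <- function(depth = 0L, alt_fwd = 0L, alt_rev = 0L,
                           ref_fwd = 0L, ref_rev = 0L) {
  structure(list(depth = as.integer(depth),
                 alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt_rev),
                 ref_fwd = as.integer(ref_fwd), ref_rev = as.integer(ref_rev)),
            class = "site_readcount")
}

#' @export
readcount_site.readcount_table <- function(variant, alignments,
                                           policy = recheck_policy()) {
  key <- paste0(variant$chrom, ":", variant$start)
  site <- alignments$sites[[key]]
  if (is.null(site)) return(site_readcount())
  want <- allele_code(variant)
  alt <- c(0L, 0L); ref <- c(0L, 0L)
  for (a in site$alleles) {
    f <- strsplit(a, ":", fixed = TRUE)[[1]]
    if (length(f) != 4L) vb_stop("malformed allele field '%s' in readcount table", a)
    cnt <- as.integer(f[3:4])
    if (f[1] == "=") ref <- ref + cnt
    else if (f[1] == want) alt <- alt + cnt
  }
  site_readcount(site$depth, alt[1], alt[2], ref[1], ref[2])
}

parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", ops)),
       op = substr(ops, nchar(ops), nchar(ops)))
}

## Evaluate one read against one canonical variant.  Returns "alt", "ref" or
## NA (neither / fails quality), plus whether the read spans the anchor.
read_support <- function(variant, read_pos, cigar, seq, qual_str, min_bq) {
  cg <- parse_cigar(cigar)
  anchor <- variant$start
  vclass <- variant$vclass
  refpos <- read_pos; qpos <- 1L
  aligned <- list()   # per reference position: query index (NA for deletion)
  ins_at <- list()    # insertions keyed by the ref position they precede
  for (i in seq_along(cg$op)) {
    L <- cg$len[i]
    switch(cg$op[i],
      "M" = , "=" = , "X" = {
        idx <- seq_len(L)
        aligned[as.character(refpos + idx - 1L)] <- as.list(qpos + idx - 1L)
        refpos <- refpos + L; qpos <- qpos + L
      },
      "I" = {
        ins_at[[as.character(refpos)]] <- substr(seq, qpos, qpos + L - 1L)
        qpos <- qpos + L
      },
      "D" = , "N" = {
        idx <- seq_len(L)
        aligned[as.character(refpos + idx - 1L)] <- list(NULL)
        refpos <- refpos + L
      },
      "S" = { qpos <- qpos + L },
      NULL)
  }
  ref_end <- refpos - 1L
  spans <- read_pos <= anchor && anchor <= ref_end
  if (!spans) return(list(spans = FALSE, support = NA_character_))
  base_at <- function(p) {
    q <- aligned[[as.character(p)]]
    if (is.null(q)) return(NA_character_)            # deleted or not aligned
    if (nchar(qual_str) >= q && qual_str != "*") {
      bq <- utf8ToInt(substr(qual_str, q, q)) - 33L
      if (bq < min_bq) return("low")
    }
    substr(seq, q, q)
  }
  support <- NA_character_
  if (vclass %in% c("SNV", "MNV") && nchar(variant$ref) == nchar(variant$alt)) {
    positions <- seq.int(variant$start, variant$end)
    bases <- vapply(positions, base_at, character(1))
    if (!anyNA(bases) && !any(bases == "low")) {
      b <- paste(bases, collapse = "")
      if (b == variant$alt) support <- "alt"
      else if (b == variant$ref) support <- "ref"
    }
  } else if (vclass == "DEL") {
    positions <- seq.int(variant$start, variant$end)
    covered <- all(vapply(positions, function(p)
      !is.null(names(aligned)) && as.character(p) %in% names(aligned),
      logical(1)))
    if (covered) {
      deleted <- vapply(positions, function(p) is.null(aligned[[as.character(p)]]),
                        logical(1))
      before_ok <- !(as.character(variant$start - 1L) %in% names(aligned)) ||
        !is.null(aligned[[as.character(variant$start - 1L)]])
      after_ok <- !(as.character(variant$end + 1L) %in% names(aligned)) ||
        !is.null(aligned[[as.character(variant$end + 1L)]])
      if (all(deleted) && before_ok && after_ok) {
        support <- "alt"
      } else if (!any(deleted)) {
        bases <- vapply(positions, base_at, character(1))
        if (!anyNA(bases) && !any(bases == "low") &&
            paste(bases, collapse = "") == variant$ref) support <- "ref"
      }
    }
  } else if (vclass == "INS") {
    ## insertion occurs between anchor (= start) and start+1
    ins <- ins_at[[as.character(anchor + 1L)]]
    covers_junction <- (anchor + 1L) <= ref_end
    if (!is.null(ins)) {
      if (ins == variant$alt) support <- "alt"
    } else if (covers_junction &&
               !is.null(aligned[[as.character(anchor)]]) &&
               !is.null(aligned[[as.character(anchor + 1L)]])) {
      support <- "ref"
    }
  }
  list(spans = TRUE, support = support)
}

#' @export
readcount_site.bam_alignments <- function(variant, alignments,
                                          policy = recheck_policy()) {
  hdr <- Rsamtools::scanBamHeader(alignments$bam)[[1]]$targets
  if (!variant$chrom %in% names(hdr)) {
    vb_warn("contig '%s' absent from BAM; site reported as uncovered",
            variant$chrom)
    return(site_readcount())
  }
  span <- GenomicRanges::GRanges(
    variant$chrom, IRanges::IRanges(max(1L, variant$start - 1L), variant$end + 1L))
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "strand", "pos", "mapq", "cigar", "seq", "qual"),
    which = span, flag = flags)
  r <- Rsamtools::scanBam(alignments$bam, param = param)[[1]]
  n <- length(r$pos)
  depth <- 0L; alt <- c(0L, 0L); ref <- c(0L, 0L)
  seqs <- as.character(r$seq)
  quals <- as.character(r$qual)
  for (i in seq_len(n)) {
    if (!is.na(r$mapq[i]) && r$mapq[i] < policy$min_mapping_quality) next
    rs <- read_support(variant, r$pos[i], r$cigar[i], seqs[i], quals[i],
                       policy$min_base_quality)
    if (!rs$spans) next
    depth <- depth + 1L
    if (is.na(rs$support)) next
    strand_idx <- if (bitwAnd(r$flag[i], 16L) > 0L) 2L else 1L
    if (rs$support == "alt") alt[strand_idx] <- alt[strand_idx] + 1L
    else ref[strand_idx] <- ref[strand_idx] + 1L
  }
  site_readcount(depth, alt[1], alt[2], ref[1], ref[2])
}

#' Caller-independent parameters from a pileup
#'
#' `DP` is the site depth; `VAF` the alt fraction of depth (`NA` at depth 0);
#' `STB` the larger strand's share of the alt reads, in `[0.5, 1]` (`NA`
#' with no alt reads): 0.5 is perfect balance, 1 fully one-sided.
#'
#' @param rc A `site_readcount`.
#' @return Named list `vaf`, `dp`, `stb`.
#' @export
derive_params <- function(rc) {
  dp <- rc$depth
  alt_n <- rc$alt_fwd + rc$alt_rev
  vaf <- if (dp == 0L) NA_real_ else alt_n / dp
  stb <- if (alt_n == 0L) NA_real_ else max(rc$alt_fwd, rc$alt_rev) / alt_n
  list(vaf = vaf, dp = as.numeric(dp), stb = stb)
}

#' Classify false negatives by read support
#'
#' Re-evaluates every FN row in the read evidence: FNs with at least
#' `policy$min_alt_reads` alt-supporting reads become bioinformatic FNs
#' (`b-FN`) and carry pileup-derived VAF/DP/STB; the rest are sequencing FNs
#' (`seq-FN`).  Without an alignment source all FNs stay `unchecked` and the
#' returned `bfn_count` is `NA` (so `recall_max` is not reported).
#'
#' @param calls A classified-call data.frame from [match_callsets()].
#' @param alignments An `alignment_source`, or `NULL`.
#' @param policy A [recheck_policy()].
#' @return List: `calls` (updated data.frame), `bfn_count`, `seqfn_count`,
#'   and `readcounts` (per-FN `site_readcount`s keyed by canonical key).
#' @export
classify_fns <- function(calls, alignments, policy = recheck_policy()) {
  idx <- which(calls$class == "FN")
  if (is.null(alignments)) {
    return(list(calls = calls, bfn_count = NA_integer_,
                seqfn_count = NA_integer_, readcounts = list()))
  }
  rcs <- list()
  for (i in idx) {
    rc <- readcount_site(calls[i, , drop = FALSE], alignments, policy)
    rcs[[calls$key[i]]] <- rc
    if (rc$alt_fwd + rc$alt_rev >= policy$min_alt_reads) {
      calls$fn_subtype[i] <- "b-FN"
      p <- derive_params(rc)
      calls$vaf[i] <- p$vaf; calls$dp[i] <- p$dp; calls$stb[i] <- p$stb
    } else {
      calls$fn_subtype[i] <- "seq-FN"
    }
  }
  list(calls = calls,
       bfn_count = sum(calls$fn_subtype == "b-FN"),
       seqfn_count = sum(calls$fn_subtype == "seq-FN"),
       readcounts = rcs)
}

#' Build the sequencing-positive (SeqPos) set
#'
#' SeqPos = TPs + b-FNs + FPs: every variant actually present in the
#' sequencing output.  TPs and b-FNs are labelled 1 (positively callable),
#' FPs 0 (should be called negative); seq-FNs are excluded.  TPs and FPs
#' carry their caller parameters, b-FNs their pileup parameters — the only
#' ones available for each.
#'
#' @param calls A classified and re-checked call data.frame.
#' @return A data.frame with `key`, `vclass`, `label` and the parameter
#'   columns.
#' @export
build_seqpos <- function(calls) {
  pos <- calls[calls$class == "TP" |
                 (calls$class == "FN" & calls$fn_subtype == "b-FN"), , drop = FALSE]
  neg <- calls[calls$class == "FP", , drop = FALSE]
  out <- rbind(
    cbind(pos[, c("key", "vclass", param_cols)], label = rep(1L, nrow(pos))),
    cbind(neg[, c("key", "vclass", param_cols)], label = rep(0L, nrow(neg)))
  )
  rownames(out) <- NULL
  out
}
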