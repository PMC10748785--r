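## Harmonization: every edit, however a caller spelled it, is mapped to one
## canonical representation so that set comparison of callsets is
## caller-independent.  The canonical form is the 5-column
## start/end/ref/alt convention with "-" for the absent allele:
##   SNV  chr start=end        ref=base     alt=base
##   DEL  chr start..end       ref=deleted  alt="-"
##   INS  chr start=end=anchor ref="-"      alt=inserted   (after `start`)
##   MNV  chr start..end       ref/alt of equal length (block substitutions
##                             of unequal length are also labelled MNV)
## This eliminates "symbolic" false negatives: truth variants that a naive
## positional diff misses only because the query spells the same edit
## differently (shifted within a repeat tract, padded, multi-allelic).

#' Split a multi-allelic record into per-allele records
#'
#' Produces one allele split per ALT allele, slicing INFO/FORMAT fields
#' declared `Number=A` (per alt) or `Number=R` (ref + alts) down to the
#' matching allele and duplicating scalar fields.  Alleles with zero
#' frequency are dropped: an allele is zero-frequency when its resolved VAF
#' is 0, or its allelic depth is 0 when no VAF is resolvable; alleles with no
#' frequency evidence at all are retained.
#'
#' @param rec A raw record (element of `read_vcf()$records`).
#' @param dialect A [caller_dialect()] used to resolve per-allele parameters.
#' @param number_map Header `Number=` declarations.
#' @return List of allele splits; each is a single-alt raw record with
#'   `allele_index` (index in the parent) and `params` (resolved quality
#'   parameters) attached.
#' @export
split_multiallelic <- function(rec, dialect = caller_dialect("generic"),
                               number_map = list()) {
  n_alt <- length(rec$alts)
  stopifnot(n_alt >= 1L)
  slice_map <- function(src, where) {
    lapply(setNames(names(src), names(src)), function(k) {
      v <- src[[k]]
      if (isTRUE(v)) return(v)
      number <- field_number(k, where, number_map)
      if (identical(number, "A")) {
        if (length(v) == n_alt) return(NULL)  # placeholder; sliced below
        vb_warn("field %s/%s has %d values for %d alt alleles; marked missing",
                where, k, length(v), n_alt)
        return(NA_character_)
      }
      if (identical(number, "R")) {
        if (length(v) == n_alt + 1L) return(NULL)
        vb_warn("field %s/%s has %d values for %d alleles; marked missing",
                where, k, length(v), n_alt + 1L)
        return(NA_character_)
      }
      v
    })
  }
  out <- vector("list", n_alt)
  kept <- logical(n_alt)
  for (ai in seq_len(n_alt)) {
    sub <- rec
    sub$alts <- rec$alts[ai]
    for (where in c("INFO", "FORMAT")) {
      src <- if (where == "INFO") rec$info else rec$format
      sliced <- slice_map(src, where)
      for (k in names(sliced)) {
        if (is.null(sliced[[k]])) {
          v <- src[[k]]
          number <- field_number(k, where, number_map)
          sliced[[k]] <- if (identical(number, "A")) v[ai] else v[c(1L, ai + 1L)]
        }
      }
      if (where == "INFO") sub$info <- sliced else sub$format <- sliced
    }
    params <- resolve_params(rec, ai, dialect, number_map)
    ## zero-frequency drop: VAF == 0, or allelic depth == 0 when VAF missing
    drop <- FALSE
    if (!is.na(params$vaf)) {
      drop <- params$vaf == 0
    } else {
      ad <- suppressWarnings(as.numeric(get_field(rec, "FORMAT", "AD")))
      if (length(ad) == n_alt + 1L && !is.na(ad[ai + 1L])) drop <- ad[ai + 1L] == 0
    }
    sub$allele_index <- ai
    sub$params <- params
    out[[ai]] <- sub
    kept[ai] <- !drop
  }
  out[kept]
}

## Apply a VCF-style edit (1-based pos, ref and alt strings) to a sequence.
## Used as the haplotype oracle throughout the tests and to validate
## reference agreement here.
apply_edit <- function(seq, pos, ref, alt) {
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
    vb_stop("REF allele '%s' does not match sequence at position %d", ref, pos)
  }
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

#' Left-align and trim a VCF-style allele pair
#'
#' Standard normalization: while `ref` and `alt` end with the same base the
#' base is dropped; whenever an allele becomes empty, the reference base at
#' `pos - 1` is prepended to both and `pos` decremented (shifting the indel
#' left through any repeat tract); finally shared leading bases are trimmed
#' while both alleles are longer than 1 base, incrementing `pos`.  The result
#' is the unique leftmost, parsimonious spelling: applied to the reference it
#' reproduces the same haplotype as the input, and no equivalent spelling
#' exists at a smaller position.
#'
#' At the contig start (`pos = 1` with a further shift required) the current
#' representation is returned with a warning rather than an error.
#'
#' @param chrom Contig name.
#' @param pos 1-based position.
#' @param ref,alt VCF-style allele strings (anchor base included for indels).
#' @param reference Accessor from [read_reference()].
#' @return List `pos`, `ref`, `alt`.
#' @export
left_align <- function(chrom, pos, ref, alt, reference) {
  if (!nzchar(ref) || !nzchar(alt)) vb_stop("empty allele at %s:%d", chrom, pos)
  ## reference agreement check
  obs <- reference(chrom, pos, nchar(ref))
  if (obs != ref) {
    vb_stop("reference mismatch at %s:%d: VCF REF '%s' but reference has '%s'",
            chrom, pos, ref, obs)
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr == 1L && na == 1L) break                      # SNV or null variant
    if (substr(ref, nr, nr) != substr(alt, na, na)) break
    if ((nr == 1L || na == 1L) && pos == 1L) {
      ## a further left shift is required but we are at the contig start
      vb_warn("left-alignment stopped at the start of contig %s", chrom)
      break
    }
    ref <- substr(ref, 1L, nr - 1L)
    alt <- substr(alt, 1L, na - 1L)
    if (!nzchar(ref) || !nzchar(alt)) {
      pos <- pos - 1L
      b <- reference(chrom, pos, 1L)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Convert a left-aligned allele pair to canonical start/end/ref/alt form
#'
#' @param chrom Contig name.
#' @param pos 1-based position of a left-aligned, parsimony-trimmed pair.
#' @param ref,alt Allele strings after [left_align()].
#' @param params Optional named list of quality parameters attached to the
#'   resulting variant.
#' @return One-row canonical data.frame (`chrom`, `start`, `end`, `ref`,
#'   `alt`, `vclass`, parameter columns, `key`), or `NULL` with a warning for
#'   a null variant (ref == alt after trimming).
#' @export
to_canonical <- function(chrom, pos, ref, alt, params = NULL) {
  core <- to_canonical_core(chrom, pos, ref, alt, params)
  if (is.null(core)) return(NULL)
  as.data.frame(c(core, list(key = canonical_key(core$chrom, core$start,
                                                 core$end, core$ref, core$alt))),
                stringsAsFactors = FALSE)
}

## List-returning workhorse; harmonize_callset batches these into one
## data.frame rather than binding one-row frames.
to_canonical_core <- function(chrom, pos, ref, alt, params = NULL) {
  p <- params %||% list()
  nr <- nchar(ref); na <- nchar(alt)
  if (ref == alt) {
    vb_warn("null variant (REF == ALT) at %s:%d dropped", chrom, pos)
    return(NULL)
  }
  if (nr == 1L && na == 1L) {
    start <- pos; end <- pos; cref <- ref; calt <- alt; vclass <- "SNV"
  } else if (na == 1L && nr > 1L && substr(ref, 1L, 1L) == alt) {
    ## deletion: anchor base + deleted bases
    start <- pos + 1L; end <- pos + nr - 1L
    cref <- substr(ref, 2L, nr); calt <- "-"; vclass <- "DEL"
  } else if (nr == 1L && na > 1L && substr(alt, 1L, 1L) == ref) {
    ## insertion after the anchor base at pos
    start <- pos; end <- pos
    cref <- "-"; calt <- substr(alt, 2L, na); vclass <- "INS"
  } else {
    ## multi-nucleotide substitution (incl. unequal-length block substitution)
    start <- pos; end <- pos + nr - 1L
    cref <- ref; calt <- alt; vclass <- "MNV"
  }
  list(chrom = chrom, start = start, end = end, ref = cref, alt = calt,
       vclass = vclass,
       vaf = num_or_na(p$vaf), dp = num_or_na(p$dp), stb = num_or_na(p$stb),
       qual = num_or_na(p$qual), qd = num_or_na(p$qd))
}

#' Re-express a canonical variant as a VCF-style (pos, ref, alt) triple
#'
#' The inverse of [to_canonical()]: indels are re-anchored on the reference
#' base before the edit.  Needed to apply canonical edits to a sequence and
#' for idempotence checks.
#'
#' @param cv One-row canonical data.frame.
#' @param reference Accessor from [read_reference()].
#' @return List `chrom`, `pos`, `ref`, `alt`.
#' @export
canonical_to_vcf <- function(cv, reference) {
  chrom <- cv$chrom
  if (cv$vclass == "INS") {
    anchor <- reference(chrom, cv$start, 1L)
    list(chrom = chrom, pos = cv$start, ref = anchor, alt = paste0(anchor, cv$alt))
  } else if (cv$vclass == "DEL") {
    pos <- cv$start - 1L
    if (pos >= 1L) {
      anchor <- reference(chrom, pos, 1L)
      list(chrom = chrom, pos = pos, ref = paste0(anchor, cv$ref), alt = anchor)
    } else {
      ## deletion at the very start of the contig: anchor on the base after
      anchor <- reference(chrom, cv$end + 1L, 1L)
      list(chrom = chrom, pos = 1L, ref = paste0(cv$ref, anchor), alt = anchor)
    }
  } else {
    list(chrom = chrom, pos = cv$start, ref = cv$ref, alt = cv$alt)
  }
}

#' Harmonize a whole callset into a canonical variant table
#'
#' Splits multi-allelic records, left-aligns, trims to parsimony and converts
#' each allele to canonical form.  The result is a set keyed by
#' `(chrom, start, end, ref, alt)`: duplicate canonical variants collapse to
#' one, keeping the copy with the highest QUAL.  Records that disagree with
#' the reference are dropped with a warning, never an abort.
#'
#' @param vcf A `raw_vcf` object (or plain list of raw records).
#' @param reference Accessor from [read_reference()].
#' @param dialect Optional [caller_dialect()]; defaults to the one stored in
#'   `vcf`.
#' @return A canonical data.frame (class `canonical_set`), one row per
#'   distinct canonical variant.
#' @export
harmonize_callset <- function(vcf, reference, dialect = NULL) {
  if (inherits(vcf, "raw_vcf")) {
    records <- vcf$records
    dialect <- dialect %||% vcf$dialect
    number_map <- vcf$number_map
  } else {
    records <- vcf
    dialect <- dialect %||% caller_dialect("generic")
    number_map <- list()
  }
  rows <- list()
  for (rec in records) {
    splits <- split_multiallelic(rec, dialect, number_map)
    for (sp in splits) {
      la <- tryCatch(
        left_align(sp$chrom, sp$pos, sp$ref, sp$alts[1], reference),
        error = function(e) { vb_warn("%s", conditionMessage(e)); NULL })
      if (is.null(la)) next
      cv <- to_canonical_core(sp$chrom, la$pos, la$ref, la$alt, sp$params)
      if (!is.null(cv)) rows[[length(rows) + 1L]] <- cv
    }
  }
  if (!length(rows)) {
    out <- empty_canonical()
    class(out) <- c("canonical_set", "data.frame")
    return(out)
  }
  grab <- function(f, mode) vapply(rows, `[[`, mode, f)
  tab <- data.frame(
    chrom = grab("chrom", character(1)),
    start = as.integer(grab("start", numeric(1))),
    end = as.integer(grab("end", numeric(1))), ref = grab("ref", character(1)),
    alt = grab("alt", character(1)), vclass = grab("vclass", character(1)),
    vaf = grab("vaf", numeric(1)), dp = grab("dp", numeric(1)),
    stb = grab("stb", numeric(1)), qual = grab("qual", numeric(1)),
    qd = grab("qd", numeric(1)), stringsAsFactors = FALSE)
  tab$key <- canonical_key(tab$chrom, tab$start, tab$end, tab$ref, tab$alt)
  ## collapse duplicates, keeping the highest-QUAL copy
  ord <- order(tab$key, -ifelse(is.na(tab$qual), -Inf, tab$qual))
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$key), , drop = FALSE]
  tab <- tab[order(tab$chrom, tab$start, tab$end, tab$ref, tab$alt), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("canonical_set", "data.frame")
  tab
}
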