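## Independent oracles and tiny fixture builders used across the suite.
## Everything here is deliberately naive (string splicing, brute-force
## enumeration) so it stays independent of the code paths it checks.

## Haplotype oracle: apply a VCF-style edit to a sequence by string splicing.
oracle_apply <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

## Apply a one-row canonical variant to a sequence via the oracle.
oracle_apply_canonical <- function(seq, cv) {
  if (cv$vclass == "INS") {
    paste0(substr(seq, 1L, cv$start), cv$alt,
           substr(seq, cv$start + 1L, nchar(seq)))
  } else if (cv$vclass == "DEL") {
    paste0(substr(seq, 1L, cv$start - 1L),
           substr(seq, cv$end + 1L, nchar(seq)))
  } else {
    paste0(substr(seq, 1L, cv$start - 1L), cv$alt,
           substr(seq, cv$end + 1L, nchar(seq)))
  }
}

## In-memory reference accessor over a named list of sequences.
string_reference <- function(...) {
  seqs <- list(...)
  lens <- vapply(seqs, nchar, integer(1))
  acc <- function(contig, start, len = 1L) {
    if (!contig %in% names(seqs)) stop("contig '", contig, "' not present")
    if (start < 1L || start + len - 1L > lens[[contig]]) stop("out of range")
    substr(seqs[[contig]], start, start + len - 1L)
  }
  attr(acc, "lengths") <- lens
  acc
}

## Raw VCF record constructor matching read_vcf()'s record layout.
raw_record <- function(chrom, pos, ref, alts, qual = NA_real_,
                       filter = "PASS", info = list(), format = list()) {
  list(chrom = chrom, pos = as.integer(pos), id = ".", ref = ref,
       alts = alts, qual = qual, filter = filter, info = info,
       format = format, line = NA_integer_)
}

## Canonical one-row table builder (for comparator/recheck tests).
cv_row <- function(chrom, start, end, ref, alt, vclass,
                   vaf = NA_real_, dp = NA_real_, stb = NA_real_,
                   qual = NA_real_, qd = NA_real_) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             ref = ref, alt = alt, vclass = vclass,
             vaf = vaf, dp = dp, stb = stb, qual = qual, qd = qd,
             key = paste(chrom, start, end, ref, alt, sep = ":"),
             stringsAsFactors = FALSE)
}

## Brute-force Mann-Whitney: exact two-sided p by full enumeration of the
## group assignments, with the same doubling convention as the exact test.
mw_enum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  vals <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(g) {
    xx <- vals[g]; yy <- vals[-g]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

## Brute-force pairwise concordance AUROC with half-credit for ties.
auroc_concordance <- function(values, labels) {
  pos <- values[labels == 1]; neg <- values[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

## Minimal SeqPos data.frame with values in the `vaf` column.
seqpos_acc <- function(vals, labels) {
  data.frame(key = paste0("k", seq_along(vals)), vclass = "SNV",
             vaf = vals, dp = NA_real_, stb = NA_real_, qual = NA_real_,
             qd = NA_real_, label = labels, stringsAsFactors = FALSE)
}

## Random reference window with an embedded homopolymer or dinucleotide
## tract; returns the window string plus the tract coordinates and unit.
random_tract_window <- function(width = 60L) {
  bases <- c("A", "C", "G", "T")
  seq_v <- sample(bases, width, replace = TRUE)
  if (runif(1) < 0.5) {
    unit <- sample(bases, 1L)
    tl <- sample(5:12, 1L)
    tract <- rep(unit, tl)
  } else {
    u2 <- sample(bases, 2L)
    tl <- 2L * sample(3:5, 1L)
    tract <- rep(u2, tl / 2L)
    unit <- paste(u2, collapse = "")
  }
  t1 <- (width - length(tract)) %/% 2L
  seq_v[t1:(t1 + length(tract) - 1L)] <- tract
  ## guard both boundaries so the tract is exactly where we say it is
  seq_v[t1 - 1L] <- sample(setdiff(bases, tract[c(1, length(tract))]), 1L)
  seq_v[t1 + length(tract)] <- sample(setdiff(bases, tract[length(tract)]), 1L)
  list(seq = paste(seq_v, collapse = ""), t1 = t1,
       t2 = t1 + length(tract) - 1L, unit = unit)
}

## All anchor-shifted spellings of a one-unit indel inside a repeat tract,
## plus padded variants of the leftmost spelling.
equivalent_spellings <- function(win, type = c("DEL", "INS"), max_pad = 2L) {
  type <- match.arg(type)
  k <- nchar(win$unit)
  s <- win$seq
  sub <- function(i, j = i) substr(s, i, j)
  sp <- list()
  if (type == "DEL") {
    anchors <- seq.int(win$t1 - 1L, win$t2 - k, by = k)
    for (p in anchors) {
      sp[[length(sp) + 1L]] <- list(pos = p, ref = sub(p, p + k), alt = sub(p))
    }
  } else {
    anchors <- seq.int(win$t1 - 1L, win$t2, by = k)
    for (p in anchors) {
      sp[[length(sp) + 1L]] <- list(pos = p, ref = sub(p),
                                    alt = paste0(sub(p), win$unit))
    }
  }
  base <- sp[[1]]
  for (j in seq_len(max_pad)) {
    p <- base$pos - j
    if (p < 1L) break
    sp[[length(sp) + 1L]] <- list(pos = p, ref = paste0(sub(p, base$pos - 1L), base$ref),
                                  alt = paste0(sub(p, base$pos - 1L), base$alt))
  }
  ## right padding
  rend <- base$pos + nchar(base$ref)
  for (j in seq_len(max_pad)) {
    if (rend + j - 1L > nchar(s)) break
    pad <- sub(rend, rend + j - 1L)
    sp[[length(sp) + 1L]] <- list(pos = base$pos, ref = paste0(base$ref, pad),
                                  alt = paste0(base$alt, pad))
  }
  sp
}

## Write a minimal single-sample VCF from raw records; returns the path.
write_tmp_vcf <- function(records, meta = character(0)) {
  path <- tempfile(fileext = ".vcf")
  varbench::write_vcf(records, path, meta = meta)
  path
}
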