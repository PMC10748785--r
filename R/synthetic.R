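## Deterministic, seedable generator of complete benchmark fixtures: a
## reference with repeat tracts, a truth callset, a degraded query callset
## (injected false positives; bioinformatic, sequencing and symbolic false
## negatives), and read evidence (SAM and a readcount table) whose per-site,
## per-strand counts are recorded in a ledger.  The ledger is the oracle for
## every downstream test: the pipeline must reproduce its confusion matrix
## exactly.

#' Simulation configuration
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param region_length Reference length in bp (>= 200).
#' @param n_snv,n_ins,n_del Truth-set variant counts by class.
#' @param homopolymer_fraction Fraction of indels placed inside generated
#'   repeat tracts (homopolymer or dinucleotide).
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model
#'   (mean and size); depths are truncated at 2 except at sequencing-FN
#'   dropout sites, which may be forced to 0.
#' @param vaf_rule Either `list(rule = "beta", mean, conc)` — callable-variant
#'   VAFs from a Beta with that mean and concentration, FP VAFs from a Beta
#'   whose mean sits `separation` standard deviations lower — or
#'   `list(rule = "split", cutoff, gap, lo, hi)` — callable VAFs uniform on
#'   `(cutoff + gap/2, hi)`, FP VAFs uniform on `(lo, cutoff - gap/2)`, i.e. a
#'   clean generative separation at `cutoff`.
#' @param strand_balance Probability an alt read of a real variant is on the
#'   forward strand (0.5 = unbiased).
#' @param fp_strand_balance Same for injected FPs (artifacts are typically
#'   strand-biased).
#' @param fp_rate Expected FPs per truth variant (binomial injection).
#' @param bfn_rate,seqfn_rate Per-truth-variant probability of being withheld
#'   from the query as a bioinformatic / sequencing FN.
#' @param symbolic_rate Probability a query TP is re-spelled as a shifted,
#'   padded or multi-allelic equivalent of the canonical edit.
#' @param separation Effect size (in SD units) by which TP quality-parameter
#'   distributions exceed FP distributions.
#' @param qual_mean,qual_sd Caller QUAL model for real calls.
#' @param flank Read half-window around each site (read length is about
#'   `2 * flank`).
#' @param contig Contig name.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, region_length = 15000L,
                       n_snv = 60L, n_ins = 20L, n_del = 20L,
                       homopolymer_fraction = 0.5,
                       depth_mean = 300, depth_dispersion = 8,
                       vaf_rule = list(rule = "beta", mean = 0.35, conc = 25),
                       strand_balance = 0.5, fp_strand_balance = 0.8,
                       fp_rate = 0.15, bfn_rate = 0.15, seqfn_rate = 0.05,
                       symbolic_rate = 0.3, separation = 2,
                       qual_mean = 80, qual_sd = 15,
                       flank = 30L, contig = "sim1") {
  cfg <- list(seed = as.integer(seed), region_length = as.integer(region_length),
              n_snv = as.integer(n_snv), n_ins = as.integer(n_ins),
              n_del = as.integer(n_del),
              homopolymer_fraction = homopolymer_fraction,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              vaf_rule = vaf_rule, strand_balance = strand_balance,
              fp_strand_balance = fp_strand_balance,
              fp_rate = fp_rate, bfn_rate = bfn_rate, seqfn_rate = seqfn_rate,
              symbolic_rate = symbolic_rate, separation = separation,
              qual_mean = qual_mean, qual_sd = qual_sd,
              flank = as.integer(flank), contig = contig)
  rates <- c(cfg$fp_rate, cfg$bfn_rate, cfg$seqfn_rate, cfg$symbolic_rate,
             cfg$homopolymer_fraction)
  stopifnot(all(rates >= 0 & rates <= 1),
            cfg$bfn_rate + cfg$seqfn_rate <= 1,
            cfg$region_length >= 200L,
            cfg$n_snv >= 0L, cfg$n_ins >= 0L, cfg$n_del >= 0L)
  class(cfg) <- "sim_config"
  cfg
}

SLOT_WIDTH <- 110L
EDGE_MARGIN <- 50L
BASES <- c("A", "C", "G", "T")

#' Generate the synthetic reference
#'
#' Builds a random reference with homopolymer (5-15 bp) and dinucleotide
#' tracts embedded at the sites where indels will be placed, and plans the
#' site layout (one variant per non-overlapping slot, so read windows never
#' interfere across sites).  Byte-identical for a given seed.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_reference` list: `contig`, `seq` (character), `length`,
#'   `tracts` (data.frame of tract coordinates and units) and `sites`
#'   (planned site table with per-site type, class and tract flag).
#' @export
generate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$region_length
  n_var <- cfg$n_snv + cfg$n_ins + cfg$n_del
  n_fp <- rbinom(1L, n_var, cfg$fp_rate)
  n_sites <- n_var + n_fp
  n_slots <- (L - 2L * EDGE_MARGIN) %/% SLOT_WIDTH
  if (n_slots < n_sites) {
    vb_stop("region_length %d allows %d sites but %d requested; enlarge it",
            L, n_slots, n_sites)
  }
  ## per-site plan
  truth_types <- sample(rep(c("SNV", "INS", "DEL"),
                            c(cfg$n_snv, cfg$n_ins, cfg$n_del)))
  u <- runif(n_var)
  truth_class <- ifelse(u < cfg$bfn_rate, "b-FN",
                 ifelse(u < cfg$bfn_rate + cfg$seqfn_rate, "seq-FN", "TP"))
  fp_types <- if (n_fp > 0L) {
    sample(c("SNV", "INS", "DEL"), n_fp, replace = TRUE,
           prob = pmax(c(cfg$n_snv, cfg$n_ins, cfg$n_del), 1e-9))
  } else character(0)
  sites <- data.frame(
    type = c(truth_types, fp_types),
    class = c(truth_class, rep("FP", n_fp)),
    stringsAsFactors = FALSE)
  sites$in_tract <- sites$type %in% c("INS", "DEL") &
    runif(n_sites) < cfg$homopolymer_fraction
  sites$slot <- sample(n_slots, n_sites)
  sites$center <- EDGE_MARGIN + (sites$slot - 1L) * SLOT_WIDTH + SLOT_WIDTH %/% 2L
  ## base sequence
  seq_v <- sample(BASES, L, replace = TRUE)
  ## embed tracts at tract sites, with boundary bases guarded to differ from
  ## the tract so the tract start is the true canonical anchor
  tracts <- list()
  for (i in which(sites$in_tract)) {
    c0 <- sites$center[i]
    homo <- runif(1) < 0.5
    if (homo) {
      unit <- sample(BASES, 1L)
      tl <- sample(5:15, 1L)
      tract_seq <- rep(unit, tl)
    } else {
      unit2 <- sample(BASES, 2L)        # two distinct bases
      nu <- sample(3:6, 1L)
      tl <- 2L * nu
      tract_seq <- rep(unit2, nu)
      unit <- paste(unit2, collapse = "")
    }
    seq_v[c0:(c0 + tl - 1L)] <- tract_seq
    seq_v[c0 - 1L] <- sample(setdiff(BASES, tract_seq[c(1L, length(tract_seq))]), 1L)
    seq_v[c0 + tl] <- sample(setdiff(BASES, tract_seq[length(tract_seq)]), 1L)
    tracts[[length(tracts) + 1L]] <- data.frame(
      site = i, start = c0, end = c0 + tl - 1L,
      unit = if (homo) unit else unit, kind = if (homo) "homopolymer" else "dinucleotide",
      stringsAsFactors = FALSE)
  }
  tracts <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(site = integer(0), start = integer(0), end = integer(0),
               unit = character(0), kind = character(0))
  structure(list(contig = cfg$contig, seq = paste(seq_v, collapse = ""),
                 length = L, tracts = tracts, sites = sites),
            class = "sim_reference")
}

#' In-memory reference accessor for a `sim_reference`
#' @param ref A `sim_reference`.
#' @return An accessor `function(contig, start, len)` as in
#'   [read_reference()].
#' @export
sim_reference_accessor <- function(ref) {
  lens <- setNames(ref$length, ref$contig)
  acc <- function(contig, start, len = 1L) {
    if (contig != ref$contig) vb_stop("contig '%s' not present in reference", contig)
    if (start < 1L || start + len - 1L > ref$length) {
      vb_stop("coordinates out of range for contig '%s'", contig)
    }
    substr(ref$seq, start, start + len - 1L)
  }
  attr(acc, "lengths") <- lens
  acc
}

## Draw VAFs for callable (TP/FN) and FP classes under the configured rule.
draw_vafs <- function(n, callable, cfg) {
  vr <- cfg$vaf_rule
  if (identical(vr$rule, "split")) {
    gap <- vr$gap %||% 0.02
    lo <- vr$lo %||% 0.01
    hi <- vr$hi %||% 0.5
    if (callable) runif(n, vr$cutoff + gap / 2, hi)
    else runif(n, lo, vr$cutoff - gap / 2)
  } else {
    m <- vr$mean %||% 0.35
    conc <- vr$conc %||% 25
    sdv <- sqrt(m * (1 - m) / (1 + conc))
    mf <- max(0.02, m - cfg$separation * sdv)
    mm <- if (callable) m else mf
    rbeta(n, mm * conc, (1 - mm) * conc)
  }
}

## Construct the allele of one planned site.  Everything is chosen so that
## the intended VCF spelling is already left-aligned and parsimonious; the
## guards (boundary bases differing from the edit's last base) are what make
## the canonical coordinates knowable by construction, independently of the
## harmonizer.
build_site_allele <- function(site_idx, ref) {
  s <- ref$sites[site_idx, ]
  seqc <- function(i, j = i) substr(ref$seq, i, j)
  c0 <- s$center
  if (s$type == "SNV") {
    refb <- seqc(c0)
    altb <- sample(setdiff(BASES, refb), 1L)
    return(list(vcf_pos = c0, vcf_ref = refb, vcf_alt = altb,
                start = c0, end = c0, cref = refb, calt = altb,
                vclass = "SNV", tract = NULL))
  }
  tract <- ref$tracts[ref$tracts$site == site_idx, ]
  if (nrow(tract) == 1L) {
    unit <- tract$unit
    k <- nchar(unit)
    t1 <- tract$start; t2 <- tract$end
    if (s$type == "DEL") {
      ## delete the first repeat unit; canonical interval [t1, t1+k-1]
      return(list(vcf_pos = t1 - 1L,
                  vcf_ref = seqc(t1 - 1L, t1 + k - 1L), vcf_alt = seqc(t1 - 1L),
                  start = t1, end = t1 + k - 1L, cref = seqc(t1, t1 + k - 1L),
                  calt = "-", vclass = "DEL", tract = tract))
    }
    ## insert one repeat unit; canonical anchor is the base before the tract
    return(list(vcf_pos = t1 - 1L,
                vcf_ref = seqc(t1 - 1L), vcf_alt = paste0(seqc(t1 - 1L), unit),
                start = t1 - 1L, end = t1 - 1L, cref = "-", calt = unit,
                vclass = "INS", tract = tract))
  }
  ## non-tract indel at the slot centre
  if (s$type == "DEL") {
    for (cc in c0 + 0:5) {
      for (k in sample(1:4)) {
        if (seqc(cc - 1L) != seqc(cc + k - 1L)) {
          return(list(vcf_pos = cc - 1L,
                      vcf_ref = seqc(cc - 1L, cc + k - 1L), vcf_alt = seqc(cc - 1L),
                      start = cc, end = cc + k - 1L,
                      cref = seqc(cc, cc + k - 1L), calt = "-",
                      vclass = "DEL", tract = NULL))
        }
      }
    }
    vb_stop("could not place a canonical deletion near position %d", c0)
  }
  ## insertion: random sequence whose last base differs from the anchor base
  k <- sample(1:4, 1L)
  ins <- c(sample(BASES, max(0L, k - 1L), replace = TRUE),
           sample(setdiff(BASES, seqc(c0 - 1L)), 1L))
  ins <- paste(ins, collapse = "")
  list(vcf_pos = c0 - 1L, vcf_ref = seqc(c0 - 1L),
       vcf_alt = paste0(seqc(c0 - 1L), ins),
       start = c0 - 1L, end = c0 - 1L, cref = "-", calt = ins,
       vclass = "INS", tract = NULL)
}

## Equivalent re-spellings of a site's edit (the "symbolic" FN generator).
respell <- function(al, ref) {
  seqc <- function(i, j = i) substr(ref$seq, i, j)
  options <- c("pad")
  if (!is.null(al$tract) && al$tract$kind == "homopolymer" &&
      al$vclass %in% c("INS", "DEL")) {
    options <- c(options, "shift")
  }
  choice <- sample(options, 1L)
  if (choice == "shift") {
    t1 <- al$tract$start; t2 <- al$tract$end
    if (al$vclass == "DEL") {
      k <- nchar(al$cref)
      p <- t2 - k                      # rightmost equivalent anchor
      return(list(pos = p, ref = seqc(p, p + k), alt = seqc(p)))
    }
    p <- t2                            # rightmost insertion anchor
    return(list(pos = p, ref = seqc(p), alt = paste0(seqc(p), al$calt)))
  }
  ## pad: prepend the previous reference base to both alleles
  p <- al$vcf_pos - 1L
  list(pos = p, ref = paste0(seqc(p), al$vcf_ref),
       alt = paste0(seqc(p), al$vcf_alt))
}

#' Generate truth and query callsets with a ground-truth ledger
#'
#' The truth VCF holds every planned real variant in canonical spelling.
#' The query VCF holds the TPs — a `symbolic_rate` share of them re-spelled
#' as shifted / padded / multi-allelic equivalents — plus the injected FPs;
#' b-FN and seq-FN variants are withheld.  Query records carry caller-style
#' fields (`AF`, `DP`, `SAF`, `SAR`, QUAL) drawn so that TP distributions
#' exceed FP distributions by the configured separation.
#'
#' @param cfg A [sim_config()].
#' @param ref A `sim_reference` from [generate_reference()].
#' @return List: `truth_records`, `query_records` (raw record lists ready for
#'   [write_vcf()]), `ledger` (data.frame, one row per emitted variant) and
#'   `meta` (VCF header lines for the query).
#' @export
generate_truth_and_query <- function(cfg, ref) {
  set.seed(cfg$seed + 1L)
  sites <- ref$sites
  n <- nrow(sites)
  alleles <- lapply(seq_len(n), build_site_allele, ref = ref)
  callable <- sites$class != "FP"
  vaf <- numeric(n)
  vaf[callable] <- draw_vafs(sum(callable), TRUE, cfg)
  vaf[!callable] <- draw_vafs(sum(!callable), FALSE, cfg)
  qual <- pmax(1, rnorm(n, ifelse(callable, cfg$qual_mean,
                                  cfg$qual_mean - cfg$separation * cfg$qual_sd),
                        cfg$qual_sd))
  caller_dp <- pmax(2, rnbinom(n, size = cfg$depth_dispersion,
                               mu = ifelse(callable, cfg$depth_mean,
                                           cfg$depth_mean * exp(-0.25 * cfg$separation))))
  alt_caller <- pmax(1L, round(vaf * caller_dp))
  saf <- rbinom(n, alt_caller,
                ifelse(callable, cfg$strand_balance, cfg$fp_strand_balance))
  sar <- alt_caller - saf
  respelled <- callable & sites$class == "TP" & runif(n) < cfg$symbolic_rate

  truth_records <- list(); query_records <- list(); ledger_rows <- list()
  for (i in seq_len(n)) {
    al <- alleles[[i]]
    base_rec <- list(chrom = cfg$contig, pos = al$vcf_pos, id = ".",
                     ref = al$vcf_ref, alts = al$vcf_alt,
                     qual = NA_real_, filter = ".", info = list(), format = list())
    if (sites$class[i] != "FP") {
      truth_records[[length(truth_records) + 1L]] <- base_rec
    }
    in_query <- sites$class[i] %in% c("TP", "FP")
    sp <- "withheld"
    if (in_query) {
      q <- base_rec
      sp <- "canonical"
      if (respelled[i]) {
        kind <- sample(c("respell", "multiallelic"), 1L)
        if (kind == "respell") {
          rs <- respell(al, ref)
          q$pos <- rs$pos; q$ref <- rs$ref; q$alts <- rs$alt
          sp <- "respelled"
        } else {
          sp <- "multiallelic"
        }
      }
      if (sp == "multiallelic") {
        ## add a zero-frequency decoy allele; decomposition must drop it
        cand <- paste0(q$ref, BASES)
        cand <- cand[cand != q$alts[1] &
                       BASES != substr(q$ref, nchar(q$ref), nchar(q$ref))]
        decoy <- sample(cand, 1L)
        q$alts <- c(q$alts, decoy)
        q$info <- list(AF = c(format(vaf[i], digits = 6), "0"),
                       DP = as.character(caller_dp[i]),
                       SAF = c(as.character(saf[i]), "0"),
                       SAR = c(as.character(sar[i]), "0"))
      } else {
        q$info <- list(AF = format(vaf[i], digits = 6),
                       DP = as.character(caller_dp[i]),
                       SAF = as.character(saf[i]),
                       SAR = as.character(sar[i]))
      }
      q$qual <- round(qual[i], 2)
      q$filter <- "PASS"
      query_records[[length(query_records) + 1L]] <- q
    }
    ledger_rows[[i]] <- list(start = al$start, end = al$end, ref = al$cref,
                             alt = al$calt, vclass = al$vclass, spelling = sp)
  }
  grab <- function(f, mode) vapply(ledger_rows, `[[`, mode, f)
  ledger <- data.frame(
    site = seq_len(n), chrom = cfg$contig,
    start = as.integer(grab("start", numeric(1))),
    end = as.integer(grab("end", numeric(1))),
    ref = grab("ref", character(1)), alt = grab("alt", character(1)),
    vclass = grab("vclass", character(1)), class = sites$class,
    in_tract = sites$in_tract, spelling = grab("spelling", character(1)),
    vaf = vaf, qual = qual, caller_dp = caller_dp, saf = saf, sar = sar,
    stringsAsFactors = FALSE)
  ledger$key <- canonical_key(ledger$chrom, ledger$start, ledger$end,
                              ledger$ref, ledger$alt)
  if (anyDuplicated(ledger$key)) {
    vb_stop("internal error: canonical-key collision in the generator")
  }
  meta <- c('##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
            '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
            '##INFO=<ID=SAF,Number=A,Type=Integer,Description="Alt reads forward">',
            '##INFO=<ID=SAR,Number=A,Type=Integer,Description="Alt reads reverse">',
            paste0("##contig=<ID=", cfg$contig, ",length=", cfg$region_length, ">"))
  list(truth_records = truth_records, query_records = query_records,
       ledger = ledger, meta = meta)
}

#' Generate reads and per-site counts from the ledger
#'
#' Draws each site's depth from the negative-binomial model, fixes exact
#' per-strand ref/alt read counts (b-FN sites get at least one alt read,
#' seq-FN sites none and may drop out entirely), records them back into the
#' ledger, and renders them as perfect reads (SAM text; indels as I/D CIGAR
#' ops) plus the equivalent readcount table.
#'
#' @param cfg A [sim_config()].
#' @param ledger Ledger from [generate_truth_and_query()].
#' @param ref A `sim_reference`.
#' @param render_sam Build the SAM text (set `FALSE` to skip the read
#'   rendering and keep only counts/readcount table, e.g. for large sweeps).
#' @return List: `ledger` (with realized counts), `sam` (character lines or
#'   `NULL`), `readcount_lines` (character lines).
#' @export
generate_reads <- function(cfg, ledger, ref, render_sam = TRUE) {
  set.seed(cfg$seed + 2L)
  n <- nrow(ledger)
  depth <- pmax(2L, rnbinom(n, size = cfg$depth_dispersion, mu = cfg$depth_mean))
  dropout <- ledger$class == "seq-FN" & runif(n) < 0.3
  depth[dropout] <- 0L
  alt_n <- ifelse(ledger$class == "seq-FN", 0L,
                  pmin(depth, pmax(1L, round(ledger$vaf * depth))))
  sb <- ifelse(ledger$class == "FP", cfg$fp_strand_balance, cfg$strand_balance)
  alt_fwd <- rbinom(n, alt_n, sb)
  ref_n <- depth - alt_n
  ref_fwd <- rbinom(n, ref_n, 0.5)
  ledger$depth <- depth
  ledger$alt_fwd <- alt_fwd
  ledger$alt_rev <- alt_n - alt_fwd
  ledger$ref_fwd <- ref_fwd
  ledger$ref_rev <- ref_n - ref_fwd
  ledger$realized_vaf <- ifelse(depth > 0L, alt_n / depth, NA_real_)
  ledger$realized_stb <- ifelse(alt_n > 0L,
                                pmax(alt_fwd, alt_n - alt_fwd) / alt_n, NA_real_)
  seqc <- function(i, j = i) substr(ref$seq, i, j)
  rc_lines <- character(n)
  sam_rows <- if (render_sam) vector("list", n) else NULL
  for (i in seq_len(n)) {
    v <- list(chrom = ledger$chrom[i], start = ledger$start[i],
              end = ledger$end[i], ref = ledger$ref[i], alt = ledger$alt[i],
              vclass = ledger$vclass[i], depth = ledger$depth[i],
              alt_fwd = ledger$alt_fwd[i], alt_rev = ledger$alt_rev[i],
              ref_fwd = ledger$ref_fwd[i], ref_rev = ledger$ref_rev[i])
    anchor <- v$start
    w1 <- max(1L, anchor - cfg$flank)
    w2 <- min(ref$length, v$end + cfg$flank)
    ref_seq <- seqc(w1, w2)
    ref_cigar <- paste0(nchar(ref_seq), "M")
    if (v$vclass == "SNV") {
      alt_seq <- paste0(seqc(w1, anchor - 1L), v$alt, seqc(anchor + 1L, w2))
      alt_cigar <- ref_cigar
    } else if (v$vclass == "DEL") {
      alt_seq <- paste0(seqc(w1, v$start - 1L), seqc(v$end + 1L, w2))
      alt_cigar <- paste0(v$start - w1, "M", v$end - v$start + 1L, "D",
                          w2 - v$end, "M")
    } else {
      alt_seq <- paste0(seqc(w1, anchor), v$alt, seqc(anchor + 1L, w2))
      alt_cigar <- paste0(anchor - w1 + 1L, "M", nchar(v$alt), "I",
                          w2 - anchor, "M")
    }
    rc_lines[i] <- paste(
      v$chrom, v$start, seqc(v$start),
      v$depth,
      paste("=", v$ref_fwd + v$ref_rev, v$ref_fwd, v$ref_rev, sep = ":"),
      paste(switch(v$vclass, INS = paste0("+", v$alt),
                   DEL = paste0("-", v$ref), v$alt),
            v$alt_fwd + v$alt_rev, v$alt_fwd, v$alt_rev, sep = ":"),
      sep = "\t")
    if (render_sam && v$depth > 0L) {
      strands <- c(rep(c(0L, 16L), c(v$ref_fwd, v$ref_rev)),
                   rep(c(0L, 16L), c(v$alt_fwd, v$alt_rev)))
      is_alt <- rep(c(FALSE, TRUE), c(v$ref_fwd + v$ref_rev,
                                      v$alt_fwd + v$alt_rev))
      k <- length(strands)
      sam_rows[[i]] <- paste(
        sprintf("s%04d_r%03d", i, seq_len(k)), strands, v$chrom, w1, 60L,
        ifelse(is_alt, alt_cigar, ref_cigar), "*", 0L, 0L,
        ifelse(is_alt, alt_seq, ref_seq),
        vapply(ifelse(is_alt, nchar(alt_seq), nchar(ref_seq)),
               function(nc) strrep("I", nc), character(1)),
        sep = "\t")
    }
  }
  sam <- NULL
  if (render_sam) {
    body <- unlist(sam_rows)
    ## already in ascending start order per site ordering by slot? sites were
    ## shuffled across slots, so sort by POS for coordinate order
    pos <- as.integer(vapply(strsplit(body, "\t", fixed = TRUE), `[[`, "", 4L))
    body <- body[order(pos)]
    sam <- c("@HD\tVN:1.6\tSO:coordinate",
             paste0("@SQ\tSN:", cfg$contig, "\tLN:", ref$length),
             body)
  }
  list(ledger = ledger, sam = sam, readcount_lines = rc_lines)
}

#' Generate a complete benchmark fixture on disk
#'
#' Runs [generate_reference()], [generate_truth_and_query()] and
#' [generate_reads()] and writes `reference.fa`, `truth.vcf`, `query.vcf`,
#' `regions.bed`, `reads.sam` (optional), `readcounts.tsv` and `ledger.json`
#' into `out_dir`.  The high-confidence BED covers the reference minus a
#' 50 bp margin at each end.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param render_sam Also write the SAM file (default `TRUE`).
#' @return Invisibly, a list with the file `paths`, the `ledger`, the
#'   `reference` object and the `cfg`.
#' @export
simulate_benchmark <- function(cfg = sim_config(), out_dir,
                               render_sam = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(cfg)
  tq <- generate_truth_and_query(cfg, ref)
  rd <- generate_reads(cfg, tq$ledger, ref, render_sam = render_sam)
  paths <- list(
    reference = file.path(out_dir, "reference.fa"),
    truth = file.path(out_dir, "truth.vcf"),
    query = file.path(out_dir, "query.vcf"),
    bed = file.path(out_dir, "regions.bed"),
    sam = if (render_sam) file.path(out_dir, "reads.sam") else NULL,
    readcounts = file.path(out_dir, "readcounts.tsv"),
    ledger = file.path(out_dir, "ledger.json"))
  writeLines(c(paste0(">", cfg$contig),
               substring(ref$seq, seq(1L, ref$length, 70L),
                         pmin(seq(1L, ref$length, 70L) + 69L, ref$length))),
             paths$reference)
  write_vcf(tq$truth_records, paths$truth,
            meta = paste0("##contig=<ID=", cfg$contig, ",length=",
                          cfg$region_length, ">"))
  write_vcf(tq$query_records, paths$query, meta = tq$meta)
  writeLines(paste(cfg$contig, EDGE_MARGIN, cfg$region_length - EDGE_MARGIN,
                   sep = "\t"), paths$bed)
  if (render_sam) writeLines(rd$sam, paths$sam)
  writeLines(rd$readcount_lines, paths$readcounts)
  jsonlite::write_json(rd$ledger, paths$ledger, digits = NA, na = "null")
  invisible(list(paths = paths, ledger = rd$ledger, reference = ref,
                 truth = tq$truth_records, query = tq$query_records, cfg = cfg))
}
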