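## Builds tiny SAM files in code and checks the pileup counting, parameter
## derivation and FN classification against construction.

sam_file <- function(reads, contig = "c1", len = 200L) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, len),
               reads), path)
  path
}

sam_read <- function(name, flag, pos, cigar, seq, contig = "c1", mapq = 60L,
                     qual = strrep("I", nchar(seq))) {
  paste(name, flag, contig, pos, mapq, cigar, "*", 0L, 0L, seq, qual,
        sep = "\t")
}

test_that("SNV pileup counts ref and alt reads by strand", {
  ## reference context: positions 1..20 = ACGTACGTACGTACGTACGT; SNV A>G at 9
  refwin <- "ACGTACGTACGTACGT"
  altwin <- paste0(substr(refwin, 1, 8), "G", substr(refwin, 10, 16))
  reads <- c(
    vapply(1:3, function(i) sam_read(paste0("rf", i), 0L, 1L, "16M", refwin), ""),
    vapply(1:3, function(i) sam_read(paste0("rr", i), 16L, 1L, "16M", refwin), ""),
    vapply(1:3, function(i) sam_read(paste0("af", i), 0L, 1L, "16M", altwin), ""),
    sam_read("ar1", 16L, 1L, "16M", altwin))
  src <- bam_source(sam_file(reads))
  cv <- cv_row("c1", 9, 9, "A", "G", "SNV")
  rc <- readcount_site(cv, src)
  expect_equal(rc$depth, 10L)
  expect_equal(c(rc$alt_fwd, rc$alt_rev), c(3L, 1L))
  expect_equal(c(rc$ref_fwd, rc$ref_rev), c(3L, 3L))

  ## derived parameters
  p <- derive_params(rc)
  expect_equal(p$vaf, 0.4)
  expect_equal(p$dp, 10)
  expect_equal(p$stb, 0.75)
})

test_that("no reads at the site means zero depth and null parameters", {
  src <- bam_source(sam_file(sam_read("r1", 0L, 100L, "10M", "ACGTACGTAC")))
  rc <- readcount_site(cv_row("c1", 5, 5, "A", "G", "SNV"), src)
  expect_equal(rc$depth, 0L)
  p <- derive_params(rc)
  expect_true(is.na(p$vaf))
  expect_true(is.na(p$stb))
})

test_that("deletion support requires deleting exactly the canonical interval", {
  ## delete positions 6-7 from reference ACGTACGTACGTACGT
  refwin <- "ACGTACGTACGTACGT"
  delseq <- paste0(substr(refwin, 1, 5), substr(refwin, 8, 16))
  reads <- c(
    sam_read("d1", 0L, 1L, "5M2D9M", delseq),
    sam_read("d2", 16L, 1L, "5M2D9M", delseq),
    sam_read("dlong", 0L, 1L, "5M3D8M",
             paste0(substr(refwin, 1, 5), substr(refwin, 9, 16))),  # wrong interval
    sam_read("r1", 0L, 1L, "16M", refwin))
  src <- bam_source(sam_file(reads))
  cv <- cv_row("c1", 6, 7, "CG", "-", "DEL")
  rc <- readcount_site(cv, src)
  expect_equal(rc$alt_fwd + rc$alt_rev, 2L)
  expect_equal(rc$ref_fwd + rc$ref_rev, 1L)
  expect_equal(rc$depth, 4L)   # all four span the anchor
})

test_that("insertion support requires inserting exactly the canonical sequence", {
  refwin <- "ACGTACGTACGTACGT"
  insseq <- paste0(substr(refwin, 1, 6), "TT", substr(refwin, 7, 16))
  wrongseq <- paste0(substr(refwin, 1, 6), "TA", substr(refwin, 7, 16))
  reads <- c(
    sam_read("i1", 0L, 1L, "6M2I10M", insseq),
    sam_read("i2", 16L, 1L, "6M2I10M", insseq),
    sam_read("iw", 0L, 1L, "6M2I10M", wrongseq),
    sam_read("r1", 0L, 1L, "16M", refwin))
  src <- bam_source(sam_file(reads))
  cv <- cv_row("c1", 6, 6, "-", "TT", "INS")
  rc <- readcount_site(cv, src)
  expect_equal(rc$alt_fwd + rc$alt_rev, 2L)
  expect_equal(rc$ref_fwd + rc$ref_rev, 1L)  # the wrong insertion supports neither
})

test_that("duplicate/secondary reads and low mapq are excluded", {
  refwin <- "ACGTACGTACGTACGT"
  reads <- c(
    sam_read("ok", 0L, 1L, "16M", refwin),
    sam_read("dup", 1024L, 1L, "16M", refwin),
    sam_read("sec", 256L, 1L, "16M", refwin),
    sam_read("lowmq", 0L, 1L, "16M", refwin, mapq = 5L))
  src <- bam_source(sam_file(reads))
  cv <- cv_row("c1", 9, 9, "A", "G", "SNV")
  rc <- readcount_site(cv, src, recheck_policy(min_mapping_quality = 20L))
  expect_equal(rc$depth, 1L)
})

test_that("bases below the quality floor do not count", {
  refwin <- "ACGTACGTACGTACGT"
  lowq <- paste0(strrep("I", 8), "#", strrep("I", 7))  # Q2 at position 9
  reads <- c(sam_read("hi", 0L, 1L, "16M", refwin),
             sam_read("lo", 0L, 1L, "16M", refwin, qual = lowq))
  src <- bam_source(sam_file(reads))
  cv <- cv_row("c1", 9, 9, "A", "G", "SNV")
  rc <- readcount_site(cv, src, recheck_policy(min_base_quality = 20L))
  expect_equal(rc$ref_fwd + rc$ref_rev, 1L)
  expect_equal(rc$depth, 2L)   # still spans; base just fails the floor
})

test_that("a contig missing from the BAM reports an uncovered site", {
  src <- bam_source(sam_file(sam_read("r1", 0L, 1L, "10M", "ACGTACGTAC")))
  expect_warning(rc <- readcount_site(cv_row("cX", 5, 5, "A", "G", "SNV"), src),
                 "absent")
  expect_equal(rc$depth, 0L)
})

test_that("classify_fns splits FNs by read support with pileup parameters", {
  refwin <- "ACGTACGTACGTACGT"
  altwin <- paste0(substr(refwin, 1, 8), "G", substr(refwin, 10, 16))
  reads <- c(vapply(1:6, function(i) sam_read(paste0("r", i), (i %% 2) * 16L,
                                              1L, "16M", refwin), ""),
             vapply(1:3, function(i) sam_read(paste0("a", i), 0L, 1L, "16M",
                                              altwin), ""),
             sam_read("a4", 16L, 1L, "16M", altwin))
  src <- bam_source(sam_file(reads))
  fns <- rbind(
    cbind(cv_row("c1", 9, 9, "A", "G", "SNV"), class = "FN", fn_subtype = "unchecked"),
    cbind(cv_row("c1", 13, 13, "A", "C", "SNV"), class = "FN", fn_subtype = "unchecked"))
  out <- classify_fns(fns, src)
  expect_equal(out$bfn_count, 1L)
  expect_equal(out$seqfn_count, 1L)
  b <- out$calls[out$calls$fn_subtype == "b-FN", ]
  expect_equal(b$vaf, 0.4)
  expect_equal(b$dp, 10)
  expect_equal(b$stb, 0.75)

  ## with min_alt_reads above the support, it becomes seq-FN (monotone)
  strict <- classify_fns(fns, src, recheck_policy(min_alt_reads = 5L))
  expect_equal(strict$bfn_count, 0L)

  ## no alignments -> everything stays unchecked
  un <- classify_fns(fns, NULL)
  expect_true(is.na(un$bfn_count))
  expect_true(all(un$calls$fn_subtype == "unchecked"))
})

test_that("STB is 0.5 for perfectly balanced alt reads", {
  rc <- varbench:::site_readcount(depth = 8, alt_fwd = 2, alt_rev = 2,
                                  ref_fwd = 2, ref_rev = 2)
  expect_equal(derive_params(rc)$stb, 0.5)
})

test_that("build_seqpos labels TPs and b-FNs 1, FPs 0, and drops seq-FNs", {
  calls <- rbind(
    cbind(cv_row("c1", 1, 1, "A", "G", "SNV", vaf = .4), class = "TP", fn_subtype = "none"),
    cbind(cv_row("c1", 2, 2, "A", "G", "SNV", vaf = .3), class = "TP", fn_subtype = "none"),
    cbind(cv_row("c1", 3, 3, "A", "G", "SNV", vaf = .2), class = "FN", fn_subtype = "b-FN"),
    cbind(cv_row("c1", 4, 4, "A", "G", "SNV"), class = "FN", fn_subtype = "seq-FN"),
    cbind(cv_row("c1", 5, 5, "A", "G", "SNV", vaf = .1), class = "FP", fn_subtype = "none"))
  sp <- build_seqpos(calls)
  expect_equal(nrow(sp), 4L)
  expect_equal(sum(sp$label), 3L)
  expect_equal(nrow(build_seqpos(calls[0, ])), 0L)
})

test_that("readcount TSV path equals the BAM path on generated fixtures", {
  fx <- simulate_benchmark(sim_config(seed = 31, n_snv = 14, n_ins = 5,
                                      n_del = 5, region_length = 3500),
                           tempfile("fx"))
  bam <- bam_source(fx$paths$sam)
  tsv <- readcount_source(fx$paths$readcounts)
  led <- fx$ledger
  for (i in which(led$class %in% c("b-FN", "seq-FN", "TP"))) {
    cv <- led[i, c("chrom", "start", "end", "ref", "alt", "vclass")]
    a <- readcount_site(cv, bam)
    b <- readcount_site(cv, tsv)
    expect_identical(a, b)
    ## and both equal the ledger's construction
    expect_equal(a$depth, led$depth[i])
    expect_equal(a$alt_fwd, led$alt_fwd[i])
    expect_equal(a$alt_rev, led$alt_rev[i])
    expect_equal(a$ref_fwd, led$ref_fwd[i])
  }
})
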