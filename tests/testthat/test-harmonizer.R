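test_that("left alignment shifts a homopolymer deletion to the tract start", {
  acc <- string_reference(c1 = "CAAAT")
  out <- left_align("c1", 3L, "AA", "A", acc)
  expect_equal(out, list(pos = 1L, ref = "CA", alt = "C"))
})

test_that("left alignment shifts a homopolymer insertion to the tract start", {
  acc <- string_reference(c1 = "ATTTTC")
  out <- left_align("c1", 5L, "T", "TT", acc)
  expect_equal(out, list(pos = 1L, ref = "A", alt = "AT"))
})

test_that("SNVs pass through left alignment unchanged", {
  acc <- string_reference(c1 = "ACGTA")
  expect_equal(left_align("c1", 3L, "G", "C", acc),
               list(pos = 3L, ref = "G", alt = "C"))
})

test_that("a REF allele disagreeing with the reference is an error", {
  acc <- string_reference(c1 = "ACGTA")
  expect_error(left_align("c1", 3L, "T", "A", acc), "reference mismatch")
})

test_that("left alignment stops with a warning at the contig start", {
  acc <- string_reference(c1 = "AAAAC")
  expect_warning(out <- left_align("c1", 1L, "AA", "A", acc), "start of contig")
  ## still a valid spelling of the same haplotype
  expect_equal(oracle_apply("AAAAC", out$pos, out$ref, out$alt), "AAAC")
})

test_that("to_canonical maps the three variant shapes", {
  del <- to_canonical("c1", 1L, "CA", "C")
  expect_equal(del[c("start", "end", "ref", "alt", "vclass")],
               data.frame(start = 2L, end = 2L, ref = "A", alt = "-",
                          vclass = "DEL"))
  ins <- to_canonical("c1", 1L, "A", "AT")
  expect_equal(ins[c("start", "end", "ref", "alt", "vclass")],
               data.frame(start = 1L, end = 1L, ref = "-", alt = "T",
                          vclass = "INS"))
  snv <- to_canonical("c1", 3L, "C", "G")
  expect_equal(snv[c("start", "end", "vclass")],
               data.frame(start = 3L, end = 3L, vclass = "SNV"))
  expect_warning(null <- to_canonical("c1", 3L, "C", "C"), "null variant")
  expect_null(null)
})

test_that("multi-allelic split slices A/R arrays and drops zero-frequency alleles", {
  nm <- list(INFO = c(AF = "A"), FORMAT = c(AD = "R"))
  rec <- raw_record("c1", 100, "A", c("G", "T"),
                    info = list(AF = c("0.4", "0.0")))
  sp <- split_multiallelic(rec, caller_dialect("generic"), nm)
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$alts, "G")
  expect_equal(sp[[1]]$params$vaf, 0.4)

  ## identity on a biallelic record
  rec1 <- raw_record("c1", 100, "A", "G")
  expect_length(split_multiallelic(rec1, caller_dialect("generic"), nm), 1L)

  ## Number=R slicing: AD = ref,alt1,alt2
  rec2 <- raw_record("c1", 100, "A", c("G", "T"),
                     format = list(AD = c("10", "6", "4")))
  sp2 <- split_multiallelic(rec2, caller_dialect("generic"), nm)
  expect_length(sp2, 2L)
  expect_equal(sp2[[1]]$params$vaf, 6 / 20)
  expect_equal(sp2[[2]]$params$vaf, 4 / 20)
  expect_equal(sp2[[1]]$format$AD, c("10", "6"))
})

test_that("mis-sized Number=A arrays are marked missing with a warning", {
  nm <- list(INFO = c(AF = "A"), FORMAT = character(0))
  rec <- raw_record("c1", 100, "A", c("G", "T"), info = list(AF = "0.4"))
  w <- testthat::capture_warnings(
    sp <- split_multiallelic(rec, caller_dialect("generic"), nm))
  expect_true(all(grepl("marked missing", w)))  # one warning per allele
  expect_length(sp, 2L)   # no frequency evidence -> retained
})

test_that("harmonize_callset collapses duplicates keeping the highest QUAL", {
  acc <- string_reference(c1 = "GCAAATG")
  ## two spellings of deleting one A from the AAA tract (pos 3..5)
  r1 <- raw_record("c1", 2, "CA", "C", qual = 10)
  r2 <- raw_record("c1", 4, "AA", "A", qual = 60)
  set <- harmonize_callset(list(r1, r2), acc)
  expect_equal(nrow(set), 1L)
  expect_equal(set$qual, 60)
  expect_equal(set$vclass, "DEL")

  expect_equal(nrow(harmonize_callset(list(), acc)), 0L)
})

test_that("harmonization is idempotent after re-expression as VCF", {
  set.seed(11)
  for (i in 1:25) {
    win <- random_tract_window()
    acc <- string_reference(w = win$seq)
    type <- sample(c("DEL", "INS"), 1)
    sp <- equivalent_spellings(win, type)[[1]]
    rec <- raw_record("w", sp$pos, sp$ref, sp$alt)
    once <- harmonize_callset(list(rec), acc)
    vcf_again <- canonical_to_vcf(once[1, ], acc)
    twice <- harmonize_callset(list(raw_record("w", vcf_again$pos,
                                               vcf_again$ref, vcf_again$alt)), acc)
    expect_equal(twice$key, once$key)
  }
})

test_that("equivalent spellings collapse to one key and preserve the haplotype", {
  set.seed(23)
  for (i in 1:40) {
    win <- random_tract_window()
    acc <- string_reference(w = win$seq)
    type <- sample(c("DEL", "INS"), 1)
    spellings <- equivalent_spellings(win, type)
    keys <- character(0)
    target <- oracle_apply(win$seq, spellings[[1]]$pos, spellings[[1]]$ref,
                           spellings[[1]]$alt)
    for (sp in spellings) {
      ## every spelling describes the same haplotype (construction check)
      expect_equal(oracle_apply(win$seq, sp$pos, sp$ref, sp$alt), target)
      cset <- harmonize_callset(list(raw_record("w", sp$pos, sp$ref, sp$alt)), acc)
      expect_equal(nrow(cset), 1L)
      ## the canonical edit reproduces the haplotype
      expect_equal(oracle_apply_canonical(win$seq, cset[1, ]), target)
      keys <- c(keys, cset$key)
    }
    expect_length(unique(keys), 1L)
  }
})

test_that("a multi-allelic spelling maps to the same key as the split spelling", {
  acc <- string_reference(w = "GGCTTTTACG")
  nm_meta <- '##INFO=<ID=AF,Number=A,Type=Float,Description="af">'
  plain <- raw_record("w", 3, "C", "CT", info = list(AF = "0.3"))
  multi <- raw_record("w", 3, "C", c("CT", "A"), info = list(AF = c("0.3", "0")))
  p1 <- write_tmp_vcf(list(plain), meta = nm_meta)
  p2 <- write_tmp_vcf(list(multi), meta = nm_meta)
  s1 <- harmonize_callset(read_vcf(p1), acc)
  s2 <- harmonize_callset(read_vcf(p2), acc)
  expect_equal(s2$key, s1$key)
  expect_equal(nrow(s2), 1L)
})

test_that("reference-mismatching records are dropped with a warning, not an abort", {
  acc <- string_reference(w = "ACGTACGT")
  good <- raw_record("w", 2, "C", "T")
  bad <- raw_record("w", 5, "C", "T")   # reference has A at 5
  expect_warning(set <- harmonize_callset(list(good, bad), acc),
                 "reference mismatch")
  expect_equal(nrow(set), 1L)
  expect_equal(set$start, 2L)
})
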