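## In-memory pipeline over a generated fixture: harmonize both callsets,
## restrict to the high-confidence regions, match, re-check against the
## readcount table.  Used by the synthetic-module tests and the acceptance
## sweeps (the file-based interface is exercised separately).
run_memory_pipeline <- function(cfg) {
  ref <- generate_reference(cfg)
  tq <- generate_truth_and_query(cfg, ref)
  rd <- generate_reads(cfg, tq$ledger, ref, render_sam = FALSE)
  acc <- sim_reference_accessor(ref)
  regions <- merge_regions(data.frame(chrom = cfg$contig, start = 50L,
                                      end = cfg$region_length - 50L))
  query <- restrict_to_regions(harmonize_callset(tq$query_records, acc), regions)
  truth <- restrict_to_regions(harmonize_callset(tq$truth_records, acc), regions)
  calls <- match_callsets(query, truth)
  rc_path <- tempfile(fileext = ".tsv")
  writeLines(rd$readcount_lines, rc_path)
  rc <- classify_fns(calls, readcount_source(rc_path))
  tn <- count_tn_bases(regions, rc$calls)
  list(ledger = rd$ledger, calls = rc$calls,
       metrics = compute_metrics(rc$calls, tn, rc$bfn_count),
       bfn_count = rc$bfn_count, seqfn_count = rc$seqfn_count,
       regions = regions, tn_bases = tn)
}
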