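# Shared fixtures, built in code. The toy reference has the canonical
# 76-nt geometry: landmarks d_loop [13,22), anticodon_loop [31,39),
# anticodon [33,36), t_loop [53,61); mature+CCA length M = 79, extended 129.

toy_gene <- function(seed = 1, ...) make_trna_gene(seed, "Thr", "TGT", ...)

toy_ref <- function(seed = 1, ...) build_mature_reference(toy_gene(seed, ...))

# a small mixed panel: plain, intron-bearing, and minus-strand genes
toy_gene_panel <- function() {
  list(make_trna_gene(1, "Thr", "TGT"),
       make_trna_gene(2, "Gly", "GCC", with_intron = TRUE),
       make_trna_gene(3, "Glu", "CTC", strand = "-"),
       make_trna_gene(4, "Lys", "TTT", strand = "-", with_intron = TRUE))
}

toy_ref_set <- function() {
  refs <- lapply(toy_gene_panel(), build_mature_reference)
  stats::setNames(refs, vapply(refs, `[[`, character(1), "trna_id"))
}

# one moderate end-to-end pipeline run, cached per test file
.pipeline_cache <- new.env(parent = emptyenv())
pipeline_fixture <- function() {
  if (!is.null(.pipeline_cache$run)) return(.pipeline_cache$run)
  refs <- toy_ref_set()
  prof <- simulation_profile(n_reads_per_sample = 800, replicates = 1,
                             days = c(0, 7),
                             tsrna_share_by_day = c("0" = 0.5, "7" = 0.8),
                             seed = 11)
  sim <- simulate_reads(refs, prof)
  recs <- list()
  totals <- numeric(0)
  hits_all <- list()
  for (sid in names(sim$reads)) {
    trimmed <- trim_adapter(sim$reads[[sid]]$seq, prof$adapter)
    kept <- length_filter(data.frame(read_id = sim$reads[[sid]]$read_id,
                                     seq = trimmed))
    h <- hierarchical_assign(kept, sim$contaminants$miRNA,
                             sim$contaminants$rRNA, refs)
    h <- classify_hits(h, refs)
    hits_all[[sid]] <- h
    recs[[sid]] <- collapse_and_count(h[h$category == "tRNA", ], refs, sid)
    totals[sid] <- sum(h$category != "unmapped")
  }
  run <- list(refs = refs, prof = prof, sim = sim, hits = hits_all,
              records = recs,
              cm = count_matrix_from_records(recs, totals))
  .pipeline_cache$run <- run
  run
}

# independent brute-force substring search used as the alignment oracle
oracle_substring_hit <- function(read, refseqs) {
  for (id in names(refseqs)) {
    s <- refseqs[[id]]
    L <- nchar(read)
    if (L > nchar(s)) next
    for (off in 0:(nchar(s) - L)) {
      if (substr(s, off + 1, off + L) == read) return(list(ref = id, start = off))
    }
  }
  NULL
}
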