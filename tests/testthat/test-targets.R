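# 3'-UTR target-site scanning and in-silico site mutagenesis.

rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# independent ungapped scoring oracle: tsRNA x against the UTR window whose
# reverse complement is y, seed positions doubled
oracle_window_score <- function(ts, win, params = target_params()) {
  x <- strsplit(ts, "")[[1]]
  y <- strsplit(rc(win), "")[[1]]
  stopifnot(length(x) == length(y))
  w <- rep(1, length(x)); w[params$seed_start:params$seed_end] <- params$seed_weight
  sum(vapply(seq_along(x), function(i) {
    base <- if (x[i] == y[i]) params$match
    else if ((x[i] == "G" && y[i] == "A") || (x[i] == "T" && y[i] == "C"))
      params$wobble
    else params$mismatch
    w[i] * base
  }, numeric(1)))
}

planted_utr <- function(ts, seed = 3, pad = 120) {
  set.seed(seed)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  left <- flank(pad)
  list(utr = paste0(left, rc(ts), flank(pad)),
       start = pad, end = pad + nchar(ts))
}

test_that("a perfect complement is found at the planted interval with the maximal score", {
  ts <- "TGGTGTCCTTGGAAAAAGGTTTTCA"  # 25 nt
  p <- planted_utr(ts)
  sites <- scan_utr(ts, p$utr)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, p$start)
  expect_equal(sites$end, p$end)
  expect_equal(sites$score, 5 * (nchar(ts) + 7))  # all matches, seed doubled
  expect_true(sites$seed_matched)
  expect_equal(sites$pairing_string, strrep("M", nchar(ts)))
  gc <- sum(strsplit(ts, "")[[1]] %in% c("G", "C"))
  expect_equal(sites$stability_proxy, -(3 * gc + 2 * (nchar(ts) - gc)))
})

test_that("the perfect site strictly dominates every other same-length window", {
  ts <- "ATGGCGTCCTAGGCAATCCA"  # 20 nt
  p <- planted_utr(ts, seed = 8, pad = 100)
  best <- 5 * (nchar(ts) + 7)
  n <- nchar(p$utr)
  scores <- vapply(0:(n - nchar(ts)), function(off) {
    oracle_window_score(ts, substr(p$utr, off + 1, off + nchar(ts)))
  }, numeric(1))
  expect_equal(max(scores), best)
  expect_equal(which.max(scores) - 1L, p$start)
  expect_true(all(scores[-(p$start + 1L)] < best))
  # and the dynamic-programming scanner attains exactly that optimum
  sites <- scan_utr(ts, p$utr)
  expect_equal(sites$score[1], best)
})

test_that("seed mutations lower the score and a threshold separates WT from mutant", {
  ts <- "TGGTGTCCTTGGAAAAAGGTTTTCA"
  p <- planted_utr(ts)
  wt <- scan_utr(ts, p$utr)
  mut <- mutate_site(p$utr, wt[1, ], ts, n_mut = 4, seed = 1)
  expect_equal(nchar(mut), nchar(p$utr))
  loose <- target_params(threshold = 1)
  mut_sites <- scan_utr(ts, mut, params = loose)
  expect_lt(mut_sites$score[1], wt$score[1])
  expect_false(mut_sites$seed_matched[1])
  mid <- (wt$score[1] + mut_sites$score[1]) / 2
  expect_equal(nrow(scan_utr(ts, p$utr, params = target_params(threshold = mid))), 1L)
  expect_equal(nrow(scan_utr(ts, mut, params = target_params(threshold = mid))), 0L)
})

test_that("each additional seed mutation never increases the site score", {
  ts <- "TGGTGTCCTTGGAAAAAGGTTTTCA"
  p <- planted_utr(ts, seed = 12)
  wt <- scan_utr(ts, p$utr)
  loose <- target_params(threshold = 1)
  prev <- wt$score[1]
  for (k in 1:4) {
    mk <- mutate_site(p$utr, wt[1, ], ts, n_mut = k, seed = 1)
    sk <- scan_utr(ts, mk, params = loose)$score[1]
    expect_lte(sk, prev)
    prev <- sk
  }
})

test_that("mutagenesis is deterministic, identity at n_mut = 0, bounded by pairing", {
  ts <- "TGGTGTCCTTGGAAAAAGGTTTTCA"
  p <- planted_utr(ts)
  wt <- scan_utr(ts, p$utr)
  expect_identical(mutate_site(p$utr, wt[1, ], ts, n_mut = 4, seed = 2),
                   mutate_site(p$utr, wt[1, ], ts, n_mut = 4, seed = 2))
  expect_identical(mutate_site(p$utr, wt[1, ], ts, n_mut = 0), p$utr)
  expect_error(mutate_site(p$utr, wt[1, ], ts, n_mut = 10), "seed positions")
})

test_that("a random UTR yields no sites at the default threshold", {
  # null behaviour for a typical 20-nt tsRNA; the attainable null score
  # grows with tsRNA length, so thresholds should be read relative to the
  # perfect-site score (here 135)
  ts <- "ATGGCGTCCTAGGCAATCCA"
  set.seed(99)
  utr <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  sites <- scan_utr(ts, utr)
  expect_equal(nrow(sites), 0L)
  # brute-force confirmation on ungapped windows
  best <- max(vapply(0:(500 - nchar(ts)), function(off)
    oracle_window_score(ts, substr(utr, off + 1, off + nchar(ts))),
    numeric(1)))
  expect_lt(best, 80)
  # even the best gapped alignment stays far below a genuine site
  loose <- scan_utr(ts, utr, params = target_params(threshold = 1,
                                                    max_sites = 1))
  expect_lt(loose$score[1], 80)
  # planting the exact complement makes it the unique, top-scoring site
  planted <- paste0(substr(utr, 1, 250), rc(ts), substr(utr, 251, 500))
  ps <- scan_utr(ts, planted)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$start, 250L)
  expect_equal(ps$score, 135)
})

test_that("multiple sites are reported non-overlapping and best-first", {
  ts <- "ATGGCGTCCTAGGCAATCCA"
  weak <- ts
  substr(weak, 12, 13) <- "TT"  # two mismatches outside the seed
  set.seed(7)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  utr <- paste0(pad(60), rc(ts), pad(40), rc(weak), pad(60))
  sites <- scan_utr(ts, utr, params = target_params(threshold = 60))
  expect_gte(nrow(sites), 2L)
  expect_true(!is.unsorted(rev(sites$score)))
  for (i in seq_len(nrow(sites) - 1)) {
    for (j in (i + 1):nrow(sites)) {
      expect_true(sites$end[i] <= sites$start[j] || sites$end[j] <= sites$start[i])
    }
  }
})

test_that("invalid scanner input is rejected", {
  expect_error(scan_utr("ACGTACGTACG", strrep("A", 50)), "12-50")
  expect_error(scan_utr(strrep("A", 51), strrep("A", 100)), "12-50")
  expect_error(scan_utr("ACGTACGTACGQ", strrep("A", 50)), "characters")
  expect_error(scan_utr(strrep("ACGT", 5), "ACGTN"), "characters")
})
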