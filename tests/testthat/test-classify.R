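# Six-class fragment taxonomy, license plates, collapse-and-count.
# The toy reference has M = 79 (76-nt mature + CCA) and widened anticodon
# window W = [28, 42) at the default loop tolerance of 3.

test_that("canonical cleavage patterns receive their classes", {
  ref <- toy_ref()
  expect_equal(classify_fragment(40, 79, ref), "3p-half")  # the 39-nt 3' half
  expect_equal(classify_fragment(0, 18, ref), "tRF-5")
  expect_equal(classify_fragment(0, 35, ref), "5p-half")
  expect_equal(classify_fragment(50, 79, ref), "tRF-3")
  expect_equal(classify_fragment(20, 50, ref), "i-tRF")
  expect_equal(classify_fragment(79, 101, ref), "tRF-1")
  # a full-length mature tRNA is not a tsRNA
  expect_equal(classify_fragment(0, 79, ref), "unclassified")
  # fragments straddling the mature/trailer boundary fit no class unless
  # their start falls in a 3'-anchored window (rule order)
  expect_equal(classify_fragment(20, 85, ref), "unclassified")
  expect_equal(classify_fragment(0, 90, ref), "unclassified")
  # end tolerance: one base of softness at the anchored ends
  expect_equal(classify_fragment(1, 18, ref), "tRF-5")
  expect_equal(classify_fragment(40, 78, ref), "3p-half")
  expect_equal(classify_fragment(78, 100, ref), "tRF-1")
  expect_error(classify_fragment(0, 200, ref), "outside")
  expect_error(classify_fragment(10, 10, ref), "outside")
})

test_that("classification matches an independent rule transcription on all 12-50 nt substrings", {
  ref <- toy_ref()
  M <- ref$trailer_start
  ext_len <- nchar(ref$extended_seq)
  w_lo <- ref$landmarks$anticodon_loop[1] - 3L
  w_hi <- ref$landmarks$anticodon_loop[2] + 3L
  tol <- 1L
  oracle <- function(s, e) {
    if (s >= M - tol) return("tRF-1")
    if (s <= tol && e >= w_lo && e < w_hi) return("5p-half")
    if (s <= tol && e < w_lo) return("tRF-5")
    if (e >= M - tol && s >= w_lo && s < w_hi) return("3p-half")
    if (e >= M - tol && s >= w_hi) return("tRF-3")
    if (s > tol && e < M - tol) return("i-tRF")
    "unclassified"
  }
  grid <- do.call(rbind, lapply(12:50, function(L) {
    s <- 0:(ext_len - L)
    cbind(s, s + L)
  }))
  got <- classify_fragment(grid[, 1], grid[, 2], ref)
  want <- mapply(oracle, grid[, 1], grid[, 2])
  expect_identical(got, unname(want))
  expect_setequal(unique(got),
                  c("tRF-5", "5p-half", "tRF-3", "3p-half", "i-tRF", "tRF-1",
                    "unclassified"))
})

test_that("classifier labels reproduce the simulation truth", {
  run <- pipeline_fixture()
  for (sid in names(run$hits)) {
    h <- run$hits[[sid]]
    truth <- run$sim$truth
    tr <- truth[match(h$read_id, truth$read_id), ]
    is_ts <- !(tr$class %in% c("miRNA", "rRNA"))
    expect_gte(mean(h$class_label[is_ts] == tr$class[is_ts]), 0.99)
  }
})

test_that("license plates have the documented shape and invert exactly", {
  seq39 <- "TGGTGTCCTTGGAAAAAGGTTTTCATCTCCGGTTTACAA"
  plate <- encode_license_plate(seq39)
  expect_match(plate, "^tRF-39-")
  code <- sub("^tRF-39-", "", plate)
  expect_equal(nchar(code), 16L)  # 7 x 5-mers -> 14 chars, final 4-mer -> 2
  expect_false(grepl("[ACGT]", code))  # code alphabet excludes the bases
  expect_identical(decode_license_plate(plate), seq39)
  # frozen regression value: guards accidental lookup-table changes
  expect_identical(plate, "tRF-39-7R49YBDO9Y5ZZ9BU")
})

test_that("encode/decode round-trips and is injective over random sequences", {
  set.seed(42)
  lens <- sample(10:60, 1000, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), character(1))
  plates <- vapply(seqs, encode_license_plate, character(1), USE.NAMES = FALSE)
  expect_identical(vapply(plates, decode_license_plate, character(1),
                          USE.NAMES = FALSE), seqs)
  expect_equal(anyDuplicated(plates[!duplicated(seqs)]), 0L)
})

test_that("invalid plate inputs are rejected", {
  expect_error(encode_license_plate("ACGTACGTN"), "characters|10-60")
  expect_error(encode_license_plate(strrep("A", 9)), "10-60")
  expect_error(encode_license_plate(strrep("A", 61)), "10-60")
  expect_error(decode_license_plate("tRF-39-ZZ"), "inconsistent")
  expect_error(decode_license_plate("tRF39ZZ"), "malformed")
  # 'A' can never occur in a code
  expect_error(decode_license_plate("tRF-10-ABCD"), "malformed|token")
})

test_that("collapse_and_count pools identical fragments and finds all parents", {
  refs <- toy_ref_set()
  ref <- refs[[1]]
  fragA <- c(40L, 79L); fragB <- c(0L, 20L)
  hits <- data.frame(
    read_id = sprintf("r%d", 1:7),
    category = "tRNA",
    ref_id = ref$trna_id,
    start = c(rep(fragA[1], 5), rep(fragB[1], 2)),
    end = c(rep(fragA[2], 5), rep(fragB[2], 2)))
  hits <- classify_hits(hits, refs)
  rec <- collapse_and_count(hits, refs, "s1")
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$count, c(5L, 2L))
  expect_equal(rec$sample_id, rep("s1", 2))
  expect_equal(nchar(rec$tsrna_seq), rec$end - rec$start)
  # a sequence present verbatim in two references lists both parents
  refs2 <- c(refs[1], list(twin = refs[[1]]))
  refs2$twin$trna_id <- "tRNA-Thr-TGT-twin"
  names(refs2) <- vapply(refs2, `[[`, character(1), "trna_id")
  rec2 <- collapse_and_count(hits, refs2, "s1")
  expect_true(all(lengths(rec2$parent_ids) == 2L))
  # empty input
  empty <- collapse_and_count(hits[0, ], refs, "s1")
  expect_equal(nrow(empty), 0L)
})
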