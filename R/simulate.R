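# Synthetic small RNA-seq experiments.
#
# The generator emulates the sequencing side of an adipogenic
# differentiation time course: four timepoints (days 0/7/14/21) with
# replicate libraries, reads drawn from the six tRF classes with lengths
# concentrated in the 17-23 and 30-36 nt modes, adapter read-through,
# miRNA/rRNA contamination, and optionally a set of planted fragments that
# are absent at day 0 and peak at day 7. Every non-contaminant read is an
# exact substring of an extended reference, so downstream stages can be
# validated against the emitted truth table.

#' Simulation profile for synthetic small RNA-seq
#'
#' @param n_reads_per_sample Reads per library (default 2000).
#' @param class_mixture Named fractions over the six tRF classes among
#'   tRNA-derived reads; must sum to <= 1 (renormalised at use).
#' @param length_modes List of two integer intervals; fragment lengths are
#'   drawn inside these where the class geometry allows (defaults
#'   `c(17, 23)` and `c(30, 36)`).
#' @param contaminant_fractions Named fractions `c(miRNA = , rRNA = )` of
#'   reads drawn from the contaminant references (defaults 0.15 and 0.10).
#' @param adapter 3' adapter appended to every read (default the Illumina
#'   small-RNA adapter `TGGAATTCTCGGGTGCCAAGG`).
#' @param replicates Libraries per timepoint (default 3).
#' @param days Timepoints (default 0, 7, 14, 21).
#' @param planted_de Optional list of planted differential fragments; see
#'   [plant_absent_then_peak()].
#' @param tsrna_share_by_day Optional named vector giving the tsRNA share of
#'   each day's library (overrides the flat contaminant fractions), e.g.
#'   `c("0" = 0.5, "7" = 0.8, ...)` to emulate a rising tsRNA fraction.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return List of class `simulation_profile`.
#' @export
simulation_profile <- function(n_reads_per_sample = 2000L,
                               class_mixture = c("tRF-5" = 0.25, "tRF-3" = 0.20,
                                                 "i-tRF" = 0.20, "5p-half" = 0.15,
                                                 "3p-half" = 0.10, "tRF-1" = 0.10),
                               length_modes = list(c(17L, 23L), c(30L, 36L)),
                               contaminant_fractions = c(miRNA = 0.15, rRNA = 0.10),
                               adapter = "TGGAATTCTCGGGTGCCAAGG",
                               replicates = 3L,
                               days = STUDY_DAYS,
                               planted_de = NULL,
                               tsrna_share_by_day = NULL,
                               seed = 1L) {
  stopifnot(n_reads_per_sample >= 1L, replicates >= 1L)
  if (any(class_mixture < 0 | class_mixture > 1) || sum(class_mixture) > 1 + 1e-9)
    stop("class_mixture fractions must be in [0,1] and sum to <= 1", call. = FALSE)
  if (!all(names(class_mixture) %in% setdiff(TRF_CLASSES, "unclassified")))
    stop("unknown class in class_mixture", call. = FALSE)
  if (any(contaminant_fractions < 0) || sum(contaminant_fractions) >= 1)
    stop("contaminant fractions must be in [0,1) and leave room for tsRNA reads",
         call. = FALSE)
  structure(list(n_reads_per_sample = as.integer(n_reads_per_sample),
                 class_mixture = class_mixture, length_modes = length_modes,
                 contaminant_fractions = contaminant_fractions,
                 adapter = as_dna(adapter), replicates = as.integer(replicates),
                 days = as.integer(days), planted_de = planted_de,
                 tsrna_share_by_day = tsrna_share_by_day,
                 seed = as.integer(seed)),
            class = "simulation_profile")
}

#' Random miRNA / rRNA contaminant references
#'
#' @param seed Integer seed.
#' @param n_mirna,n_rrna Number of reference entries.
#' @param rrna_len Length of each rRNA entry.
#' @return List with named character vectors `miRNA` and `rRNA`.
#' @export
make_contaminant_refs <- function(seed, n_mirna = 8L, n_rrna = 3L,
                                  rrna_len = 150L) {
  with_seed(seed, {
    mi <- stats::setNames(
      vapply(seq_len(n_mirna),
             function(i) random_dna(sample(21:22, 1L)), character(1)),
      sprintf("mir-%03d", seq_len(n_mirna)))
    rr <- stats::setNames(random_dna(rrna_len, n_rrna),
                          sprintf("rrna-%d", seq_len(n_rrna)))
    list(miRNA = mi, rRNA = rr)
  })
}

# Feasible fragment geometry per class on one reference, honouring the
# classifier's default tolerances. Returns NULL if the class cannot be
# realised on this reference, otherwise a function(len) -> start and the
# feasible length range.
class_geometry <- function(ref, min_len = 12L, max_len = 50L,
                           end_tol = 1L, loop_tol = 3L) {
  M <- ref$trailer_start
  ext_len <- nchar(ref$extended_seq)
  w_lo <- ref$landmarks$anticodon_loop[1] - loop_tol
  w_hi <- ref$landmarks$anticodon_loop[2] + loop_tol
  g <- list(
    "tRF-5"   = list(lens = seq2(min_len, min(w_lo - 1L, max_len)),
                     start = function(len) 0L),
    "5p-half" = list(lens = seq2(max(w_lo, min_len), min(w_hi - 1L, max_len)),
                     start = function(len) 0L),
    "3p-half" = list(lens = seq2(max(M - w_hi + 1L, min_len), min(M - w_lo, max_len)),
                     start = function(len) M - len),
    "tRF-3"   = list(lens = seq2(min_len, min(M - w_hi, max_len)),
                     start = function(len) M - len),
    "i-tRF"   = list(lens = seq2(min_len, min(M - 4L, max_len)),
                     start = function(len) {
                       pool <- seq2(2L, M - end_tol - 1L - len)
                       if (length(pool) == 1L) pool else sample(pool, 1L)
                     }),
    "tRF-1"   = list(lens = seq2(min_len, min(ext_len - M, max_len)),
                     start = function(len) M)
  )
  g[vapply(g, function(e) length(e$lens) > 0L, logical(1))]
}

# seq() that returns integer(0) when from > to
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

# draw a fragment length: prefer the profile's length modes where feasible
draw_len <- function(lens, modes) {
  inmode <- lens[vapply(lens, function(l)
    any(vapply(modes, function(m) l >= m[1] && l <= m[2], logical(1))),
    logical(1))]
  pool <- if (length(inmode)) inmode else lens
  if (length(pool) == 1L) pool else sample(pool, 1L)
}

#' Plant fragments that are absent at day 0 and peak at day 7
#'
#' Builds `n` planted differential fragments (3' halves by default) on the
#' given references, with per-day abundance multipliers 0 (day 0), 1
#' (day 7), 0.5 (day 14), 0.25 (day 21) on a base per-read fraction.
#'
#' @param refs Named list of `mature_reference` objects.
#' @param n Number of planted fragments (default 6).
#' @param base_fraction Fraction of a library the fragment reaches at its
#'   day-7 peak (default 0.005).
#' @param seed Integer seed used to choose distinct fragment geometries.
#' @return List suitable for `simulation_profile(planted_de = )`.
#' @export
plant_absent_then_peak <- function(refs, n = 6L, base_fraction = 0.005,
                                   seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ref <- refs[[(i - 1L) %% length(refs) + 1L]]
      geom <- class_geometry(ref)[["3p-half"]]
      len <- if (length(geom$lens) == 1L) geom$lens else sample(geom$lens, 1L)
      st <- geom$start(len)
      list(parent = ref$trna_id, start = st, end = st + len,
           base_fraction = base_fraction,
           multipliers = c("0" = 0, "7" = 1, "14" = 0.5, "21" = 0.25))
    })
  })
}

#' Simulate a small RNA-seq time course
#'
#' Draws reads per library: contaminant reads from the miRNA/rRNA
#' references, tRNA-derived reads by sampling a class from the profile's
#' mixture and then a cut-position pair consistent with that class's
#' coordinate rule on a randomly chosen reference, plus any planted
#' differential fragments. The 3' adapter is appended to every read; base
#' qualities are constant `I`. A truth table records every read's origin.
#'
#' @param refs Named list of `mature_reference` objects.
#' @param profile A [simulation_profile()].
#' @param contaminants Optional list from [make_contaminant_refs()];
#'   generated from the profile seed when `NULL`.
#' @param out_dir Optional directory; when given, one FASTQ per sample,
#'   `truth.tsv`, and the contaminant FASTAs are written there.
#' @return List with `reads` (named list of per-sample data frames:
#'   `read_id`, `seq`, `qual`), `truth` (data frame: `read_id`, `parent_id`,
#'   `class`, `start`, `end`, `sample_id`), `sample_meta`, `contaminants`,
#'   and `paths` when `out_dir` is given.
#' @export
simulate_reads <- function(refs, profile, contaminants = NULL, out_dir = NULL) {
  stopifnot(inherits(profile, "simulation_profile"), length(refs) > 0L)
  if (inherits(refs, "mature_reference")) refs <- list(refs)
  if (is.null(names(refs)))
    names(refs) <- vapply(refs, `[[`, character(1), "trna_id")

  geoms <- lapply(refs, class_geometry)
  mix <- profile$class_mixture[profile$class_mixture > 0]
  for (cl in names(mix)) {
    if (!any(vapply(geoms, function(g) cl %in% names(g), logical(1))))
      stop(sprintf("class %s is not realizable on any reference", cl),
           call. = FALSE)
  }

  out <- with_seed(profile$seed, {
    contam <- contaminants %||% make_contaminant_refs(sample.int(1e6, 1L))
    n <- profile$n_reads_per_sample
    cf <- profile$contaminant_fractions
    reads <- list(); truth <- list()
    sample_meta <- expand.grid(replicate = seq_len(profile$replicates),
                               day = profile$days)[, c("day", "replicate")]
    sample_meta$sample_id <- sprintf("day%d_rep%d", sample_meta$day,
                                     sample_meta$replicate)
    for (si in seq_len(nrow(sample_meta))) {
      day <- sample_meta$day[si]
      sid <- sample_meta$sample_id[si]
      if (!is.null(profile$tsrna_share_by_day)) {
        share <- profile$tsrna_share_by_day[[as.character(day)]]
        n_ts <- round(n * share)
        rest <- n - n_ts
        cw <- if (sum(cf) > 0) cf / sum(cf) else c(miRNA = 0.5, rRNA = 0.5)
        n_mi <- round(rest * cw[["miRNA"]]); n_rr <- rest - n_mi
      } else {
        n_mi <- round(n * cf[["miRNA"]]); n_rr <- round(n * cf[["rRNA"]])
        n_ts <- n - n_mi - n_rr
      }
      n_cls <- if (n_ts > 0)
        stats::setNames(as.integer(stats::rmultinom(1, n_ts, mix / sum(mix))),
                        names(mix))
      else stats::setNames(integer(length(mix)), names(mix))

      seqs <- character(0); t_parent <- character(0); t_class <- character(0)
      t_start <- integer(0); t_end <- integer(0)
      emit <- function(body, parent, cls, st, en) {
        seqs <<- c(seqs, paste0(body, profile$adapter))
        t_parent <<- c(t_parent, parent); t_class <<- c(t_class, cls)
        t_start <<- c(t_start, st); t_end <<- c(t_end, en)
      }
      # contaminants
      for (k in seq2(1L, n_mi)) {
        ri <- sample.int(length(contam$miRNA), 1L)
        emit(contam$miRNA[[ri]], names(contam$miRNA)[ri], "miRNA",
             0L, nchar(contam$miRNA[[ri]]))
      }
      for (k in seq2(1L, n_rr)) {
        ri <- sample.int(length(contam$rRNA), 1L)
        rl <- nchar(contam$rRNA[[ri]])
        len <- draw_len(seq2(12L, min(50L, rl)), profile$length_modes)
        st <- sample.int(rl - len + 1L, 1L) - 1L
        emit(substr(contam$rRNA[[ri]], st + 1L, st + len),
             names(contam$rRNA)[ri], "rRNA", st, st + len)
      }
      # tRNA-derived reads
      for (cl in names(n_cls)) {
        ok_refs <- which(vapply(geoms, function(g) cl %in% names(g), logical(1)))
        for (k in seq2(1L, n_cls[[cl]])) {
          ri <- if (length(ok_refs) == 1L) ok_refs else sample(ok_refs, 1L)
          geom <- geoms[[ri]][[cl]]
          len <- draw_len(geom$lens, profile$length_modes)
          st <- geom$start(len)
          emit(substr(refs[[ri]]$extended_seq, st + 1L, st + len),
               names(refs)[ri], cl, st, st + len)
        }
      }
      # planted differential fragments
      for (pd in profile$planted_de %||% list()) {
        mult <- if (as.character(day) %in% names(pd$multipliers))
          pd$multipliers[[as.character(day)]] else 0
        extra <- round(n * pd$base_fraction * mult)
        ref <- refs[[pd$parent]]
        cls <- classify_fragment(pd$start, pd$end, ref)
        for (k in seq2(1L, extra))
          emit(substr(ref$extended_seq, pd$start + 1L, pd$end),
               pd$parent, cls, pd$start, pd$end)
      }
      ids <- sprintf("%s_r%06d", sid, seq_along(seqs))
      reads[[sid]] <- data.frame(read_id = ids, seq = seqs,
                                 qual = strrep("I", nchar(seqs)),
                                 stringsAsFactors = FALSE)
      truth[[sid]] <- data.frame(read_id = ids, parent_id = t_parent,
                                 class = t_class, start = t_start, end = t_end,
                                 sample_id = sid, stringsAsFactors = FALSE)
    }
    list(reads = reads, truth = do.call(rbind, c(truth, make.row.names = FALSE)),
         sample_meta = sample_meta, contaminants = contam)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fastq = character(0))
    for (sid in names(out$reads)) {
      p <- file.path(out_dir, paste0(sid, ".fastq"))
      write_fastq(out$reads[[sid]], p)
      paths$fastq[sid] <- p
    }
    paths$truth <- file.path(out_dir, "truth.tsv")
    utils::write.table(out$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (ct in names(out$contaminants)) {
      p <- file.path(out_dir, paste0(tolower(ct), ".fasta"))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(out$contaminants[[ct]]), p)
      paths[[ct]] <- p
    }
    out$paths <- paths
  }
  out
}

#' Simulate a count matrix with planted differential expression
#'
#' Counts are negative binomial with the given mean and dispersion
#' (`var = mu + dispersion * mu^2`; `dispersion = 0` gives Poisson).
#' Exactly `n_de` rows carry a true fold change of `effect` between the
#' day-0 and day-7 groups (`mode = "shift"`: means `base_mean` vs
#' `base_mean * effect`; `mode = "absent-then-peak"`: day-0 mean 0, day-7
#' mean `base_mean * effect`); the remaining rows have identical means.
#'
#' @param n_tsrna Number of fragments (rows).
#' @param n_de Number of planted differential rows (`<= n_tsrna`).
#' @param effect True fold change of planted rows (>= 1; `effect = 1`
#'   plants nothing and all rows are labelled null).
#' @param base_mean Mean count of a null row (> 0).
#' @param replicates Libraries per group (positive integer).
#' @param seed Integer seed; fixed seed gives an identical matrix.
#' @param dispersion NB dispersion (default 0.1).
#' @param mode `"shift"` or `"absent-then-peak"`.
#' @return A `trf_counts` object (days 0 and 7) with an extra `truth`
#'   element: data frame `plate_id`, `is_de`, `true_fc`.
#' @export
simulate_count_experiment <- function(n_tsrna, n_de, effect, base_mean,
                                      replicates, seed, dispersion = 0.1,
                                      mode = c("shift", "absent-then-peak")) {
  mode <- match.arg(mode)
  if (replicates != as.integer(replicates) || replicates < 1L)
    stop("replicates must be a positive integer", call. = FALSE)
  if (base_mean <= 0) stop("base_mean must be positive", call. = FALSE)
  if (n_de > n_tsrna) stop("n_de must be <= n_tsrna", call. = FALSE)
  if (effect < 1) stop("effect must be >= 1", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  replicates <- as.integer(replicates)
  if (effect == 1) n_de <- 0L

  samples <- c(sprintf("day0_rep%d", seq_len(replicates)),
               sprintf("day7_rep%d", seq_len(replicates)))
  is_b <- grepl("^day7", samples)
  plates <- sprintf("ts%04d", seq_len(n_tsrna))

  out <- with_seed(seed, {
    de_rows <- if (n_de > 0) sort(sample.int(n_tsrna, n_de)) else integer(0)
    mu <- matrix(base_mean, n_tsrna, length(samples),
                 dimnames = list(plates, samples))
    if (n_de > 0) {
      mu[de_rows, is_b] <- base_mean * effect
      if (mode == "absent-then-peak") mu[de_rows, !is_b] <- 0
    }
    counts <- if (dispersion == 0)
      matrix(stats::rpois(length(mu), mu), nrow = n_tsrna, dimnames = dimnames(mu))
    else
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow = n_tsrna, dimnames = dimnames(mu))
    list(counts = counts, de_rows = de_rows)
  })
  x <- trf_counts(out$counts)
  x$truth <- data.frame(plate_id = plates,
                        is_de = seq_len(n_tsrna) %in% out$de_rows,
                        true_fc = ifelse(seq_len(n_tsrna) %in% out$de_rows,
                                         effect, 1))
  x
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ path.
#' @return Data frame with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a simulation profile from a YAML config file
#'
#' Scalar fields map directly to [simulation_profile()] arguments;
#' `length_modes` is a list of two `[lo, hi]` pairs, `class_mixture` and
#' `contaminant_fractions` are named maps, and `planted_de` is a list of
#' entries with `parent`, `start`, `end`, `base_fraction` and a
#' `multipliers` map keyed by day.
#'
#' @param path Path to a YAML file.
#' @return A `simulation_profile`.
#' @export
read_simulation_profile <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(simulation_profile))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown profile fields: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!is.null(cfg$class_mixture)) cfg$class_mixture <- unlist(cfg$class_mixture)
  if (!is.null(cfg$contaminant_fractions))
    cfg$contaminant_fractions <- unlist(cfg$contaminant_fractions)
  if (!is.null(cfg$tsrna_share_by_day))
    cfg$tsrna_share_by_day <- unlist(cfg$tsrna_share_by_day)
  if (!is.null(cfg$length_modes))
    cfg$length_modes <- lapply(cfg$length_modes, as.integer)
  if (!is.null(cfg$planted_de))
    cfg$planted_de <- lapply(cfg$planted_de, function(p) {
      p$multipliers <- unlist(p$multipliers)
      p
    })
  do.call(simulation_profile, cfg)
}
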