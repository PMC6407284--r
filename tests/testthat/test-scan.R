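# a 78-mer with C every 13 nt starting at position 13: qualifies exactly,
# and no window overlapping it from the left does (leading gap > 13)
tight_rut <- function() {
  w <- strsplit(strrep("A", 78), "")[[1]]
  w[seq(13, 78, by = 13)] <- "C"
  paste(w, collapse = "")
}

test_that("seed scan finds the first qualifying window at its exact offset", {
  expect_identical(rut_seed_scan(strrep("A", 500)), NA_integer_)
  expect_identical(rut_seed_scan(strrep("A", 50)), NA_integer_)
  s <- paste0(strrep("A", 200), tight_rut(), strrep("A", 200))
  expect_identical(rut_seed_scan(s), 201L)
  expect_identical(rut_seed_scan(s, from = 202L), 202L)  # trailing gap still 13
  # beyond the planted element nothing qualifies
  expect_identical(rut_seed_scan(s, from = 214L), NA_integer_)
})

test_that("refinement picks the maximal-ratio window, earliest on ties", {
  s <- paste0(strrep("A", 200), tight_rut(), strrep("A", 200))
  rut <- refine_rut(s, 201L)
  # windows 201..213 all qualify with ratio Inf (no G): tie broken earliest
  expect_identical(rut$start, 201L)
  expect_identical(rut$end, 278L)
  expect_identical(rut$cg_ratio, Inf)
  expect_error(refine_rut(strrep("A", 500), 10L), "does not satisfy")
})

test_that("refinement agrees with brute-force block enumeration", {
  set.seed(77)
  for (rep in 1:15) {
    s <- random_seq(700, sample(c(40, 50, 60), 1))
    qual <- oracle_qualifying_windows(s)
    from <- 1L
    repeat {
      seed <- rut_seed_scan(s, from)
      if (is.na(seed)) break
      # the seed is the first brute-force qualifying window at or after `from`
      expect_identical(seed, qual[qual >= from][1L])
      rut <- refine_rut(s, seed)
      block <- qual[qual >= seed & qual <= seed + 50L]
      ratios <- vapply(block, function(i) {
        oracle_cg_ratio(substr(s, i, i + 77L))
      }, numeric(1L))
      expect_identical(rut$start, block[which.max(ratios)])
      from <- seed + 1L
    }
  }
})

test_that("hairpin detection matches the constructed example", {
  region <- paste0("AA", "GCGCG", "AAAA", "CGCGC", "AA")
  hp <- find_hairpins(region, genome_gc = 40)
  # the planted stem-5 / loop-4 inverted repeat is reported at its offset
  # (an inner stem-4 / loop-6 reading of the same repeat is also maximal
  # for its own loop position and is legitimately reported alongside)
  expect_true(any(hp$start == 3L & hp$end == 16L & hp$stem_len == 5L &
                    hp$loop_len == 4L & hp$stem_gc_percent == 100))
  expect_true(all(hp$start == 3L & hp$end == 16L))
  expect_equal(hp, oracle_hairpins(region, 40))
  expect_equal(nrow(find_hairpins(strrep("A", 150), 40)), 0L)
  # the same stem below the genome GC threshold is rejected
  low <- paste0("AA", "ATATA", "CCCC", "TATAT", "AA")
  expect_equal(nrow(find_hairpins(low, genome_gc = 40)), 0L)
  expect_gt(nrow(find_hairpins(low, genome_gc = 0)), 0L)
  # N never pairs
  expect_equal(nrow(find_hairpins("AANNNNAAAANNNNAA", 0)), 0L)
})

test_that("hairpin detection equals the exhaustive oracle on random regions", {
  set.seed(303)
  for (i in 1:25) {
    gc <- sample(c(30, 50, 70), 1)
    region <- random_seq(150, gc)
    expect_equal(find_hairpins(region, gc), oracle_hairpins(region, gc))
  }
})

test_that("consensus element search matches the pattern definition", {
  expect_equal(find_consensus_elements("GGAAAAAAAATG")$start, 1L)
  expect_equal(nrow(find_consensus_elements("GAAAAAAAAATG")), 0L)
  expect_equal(nrow(find_consensus_elements("GGAAAAAAAAAG")), 0L)  # pos 11 not C/T
  expect_equal(nrow(find_consensus_elements("GGAAAANAAATG")), 0L)  # N never matches
  # overlapping matches are all reported
  both <- find_consensus_elements("GGAAAAAAAATGGAAAAAAAATG")
  expect_equal(both$start, c(1L, 12L))
  set.seed(404)
  for (i in 1:30) {
    region <- random_seq(150, sample(c(40, 60), 1))
    expect_identical(find_consensus_elements(region)$start,
                     oracle_consensus(region))
  }
})

test_that("pause-site selection follows the decision rule", {
  # single hairpin, no consensus element anywhere
  region <- paste0("AA", "GCGCG", "AAAA", "CGCGC", "AA")
  ps <- select_pause_site(region, 40)
  expect_equal(ps$type, "hairpin")
  expect_false(ps$proximal)
  # consensus element overlapping the hairpin: proximal, +3 applies
  hp_cons <- paste0("AAA", make_hairpin(7, 4, include_consensus = TRUE), "AAA")
  ps2 <- select_pause_site(hp_cons, 40)
  expect_equal(ps2$type, "hairpin+consensus")
  expect_true(ps2$proximal)
  # consensus-only region
  ps3 <- select_pause_site(paste0("AAAA", "GGAAAAAAAATG", "AAAA"), 40)
  expect_equal(ps3$type, "consensus")
  expect_false(ps3$proximal)
  expect_equal(ps3$start, 5L)
  # neither: candidate discarded
  expect_null(select_pause_site(strrep("A", 150), 40))
})

test_that("among several hairpins the score-maximising one is selected", {
  set.seed(11)
  weak <- paste0("GCGC", strrep("A", 7), "GCGC")       # stem 4, loop 7: no half points
  strong <- make_hairpin(7, 4, include_consensus = TRUE)
  region <- paste0("AA", weak, strrep("A", 20), strong, "AA")
  ps <- select_pause_site(region, 40)
  expect_true(ps$proximal)
  # the weak stem-4/loop-7 hairpin (bonus 2) loses to a hairpin carrying
  # the proximal consensus element (+3)
  expect_gt(ps$hairpin$start, 2L + nchar(weak))
  # scoring module confirms the argmax
  rut <- list(cg_ratio = 1.1)
  s_weak <- score_prediction(rut, list(hairpin = data.frame(
    stem_len = 4, loop_len = 7, stem_gc_percent = 100), proximal = FALSE), 40)
  s_strong <- score_prediction(rut, list(
    hairpin = ps$hairpin, consensus = ps$consensus, proximal = TRUE), 40)
  expect_gt(s_strong$total, s_weak$total)
})

test_that("scan_record honours the RUT invariants on every prediction", {
  set.seed(555)
  for (rep in 1:10) {
    s <- random_seq(2000, sample(c(40, 55), 1))
    rec <- genome_record(paste0("r", rep), s)
    for (strand in c("+", "-")) {
      pred <- scan_record(rec, strand)
      if (!nrow(pred)) next
      expect_true(all(pred$rut_end - pred$rut_start + 1L == 78L))
      for (i in seq_len(nrow(pred))) {
        w <- substr(s, pred$rut_start[i], pred$rut_end[i])
        if (strand == "-") w <- revcomp(w)
        expect_gt(compute_cg_ratio(w), 1)
        expect_lte(max_c_gap(w), 13)
        # pause feature starts within 150 nt downstream on the scanned strand
        if (strand == "+") {
          expect_gte(pred$pause_start[i], pred$rut_end[i] + 1L)
          expect_lte(pred$pause_start[i], pred$rut_end[i] + 150L)
        } else {
          expect_lte(pred$pause_end[i], pred$rut_start[i] - 1L)
          expect_gte(pred$pause_end[i], pred$rut_start[i] - 150L)
        }
        expect_gte(pred$score[i], 6)
        expect_lte(pred$score[i], 15)
      }
    }
  }
})

test_that("short sequences and planted genomes behave as specified", {
  expect_equal(nrow(scan_record(genome_record("s", strrep("ACGT", 15)), "+")), 0L)
  g <- generate_genome(fixture_spec(seed = 21))
  pred <- scan_genome(g$record)
  expect_true(all(planted_hits(pred, g$truth)))
})

test_that("minus-strand predictions mirror the reverse complement scan", {
  set.seed(909)
  for (rep in 1:8) {
    s <- random_seq(800, sample(c(40, 50), 1))
    n <- nchar(s)
    pm <- as.data.frame(scan_record(genome_record("s", s), "-"))
    pp <- as.data.frame(scan_record(genome_record("s", revcomp(s)), "+"))
    expect_equal(nrow(pm), nrow(pp))
    if (!nrow(pm)) next
    mir <- pp
    for (cols in list(c("rut_start", "rut_end"), c("pause_start", "pause_end"),
                      c("consensus_start", "consensus_end"))) {
      mir[[cols[1L]]] <- n - pp[[cols[2L]]] + 1L
      mir[[cols[2L]]] <- n - pp[[cols[1L]]] + 1L
    }
    mir <- mir[order(mir$rut_start), ]
    rownames(mir) <- NULL
    cols <- c("rut_start", "rut_end", "cg_ratio", "max_c_gap", "pause_type",
              "pause_start", "pause_end", "stem_len", "loop_len",
              "stem_gc_percent", "consensus_start", "consensus_end", "score")
    expect_equal(pm[, cols], mir[, cols])
  }
})
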